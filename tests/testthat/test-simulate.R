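test_that("the same seed reproduces byte-identical VCF output", {
  cfg <- sim_config(seed = 13, n_sv = 200, n_snv = 400,
                    genotype_error_rate = 0.02, de_novo_rate = 1)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  sim1 <- simulate_trio_cohort(cfg)
  sim2 <- simulate_trio_cohort(cfg)
  write_variant_vcf(sim1$sv, p1, cfg$contigs)
  write_variant_vcf(sim2$sv, p2, cfg$contigs)
  expect_identical(readLines(p1), readLines(p2))
  ## a different seed gives different data
  sim3 <- simulate_trio_cohort(sim_config(seed = 14, n_sv = 200, n_snv = 400))
  expect_false(identical(sim1$sv$sites$start, sim3$sv$sites$start))
})

test_that("error-free, de-novo-free cohorts have zero MIE everywhere", {
  cfg <- sim_config(seed = 3, n_sv = 400, n_snv = 800, de_novo_rate = 0)
  sim <- simulate_trio_cohort(cfg)
  for (i in seq_len(nrow(sim$pedigree))) {
    trio <- as.list(sim$pedigree[i, ])
    expect_equal(mie_summary(sim$sv, trio)$mie_rate, 0)
    expect_equal(mie_summary(sim$snv, trio)$mie_rate, 0)
  }
})

test_that("truth genotypes are Mendelian-consistent at non-de-novo sites", {
  cfg <- sim_config(seed = 8, n_sv = 300, n_snv = 300, de_novo_rate = 2,
                    genotype_error_rate = 0.05)
  sim <- simulate_trio_cohort(cfg)
  led <- sim$ledger
  founder <- led$sv_sites$origin == "founder"
  gt_true <- matrix(c("0/0", "0/1", "1/1")[led$sv_code_true + 1L],
                    nrow(led$sv_code_true),
                    dimnames = dimnames(led$sv_code_true))
  for (i in seq_len(nrow(sim$pedigree))) {
    trio <- as.list(sim$pedigree[i, ])
    status <- mendelian_consistent(gt_true[founder, trio$proband],
                                   gt_true[founder, trio$father],
                                   gt_true[founder, trio$mother])
    expect_true(all(status == "consistent"))
  }
  ## de novo sites are het in exactly the assigned child, ref elsewhere
  dn <- which(led$sv_sites$origin == "de_novo")
  for (i in dn) {
    child <- led$sv_sites$denovo_child[i]
    expect_equal(unname(led$sv_code_true[i, child]), 1L)
    expect_true(all(led$sv_code_true[i, setdiff(led$samples, child)] == 0L))
  }
})

test_that("SV type mix and Ti/Tv track their configured targets", {
  cfg <- sim_config(seed = 9, n_sv = 10000, n_snv = 100000)
  sites <- suppressWarnings(triosv:::place_sv_sites(cfg$n_sv, cfg))
  ins_frac <- mean(sites$svtype == "INS")
  se <- sqrt(0.63 * 0.37 / nrow(sites))
  expect_lt(abs(ins_frac - 0.63), 3 * se)

  snv <- simulate_snvs(cfg)
  x <- snv_set(snv$sites,
               matrix("0/1", nrow(snv$sites), 15,
                      dimnames = list(NULL, colnames(snv$code_true))))
  tt <- ti_tv_ratio(x)
  p <- 2.1 / 3.1
  n <- n_sites(x)
  se_p <- 3 * sqrt(p * (1 - p) / n)
  expect_gt(tt, (p - se_p) / (1 - p + se_p))
  expect_lt(tt, (p + se_p) / (1 - p - se_p))
  ## symmetric target gives a ratio near 1
  cfg1 <- sim_config(seed = 9, n_snv = 50000, ti_tv_target = 1)
  snv1 <- simulate_snvs(cfg1)
  x1 <- snv_set(snv1$sites,
                matrix("0/1", nrow(snv1$sites), 15,
                       dimnames = list(NULL, colnames(snv1$code_true))))
  expect_lt(abs(ti_tv_ratio(x1) - 1), 0.05)
})

test_that("SV sizes respect type bounds and DEL/INV footprints never overlap", {
  cfg <- sim_config(seed = 10, n_sv = 3000)
  sites <- triosv:::place_sv_sites(cfg$n_sv, cfg)
  for (t in unique(sites$svtype)) {
    b <- cfg$sv_size_bounds[[t]]
    expect_true(all(sites$svlen[sites$svtype == t] >= b[1]))
    expect_true(all(sites$svlen[sites$svtype == t] <= b[2]))
  }
  fp <- sites[sites$svtype != "INS", ]
  gr <- GenomicRanges::GRanges(fp$chrom,
                               IRanges::IRanges(fp$start + 1L, fp$end))
  expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1))
})

test_that("read-support detection matches the analytic oracle", {
  set.seed(77)
  n <- 10000
  ## heterozygous carrier at 40x with k = 3
  code <- matrix(1L, n, 1, dimnames = list(NULL, "S"))
  rs <- simulate_read_support(code, coverage = 40, k = 3, seed = 41)
  p <- oracle_detection_prob(40, 0.5, 3)
  expect_lt(abs(mean(rs$detected) - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  ## hom-alt with k = 1 at 10x: closed form 1 - exp(-10)
  code2 <- matrix(2L, n, 1, dimnames = list(NULL, "S"))
  rs2 <- simulate_read_support(code2, coverage = 10, k = 1, seed = 42)
  p2 <- 1 - exp(-10)
  expect_lt(abs(mean(rs2$detected) - p2), 3 * sqrt(p2 * (1 - p2) / n) + 1e-9)
  ## saturation at very deep coverage
  rs3 <- simulate_read_support(code[1:2000, , drop = FALSE], 1000, k = 3,
                               seed = 43)
  expect_gte(mean(rs3$detected), 0.999)
  ## read-count identities
  expect_true(all(rs$alt + rs$ref == rs$dp))
  expect_true(all(rs$alt >= 0))
})

test_that("parental dropout keeps alt reads while the call goes hom-ref", {
  cfg <- sim_config(seed = 15, n_sv = 600, n_snv = 100,
                    parental_dropout_rate = 0.05)
  sim <- simulate_trio_cohort(cfg)
  led <- sim$ledger
  drops <- led$sv_errors[led$sv_errors$kind == "dropout", ]
  expect_gt(nrow(drops), 0)
  for (j in seq_len(nrow(drops))) {
    i <- match(drops$id[j], led$sv_sites$id)
    expect_equal(unname(led$sv_code_true[i, drops$sample[j]]), 1L)
    expect_equal(unname(led$sv_code_called[i, drops$sample[j]]), 0L)
  }
  ## emitted records for dropout sites still carry the simulated alt reads
  emitted <- drops[drops$id %in% sim$sv$sites$id, ]
  rows <- match(emitted$id, sim$sv$sites$id)
  alt <- sim$sv$ad_alt[cbind(rows, match(emitted$sample, sim$sv$samples))]
  expect_gt(mean(alt > 0), 0.9)  # Binomial(Poisson(40), 0.5) is rarely 0
})

test_that("GC-biased tracks starve high-GC genes of short-read coverage", {
  cfg <- sim_config(seed = 19, gc_bias_strength = 4)
  genes <- simulate_genes(cfg, n_genes = 150)
  tracks <- simulate_coverage_tracks(cfg, genes)
  cls <- gene_coverage_classify(genes, tracks$srs)
  poor <- cls[cls$status == "poorly_covered", ]
  well <- cls[cls$status == "well_covered", ]
  expect_gt(nrow(poor), 0)
  res <- gc_comparison(poor, well, seed = 5)
  expect_gt(res$mean_poor, res$mean_control)
  ## without bias the exclusive partition is (nearly) empty
  cfg0 <- sim_config(seed = 19, gc_bias_strength = 0)
  tracks0 <- simulate_coverage_tracks(cfg0, genes)
  part0 <- partition_coverage(tracks0$lrs, tracks0$srs)
  expect_lt(regions_total_length(part0$srs_only) +
              regions_total_length(part0$lrs_only),
            1e-4 * part0$genome_length)
  ## determinism of the track stage
  tracks_again <- simulate_coverage_tracks(cfg, genes)
  expect_identical(lapply(tracks$srs$depth, S4Vectors::runValue),
                   lapply(tracks_again$srs$depth, S4Vectors::runValue))
})

test_that("every emitted VCF record maps to exactly one ledger entry", {
  cfg <- sim_config(seed = 23, n_sv = 300, n_snv = 300,
                    genotype_error_rate = 0.01, de_novo_rate = 1)
  sim <- simulate_trio_cohort(cfg)
  led <- sim$ledger
  expect_true(all(sim$sv$sites$id %in% led$sv_sites$id))
  expect_false(any(duplicated(led$sv_sites$id)))
  expect_equal(n_sites(sim$sv), sum(led$sv_emitted))
  key_vcf <- paste(sim$snv$sites$chrom, sim$snv$sites$pos)
  key_led <- paste(led$snv_sites$chrom, led$snv_sites$pos)[led$snv_emitted]
  expect_identical(key_vcf, key_led)
})
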