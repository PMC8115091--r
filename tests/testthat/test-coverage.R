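two_contigs <- c(c1 = 10000L, c2 = 5000L)

flat_track <- function(depth, contigs = two_contigs, label = "t") {
  iv <- data.frame(chrom = names(contigs), start = 0L,
                   end = as.integer(contigs), depth = depth,
                   stringsAsFactors = FALSE)
  coverage_track(iv, contigs, label)
}

random_track <- function(contigs, p_zero = 0.3, step = 500L) {
  ivs <- lapply(names(contigs), function(ctg) {
    start <- seq(0L, contigs[[ctg]] - 1L, by = step)
    depth <- ifelse(runif(length(start)) < p_zero, 0L,
                    rpois(length(start), 20))
    data.frame(chrom = ctg, start = start,
               end = pmin(start + step, contigs[[ctg]]), depth = depth,
               stringsAsFactors = FALSE)
  })
  coverage_track(do.call(rbind, ivs), contigs)
}

test_that("coverage partition separates technology-exclusive regions", {
  lrs <- flat_track(10)
  srs_iv <- data.frame(chrom = c("c1", "c1", "c2"),
                       start = c(0L, 2000L, 0L),
                       end = c(2000L, 10000L, 5000L),
                       depth = c(0L, 8L, 8L))
  srs <- coverage_track(srs_iv, two_contigs, "SRS")
  part <- partition_coverage(lrs, srs)
  expect_equal(regions_total_length(part$lrs_only), 2000)
  expect_equal(regions_total_length(part$srs_only), 0)
  expect_equal(regions_total_length(part$neither), 0)
  expect_equal(regions_total_length(part$both), 13000)
  expect_equal(regions_df(part$lrs_only),
               data.frame(chrom = "c1", start = 0L, end = 2000L))
})

test_that("identical tracks have empty exclusive sets", {
  a <- flat_track(5)
  part <- partition_coverage(a, a)
  expect_equal(regions_total_length(part$lrs_only), 0)
  expect_equal(regions_total_length(part$srs_only), 0)
})

test_that("the partition conserves the genome and is label-symmetric", {
  set.seed(99)
  for (i in 1:15) {
    a <- random_track(two_contigs)
    b <- random_track(two_contigs)
    p <- partition_coverage(a, b)
    s <- partition_summary(p)
    expect_equal(sum(s$total_bp), p$genome_length)
    ## pairwise disjoint
    sets <- list(p$lrs_only, p$srs_only, p$neither, p$both)
    for (u in 1:3) for (v in (u + 1):4)
      expect_equal(regions_total_length(regions_intersect(sets[[u]],
                                                          sets[[v]])), 0)
    ## swapping the tracks swaps the exclusive sets
    q <- partition_coverage(b, a)
    expect_equal(regions_df(q$lrs_only), regions_df(p$srs_only))
    expect_equal(regions_df(q$srs_only), regions_df(p$lrs_only))
    expect_equal(regions_df(q$both), regions_df(p$both))
  }
})

test_that("a contig present in one track only is a named error", {
  a <- flat_track(5, c(c1 = 1000L))
  b <- flat_track(5, c(c2 = 1000L))
  expect_error(partition_coverage(a, b), "c1")
})

test_that("fold-coverage fractions respect difficult regions and chrY", {
  contigs <- c(c1 = 10000L, chrY = 2000L)
  iv <- data.frame(chrom = c("c1", "c1", "chrY"),
                   start = c(0L, 8000L, 0L), end = c(8000L, 10000L, 2000L),
                   depth = c(5L, 0L, 0L))
  tr <- coverage_track(iv, contigs)
  difficult <- region_set("c1", 8000L, 10000L)
  fc <- fold_coverage_summary(tr, difficult, thresholds = c(5, 10))
  expect_equal(fc$fraction_easy[fc$threshold == 5], 1.0)
  expect_lt(fc$fraction_genome[fc$threshold == 5], 1.0)
  expect_equal(fc$fraction_genome[fc$threshold == 5], 8000 / 12000)
  ## fractions are non-increasing in the threshold
  fc2 <- fold_coverage_summary(random_track(two_contigs), NULL,
                               thresholds = c(5, 10, 15, 20))
  expect_true(all(diff(fc2$fraction_genome) <= 0))
  expect_true(all(diff(fc2$fraction_easy) <= 0))
})

test_that("gene classification is inclusive at exactly 10% uncovered", {
  genes <- gene_models(c("A", "B", "C"), "c1",
                       c(0L, 2000L, 4000L), c(1000L, 3000L, 5000L),
                       c(0.5, 0.5, 0.5))
  ## zero depth on [0,100) (10% of A) and [2000,2099) (9.9% of B)
  iv <- data.frame(chrom = "c1",
                   start = c(0L, 100L, 2000L, 2099L),
                   end = c(100L, 2000L, 2099L, 10000L),
                   depth = c(0L, 9L, 0L, 9L))
  tr <- coverage_track(iv, c(c1 = 10000L))
  cls <- gene_coverage_classify(genes, tr)
  expect_equal(cls$status, c("poorly_covered", "well_covered",
                             "well_covered"))
  expect_equal(cls$uncovered_frac, c(0.10, 0.099, 0))
})

test_that("bedGraph round trip preserves a coverage track", {
  tr <- random_track(two_contigs)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_coverage_track(tr, path)
  tr2 <- read_coverage_track(path, two_contigs)
  expect_equal(lapply(tr2$depth, as.integer), lapply(tr$depth, as.integer))
})

test_that("GC comparison reproduces a direct Welch t-test", {
  poor <- data.frame(gene = c("p1", "p2", "p3"),
                     length = c(1000, 2000, 3000),
                     gc_fraction = c(0.55, 0.60, 0.52))
  ctrl <- data.frame(gene = sprintf("w%d", 1:6),
                     length = c(1000, 1100, 2000, 2100, 3000, 3100),
                     gc_fraction = c(0.44, 0.46, 0.45, 0.43, 0.47, 0.42))
  res <- gc_comparison(poor, ctrl, seed = 7)
  expect_equal(res$mean_poor, mean(poor$gc_fraction))
  ref <- t.test(poor$gc_fraction, ctrl$gc_fraction[match(res$matches$control,
                                                         ctrl$gene)],
                var.equal = FALSE)
  expect_equal(res$t_statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  ## all matches fall in the +/-20% length window and are distinct
  len <- ctrl$length[match(res$matches$control, ctrl$gene)]
  expect_true(all(abs(len - poor$length) <= 0.2 * poor$length))
  expect_false(anyDuplicated(res$matches$control) > 0)
  ## identical groups: zero t, unit p
  same <- gc_comparison(poor, transform(poor, gene = paste0(gene, "c")),
                        seed = 1)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("an empty length window is widened with a warning", {
  poor <- data.frame(gene = c("p1", "p2"), length = c(1000, 1100),
                     gc_fraction = c(0.6, 0.58))
  ctrl <- data.frame(gene = c("w1", "w2"), length = c(5000, 6000),
                     gc_fraction = c(0.4, 0.42))
  w <- capture_warnings(res <- gc_comparison(poor, ctrl, seed = 1))
  expect_true(any(grepl("widened", w)))
  expect_setequal(res$matches$control, c("w1", "w2"))
})

test_that("the p-value is roughly uniform under the null", {
  set.seed(123)
  p <- replicate(200, {
    n <- 20
    poor <- data.frame(gene = sprintf("p%d", 1:n),
                       length = runif(n, 1000, 5000),
                       gc_fraction = rnorm(n, 0.45, 0.05))
    ctrl <- data.frame(gene = sprintf("w%d", 1:(3 * n)),
                       length = runif(3 * n, 1000, 5000),
                       gc_fraction = rnorm(3 * n, 0.45, 0.05))
    suppressWarnings(gc_comparison(poor, ctrl, seed = sample.int(1e6, 1))$p_value)
  })
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.001)
})
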