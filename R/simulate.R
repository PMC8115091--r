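#' Simulation configuration for synthetic trio cohorts
#'
#' Defines the statistical structure of a simulated joint-called trio
#' cohort: founder SV/SNV site pools with population carrier
#' frequencies, Mendelian transmission to probands, Poisson-distributed
#' de novo SVs, genotype-error and parental-dropout processes,
#' per-sample read support under a Poisson depth / binomial allele
#' sampling model, Ti/Tv-controlled substitutions, and GC-biased
#' short-read coverage. Defaults emulate a long-read trio study:
#' insertions dominate the SV spectrum (63% INS, 37% DEL, 0.05% INV),
#' sizes decay as a truncated power law with point-mass peaks at 300 bp
#' (Alu) and 6.4 kb (LINE1), the de novo SV rate is 0.2 events per
#' genome per generation, and the SNV Ti/Tv target is 2.1. The genome
#' is scaled to three 10 Mb contigs so that a full cohort simulates in
#' seconds.
#'
#' @param contigs named vector of contig lengths in bp.
#' @param n_trios number of trios (samples are named T1P/T1F/T1M, ...).
#' @param n_sv,n_snv founder site-pool sizes.
#' @param sv_type_weights named weights for DEL/INS/INV (normalized).
#' @param sv_size_bounds named list of `c(min, max)` size bounds per type.
#' @param size_alpha power-law decay exponent of the SV size spectrum.
#' @param peak_weights weights of the 300 bp and 6400 bp size peaks
#'   (remainder goes to the power-law component).
#' @param carrier_prob probability that a founder carries a pool variant.
#' @param hom_fraction probability a carried founder variant is
#'   homozygous (else heterozygous).
#' @param de_novo_rate mean de novo SVs per child genome (Poisson).
#' @param genotype_error_rate per-genotype probability that a called
#'   genotype is replaced by one of the other two diploid genotypes.
#' @param parental_dropout_rate probability that a true heterozygous
#'   parental call is emitted as homozygous reference (read support is
#'   retained).
#' @param coverage mean sequencing depth per sample.
#' @param min_supporting_reads reads supporting the alternative allele
#'   required to detect a variant (`k`).
#' @param het_alt_read_prob per-read probability of sampling the
#'   alternative allele at a heterozygous site (0.5 = no allelic bias).
#' @param ti_tv_target transition/transversion ratio of simulated SNVs.
#' @param func_class_probs named probabilities of SNV functional classes.
#' @param qual_mean,qual_sd SNV quality score distribution (normal,
#'   truncated below at 1), chosen so both sides of a cutoff at 30 are
#'   populated.
#' @param gc_bias_strength exponential GC penalty on short-read depth;
#'   0 disables the bias.
#' @param gc_knee GC fraction above which short-read coverage drops out.
#' @param track_window window size in bp of simulated coverage tracks.
#' @param seed integer seed; one global seed feeds fixed per-stage
#'   substreams.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(contigs = c(ctg1 = 1e7, ctg2 = 1e7, ctg3 = 1e7),
                       n_trios = 5,
                       n_sv = 5000,
                       n_snv = 50000,
                       sv_type_weights = c(DEL = 0.37, INS = 0.63, INV = 0.0005),
                       sv_size_bounds = list(INS = c(50, 5000),
                                             DEL = c(50, 100000),
                                             INV = c(200, 5000)),
                       size_alpha = 1.2,
                       peak_weights = c(alu = 0.12, line = 0.03),
                       carrier_prob = 0.35,
                       hom_fraction = 0.2,
                       de_novo_rate = 0.2,
                       genotype_error_rate = 0,
                       parental_dropout_rate = 0,
                       coverage = 40,
                       min_supporting_reads = 3,
                       het_alt_read_prob = 0.5,
                       ti_tv_target = 2.1,
                       func_class_probs = c(noncoding = 0.90,
                                            synonymous = 0.04,
                                            missense = 0.04,
                                            lof = 0.01, other = 0.01),
                       qual_mean = 50, qual_sd = 20,
                       gc_bias_strength = 4,
                       gc_knee = 0.55,
                       track_window = 1000,
                       seed = 1) {
  stopifnot(all(sv_type_weights >= 0), sum(sv_type_weights) > 0,
            carrier_prob > 0, carrier_prob <= 1,
            hom_fraction >= 0, hom_fraction <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            parental_dropout_rate >= 0, parental_dropout_rate <= 1,
            de_novo_rate >= 0, coverage > 0, min_supporting_reads >= 1,
            ti_tv_target > 0, n_trios >= 1)
  cfg <- as.list(environment())
  cfg$sv_type_weights <- sv_type_weights / sum(sv_type_weights)
  cfg$func_class_probs <- func_class_probs / sum(func_class_probs)
  structure(cfg, class = "sim_config")
}

sim_pedigree <- function(config) {
  i <- seq_len(config$n_trios)
  trio_pedigree(sprintf("T%d", i), sprintf("T%dP", i),
                sprintf("T%dF", i), sprintf("T%dM", i))
}

## fixed per-stage substream seeds derived from the global seed
stage_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, 10)
  names(s) <- c("sv_sites", "sv_geno", "denovo", "snv_sites", "snv_geno",
                "errors", "reads", "tracks", "genes", "titration")
  s
}

## genotype codes: 0 = hom-ref, 1 = het, 2 = hom-alt
code_to_gt <- function(code) c("0/0", "0/1", "1/1")[code + 1L]

## founder genotypes + Mendelian transmission for every site
sample_cohort_genotypes <- function(n, ped, config) {
  samples <- as.character(t(as.matrix(ped[, c("proband", "father", "mother")])))
  code <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(nrow(ped))) {
    for (par in c(ped$father[i], ped$mother[i])) {
      carried <- stats::runif(n) < config$carrier_prob
      hom <- stats::runif(n) < config$hom_fraction
      code[, par] <- ifelse(carried, ifelse(hom, 2L, 1L), 0L)
    }
    ## transmit one allele per parent, uniformly for heterozygotes
    transmit <- function(pcode) {
      ifelse(pcode == 2L, 1L,
             ifelse(pcode == 1L, as.integer(stats::runif(n) < 0.5), 0L))
    }
    code[, ped$proband[i]] <- transmit(code[, ped$father[i]]) +
      transmit(code[, ped$mother[i]])
  }
  code
}

## draw SV sizes: truncated power law plus Alu/LINE1 point-mass peaks
draw_sv_sizes <- function(n, type, config) {
  b <- config$sv_size_bounds[[type]]
  smin <- b[1]; smax <- b[2]
  comp <- sample(c("alu", "line", "pl"), n, replace = TRUE,
                 prob = c(config$peak_weights["alu"],
                          config$peak_weights["line"],
                          1 - sum(config$peak_weights)))
  size <- numeric(n)
  a <- config$size_alpha
  u <- stats::runif(sum(comp == "pl"))
  ## inverse CDF of a Pareto truncated to [smin, smax]
  size[comp == "pl"] <- smin * (1 - u * (1 - (smin / smax)^a))^(-1 / a)
  size[comp == "alu"] <- stats::rnorm(sum(comp == "alu"), 300, 20)
  size[comp == "line"] <- stats::rnorm(sum(comp == "line"), 6400, 300)
  as.integer(pmin(pmax(round(size), smin), smax))
}

## place n SV sites with non-overlapping reference footprints
place_sv_sites <- function(n, config, id_prefix = "sv") {
  contigs <- config$contigs
  types <- sample(names(config$sv_type_weights), n, replace = TRUE,
                  prob = config$sv_type_weights)
  svlen <- integer(n)
  for (t in unique(types))
    svlen[types == t] <- draw_sv_sizes(sum(types == t), t, config)
  placed <- data.frame(chrom = character(), start = integer(),
                       end = integer(), svtype = character(),
                       svlen = integer(), stringsAsFactors = FALSE)
  occupied <- GenomicRanges::GRanges()
  todo <- seq_len(n)
  skipped <- integer()
  for (round in 1:10) {
    if (!length(todo)) break
    m <- length(todo)
    chrom <- sample(names(contigs), m, replace = TRUE,
                    prob = as.numeric(contigs))
    fp <- ifelse(types[todo] == "INS", 1L, svlen[todo])
    start <- as.integer(floor(stats::runif(m) * (contigs[chrom] - fp - 1)))
    prop <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(start + 1L, start + fp))
    ## reject proposals that clash with placed sites or with each other
    selfhit <- GenomicRanges::countOverlaps(prop, prop) > 1
    occhit <- GenomicRanges::countOverlaps(prop, occupied) > 0
    ok <- !selfhit & !occhit
    if (any(ok)) {
      idx <- todo[ok]
      placed <- rbind(placed, data.frame(
        chrom = chrom[ok], start = start[ok],
        end = ifelse(types[idx] == "INS", start[ok], start[ok] + svlen[idx]),
        svtype = types[idx], svlen = svlen[idx], stringsAsFactors = FALSE))
      occupied <- c(occupied, prop[ok])
    }
    todo <- todo[!ok]
    if (round == 10 && length(todo)) skipped <- todo
  }
  if (length(skipped))
    warning(length(skipped), " SV placement(s) skipped after bounded retries")
  placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
  placed$id <- sprintf("%s%05d", id_prefix, seq_len(nrow(placed)))
  placed$filter <- "PASS"
  rownames(placed) <- NULL
  placed
}

#' Simulate SNV sites and cohort genotypes
#'
#' Draws substitution sites uniformly over the configured contigs with
#' the transition probability `ti_tv_target / (1 + ti_tv_target)`,
#' functional classes from `func_class_probs`, truncated-normal quality
#' scores, and founder/transmitted genotypes for the whole cohort. When
#' gene models are supplied, sites falling inside a gene interval are
#' annotated with its symbol.
#'
#' @param config a [sim_config()].
#' @param genes optional [gene_models()] for gene annotation.
#' @param ped pedigree (defaults to the config's standard cohort).
#' @return list with `sites` (snv site data.frame) and `code_true`
#'   (sites x samples matrix of genotype codes 0/1/2).
#' @export
simulate_snvs <- function(config, genes = NULL, ped = sim_pedigree(config)) {
  ss <- stage_seeds(config$seed)
  n <- config$n_snv
  set.seed(ss["snv_sites"])
  chrom <- sample(names(config$contigs), n, replace = TRUE,
                  prob = as.numeric(config$contigs))
  pos <- as.integer(floor(stats::runif(n) * (config$contigs[chrom] - 1)))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  p_ti <- config$ti_tv_target / (1 + config$ti_tv_target)
  is_ti <- stats::runif(n) < p_ti
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  alt <- ifelse(is_ti, transition[ref],
                vapply(ref, function(r) sample(transversions[[r]], 1), ""))
  func_class <- sample(names(config$func_class_probs), n, replace = TRUE,
                       prob = config$func_class_probs)
  qual <- round(pmax(stats::rnorm(n, config$qual_mean, config$qual_sd), 1), 1)
  gene <- rep(NA_character_, n)
  if (!is.null(genes) && nrow(genes)) {
    pgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
    hits <- GenomicRanges::findOverlaps(pgr, genes_gr(genes),
                                        ignore.strand = TRUE,
                                        select = "first")
    gene[!is.na(hits)] <- genes$gene[hits[!is.na(hits)]]
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                      alt = unname(alt), qual = qual,
                      func_class = func_class, gene = gene,
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  sites <- sites[!duplicated(sites[, c("chrom", "pos")]), , drop = FALSE]
  rownames(sites) <- NULL
  set.seed(ss["snv_geno"])
  code <- sample_cohort_genotypes(nrow(sites), ped, config)
  list(sites = sites, code_true = code)
}

#' Simulate read support and detection under a depth model
#'
#' Per sample and site: total depth is Poisson(`coverage`); reads
#' supporting the alternative allele are Binomial(depth, p) with p = 0
#' for homozygous reference, `het_alt_read_prob` for heterozygous and 1
#' for homozygous alternative genotypes. A variant is detected in a
#' sample when its alternative support reaches `k` reads.
#'
#' @param code_true integer matrix (sites x samples) of genotype codes
#'   (0 = hom-ref, 1 = het, 2 = hom-alt).
#' @param coverage mean depth.
#' @param k minimum alternative-supporting reads for detection.
#' @param het_alt_read_prob see [sim_config()].
#' @param seed optional seed for this draw.
#' @return list of matrices `dp`, `alt`, `ref`, `detected`.
#' @export
simulate_read_support <- function(code_true, coverage, k = 3,
                                  het_alt_read_prob = 0.5, seed = NULL) {
  stopifnot(coverage > 0, k >= 1)
  if (!is.null(seed)) set.seed(seed)
  code_true <- as.matrix(code_true)
  n <- length(code_true)
  dp <- matrix(stats::rpois(n, coverage), nrow(code_true))
  p <- c(0, het_alt_read_prob, 1)[code_true + 1L]
  alt <- matrix(stats::rbinom(n, as.vector(dp), p), nrow(code_true))
  dimnames(dp) <- dimnames(alt) <- dimnames(code_true)
  list(dp = dp, alt = alt, ref = dp - alt, detected = alt >= k)
}

#' Simulate a joint-called trio cohort with a truth ledger
#'
#' Runs the full generative model of [sim_config()]: founder SV and SNV
#' pools with Mendelian transmission, Poisson de novo SVs (het in one
#' proband, absent elsewhere), genotype errors (a called genotype is
#' replaced by one of the other two diploid genotypes at
#' `genotype_error_rate`), parental dropout (a true heterozygous
#' parental call becomes homozygous reference while its simulated
#' alternative reads remain), and per-sample read support. Emitted call
#' sets contain the sites with at least one non-reference called
#' genotype, as a joint caller would output. The same seed yields
#' byte-identical VCFs.
#'
#' @param config a [sim_config()].
#' @param genes optional [gene_models()] used to annotate SNVs.
#' @return list of class `trio_sim`: `sv` (an [sv_set()]), `snv` (an
#'   [snv_set()]), `pedigree`, `ledger` and `config`. The ledger
#'   carries, for each variant class, the full site table (including
#'   non-emitted sites), true and called genotype-code matrices, the
#'   injected error events, and the emission flags.
#' @export
simulate_trio_cohort <- function(config = sim_config(), genes = NULL) {
  ss <- stage_seeds(config$seed)
  ped <- sim_pedigree(config)
  samples <- as.character(t(as.matrix(ped[, c("proband", "father", "mother")])))
  parents <- as.character(unlist(ped[, c("father", "mother")]))

  ## --- SV sites and genotypes -------------------------------------------
  set.seed(ss["sv_sites"])
  sv_sites <- place_sv_sites(config$n_sv, config)
  sv_sites$origin <- "founder"
  sv_sites$denovo_child <- NA_character_
  set.seed(ss["sv_geno"])
  sv_code <- sample_cohort_genotypes(nrow(sv_sites), ped, config)

  ## --- de novo SVs -------------------------------------------------------
  set.seed(ss["denovo"])
  n_dn <- stats::rpois(config$n_trios, config$de_novo_rate)
  if (sum(n_dn) > 0) {
    dn_sites <- place_sv_sites(sum(n_dn), config, id_prefix = "dnsv")
    dn_sites$origin <- "de_novo"
    ## site placement is exchangeable: assign children to placed sites in order
    dn_sites$denovo_child <- rep(ped$proband, n_dn)[seq_len(nrow(dn_sites))]
    dn_code <- matrix(0L, nrow(dn_sites), length(samples),
                      dimnames = list(NULL, samples))
    for (i in seq_len(nrow(dn_sites)))
      dn_code[i, dn_sites$denovo_child[i]] <- 1L
    sv_sites <- rbind(sv_sites, dn_sites)
    sv_code <- rbind(sv_code, dn_code)
    ord <- order(sv_sites$chrom, sv_sites$start)
    sv_sites <- sv_sites[ord, , drop = FALSE]
    sv_code <- sv_code[ord, , drop = FALSE]
    rownames(sv_sites) <- NULL
  }

  ## --- SNVs --------------------------------------------------------------
  snv <- simulate_snvs(config, genes, ped)

  ## --- genotype errors and parental dropout ------------------------------
  set.seed(ss["errors"])
  sv_err <- apply_call_errors(sv_sites$id, sv_code, parents, config)
  snv_ids <- paste(snv$sites$chrom, snv$sites$pos, sep = ":")
  snv_err <- apply_call_errors(snv_ids, snv$code_true, parents, config)

  ## --- read support -------------------------------------------------------
  set.seed(ss["reads"])
  sv_reads <- simulate_read_support(sv_code, config$coverage,
                                    config$min_supporting_reads,
                                    config$het_alt_read_prob)
  snv_reads <- simulate_read_support(snv$code_true, config$coverage,
                                     config$min_supporting_reads,
                                     config$het_alt_read_prob)

  ## --- emitted call sets ---------------------------------------------------
  sv_emit <- rowSums(sv_err$code_called > 0L) > 0L
  snv_emit <- rowSums(snv_err$code_called > 0L) > 0L
  sv <- sv_set(sv_sites[sv_emit, c("chrom", "start", "end", "svtype",
                                   "svlen", "id", "filter")],
               gt = matrix(code_to_gt(sv_err$code_called[sv_emit, ]),
                           sum(sv_emit), dimnames = list(NULL, samples)),
               dp = sv_reads$dp[sv_emit, , drop = FALSE],
               ad_ref = sv_reads$ref[sv_emit, , drop = FALSE],
               ad_alt = sv_reads$alt[sv_emit, , drop = FALSE],
               samples = samples)
  snv_sites_out <- snv$sites[snv_emit, , drop = FALSE]
  snvset <- snv_set(snv_sites_out,
                    gt = matrix(code_to_gt(snv_err$code_called[snv_emit, ]),
                                sum(snv_emit), dimnames = list(NULL, samples)),
                    dp = snv_reads$dp[snv_emit, , drop = FALSE],
                    ad_ref = snv_reads$ref[snv_emit, , drop = FALSE],
                    ad_alt = snv_reads$alt[snv_emit, , drop = FALSE],
                    samples = samples)

  ledger <- list(
    sv_sites = sv_sites, sv_code_true = sv_code,
    sv_code_called = sv_err$code_called, sv_errors = sv_err$events,
    sv_emitted = sv_emit,
    snv_sites = snv$sites, snv_code_true = snv$code_true,
    snv_code_called = snv_err$code_called, snv_errors = snv_err$events,
    snv_emitted = snv_emit,
    samples = samples, parents = parents
  )
  structure(list(sv = sv, snv = snvset, pedigree = ped, ledger = ledger,
                 config = config),
            class = "trio_sim")
}

## genotype-error then parental-dropout processes on a code matrix
apply_call_errors <- function(ids, code_true, parents, config) {
  called <- code_true
  events <- data.frame(id = character(), sample = character(),
                       kind = character(), stringsAsFactors = FALSE)
  e <- config$genotype_error_rate
  if (e > 0) {
    flip <- matrix(stats::runif(length(called)) < e, nrow(called))
    if (any(flip)) {
      shift <- matrix(sample(1:2, length(called), replace = TRUE),
                      nrow(called))
      called[flip] <- (called[flip] + shift[flip]) %% 3L
      w <- which(flip, arr.ind = TRUE)
      events <- rbind(events, data.frame(
        id = ids[w[, 1]], sample = colnames(code_true)[w[, 2]],
        kind = "genotype_error", stringsAsFactors = FALSE))
    }
  }
  d <- config$parental_dropout_rate
  if (d > 0) {
    pm <- code_true[, parents, drop = FALSE]
    drop <- matrix(stats::runif(length(pm)) < d, nrow(pm)) & pm == 1L
    if (any(drop)) {
      sub <- called[, parents, drop = FALSE]
      sub[drop] <- 0L
      called[, parents] <- sub
      w <- which(drop, arr.ind = TRUE)
      events <- rbind(events, data.frame(
        id = ids[w[, 1]], sample = parents[w[, 2]],
        kind = "dropout", stringsAsFactors = FALSE))
    }
  }
  list(code_called = called, events = events)
}

#' @export
print.trio_sim <- function(x, ...) {
  cat(sprintf("<trio cohort simulation: %d trios, %d/%d SV and %d/%d SNV sites emitted>\n",
              nrow(x$pedigree),
              n_sites(x$sv), nrow(x$ledger$sv_sites),
              n_sites(x$snv), nrow(x$ledger$snv_sites)))
  invisible(x)
}

#' Simulate gene models
#'
#' Places non-overlapping single-interval genes uniformly over the
#' configured contigs with log-uniform lengths between 2 and 50 kb and
#' GC fractions from a truncated normal (mean 0.45, sd 0.06, clamped to
#' [0.30, 0.75]), the typical spread of human gene GC content.
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes.
#' @return a [gene_models()] table.
#' @export
simulate_genes <- function(config, n_genes = 250) {
  ss <- stage_seeds(config$seed)
  set.seed(ss["genes"])
  contigs <- config$contigs
  len <- as.integer(round(exp(stats::runif(n_genes, log(2000), log(50000)))))
  placed <- data.frame()
  occupied <- GenomicRanges::GRanges()
  todo <- seq_len(n_genes)
  for (round in 1:10) {
    if (!length(todo)) break
    chrom <- sample(names(contigs), length(todo), replace = TRUE,
                    prob = as.numeric(contigs))
    start <- as.integer(floor(stats::runif(length(todo)) *
                                (contigs[chrom] - len[todo] - 1)))
    prop <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L,
                                                           start + len[todo]))
    ok <- GenomicRanges::countOverlaps(prop, prop) == 1 &
      GenomicRanges::countOverlaps(prop, occupied) == 0
    if (any(ok)) {
      placed <- rbind(placed, data.frame(chrom = chrom[ok], start = start[ok],
                                         end = start[ok] + len[todo][ok],
                                         stringsAsFactors = FALSE))
      occupied <- c(occupied, prop[ok])
    }
    todo <- todo[!ok]
  }
  gc <- pmin(pmax(stats::rnorm(nrow(placed), 0.45, 0.06), 0.30), 0.75)
  ord <- order(placed$chrom, placed$start)
  placed <- placed[ord, , drop = FALSE]
  gene_models(sprintf("G%04d", seq_len(nrow(placed))), placed$chrom,
              placed$start, placed$end, gc[ord])
}

#' Simulate paired LRS/SRS coverage tracks with GC bias
#'
#' Long-read depth is Poisson(`coverage`) per window. Short-read depth
#' is Poisson with its mean scaled by
#' `exp(-gc_bias_strength * max(0, gc - 0.5))` and drops to zero with
#' probability proportional to the GC excess above `gc_knee`, so that
#' high-GC genes lose short-read coverage while long-read coverage is
#' uniform. Window GC is the overlapping gene's GC fraction where a
#' gene model overlaps, and background GC (normal around 0.45)
#' elsewhere.
#'
#' @param config a [sim_config()].
#' @param genes a [gene_models()] table.
#' @return list with `lrs` and `srs` [coverage_track()] objects.
#' @export
simulate_coverage_tracks <- function(config, genes) {
  ss <- stage_seeds(config$seed)
  set.seed(ss["tracks"])
  w <- config$track_window
  dfs <- lapply(names(config$contigs), function(ctg) {
    len <- as.integer(config$contigs[[ctg]])
    start <- seq(0L, len - 1L, by = w)
    end <- pmin(start + w, len)
    gc <- pmin(pmax(stats::rnorm(length(start), 0.45, 0.03), 0.30), 0.75)
    g <- genes[genes$chrom == ctg, , drop = FALSE]
    if (nrow(g)) {
      wgr <- GenomicRanges::GRanges(ctg, IRanges::IRanges(start + 1L, end))
      hit <- GenomicRanges::findOverlaps(wgr, genes_gr(g),
                                         ignore.strand = TRUE,
                                         select = "first")
      gc[!is.na(hit)] <- g$gc_fraction[hit[!is.na(hit)]]
    }
    data.frame(chrom = ctg, start = start, end = end, gc = gc,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, dfs)
  lrs_depth <- stats::rpois(nrow(win), config$coverage)
  srs_mean <- config$coverage *
    exp(-config$gc_bias_strength * pmax(0, win$gc - 0.5))
  srs_depth <- stats::rpois(nrow(win), srs_mean)
  p_drop <- pmin(1, 5 * config$gc_bias_strength * pmax(0, win$gc - config$gc_knee))
  srs_depth[stats::runif(nrow(win)) < p_drop] <- 0L
  mk <- function(depth, label) {
    coverage_track(data.frame(chrom = win$chrom, start = win$start,
                              end = win$end, depth = depth,
                              stringsAsFactors = FALSE),
                   config$contigs, label = label, mapq_floor = 10)
  }
  list(lrs = mk(lrs_depth, "LRS"), srs = mk(srs_depth, "SRS"))
}

#' Simulated call sets at reduced coverage
#'
#' Re-draws read support for one sample's true variants at each
#' requested coverage and returns, per coverage, the `sv_set` of
#' detected sites (at least `k` alternative-supporting reads) — the
#' in-silico analogue of subsampling reads and re-calling.
#'
#' @param sim a `trio_sim` object.
#' @param sample sample id (default: first proband).
#' @param coverages numeric vector of fold coverages.
#' @param k detection threshold (default from the config).
#' @param seed seed for the detection redraws.
#' @return named list of `sv_set` objects, one per coverage; each site
#'   also records the drawn `dp`/`ad_alt` for the sample.
#' @export
simulate_titration_callsets <- function(sim, sample = sim$pedigree$proband[1],
                                        coverages = c(5, 10, 15, 20, 30),
                                        k = sim$config$min_supporting_reads,
                                        seed = stage_seeds(sim$config$seed)["titration"]) {
  led <- sim$ledger
  carried <- led$sv_code_true[, sample] > 0L
  sites <- led$sv_sites[carried, , drop = FALSE]
  codes <- led$sv_code_true[carried, sample, drop = FALSE]
  set.seed(seed)
  out <- list()
  for (cv in coverages) {
    rs <- simulate_read_support(codes, cv, k,
                                sim$config$het_alt_read_prob)
    det <- rs$detected[, 1]
    out[[as.character(cv)]] <- sv_set(
      sites[det, c("chrom", "start", "end", "svtype", "svlen", "id",
                   "filter")],
      gt = matrix(code_to_gt(codes[det, 1]), sum(det),
                  dimnames = list(NULL, sample)),
      dp = rs$dp[det, , drop = FALSE],
      ad_ref = rs$dp[det, , drop = FALSE] - rs$alt[det, , drop = FALSE],
      ad_alt = rs$alt[det, , drop = FALSE],
      samples = sample)
  }
  out
}
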