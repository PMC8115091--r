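#' De novo SV filter parameters
#'
#' The five-criterion filter for high-quality de novo SV candidates in
#' a joint-called cohort: (1) heterozygous alternative allele only in
#' the proband; (2) proband alternative-allele read ratio between
#' `ratio_min` and `ratio_max` (inclusive); (3) read depth of at least
#' `min_depth` at the SV coordinates in every sample; (4) all other
#' samples homozygous reference; (5) at most `max_other_alt_reads`
#' reads supporting the alternative allele in any other sample.
#'
#' @param ratio_min,ratio_max inclusive bounds on the proband
#'   alt-support ratio (defaults 0.3 and 0.7).
#' @param min_depth minimum depth in every sample (default 6 reads).
#' @param max_other_alt_reads maximum alt-supporting reads tolerated in
#'   any non-proband sample (default 0).
#' @return a list of class `denovo_sv_params`.
#' @export
denovo_sv_params <- function(ratio_min = 0.3, ratio_max = 0.7,
                             min_depth = 6, max_other_alt_reads = 0) {
  stopifnot(ratio_min >= 0, ratio_min < ratio_max, ratio_max <= 1,
            min_depth >= 1)
  structure(list(ratio_min = ratio_min, ratio_max = ratio_max,
                 min_depth = min_depth,
                 max_other_alt_reads = max_other_alt_reads),
            class = "denovo_sv_params")
}

#' Filter a cohort SV call set for de novo candidates
#'
#' Applies the five criteria of [denovo_sv_params()]. "All samples" in
#' the depth criterion means every sample in `cohort_samples`
#' (defaulting to the full joint-called cohort); "other samples" means
#' every cohort sample except the proband. Records with a missing
#' genotype or missing read support in any cohort sample are excluded
#' with a logged reason.
#'
#' @param x a cohort `sv_set`.
#' @param trio list with `proband`, `father`, `mother` sample ids.
#' @param cohort_samples samples over which depth/absence criteria are
#'   enforced (default: all samples of `x`).
#' @param params a [denovo_sv_params()] object.
#' @param verbose log exclusion reasons with `message()`.
#' @return the subset `sv_set` of candidate de novo SVs.
#' @export
denovo_sv_candidates <- function(x, trio, cohort_samples = x$samples,
                                 params = denovo_sv_params(),
                                 verbose = FALSE) {
  trio <- as.list(trio)
  stopifnot(trio$proband %in% cohort_samples)
  others <- setdiff(cohort_samples, trio$proband)

  gt <- x$gt[, cohort_samples, drop = FALSE]
  dp <- x$dp[, cohort_samples, drop = FALSE]
  alt <- x$ad_alt[, cohort_samples, drop = FALSE]

  pro_het <- gt_is_het(gt[, trio$proband])
  ratio <- x$ad_alt[, trio$proband] / pmax(x$dp[, trio$proband], 1L)
  ratio_ok <- x$dp[, trio$proband] > 0 &
    ratio >= params$ratio_min & ratio <= params$ratio_max
  depth_ok <- rowSums(dp >= params$min_depth) == length(cohort_samples)
  oth_gt <- gt[, others, drop = FALSE]
  others_homref <- rowSums(matrix(gt_is_homref(oth_gt), nrow = nrow(gt))) ==
    length(others)
  others_no_alt <- rowSums(alt[, others, drop = FALSE] >
                             params$max_other_alt_reads) == 0
  any_missing <- rowSums(matrix(gt_is_missing(gt), nrow = nrow(gt))) > 0 |
    rowSums(is.na(dp) | is.na(alt)) > 0

  keep <- pro_het & ratio_ok & depth_ok & others_homref & others_no_alt &
    !any_missing
  keep[is.na(keep)] <- FALSE
  dropped_missing <- pro_het & ratio_ok & depth_ok & any_missing
  if (verbose && any(dropped_missing))
    message(sum(dropped_missing),
            " candidate record(s) excluded for missing genotype or read support")
  x[keep]
}

#' Filter trio SNVs for de novo candidates
#'
#' Retains Mendelian-violating sites whose functional class is
#' loss-of-function (any quality) or missense with quality at least
#' `qual_min` (inclusive).
#'
#' @param snvs an `snv_set`.
#' @param trio list with `proband`, `father`, `mother` sample ids.
#' @param qual_min quality cutoff for missense candidates (default 30).
#' @param classes functional classes considered potentially damaging.
#' @return the subset `snv_set` of candidate de novo SNVs.
#' @export
denovo_snv_candidates <- function(snvs, trio, qual_min = 30,
                                  classes = c("missense", "lof")) {
  trio <- as.list(trio)
  status <- mendelian_consistent(snvs$gt[, trio$proband],
                                 snvs$gt[, trio$father],
                                 snvs$gt[, trio$mother])
  cls <- snvs$sites$func_class
  class_ok <- (cls == "lof" & "lof" %in% classes) |
    (cls == "missense" & "missense" %in% classes &
       !is.na(snvs$sites$qual) & snvs$sites$qual >= qual_min)
  snvs[status == "violation" & class_ok]
}

#' Classify de novo candidates by read evidence
#'
#' Programmatic stand-in for the visual re-inspection of candidate de
#' novo variants in read alignments. A candidate is `inherited` when
#' either parent shows any alternative-allele read support (the call
#' was likely dropped in that parent); `false_positive` when the
#' proband's own evidence is substandard (alt-read ratio outside the
#' relaxed band `[0.2, 0.8]`, or depth below `min_depth`); otherwise
#' `putative_de_novo`.
#'
#' @param x an `sv_set` or `snv_set` of candidates.
#' @param trio list with `proband`, `father`, `mother` sample ids.
#' @param min_depth minimum proband depth (default 6).
#' @param relaxed_band inclusive bounds of the acceptable proband
#'   alt-read ratio.
#' @return data.frame with columns `id` (or site index), `label`
#'   (`inherited`, `false_positive`, `putative_de_novo`) and `reason`.
#' @export
classify_candidate <- function(x, trio, min_depth = 6,
                               relaxed_band = c(0.2, 0.8)) {
  trio <- as.list(trio)
  n <- n_sites(x)
  parent_alt <- x$ad_alt[, trio$father] + x$ad_alt[, trio$mother]
  dp <- x$dp[, trio$proband]
  ratio <- x$ad_alt[, trio$proband] / pmax(dp, 1L)
  label <- rep("putative_de_novo", n)
  reason <- rep("adequate depth, balanced alt ratio, no parental alt reads", n)
  fp <- dp < min_depth | ratio < relaxed_band[1] | ratio > relaxed_band[2]
  label[fp] <- "false_positive"
  reason[fp] <- sprintf("proband evidence substandard (depth %d, ratio %.2f)",
                        dp, ratio)[fp]
  inh <- parent_alt >= 1
  label[inh] <- "inherited"
  reason[inh] <- sprintf("parental alt support (%d reads)", parent_alt)[inh]
  id <- if (inherits(x, "sv_set")) x$sites$id else
    paste(x$sites$chrom, x$sites$pos, sep = ":")
  data.frame(id = id, label = label, reason = reason,
             stringsAsFactors = FALSE)
}
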