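#' Mendelian consistency of a trio genotype
#'
#' A child genotype is Mendelian-consistent when its two alleles can be
#' partitioned so that one is carried by the father and the other by
#' the mother. Any missing genotype makes the site uncountable.
#' Vectorized over sites.
#'
#' @param child,father,mother character vectors of genotype strings
#'   (see [gt_alleles()]).
#' @return character vector with values `"consistent"`, `"violation"`
#'   or `"uncounted"`.
#' @examples
#' mendelian_consistent("0/1", "0/0", "0/0")  # violation
#' mendelian_consistent("0/1", "0/1", "0/0")  # consistent
#' @export
mendelian_consistent <- function(child, father, mother) {
  ca <- gt_alleles(child)
  fa <- gt_alleles(father)
  ma <- gt_alleles(mother)
  miss <- is.na(ca[, 1]) | is.na(fa[, 1]) | is.na(ma[, 1])
  in_gt <- function(allele, gtm) allele == gtm[, 1] | allele == gtm[, 2]
  ok <- (in_gt(ca[, 1], fa) & in_gt(ca[, 2], ma)) |
        (in_gt(ca[, 2], fa) & in_gt(ca[, 1], ma))
  out <- ifelse(ok, "consistent", "violation")
  out[miss] <- "uncounted"
  out
}

#' Mendelian inheritance error (MIE) summary for a trio
#'
#' Scores every site at which all three trio members have a called
#' genotype; sites with any missing genotype are excluded from the
#' denominator (they are reported as `uncounted`). De novo variants
#' count as violations under this definition; at genome scale they are
#' a negligible contribution to the rate.
#'
#' @param x an `sv_set` or `snv_set`.
#' @param trio a list or one-row pedigree with `proband`, `father`,
#'   `mother` sample ids.
#' @param autosomes_only restrict to chr1-chr22 (with or without the
#'   `"chr"` prefix), the convention for SNV concordance checks.
#' @return a list of class `mie_summary`: `sites_evaluated`,
#'   `violations`, `mie_rate`, `concordance`, `uncounted`.
#' @export
mie_summary <- function(x, trio, autosomes_only = FALSE) {
  trio <- as.list(trio)
  ids <- c(trio$proband, trio$father, trio$mother)
  absent <- setdiff(ids, x$samples)
  if (length(absent))
    stop("trio sample(s) not present in call set: ",
         paste(absent, collapse = ", "))
  keep <- rep(TRUE, n_sites(x))
  if (autosomes_only) keep <- is_autosome(x$sites$chrom)
  status <- mendelian_consistent(x$gt[keep, trio$proband],
                                 x$gt[keep, trio$father],
                                 x$gt[keep, trio$mother])
  evaluated <- sum(status != "uncounted")
  violations <- sum(status == "violation")
  structure(list(
    sites_evaluated = evaluated,
    violations = violations,
    mie_rate = if (evaluated > 0) violations / evaluated else NA_real_,
    concordance = if (evaluated > 0) 1 - violations / evaluated else NA_real_,
    uncounted = sum(status == "uncounted")
  ), class = "mie_summary")
}

#' @export
print.mie_summary <- function(x, ...) {
  cat(sprintf("MIE: %d/%d sites (rate %s; %d uncounted)\n",
              x$violations, x$sites_evaluated,
              ifelse(is.na(x$mie_rate), "NA", sprintf("%.4f", x$mie_rate)),
              x$uncounted))
  invisible(x)
}

is_autosome <- function(chrom) {
  grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", chrom)
}

#' Count variants unique to each sample in a cohort
#'
#' A variant is unique to sample `s` when `s` carries a non-reference
#' genotype and every other sample is homozygous reference. A missing
#' genotype in any other sample disqualifies the site: missingness
#' cannot certify absence.
#'
#' @param x a `variant_set` over the whole cohort.
#' @param samples sample ids to consider (default all samples in `x`);
#'   e.g. the probands of each trio when counting proband-unique SVs.
#' @return named integer vector of unique-variant counts per sample.
#' @export
unique_sample_variants <- function(x, samples = x$samples) {
  absent <- setdiff(samples, x$samples)
  if (length(absent))
    stop("sample(s) not in call set: ", paste(absent, collapse = ", "))
  gt <- x$gt[, samples, drop = FALSE]
  nonref <- apply(gt, 2, gt_has_alt)
  homref <- apply(gt, 2, gt_is_homref)
  dim(nonref) <- dim(homref) <- dim(gt)
  n_nonref <- rowSums(nonref)
  all_others_homref <- rowSums(homref) == (length(samples) - 1L)
  counts <- integer(length(samples))
  names(counts) <- samples
  eligible <- n_nonref == 1L & all_others_homref
  if (any(eligible)) {
    which_sample <- max.col(nonref[eligible, , drop = FALSE])
    tab <- table(factor(samples[which_sample], levels = samples))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
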