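#' Per-sample cohort summary report
#'
#' Assembles the per-sample summary table of a trio cohort analysis:
#' number of SVs (at least `min_sv_size` bp) with a non-reference
#' genotype, total sequence affected by those SVs (sum of `svlen`, each
#' SV counted once per carrying sample), per-trio SV and SNV Mendelian
#' inheritance error percentages (reported on the proband row), SVs
#' unique to the sample within the cohort, and SNV counts. A totals row
#' is appended.
#'
#' @param sv cohort `sv_set` (or `NULL`; SV columns become `NA`).
#' @param snv cohort `snv_set` (or `NULL`).
#' @param ped a [trio_pedigree()].
#' @param min_sv_size minimum SV size in bp (default 50).
#' @return data.frame with one row per sample plus a `Total` row.
#' @export
trio_report <- function(sv, snv, ped, min_sv_size = 50) {
  samples <- as.character(t(as.matrix(ped[, c("proband", "father", "mother")])))
  out <- data.frame(sample = samples,
                    n_sv = NA_real_, sv_affected_bp = NA_real_,
                    sv_mie_pct = NA_real_, unique_sv = NA_real_,
                    n_snv = NA_real_, snv_mie_pct = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(sv)) {
    sv <- filter_min_sv_size(sv, min_sv_size)
    carried <- apply(sv$gt[, samples, drop = FALSE], 2, gt_has_alt)
    dim(carried) <- c(n_sites(sv), length(samples))
    out$n_sv <- colSums(carried)
    out$sv_affected_bp <- colSums(carried * sv$sites$svlen)
    uniq <- unique_sample_variants(sv, samples)
    out$unique_sv <- uniq[out$sample]
  }
  if (!is.null(snv)) {
    carried <- apply(snv$gt[, samples, drop = FALSE], 2, gt_has_alt)
    dim(carried) <- c(n_sites(snv), length(samples))
    out$n_snv <- colSums(carried)
  }
  for (i in seq_len(nrow(ped))) {
    trio <- trio_members(ped, i)
    row <- out$sample == trio$proband
    if (!is.null(sv))
      out$sv_mie_pct[row] <- 100 * mie_summary(sv, trio)$mie_rate
    if (!is.null(snv))
      out$snv_mie_pct[row] <- 100 *
        mie_summary(snv, trio, autosomes_only = FALSE)$mie_rate
  }
  total <- data.frame(sample = "Total",
                      n_sv = sum(out$n_sv), sv_affected_bp = sum(out$sv_affected_bp),
                      sv_mie_pct = NA_real_, unique_sv = sum(out$unique_sv),
                      n_snv = sum(out$n_snv), snv_mie_pct = NA_real_,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Write a report as paired TSV and JSON
#'
#' @param report a data.frame (e.g. from [trio_report()]).
#' @param path_prefix output path without extension; `.tsv` and `.json`
#'   files are written.
#' @return invisibly, the two paths.
#' @export
write_report <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, json, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
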