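#' Precision/recall titration curve against a full-coverage truth set
#'
#' Compares the call set obtained at each reduced coverage to the
#' full-coverage calls as truth, using [match_callsets()]. Defaults
#' mirror a Truvari titration comparison: multimatch on, events of
#' 50 bp to 1 Mb, breakpoints within 1 kb.
#'
#' @param truth_calls the full-coverage `sv_set`.
#' @param callsets_by_coverage named list of `sv_set` objects; names are
#'   the fold coverages (e.g. `"5"`, `"10"`).
#' @param params a [match_params()]; default `multimatch = TRUE`.
#' @return data.frame with one row per coverage: `coverage`,
#'   `precision`, `recall`, `n_calls`, `tp`, `fp`, `fn`.
#' @export
titration_curve <- function(truth_calls, callsets_by_coverage,
                            params = match_params(multimatch = TRUE)) {
  if (n_sites(truth_calls) == 0) stop("empty truth call set")
  if (is.null(names(callsets_by_coverage)))
    stop("callsets_by_coverage must be named by fold coverage")
  rows <- lapply(names(callsets_by_coverage), function(cv) {
    res <- match_callsets(truth_calls, callsets_by_coverage[[cv]], params)
    data.frame(coverage = as.numeric(cv), precision = res$precision,
               recall = res$recall, n_calls = res$n_comp, tp = res$tp,
               fp = res$fp, fn = res$fn)
  })
  out <- do.call(rbind, rows)
  out[order(out$coverage), , drop = FALSE]
}
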