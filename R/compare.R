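#' SV call-set matching parameters
#'
#' Defaults reproduce a Truvari-style comparison of non-sequence-resolved
#' long-read SV calls: breakpoints within 1 kb, size ratio at least 0.7,
#' same SV type, events between 50 bp and 1 Mb. All boundaries are
#' inclusive. Sequence similarity is never computed.
#'
#' @param refdist maximum distance between start coordinates and between
#'   end coordinates of two SVs, in bp.
#' @param size_ratio_min minimum ratio of the smaller over the larger
#'   `svlen`.
#' @param require_same_type require identical `svtype` for a match.
#' @param sizemin,sizemax size range of records eligible for matching.
#' @param multimatch allow one record to match several records in the
#'   other set (recall and precision are then counted per side).
#' @return a list of class `match_params`.
#' @export
match_params <- function(refdist = 1000, size_ratio_min = 0.7,
                         require_same_type = TRUE,
                         sizemin = 50, sizemax = 1e6, multimatch = FALSE) {
  stopifnot(refdist >= 0, size_ratio_min > 0, size_ratio_min <= 1,
            sizemin <= sizemax)
  structure(list(refdist = refdist, size_ratio_min = size_ratio_min,
                 require_same_type = require_same_type,
                 sizemin = sizemin, sizemax = sizemax,
                 multimatch = multimatch),
            class = "match_params")
}

#' Pairwise SV match predicate
#'
#' Two SVs match when (if required) they are of the same type, their
#' start coordinates and their end coordinates each lie within
#' `refdist`, and the ratio of the smaller over the larger size is at
#' least `size_ratio_min`. Vectorized over rows of two site tables.
#'
#' @param a,b one-row (or equal-length) SV site data.frames with
#'   columns `start`, `end`, `svtype`, `svlen` (see [sv_set()]).
#' @param params a [match_params()] object.
#' @return logical vector.
#' @export
sv_pair_matches <- function(a, b, params = match_params()) {
  ratio <- pmin(a$svlen, b$svlen) / pmax(a$svlen, b$svlen)
  ok <- abs(a$start - b$start) <= params$refdist &
        abs(a$end - b$end) <= params$refdist &
        ratio >= params$size_ratio_min
  if (params$require_same_type) ok <- ok & (a$svtype == b$svtype)
  ok
}

#' Match two SV call sets
#'
#' Records outside `[sizemin, sizemax]` are excluded before matching.
#' Candidate pairs satisfying [sv_pair_matches()] are assigned greedily
#' 1:1, nearest first: ordered by start distance, then by deviation of
#' the size ratio from 1, then by input order. With `multimatch`, a
#' record may participate in several pairs; recall counts matched base
#' records and precision counts matched comparison records, each once.
#' Precision and recall are `NA` (not 0) when their denominator is 0.
#'
#' @param base the truth/reference `sv_set` (single- or multi-sample;
#'   only site coordinates are compared).
#' @param comp the comparison `sv_set`.
#' @param params a [match_params()] object.
#' @return a list of class `match_result`: `pairs` (data.frame of
#'   `base_idx`, `comp_idx`, `base_id`, `comp_id`), `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `n_base`, `n_comp`.
#' @export
match_callsets <- function(base, comp, params = match_params()) {
  bs <- base$sites
  cs <- comp$sites
  bs <- bs[bs$svlen >= params$sizemin & bs$svlen <= params$sizemax, , drop = FALSE]
  cs <- cs[cs$svlen >= params$sizemin & cs$svlen <= params$sizemax, , drop = FALSE]
  nb <- nrow(bs); nc <- nrow(cs)
  shared <- intersect(unique(bs$chrom), unique(cs$chrom))
  if (nb > 0 && nc > 0 && length(shared) == 0) {
    warning("no shared contigs between call sets")
    return(new_match_result(empty_pairs(), 0L, nb, nc))
  }

  cand <- candidate_pairs(bs, cs, params)
  if (nrow(cand)) {
    ord <- order(cand$start_dist, cand$ratio_dev, cand$base_idx, cand$comp_idx)
    cand <- cand[ord, , drop = FALSE]
  }

  if (params$multimatch) {
    base_hit <- unique(cand$base_idx)
    comp_hit <- unique(cand$comp_idx)
    pairs <- cand[, c("base_idx", "comp_idx")]
    res <- new_match_result(
      data.frame(pairs,
                 base_id = bs$id[pairs$base_idx],
                 comp_id = cs$id[pairs$comp_idx],
                 stringsAsFactors = FALSE),
      tp_base = length(base_hit), nb = nb, nc = nc,
      tp_comp = length(comp_hit))
    return(res)
  }

  used_b <- logical(nb); used_c <- logical(nc)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    bi <- cand$base_idx[i]; ci <- cand$comp_idx[i]
    if (!used_b[bi] && !used_c[ci]) {
      used_b[bi] <- TRUE; used_c[ci] <- TRUE; keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  new_match_result(
    data.frame(base_idx = cand$base_idx, comp_idx = cand$comp_idx,
               base_id = bs$id[cand$base_idx], comp_id = cs$id[cand$comp_idx],
               stringsAsFactors = FALSE),
    tp_base = nrow(cand), nb = nb, nc = nc)
}

empty_pairs <- function() {
  data.frame(base_idx = integer(), comp_idx = integer(),
             base_id = character(), comp_id = character(),
             stringsAsFactors = FALSE)
}

new_match_result <- function(pairs, tp_base, nb, nc, tp_comp = tp_base) {
  structure(list(
    pairs = pairs, tp = tp_base, fp = nc - tp_comp, fn = nb - tp_base,
    precision = if (nc > 0) tp_comp / nc else NA_real_,
    recall = if (nb > 0) tp_base / nb else NA_real_,
    n_base = nb, n_comp = nc
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match result: tp=%d fp=%d fn=%d precision=%s recall=%s\n",
              x$tp, x$fp, x$fn,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall))))
  invisible(x)
}

## enumerate candidate pairs: all same-contig pairs for small inputs, an
## interval-overlap prefilter on start coordinates (expanded by refdist)
## for large ones; the full predicate is applied either way
candidate_pairs <- function(bs, cs, params) {
  if (nrow(bs) == 0 || nrow(cs) == 0)
    return(data.frame(base_idx = integer(), comp_idx = integer(),
                      start_dist = numeric(), ratio_dev = numeric()))
  if (as.numeric(nrow(bs)) * nrow(cs) <= 1e5) {
    bi <- rep(seq_len(nrow(bs)), times = nrow(cs))
    ci <- rep(seq_len(nrow(cs)), each = nrow(bs))
    same <- bs$chrom[bi] == cs$chrom[ci]
    bi <- bi[same]; ci <- ci[same]
  } else {
    bgr <- GenomicRanges::GRanges(
      bs$chrom, IRanges::IRanges(pmax(bs$start - params$refdist, 0L) + 1L,
                                 bs$start + params$refdist + 1L))
    cgr <- GenomicRanges::GRanges(cs$chrom,
                                  IRanges::IRanges(cs$start + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(bgr, cgr, ignore.strand = TRUE)
    bi <- S4Vectors::queryHits(hits)
    ci <- S4Vectors::subjectHits(hits)
  }
  ok <- sv_pair_matches(bs[bi, , drop = FALSE], cs[ci, , drop = FALSE], params)
  bi <- bi[ok]; ci <- ci[ok]
  data.frame(
    base_idx = bi, comp_idx = ci,
    start_dist = abs(bs$start[bi] - cs$start[ci]),
    ratio_dev = abs(1 - pmin(bs$svlen[bi], cs$svlen[ci]) /
                        pmax(bs$svlen[bi], cs$svlen[ci]))
  )
}

#' Compare SV calls to an external interval set by reciprocal overlap
#'
#' Deletions and inversions are matched by footprint: some external
#' interval of the same type must cover at least `frac` of the call and
#' the call at least `frac` of that interval (both inclusive).
#' Insertions have no reference footprint; an insertion is matched when
#' an external insertion interval starts within `refdist` of its anchor
#' and the width ratio is at least `frac`.
#'
#' @param calls an `sv_set`.
#' @param external named list of region sets (`GRanges`) keyed by
#'   svtype (`DEL`, `INS`, `INV`); for `INS` the interval width encodes
#'   the inserted length.
#' @param frac minimum reciprocal overlap fraction (default 0.5).
#' @param refdist anchor distance for insertions (default 1000).
#' @return logical vector: is each call matched by the external set.
#' @export
reciprocal_overlap_compare <- function(calls, external, frac = 0.5,
                                       refdist = 1000) {
  s <- calls$sites
  matched <- logical(nrow(s))
  for (type in intersect(unique(s$svtype), names(external))) {
    idx <- which(s$svtype == type)
    ext <- external[[type]]
    if (length(ext) == 0) next
    if (type == "INS") {
      cgr <- GenomicRanges::GRanges(
        s$chrom[idx],
        IRanges::IRanges(pmax(s$start[idx] - refdist, 0L) + 1L,
                         s$start[idx] + refdist + 1L))
      hits <- GenomicRanges::findOverlaps(
        cgr, GenomicRanges::resize(ext, 1L, fix = "start"),
        ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ratio <- pmin(s$svlen[idx][qi], GenomicRanges::width(ext)[si]) /
               pmax(s$svlen[idx][qi], GenomicRanges::width(ext)[si])
      matched[idx[unique(qi[ratio >= frac])]] <- TRUE
    } else {
      cgr <- GenomicRanges::GRanges(
        s$chrom[idx], IRanges::IRanges(s$start[idx] + 1L, s$end[idx]))
      hits <- GenomicRanges::findOverlaps(cgr, ext, ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(cgr)[qi], GenomicRanges::ranges(ext)[si]))
      recip <- ov >= frac * GenomicRanges::width(cgr)[qi] &
               ov >= frac * GenomicRanges::width(ext)[si]
      matched[idx[unique(qi[recip])]] <- TRUE
    }
  }
  matched
}

#' Exact SNV set comparison
#'
#' Partitions two SNV call sets by site identity
#' `(chrom, pos, ref, alt)` into shared and set-unique sites.
#'
#' @param set_a,set_b `snv_set` objects.
#' @return list with `shared`, `only_a`, `only_b` (subsets of `set_a`
#'   resp. `set_b`) and `counts` (named integer vector).
#' @export
snv_set_compare <- function(set_a, set_b) {
  key <- function(x) paste(x$sites$chrom, x$sites$pos, x$sites$ref,
                           x$sites$alt, sep = ":")
  ka <- key(set_a); kb <- key(set_b)
  in_b <- ka %in% kb
  in_a <- kb %in% ka
  list(shared = set_a[in_b], only_a = set_a[!in_b], only_b = set_b[!in_a],
       counts = c(shared = sum(in_b), only_a = sum(!in_b),
                  only_b = sum(!in_a)))
}

#' Transition/transversion ratio
#'
#' Ratio of transitions (A<->G, C<->T) to transversions (all other
#' substitutions). A ratio near 2.1 is expected for genuine human
#' whole-genome call sets; marked deviations indicate enrichment for
#' artefacts.
#'
#' @param snvs an `snv_set`.
#' @return the Ti/Tv ratio, or `NA` for an empty set or when the
#'   transversion count is zero.
#' @export
ti_tv_ratio <- function(snvs) {
  s <- snvs$sites
  if (nrow(s) == 0) return(NA_real_)
  ti <- is_transition(s$ref, s$alt)
  n_tv <- sum(!ti)
  if (n_tv == 0) return(NA_real_)
  sum(ti) / n_tv
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}
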