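#' Region sets: half-open genomic interval algebra
#'
#' A *region set* is a strand-free, reduced \link[GenomicRanges]{GRanges}
#' object: per-contig sorted, non-overlapping intervals. All `triosv`
#' functions take and return coordinates in the 0-based half-open (BED)
#' convention; conversion to the 1-based closed convention used by
#' `GRanges` happens inside these wrappers. Book-ended intervals (e.g.
#' `[0,100)` and `[100,200)`) are merged, matching `bedtools merge`.
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors, 0-based half-open (`start <= end`).
#' @return A reduced `GRanges` object.
#' @examples
#' rs <- region_set("chr1", c(0L, 50L), c(100L, 150L))
#' regions_total_length(rs)  # 150
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  if (length(start) && any(end < start))
    stop("region_set: end < start at entry ", which(end < start)[1])
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  regions_reduce(gr)
}

## normalize to the reduced, unstranded, sorted form
regions_reduce <- function(gr) {
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::reduce(GenomicRanges::sort(gr), drop.empty.ranges = TRUE)
}

#' @rdname region_set
#' @param x,y region sets (`GRanges`).
#' @export
regions_union <- function(x, y) {
  regions_reduce(suppressWarnings(
    GenomicRanges::union(x, y, ignore.strand = TRUE)))
}

#' @rdname region_set
#' @export
regions_intersect <- function(x, y) {
  regions_reduce(suppressWarnings(
    GenomicRanges::intersect(x, y, ignore.strand = TRUE)))
}

#' @rdname region_set
#' @export
regions_subtract <- function(x, y) {
  regions_reduce(suppressWarnings(
    GenomicRanges::setdiff(x, y, ignore.strand = TRUE)))
}

#' @rdname region_set
#' @export
regions_total_length <- function(x) {
  sum(as.numeric(GenomicRanges::width(x)))
}

#' @rdname region_set
#' @export
regions_df <- function(x) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end   = GenomicRanges::end(x),
    stringsAsFactors = FALSE
  )
}

#' Read a BED file as a region set
#'
#' Overlapping and book-ended input intervals are merged.
#'
#' @param path path to a BED3+ file (0-based half-open).
#' @return A reduced `GRanges` region set.
#' @export
read_regions <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  regions_reduce(gr)
}

#' Write a region set to a BED file
#'
#' @param x a region set (`GRanges`).
#' @param path output path.
#' @export
write_regions <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
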