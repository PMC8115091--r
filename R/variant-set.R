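#' Multi-sample SV and SNV call sets
#'
#' `sv_set()` and `snv_set()` build the two core containers of the
#' package: a site table plus per-sample genotype matrices, mirroring a
#' joint-called multi-sample VCF. Coordinates are 0-based half-open.
#'
#' For an `sv_set` the site table has columns `chrom`, `start`, `end`,
#' `svtype` (DEL/INS/INV), `svlen` (absolute affected length; for an
#' insertion the inserted length), `id` and `filter`. Invariants:
#' `end >= start`; `svlen >= 1`; for DEL/INV `svlen == end - start`;
#' for INS `end == start` (a zero-length reference anchor).
#'
#' For an `snv_set` the site table has columns `chrom`, `pos`, `ref`,
#' `alt` (single bases, `ref != alt`), `qual`, `func_class` (one of
#' missense/lof/synonymous/noncoding/other) and `gene` (`NA` if
#' unannotated).
#'
#' @param sites data.frame of sites as described above.
#' @param gt character matrix (sites x samples) of unphased genotypes
#'   (`"0/0"`, `"0/1"`, ...); `NA` or `"./."` marks a missing call.
#' @param dp,ad_ref,ad_alt integer matrices (sites x samples): total
#'   read depth and reads supporting the reference / alternative allele.
#' @param samples character vector of sample ids (defaults to the
#'   column names of `gt`).
#' @return An object of class `sv_set` or `snv_set` (both inherit from
#'   `variant_set`).
#' @export
sv_set <- function(sites, gt, dp = NULL, ad_ref = NULL, ad_alt = NULL,
                   samples = colnames(gt)) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "svtype", "svlen", "id", "filter")
  if (!all(need %in% names(sites)))
    stop("sv_set sites must have columns: ", paste(need, collapse = ", "))
  bad <- !sites$svtype %in% c("DEL", "INS", "INV")
  if (any(bad)) stop("unsupported svtype: ", sites$svtype[which(bad)[1]])
  if (any(sites$end < sites$start)) stop("sv_set: end < start")
  if (any(sites$svlen < 1)) stop("sv_set: svlen must be >= 1")
  fp <- sites$svtype %in% c("DEL", "INV")
  if (any(sites$svlen[fp] != (sites$end - sites$start)[fp]))
    stop("sv_set: svlen must equal end - start for DEL/INV")
  if (any(sites$end[!fp] != sites$start[!fp]))
    stop("sv_set: INS records must have end == start")
  new_variant_set(sites, gt, dp, ad_ref, ad_alt, samples, "sv_set")
}

#' @rdname sv_set
#' @export
snv_set <- function(sites, gt, dp = NULL, ad_ref = NULL, ad_alt = NULL,
                    samples = colnames(gt)) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "qual", "func_class", "gene")
  if (!all(need %in% names(sites)))
    stop("snv_set sites must have columns: ", paste(need, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  if (any(!sites$ref %in% bases) || any(!sites$alt %in% bases))
    stop("snv_set: ref and alt must be single bases in {A,C,G,T}")
  if (any(sites$ref == sites$alt)) stop("snv_set: ref must differ from alt")
  new_variant_set(sites, gt, dp, ad_ref, ad_alt, samples, "snv_set")
}

new_variant_set <- function(sites, gt, dp, ad_ref, ad_alt, samples, class) {
  gt <- as.matrix(gt)
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_  # canonical missing
  n <- nrow(sites)
  if (nrow(gt) != n) stop("gt must have one row per site")
  if (is.null(samples)) stop("sample ids are required (gt column names)")
  zero <- matrix(0L, n, length(samples))
  if (is.null(dp)) dp <- zero
  if (is.null(ad_ref)) ad_ref <- zero
  if (is.null(ad_alt)) ad_alt <- zero
  dims <- list(dp = dim(dp), ad_ref = dim(ad_ref), ad_alt = dim(ad_alt))
  for (nm in names(dims))
    if (!identical(as.integer(dims[[nm]]), c(n, length(samples))))
      stop(nm, " must be a sites x samples matrix")
  if (any(ad_ref + ad_alt > dp, na.rm = TRUE))
    stop("ad_ref + ad_alt must not exceed dp")
  if (any(c(dp, ad_ref, ad_alt) < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  dimnames(gt) <- dimnames(dp) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
    list(NULL, samples)
  structure(
    list(sites = sites, gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
         samples = samples),
    class = c(class, "variant_set")
  )
}

#' @export
print.variant_set <- function(x, ...) {
  kind <- if (inherits(x, "sv_set")) "SV" else "SNV"
  cat(sprintf("<%s call set: %d sites x %d samples>\n",
              kind, nrow(x$sites), length(x$samples)))
  if (nrow(x$sites)) print(utils::head(x$sites, 5))
  invisible(x)
}

#' Subset a variant set by site
#'
#' @param x a `variant_set`.
#' @param i site indices (logical or integer).
#' @param ... ignored.
#' @export
`[.variant_set` <- function(x, i, ...) {
  x$sites <- x$sites[i, , drop = FALSE]
  rownames(x$sites) <- NULL
  for (f in c("gt", "dp", "ad_ref", "ad_alt"))
    x[[f]] <- x[[f]][i, , drop = FALSE]
  x
}

#' @rdname sv_set
#' @param x a `variant_set`.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname sv_set
#' @export
vs_samples <- function(x) x$samples

## ---- genotype utilities ------------------------------------------------

#' Genotype string helpers
#'
#' Genotypes are unphased strings such as `"0/1"`; `"./."`, `"."` or
#' `NA` denote a missing call. `gt_alleles()` parses a vector of
#' genotype strings into a two-column integer matrix of allele indices
#' (both `NA` when missing). Phased separators (`|`) are accepted and
#' treated as unphased.
#'
#' @param gt character vector of genotype strings.
#' @return `gt_alleles()`: an n x 2 integer matrix. The predicates
#'   return logical vectors (`FALSE` for missing genotypes, except
#'   `gt_is_missing`).
#' @export
gt_alleles <- function(gt) {
  gt <- as.character(gt)
  parts <- strsplit(gt, "[/|]")
  a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".", "")
  a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".", "")
  m <- cbind(suppressWarnings(as.integer(a1)), suppressWarnings(as.integer(a2)))
  m[is.na(gt) | is.na(m[, 1]) | is.na(m[, 2]), ] <- NA_integer_
  m
}

#' @rdname gt_alleles
#' @export
gt_is_missing <- function(gt) {
  al <- gt_alleles(gt)
  is.na(al[, 1]) | is.na(al[, 2])
}

#' @rdname gt_alleles
#' @export
gt_is_homref <- function(gt) {
  al <- gt_alleles(gt)
  !is.na(al[, 1]) & !is.na(al[, 2]) & al[, 1] == 0L & al[, 2] == 0L
}

#' @rdname gt_alleles
#' @export
gt_is_het <- function(gt) {
  al <- gt_alleles(gt)
  !is.na(al[, 1]) & !is.na(al[, 2]) & (al[, 1] != al[, 2])
}

#' @rdname gt_alleles
#' @export
gt_is_homalt <- function(gt) {
  al <- gt_alleles(gt)
  !is.na(al[, 1]) & !is.na(al[, 2]) & al[, 1] > 0L & al[, 1] == al[, 2]
}

#' @rdname gt_alleles
#' @export
gt_has_alt <- function(gt) {
  al <- gt_alleles(gt)
  !is.na(al[, 1]) & !is.na(al[, 2]) & (al[, 1] > 0L | al[, 2] > 0L)
}

## ---- pedigree ----------------------------------------------------------

#' Trio pedigrees
#'
#' A pedigree is a data.frame with columns `family`, `proband`,
#' `father` and `mother`, one row per trio. `read_pedigree()` /
#' `write_pedigree()` use a tab-separated file with a header line.
#'
#' @param family,proband,father,mother character vectors of equal length.
#' @return a `trio_pedigree` data.frame.
#' @export
trio_pedigree <- function(family, proband, father, mother) {
  ped <- data.frame(family = as.character(family),
                    proband = as.character(proband),
                    father = as.character(father),
                    mother = as.character(mother),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ped))) {
    ids <- unlist(ped[i, c("proband", "father", "mother")])
    if (anyDuplicated(ids))
      stop("duplicate sample id within trio '", ped$family[i], "'")
  }
  class(ped) <- c("trio_pedigree", "data.frame")
  ped
}

#' @rdname trio_pedigree
#' @param path path to a tab-separated pedigree file.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "proband", "father", "mother")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  trio_pedigree(ped$family, ped$proband, ped$father, ped$mother)
}

#' @rdname trio_pedigree
#' @param ped a `trio_pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## single-trio accessor: returns list(proband=, father=, mother=)
trio_members <- function(ped, i = 1L) {
  as.list(ped[i, c("proband", "father", "mother")])
}
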