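#' Read a joint-called multi-sample VCF
#'
#' Reads SV or SNV records from a VCF v4.2 file into an [sv_set()] or
#' [snv_set()]. The 1-based VCF `POS` is converted to a 0-based start;
#' missing genotypes are preserved. SV records must carry `SVTYPE` and
#' `SVLEN` and/or `END` in INFO; records without a usable `SVTYPE` are
#' skipped with a warning when `kind = "sv"`. SNV functional class and
#' gene are read from the `FCLASS` and `GENE` INFO keys when present.
#'
#' @param path path to a VCF file.
#' @param kind `"sv"` or `"snv"`.
#' @param passonly drop records whose FILTER is neither `PASS` nor `.`
#'   (default `TRUE`, matching a `--passonly` comparison workflow).
#' @return an `sv_set` or `snv_set`.
#' @export
read_cohort_vcf <- function(path, kind = c("sv", "snv"), passonly = TRUE) {
  kind <- match.arg(kind)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix)))  # single-record VCF
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  if (length(samples) == 0) stop("VCF '", path, "' has no sample columns")
  n <- nrow(fix)
  if (is.null(n)) n <- 0L
  if (n == 0) return(empty_variant_set(kind, samples))

  gt <- vcfR::extract.gt(v, "GT")
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  if (is.null(gt)) stop("VCF '", path, "' lacks the GT FORMAT field")
  split_ad <- function(col, idx) {
    out <- rep(NA_integer_, length(col))
    ok <- !is.na(col)
    parts <- strsplit(col[ok], ",", fixed = TRUE)
    out[ok] <- suppressWarnings(as.integer(vapply(
      parts, function(p) if (length(p) >= idx) p[idx] else NA_character_, "")))
    out
  }
  ad_ref <- apply(ad, 2, split_ad, idx = 1L)
  ad_alt <- apply(ad, 2, split_ad, idx = 2L)
  dim(ad_ref) <- dim(ad_alt) <- dim(gt)
  storage.mode(dp) <- "integer"
  dp[is.na(dp)] <- NA_integer_

  filter <- fix[, "FILTER"]
  filter[is.na(filter)] <- "."
  keep <- rep(TRUE, n)
  if (passonly) keep <- filter %in% c("PASS", ".")

  pos1 <- as.integer(fix[, "POS"])

  if (kind == "sv") {
    svtype <- vcfR::extract.info(v, "SVTYPE")
    svlen <- suppressWarnings(vcfR::extract.info(v, "SVLEN", as.numeric = TRUE))
    endi <- suppressWarnings(vcfR::extract.info(v, "END", as.numeric = TRUE))
    no_type <- is.na(svtype) | !svtype %in% c("DEL", "INS", "INV")
    if (any(no_type & keep))
      warning(sum(no_type & keep), " record(s) without a usable SVTYPE skipped")
    keep <- keep & !no_type
    start <- pos1 - 1L
    svlen_abs <- as.integer(abs(svlen))
    svlen_abs[is.na(svlen_abs)] <- as.integer(endi - start)[is.na(svlen_abs)]
    end <- as.integer(ifelse(svtype == "INS", start,
                             ifelse(!is.na(endi), endi, start + svlen_abs)))
    if (any(keep & is.na(svlen_abs)))
      stop("SV record without SVLEN or END at line with POS=",
           pos1[which(keep & is.na(svlen_abs))[1]])
    sites <- data.frame(chrom = fix[, "CHROM"], start = start, end = end,
                        svtype = svtype, svlen = svlen_abs,
                        id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                        filter = filter, stringsAsFactors = FALSE)
    out <- sv_set(sites[keep, , drop = FALSE],
                  gt[keep, , drop = FALSE],
                  dp[keep, , drop = FALSE],
                  ad_ref[keep, , drop = FALSE],
                  ad_alt[keep, , drop = FALSE],
                  samples = samples)
  } else {
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    fclass <- vcfR::extract.info(v, "FCLASS")
    gene <- vcfR::extract.info(v, "GENE")
    if (is.null(fclass)) fclass <- rep(NA_character_, n)
    if (is.null(gene)) gene <- rep(NA_character_, n)
    fclass <- as.character(fclass)
    gene <- as.character(gene)
    fclass[is.na(fclass)] <- "other"
    snv_ok <- fix[, "REF"] %in% c("A", "C", "G", "T") &
      fix[, "ALT"] %in% c("A", "C", "G", "T")
    keep <- keep & snv_ok
    sites <- data.frame(chrom = fix[, "CHROM"], pos = pos1 - 1L,
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        qual = qual, func_class = fclass, gene = gene,
                        stringsAsFactors = FALSE)
    out <- snv_set(sites[keep, , drop = FALSE],
                   gt[keep, , drop = FALSE],
                   dp[keep, , drop = FALSE],
                   ad_ref[keep, , drop = FALSE],
                   ad_alt[keep, , drop = FALSE],
                   samples = samples)
  }
  ## normalize missing support counts to 0 with missing genotype kept
  for (f in c("dp", "ad_ref", "ad_alt"))
    out[[f]][is.na(out[[f]])] <- 0L
  out
}

empty_variant_set <- function(kind, samples) {
  m <- matrix(character(), 0, length(samples),
              dimnames = list(NULL, samples))
  z <- matrix(integer(), 0, length(samples))
  if (kind == "sv") {
    sv_set(data.frame(chrom = character(), start = integer(),
                      end = integer(), svtype = character(),
                      svlen = integer(), id = character(),
                      filter = character()), m, z, z, z, samples = samples)
  } else {
    snv_set(data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       qual = numeric(), func_class = character(),
                       gene = character()), m, z, z, z, samples = samples)
  }
}

#' Write a variant set as VCF v4.2
#'
#' The inverse of [read_cohort_vcf()]: SV records are written with
#' symbolic ALT alleles and `SVTYPE`/`SVLEN`/`END` INFO keys (negative
#' `SVLEN` for deletions, as emitted by long-read SV callers); SNV
#' records carry `FCLASS` and `GENE` INFO keys. Genotypes are written
#' as `GT:AD:DP`.
#'
#' @param x an `sv_set` or `snv_set`.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @export
write_variant_vcf <- function(x, path, contigs = NULL) {
  is_sv <- inherits(x, "sv_set")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=triosv-%s",
                   as.character(utils::packageVersion("triosv"))))
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  if (is_sv) {
    hdr <- c(hdr,
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">")
  } else {
    hdr <- c(hdr,
      "##INFO=<ID=FCLASS,Number=1,Type=String,Description=\"Functional class\">",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">")
  }
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))

  s <- x$sites
  n <- nrow(s)
  if (n) {
    gt <- x$gt
    gt[is.na(gt)] <- "./."
    sample_cols <- vapply(seq_len(n), function(i) {
      paste(sprintf("%s:%d,%d:%d", gt[i, ], x$ad_ref[i, ], x$ad_alt[i, ],
                    x$dp[i, ]), collapse = "\t")
    }, "")
    if (is_sv) {
      svlen_signed <- ifelse(s$svtype == "DEL", -s$svlen, s$svlen)
      info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", s$svtype,
                      as.integer(svlen_signed),
                      as.integer(ifelse(s$svtype == "INS", s$start + 1L, s$end)))
      body <- paste(s$chrom, s$start + 1L, s$id, "N",
                    sprintf("<%s>", s$svtype), ".", s$filter, info,
                    "GT:AD:DP", sample_cols, sep = "\t")
    } else {
      info <- sprintf("FCLASS=%s%s", s$func_class,
                      ifelse(is.na(s$gene), "", sprintf(";GENE=%s", s$gene)))
      qual <- ifelse(is.na(s$qual), ".", format(s$qual, trim = TRUE))
      body <- paste(s$chrom, s$pos + 1L, ".", s$ref, s$alt, qual, "PASS",
                    info, "GT:AD:DP", sample_cols, sep = "\t")
    }
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply the minimum SV size rule
#'
#' Retains structural variants whose affected length is at least
#' `min_size` base pairs (inclusive). Long-read SV callers emit events
#' down to tens of bases; only events of 50 bp and above are treated as
#' SVs throughout this package.
#'
#' @param x an `sv_set`.
#' @param min_size minimum `svlen` in bp (default 50).
#' @return the filtered `sv_set`, input order preserved.
#' @export
filter_min_sv_size <- function(x, min_size = 50) {
  stopifnot(inherits(x, "sv_set"))
  x[x$sites$svlen >= min_size]
}
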