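#' Gene models
#'
#' A gene model table has one row per (gene, interval): columns `gene`,
#' `chrom`, `start`, `end` (0-based half-open coding intervals) and
#' `gc_fraction` (per-gene GC content in [0,1], repeated across a
#' gene's intervals). `read_genes()` reads intervals from a BED file
#' (name column = gene symbol) and GC fractions from a two-column
#' tab-separated file (`gene`, `gc_fraction`).
#'
#' @param gene,chrom character vectors.
#' @param start,end integer vectors (0-based half-open).
#' @param gc_fraction numeric in [0,1] (default `NA`).
#' @return a `gene_models` data.frame.
#' @export
gene_models <- function(gene, chrom, start, end, gc_fraction = NA_real_) {
  stopifnot(all(end > start))
  gc_fraction <- rep_len(gc_fraction, length(gene))
  if (any(!is.na(gc_fraction) & (gc_fraction < 0 | gc_fraction > 1)))
    stop("gc_fraction must lie in [0,1]")
  structure(data.frame(gene = as.character(gene), chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       gc_fraction = gc_fraction, stringsAsFactors = FALSE),
            class = c("gene_models", "data.frame"))
}

#' @rdname gene_models
#' @param bed_path BED file of gene/exon intervals (name = gene symbol).
#' @param gc_path optional TSV with columns `gene`, `gc_fraction`.
#' @export
read_genes <- function(bed_path, gc_path = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (is.null(gr$name)) stop("gene BED file must carry gene symbols (column 4)")
  gc <- rep(NA_real_, length(gr))
  if (!is.null(gc_path)) {
    tab <- utils::read.delim(gc_path, stringsAsFactors = FALSE)
    gc <- tab$gc_fraction[match(gr$name, tab$gene)]
  }
  gene_models(gr$name, as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), gc)
}

#' @rdname gene_models
#' @param genes a `gene_models` data.frame.
#' @param path output BED path.
#' @export
write_genes <- function(genes, path) {
  gr <- genes_gr(genes)
  gr$name <- genes$gene
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

genes_gr <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end))
}

## GRanges footprint of variants: DEL/INV by span, INS and SNV by a
## 1 bp anchor point
variant_gr <- function(x) {
  s <- x$sites
  if (inherits(x, "sv_set")) {
    w_start <- ifelse(s$svtype == "INS", s$start + 1L, s$start + 1L)
    w_end <- ifelse(s$svtype == "INS", s$start + 1L, s$end)
    GenomicRanges::GRanges(s$chrom, IRanges::IRanges(w_start, w_end))
  } else {
    GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos + 1L, s$pos + 1L))
  }
}

#' Build the per-gene variant table for one sample
#'
#' Assigns a sample's variants to genes: deletions and inversions by
#' footprint overlap of at least 1 bp with a gene interval, insertions
#' and SNVs by their anchor point. Only variants the sample actually
#' carries (non-reference genotype) are listed. Parental origin of
#' heterozygous variants is inferred from trio genotypes where
#' unambiguous (exactly one parent carries the allele), else `unknown`.
#'
#' @param svs,snvs cohort call sets (either may be `NULL`).
#' @param genes a `gene_models` table.
#' @param sample sample id whose variants are tabulated.
#' @param trio optional list with `proband`, `father`, `mother` ids for
#'   origin inference (the sample must be the proband).
#' @return a `gene_variant_table` data.frame with columns `gene`,
#'   `variant_id`, `type` (`sv`/`snv`), `svtype`, `func_class`, `qual`,
#'   `genotype`, `origin`.
#' @export
build_gene_table <- function(svs, snvs, genes, sample, trio = NULL) {
  ggr <- genes_gr(genes)
  one <- function(x, type) {
    if (is.null(x) || n_sites(x) == 0) return(NULL)
    carried <- gt_has_alt(x$gt[, sample])
    hits <- GenomicRanges::findOverlaps(variant_gr(x), ggr,
                                        ignore.strand = TRUE)
    vi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
    sel <- carried[vi]
    vi <- vi[sel]; gi <- gi[sel]
    if (!length(vi)) return(NULL)
    s <- x$sites
    df <- data.frame(
      gene = genes$gene[gi],
      variant_id = if (type == "sv") s$id[vi] else
        paste(s$chrom[vi], s$pos[vi], s$ref[vi], s$alt[vi], sep = ":"),
      type = type,
      svtype = if (type == "sv") s$svtype[vi] else NA_character_,
      func_class = if (type == "sv") NA_character_ else s$func_class[vi],
      qual = if (type == "sv") NA_real_ else s$qual[vi],
      genotype = x$gt[vi, sample],
      origin = infer_origin(x, vi, trio),
      stringsAsFactors = FALSE)
    unique(df)
  }
  out <- rbind(one(svs, "sv"), one(snvs, "snv"))
  if (is.null(out))
    out <- data.frame(gene = character(), variant_id = character(),
                      type = character(), svtype = character(),
                      func_class = character(), qual = numeric(),
                      genotype = character(), origin = character(),
                      stringsAsFactors = FALSE)
  class(out) <- c("gene_variant_table", "data.frame")
  out
}

infer_origin <- function(x, vi, trio) {
  if (is.null(trio)) return(rep("unknown", length(vi)))
  trio <- as.list(trio)
  f <- gt_has_alt(x$gt[vi, trio$father])
  m <- gt_has_alt(x$gt[vi, trio$mother])
  fm <- is.na(x$gt[vi, trio$father]) | is.na(x$gt[vi, trio$mother])
  out <- rep("unknown", length(vi))
  out[f & !m & !fm] <- "father"
  out[m & !f & !fm] <- "mother"
  out
}

#' Recessive candidate genes: homozygous and compound het SV-SNV pairs
#'
#' Emits, per gene, the recessive mechanisms supported by the proband's
#' coding variants: `hom_sv` (homozygous SV), `hom_snv` (homozygous
#' loss-of-function SNV with quality strictly above `lof_qual_min`),
#' and `comphet_sv_snv` (heterozygous coding SV paired with a
#' heterozygous LoF SNV, quality strictly above `lof_qual_min`, in the
#' same gene). With `phase = TRUE` a compound het pair is only reported
#' when the two parental origins are not provably cis (distinct, or at
#' least one unknown); `phase = FALSE` reproduces naive pairing without
#' origin inference.
#'
#' @param table a `gene_variant_table` built for the proband.
#' @param lof_qual_min strict lower bound on LoF SNV quality
#'   (default 30; a quality of exactly 30 is excluded).
#' @param phase apply the trans-configuration origin rule.
#' @return data.frame with columns `gene`, `mechanism`, `variant_ids`,
#'   `origins`.
#' @export
recessive_candidates <- function(table, lof_qual_min = 30, phase = TRUE) {
  out <- list()
  add <- function(gene, mech, ids, origins) {
    out[[length(out) + 1L]] <<- data.frame(
      gene = gene, mechanism = mech,
      variant_ids = paste(ids, collapse = ","),
      origins = paste(origins, collapse = ","), stringsAsFactors = FALSE)
  }
  lof_ok <- table$type == "snv" & table$func_class == "lof" &
    !is.na(table$qual) & table$qual > lof_qual_min
  for (g in unique(table$gene)) {
    tg <- table[table$gene == g, , drop = FALSE]
    lg <- lof_ok[table$gene == g]
    hom_sv <- tg$type == "sv" & gt_is_homalt(tg$genotype)
    for (i in which(hom_sv)) add(g, "hom_sv", tg$variant_id[i], tg$origin[i])
    hom_snv <- lg & gt_is_homalt(tg$genotype)
    for (i in which(hom_snv)) add(g, "hom_snv", tg$variant_id[i], tg$origin[i])
    het_sv <- which(tg$type == "sv" & gt_is_het(tg$genotype))
    het_snv <- which(lg & gt_is_het(tg$genotype))
    for (i in het_sv) for (j in het_snv) {
      oi <- tg$origin[i]; oj <- tg$origin[j]
      trans_possible <- !phase || oi == "unknown" || oj == "unknown" || oi != oj
      if (trans_possible)
        add(g, "comphet_sv_snv", c(tg$variant_id[i], tg$variant_id[j]),
            c(oi, oj))
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), mechanism = character(),
                      variant_ids = character(), origins = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
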