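#' Per-base coverage tracks
#'
#' A coverage track stores integer read depth as a run-length encoding
#' per contig. Input intervals are 0-based half-open; gaps between
#' intervals are filled with depth 0 so that every contig is tiled
#' completely. Mapping-quality filtering is assumed to have happened
#' upstream (when tracks are computed from alignments); `mapq_floor` is
#' carried as metadata only.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `depth` (half-open, non-overlapping).
#' @param contigs named integer vector of contig lengths.
#' @param label provenance label, e.g. `"LRS"` or `"SRS"`.
#' @param mapq_floor minimum mapping quality the track was built with.
#' @return object of class `coverage_track` with a list of
#'   \link[S4Vectors]{Rle} depth vectors, one per contig.
#' @export
coverage_track <- function(intervals, contigs, label = "", mapq_floor = 10) {
  stopifnot(!is.null(names(contigs)), all(contigs > 0))
  depth <- list()
  for (ctg in names(contigs)) {
    iv <- intervals[intervals$chrom == ctg, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    len <- as.integer(contigs[[ctg]])
    if (nrow(iv)) {
      if (any(iv$end > len) || any(iv$start < 0))
        stop("interval outside contig '", ctg, "'")
      if (any(iv$start[-1] < iv$end[-nrow(iv)]))
        stop("overlapping coverage intervals on contig '", ctg, "'")
      starts <- c(iv$start, len)
      prev_end <- c(0L, iv$end)
      gap <- starts - prev_end
      widths <- as.vector(rbind(gap, c(iv$end - iv$start, 0L)))
      values <- as.vector(rbind(0L, c(as.integer(iv$depth), 0L)))
      keep <- widths > 0
      depth[[ctg]] <- S4Vectors::Rle(values[keep], widths[keep])
    } else {
      depth[[ctg]] <- S4Vectors::Rle(0L, len)
    }
    if (any(S4Vectors::runValue(depth[[ctg]]) < 0))
      stop("negative depth on contig '", ctg, "'")
  }
  structure(list(depth = depth, contigs = contigs, label = label,
                 mapq_floor = mapq_floor),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage track '%s': %d contig(s), %.0f bp, mean depth %.2f>\n",
              x$label, length(x$contigs), sum(as.numeric(x$contigs)),
              stats::weighted.mean(
                vapply(x$depth, function(d) mean(as.numeric(d)), 0),
                as.numeric(x$contigs))))
  invisible(x)
}

#' @rdname coverage_track
#' @param path bedGraph file path.
#' @export
read_coverage_track <- function(path, contigs, label = "", mapq_floor = 10) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1L,
                            end = GenomicRanges::end(gr),
                            depth = gr$score, stringsAsFactors = FALSE),
                 contigs, label, mapq_floor)
}

#' @rdname coverage_track
#' @param track a `coverage_track`.
#' @export
write_coverage_track <- function(track, path) {
  dfs <- lapply(names(track$contigs), function(ctg) {
    r <- track$depth[[ctg]]
    w <- S4Vectors::runLength(r)
    e <- cumsum(w)
    data.frame(chrom = ctg, start = e - w, end = e,
               depth = S4Vectors::runValue(r), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = df$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

## logical Rle per contig -> GRanges of TRUE runs
rle_true_regions <- function(mask_list) {
  dfs <- lapply(names(mask_list), function(ctg) {
    ir <- methods::as(mask_list[[ctg]], "IRanges")
    if (length(ir) == 0) return(NULL)
    data.frame(chrom = ctg, start = IRanges::start(ir),
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  if (is.null(df)) return(GenomicRanges::GRanges())
  regions_reduce(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end)))
}

#' Partition the genome by cross-technology accessibility
#'
#' Classifies every base by presence of coverage in two tracks:
#' `neither` (depth 0 in both), `lrs_only` (no SRS coverage, LRS depth
#' at least `min_depth`... see below), `srs_only`, and `both`. "Covered"
#' means depth >= `min_depth` (default 1, i.e. the partition is defined
#' by absence of coverage). The four sets are disjoint and their union
#' tiles the genome.
#'
#' @param lrs,srs `coverage_track` objects over the same contigs.
#' @param min_report_length intervals shorter than this are still part
#'   of the partition but flagged sub-threshold in the summary
#'   (default 1000 bp).
#' @param min_depth minimum depth to count a base as covered.
#' @return object of class `accessibility_partition`: region sets
#'   `lrs_only`, `srs_only`, `neither`, `both`, plus `genome_length`
#'   and `min_report_length`.
#' @export
partition_coverage <- function(lrs, srs, min_report_length = 1000,
                               min_depth = 1) {
  only <- c(setdiff(names(lrs$contigs), names(srs$contigs)),
            setdiff(names(srs$contigs), names(lrs$contigs)))
  if (length(only))
    stop("contig(s) present in one track only: ", paste(only, collapse = ", "))
  masks <- list(lrs_only = list(), srs_only = list(), neither = list(),
                both = list())
  for (ctg in names(lrs$contigs)) {
    l <- lrs$depth[[ctg]] >= min_depth
    s <- srs$depth[[ctg]] >= min_depth
    masks$lrs_only[[ctg]] <- l & !s
    masks$srs_only[[ctg]] <- s & !l
    masks$neither[[ctg]] <- !l & !s
    masks$both[[ctg]] <- l & s
  }
  structure(c(lapply(masks, rle_true_regions),
              list(genome_length = sum(as.numeric(lrs$contigs)),
                   min_report_length = min_report_length)),
            class = "accessibility_partition")
}

#' @rdname partition_coverage
#' @param x an `accessibility_partition`.
#' @return `partition_summary()`: data.frame with, per set, total bp
#'   and bp in intervals of at least `min_report_length`.
#' @export
partition_summary <- function(x) {
  sets <- c("lrs_only", "srs_only", "neither", "both")
  data.frame(
    set = sets,
    total_bp = vapply(sets, function(s) regions_total_length(x[[s]]), 0),
    reportable_bp = vapply(sets, function(s) {
      gr <- x[[s]]
      sum(as.numeric(GenomicRanges::width(gr)[
        GenomicRanges::width(gr) >= x$min_report_length]))
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.accessibility_partition <- function(x, ...) {
  print(partition_summary(x))
  invisible(x)
}

#' Fold-coverage summary excluding difficult regions
#'
#' Fraction of the genome with depth at least each threshold, computed
#' over the easily accessible genome (everything outside the supplied
#' difficult regions — assembly gaps, centromeres, telomeres and
#' similar — with chrY appended automatically) and, for reference, over
#' the whole genome.
#'
#' @param track a `coverage_track`.
#' @param difficult region set (`GRanges`) of difficult regions, or
#'   `NULL`.
#' @param thresholds integer vector of fold-coverage thresholds.
#' @return data.frame with columns `threshold`, `fraction_easy`,
#'   `fraction_genome`.
#' @export
fold_coverage_summary <- function(track, difficult = NULL,
                                  thresholds = c(5, 10, 15, 20)) {
  genome <- region_set(names(track$contigs),
                       rep(0L, length(track$contigs)),
                       as.integer(track$contigs))
  if (is.null(difficult)) difficult <- GenomicRanges::GRanges()
  chry <- names(track$contigs)[names(track$contigs) %in% c("chrY", "Y")]
  if (length(chry))
    difficult <- regions_union(difficult,
                               region_set(chry, rep(0L, length(chry)),
                                          as.integer(track$contigs[chry])))
  easy <- regions_subtract(genome, difficult)
  easy_len <- regions_total_length(easy)
  genome_len <- regions_total_length(genome)
  frac_easy <- frac_genome <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    masks <- lapply(track$depth, function(d) d >= thresholds[i])
    cov <- rle_true_regions(masks)
    frac_genome[i] <- regions_total_length(cov) / genome_len
    frac_easy[i] <- if (easy_len > 0)
      regions_total_length(regions_intersect(cov, easy)) / easy_len
      else NA_real_
  }
  data.frame(threshold = thresholds, fraction_easy = frac_easy,
             fraction_genome = frac_genome)
}

#' Classify genes by short-read coverage
#'
#' A gene is poorly covered when at least `uncovered_frac` of its
#' length (inclusive) has zero depth in the supplied track.
#'
#' @param genes a [gene_models()] table.
#' @param track a `coverage_track` (typically the SRS track).
#' @param uncovered_frac inclusive fraction threshold (default 0.10).
#' @return data.frame with one row per gene: `gene`, `length`,
#'   `uncovered_bp`, `uncovered_frac`, `gc_fraction`, `status`
#'   (`well_covered` / `poorly_covered`).
#' @export
gene_coverage_classify <- function(genes, track, uncovered_frac = 0.10) {
  zero <- rle_true_regions(lapply(track$depth, function(d) d == 0L))
  grl <- GenomicRanges::reduce(S4Vectors::split(genes_gr(genes), genes$gene))
  flat <- unlist(grl)
  gene_of <- names(flat)
  len <- vapply(S4Vectors::split(GenomicRanges::width(flat), gene_of), sum, 0)
  hits <- GenomicRanges::findOverlaps(flat, zero, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(flat)[qi], GenomicRanges::ranges(zero)[si]))
  unc <- stats::setNames(rep(0, length(len)), names(len))
  if (length(qi)) {
    agg <- tapply(ov, gene_of[qi], sum)
    unc[names(agg)] <- agg
  }
  first <- !duplicated(genes$gene)
  ord_genes <- genes$gene[first]
  out <- data.frame(gene = ord_genes, length = unname(len[ord_genes]),
                    uncovered_bp = unname(unc[ord_genes]),
                    uncovered_frac = unname(unc[ord_genes] / len[ord_genes]),
                    gc_fraction = genes$gc_fraction[first],
                    stringsAsFactors = FALSE)
  out$status <- ifelse(out$uncovered_frac >= uncovered_frac,
                       "poorly_covered", "well_covered")
  out
}

#' Compare GC content of poorly covered genes to length-matched controls
#'
#' For every poorly covered gene one control is drawn from the
#' well-covered genes: the nearest-length unused control within a
#' +/-`window` relative length window (ties broken at random, seeded);
#' when a window is empty it is widened with a warning. GC fractions of
#' the two groups are compared with Welch's two-sample t-test.
#'
#' @param poor,controls data.frames with columns `gene`, `length`,
#'   `gc_fraction` (e.g. rows of [gene_coverage_classify()] output).
#' @param seed integer seed for the control draw.
#' @param window relative length-matching half-width (default 0.2).
#' @return list: `mean_poor`, `mean_control`, `t_statistic`, `p_value`,
#'   `matches` (data.frame of gene/control pairs).
#' @export
gc_comparison <- function(poor, controls, seed = 1, window = 0.2) {
  stopifnot(nrow(poor) >= 1, nrow(controls) >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  used <- logical(nrow(controls))
  pick <- integer(nrow(poor))
  for (i in sample(seq_len(nrow(poor)))) {
    w <- window
    repeat {
      cand <- which(!used &
                      abs(controls$length - poor$length[i]) <= w * poor$length[i])
      if (length(cand)) break
      w <- w * 2
      warning("no length-matched control within +/-", window * 100,
              "% for gene '", poor$gene[i], "'; window widened")
      if (w > 100) stop("no unused control genes left")
    }
    d <- abs(controls$length[cand] - poor$length[i])
    best <- cand[d == min(d)]
    pick[i] <- if (length(best) == 1) best else sample(best, 1)
    used[pick[i]] <- TRUE
  }
  gc_poor <- poor$gc_fraction
  gc_ctrl <- controls$gc_fraction[pick]
  tt <- stats::t.test(gc_poor, gc_ctrl, var.equal = FALSE)
  list(mean_poor = mean(gc_poor), mean_control = mean(gc_ctrl),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       matches = data.frame(gene = poor$gene, control = controls$gene[pick],
                            stringsAsFactors = FALSE))
}
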