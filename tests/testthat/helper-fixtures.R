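## Small constructors used across tests ------------------------------------

make_sv_sites <- function(chrom, start, svtype, svlen, id = NULL) {
  svtype <- rep_len(svtype, length(start))
  svlen <- rep_len(svlen, length(start))
  end <- ifelse(svtype == "INS", start, start + svlen)
  if (is.null(id)) id <- sprintf("v%03d", seq_along(start))
  data.frame(chrom = rep_len(chrom, length(start)),
             start = as.integer(start), end = as.integer(end),
             svtype = svtype, svlen = as.integer(svlen), id = id,
             filter = rep_len("PASS", length(start)),
             stringsAsFactors = FALSE)
}

## sv_set with explicit per-sample genotypes and optional read support
make_sv_set <- function(sites, gt, dp = NULL, ad_alt = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(sites)
  if (is.null(dp)) dp <- matrix(20L, n, ncol(gt))
  if (is.null(ad_alt)) {
    p <- c("0/0" = 0, "0/1" = 0.5, "1/1" = 1)[gt]
    p[is.na(p)] <- 0
    ad_alt <- matrix(as.integer(round(dp * p)), n, ncol(gt))
  }
  colnames(dp) <- colnames(ad_alt) <- colnames(gt)
  sv_set(sites, gt, dp, dp - ad_alt, ad_alt)
}

make_snv_set <- function(chrom, pos, ref, alt, gt, qual = 50,
                         func_class = "other", gene = NA_character_,
                         dp = NULL, ad_alt = NULL) {
  sites <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                      alt = alt, qual = qual, func_class = func_class,
                      gene = gene, stringsAsFactors = FALSE)
  gt <- as.matrix(gt)
  n <- nrow(sites)
  if (is.null(dp)) dp <- matrix(20L, n, ncol(gt))
  if (is.null(ad_alt)) {
    p <- c("0/0" = 0, "0/1" = 0.5, "1/1" = 1)[gt]
    p[is.na(p)] <- 0
    ad_alt <- matrix(as.integer(round(dp * p)), n, ncol(gt))
  }
  colnames(dp) <- colnames(ad_alt) <- colnames(gt)
  snv_set(sites, gt, dp, dp - ad_alt, ad_alt)
}

trio1 <- list(proband = "P", father = "F", mother = "M")

## Brute-force oracles ------------------------------------------------------

## allele-transmission oracle: enumerate every (paternal, maternal)
## transmission and check the child's unordered genotype
oracle_mendelian <- function(child, father, mother) {
  parse <- function(g) {
    if (is.na(g) || g %in% c(".", "./.")) return(NULL)
    as.integer(strsplit(g, "[/|]")[[1]])
  }
  ca <- parse(child); fa <- parse(father); ma <- parse(mother)
  if (is.null(ca) || is.null(fa) || is.null(ma)) return("uncounted")
  for (f in fa) for (m in ma)
    if (identical(sort(ca), sort(c(f, m)))) return("consistent")
  "violation"
}

## per-base bitmap oracle for region-set algebra on small contigs
bitmap_from_df <- function(df, contig_len) {
  bm <- lapply(contig_len, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i])
      bm[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  bm
}

bitmap_of_regions <- function(gr, contig_len) {
  bitmap_from_df(regions_df(gr), contig_len)
}

## maximum bipartite matching by augmenting paths (Kuhn's algorithm)
oracle_max_matching <- function(adj, n_base, n_comp) {
  match_comp <- rep(0L, n_comp)
  try_kuhn <- function(b, visited) {
    for (c in which(adj[b, ])) {
      if (!visited[c]) {
        visited[c] <- TRUE
        if (match_comp[c] == 0L) {
          match_comp[c] <<- b
          return(TRUE)
        }
        saved <- match_comp[c]
        match_comp[c] <<- 0L
        if (try_kuhn(saved, visited)) {
          match_comp[c] <<- b
          return(TRUE)
        }
        match_comp[c] <<- saved
      }
    }
    FALSE
  }
  tp <- 0L
  for (b in seq_len(n_base))
    if (try_kuhn(b, logical(n_comp))) tp <- tp + 1L
  tp
}

## Analytic oracles for the simulator ---------------------------------------

## P(detected) under depth ~ Poisson(coverage), alt ~ Binomial(depth, p)
oracle_detection_prob <- function(coverage, p_alt, k) {
  dmax <- stats::qpois(1 - 1e-13, coverage)
  d <- 0:dmax
  sum(stats::dpois(d, coverage) *
        stats::pbinom(k - 1, d, p_alt, lower.tail = FALSE))
}

## P(called genotype | true genotype) under the simulator's error model;
## dropout applies only to true heterozygous parental calls
oracle_call_probs <- function(true_code, e, d = 0) {
  p <- rep(e / 2, 3)
  p[true_code + 1] <- 1 - e
  if (d > 0 && true_code == 1) p <- (1 - d) * p + d * c(1, 0, 0)
  p
}

## expected P(Mendelian violation | true trio genotype codes) after the
## error/dropout processes; uses the transmission oracle, not the package
oracle_violation_matrix <- function(e, d) {
  gts <- c("0/0", "0/1", "1/1")
  viol <- array(0, c(3, 3, 3))
  for (tc in 0:2) for (tf in 0:2) for (tm in 0:2) {
    pc <- oracle_call_probs(tc, e, 0)
    pf <- oracle_call_probs(tf, e, d)
    pm <- oracle_call_probs(tm, e, d)
    pv <- 0
    for (cc in 0:2) for (cf in 0:2) for (cm in 0:2) {
      if (oracle_mendelian(gts[cc + 1], gts[cf + 1], gts[cm + 1]) ==
          "violation")
        pv <- pv + pc[cc + 1] * pf[cf + 1] * pm[cm + 1]
    }
    viol[tc + 1, tf + 1, tm + 1] <- pv
  }
  viol
}
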