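sv_row <- function(start, svlen, svtype = "DEL") {
  make_sv_sites("chr1", start, svtype, svlen)
}

test_that("pairwise SV match rule applies distance, size-ratio and type", {
  p <- match_params()
  expect_true(sv_pair_matches(sv_row(1000, 100), sv_row(1500, 100), p))
  ## same coordinates, different type
  expect_false(sv_pair_matches(sv_row(1000, 100, "DEL"),
                               sv_row(1000, 100, "INS"), p))
  expect_true(sv_pair_matches(sv_row(1000, 100, "DEL"),
                              sv_row(1000, 100, "INS"),
                              match_params(require_same_type = FALSE)))
  ## size ratio boundary is inclusive at exactly 0.7
  expect_true(sv_pair_matches(sv_row(1000, 70), sv_row(1000, 100), p))
  expect_false(sv_pair_matches(sv_row(1000, 69), sv_row(1000, 100), p))
  ## breakpoint distance boundary
  expect_true(sv_pair_matches(sv_row(1000, 100), sv_row(2000, 100), p))
  expect_false(sv_pair_matches(sv_row(1000, 100), sv_row(2001, 100), p))
})

random_callset <- function(n, seed, contig = "chr1", spread = 1e6) {
  set.seed(seed)
  start <- sort(as.integer(floor(runif(n) * spread)))
  svtype <- sample(c("DEL", "INS"), n, replace = TRUE)
  svlen <- as.integer(50 + floor(rexp(n, 1 / 300)))
  gt <- matrix("0/1", n, 1, dimnames = list(NULL, "S"))
  make_sv_set(make_sv_sites(contig, start, svtype, svlen), gt)
}

test_that("matching a call set against itself is perfect", {
  x <- random_callset(40, seed = 1)
  res <- match_callsets(x, x)
  expect_equal(res$tp, n_sites(filter_min_sv_size(x)))
  expect_equal(res$fp, 0)
  expect_equal(res$fn, 0)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
})

test_that("a subset comparison yields recall = fraction, precision 1", {
  x <- random_callset(10, seed = 2, spread = 1e7)
  sub <- x[c(1, 3, 4, 6, 8, 10)]
  res <- match_callsets(x, sub)
  expect_equal(res$recall, 0.6)
  expect_equal(res$precision, 1)
})

test_that("empty call sets give NA precision/recall, not zero", {
  x <- random_callset(5, seed = 3)
  e <- x[integer(0)]
  expect_true(is.na(match_callsets(x, e)$precision))
  expect_equal(match_callsets(x, e)$recall, 0)
  expect_true(is.na(match_callsets(e, x)$recall))
  res <- match_callsets(e, e)
  expect_true(is.na(res$precision) && is.na(res$recall))
})

test_that("disjoint contig namespaces warn and return an empty result", {
  a <- random_callset(5, seed = 4, contig = "chr1")
  b <- random_callset(5, seed = 5, contig = "chr2")
  expect_warning(res <- match_callsets(a, b), "no shared contigs")
  expect_equal(res$tp, 0)
})

test_that("swapping base and comp swaps precision and recall", {
  for (seed in 1:5) {
    a <- random_callset(15, seed = seed)
    b <- random_callset(12, seed = seed + 100)
    r1 <- match_callsets(a, b)
    r2 <- match_callsets(b, a)
    expect_equal(r1$tp, r2$tp)
    expect_equal(r1$precision, r2$recall)
    expect_equal(r1$recall, r2$precision)
  }
})

test_that("tp is monotone in refdist and in lowering the size-ratio floor", {
  a <- random_callset(25, seed = 6, spread = 2e5)
  b <- random_callset(25, seed = 7, spread = 2e5)
  tp <- vapply(c(100, 500, 1000, 5000), function(rd)
    match_callsets(a, b, match_params(refdist = rd))$tp, 0)
  expect_true(all(diff(tp) >= 0))
  tp2 <- vapply(c(0.9, 0.7, 0.5, 0.1), function(r)
    match_callsets(a, b, match_params(size_ratio_min = r))$tp, 0)
  expect_true(all(diff(tp2) >= 0))
})

test_that("reciprocal overlap comparison applies the 50% rule inclusively", {
  sites <- make_sv_sites("chr1", c(100, 100, 100), "DEL", c(100, 100, 100))
  gt <- matrix("0/1", 3, 1, dimnames = list(NULL, "S"))
  calls <- make_sv_set(sites, gt)
  ## [100,200) vs [150,250): overlap 50 = 50% of both -> matched
  ext1 <- list(DEL = region_set("chr1", 150L, 250L))
  expect_true(reciprocal_overlap_compare(calls[1], ext1)[1])
  ## [100,200) vs [100,120): reciprocity fails
  ext2 <- list(DEL = region_set("chr1", 100L, 120L))
  expect_false(reciprocal_overlap_compare(calls[1], ext2)[1])
  ## identical interval
  ext3 <- list(DEL = region_set("chr1", 100L, 200L))
  expect_true(reciprocal_overlap_compare(calls[1], ext3)[1])
  ## insertions: anchor within refdist and size ratio >= frac
  ins <- make_sv_set(make_sv_sites("chr1", 5000, "INS", 300),
                     matrix("0/1", 1, 1, dimnames = list(NULL, "S")))
  expect_true(reciprocal_overlap_compare(
    ins, list(INS = region_set("chr1", 5400L, 5700L))))
  expect_false(reciprocal_overlap_compare(
    ins, list(INS = region_set("chr1", 6500L, 6800L))))
  expect_false(reciprocal_overlap_compare(
    ins, list(INS = region_set("chr1", 5400L, 5500L))))
})

test_that("SNV set comparison is an exhaustive disjoint partition", {
  a <- make_snv_set("chr1", c(100, 200, 300), "A", "G",
                    matrix("0/1", 3, 1, dimnames = list(NULL, "S")))
  b <- make_snv_set("chr1", c(200, 300, 400), "A", "G",
                    matrix("0/1", 3, 1, dimnames = list(NULL, "S")))
  cmp <- snv_set_compare(a, b)
  expect_equal(unname(cmp$counts), c(2, 1, 1))
  expect_equal(cmp$counts[["shared"]] + cmp$counts[["only_a"]], n_sites(a))
  expect_equal(cmp$counts[["shared"]] + cmp$counts[["only_b"]], n_sites(b))
  same <- snv_set_compare(a, a)
  expect_equal(n_sites(same$only_a), 0)
  expect_equal(n_sites(same$only_b), 0)
  ## same position, different alt allele is not shared
  b2 <- make_snv_set("chr1", 100, "A", "C",
                     matrix("0/1", 1, 1, dimnames = list(NULL, "S")))
  expect_equal(snv_set_compare(a, b2)$counts[["shared"]], 0L)
})

test_that("Ti/Tv ratio counts transitions over transversions", {
  x <- make_snv_set("chr1", 1:6, c("A", "G", "C", "T", "A", "C"),
                    c("G", "A", "T", "C", "C", "A"),
                    matrix("0/1", 6, 1, dimnames = list(NULL, "S")))
  expect_equal(ti_tv_ratio(x), 2.0)
  only_ti <- make_snv_set("chr1", 1:2, c("A", "C"), c("G", "T"),
                          matrix("0/1", 2, 1, dimnames = list(NULL, "S")))
  expect_true(is.na(ti_tv_ratio(only_ti)))
  expect_true(is.na(ti_tv_ratio(only_ti[integer(0)])))
})
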