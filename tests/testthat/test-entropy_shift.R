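dist16 <- function(...) {
  idx <- list(...)
  p <- numeric(16)
  for (iv in idx) p[iv[1] + 1] <- iv[2]
  p
}

patterns_from_dist <- function(p, depth = 100, chrom = "chr1",
                               positions = c(100L, 110L, 120L, 130L)) {
  make_patterns(round(p * depth), chrom, positions)
}

test_that("delta-S algebra: zero on identity, antisymmetric when signed", {
  set.seed(5)
  counts <- random_counts(60, 120)
  a <- make_patterns(counts)
  cmp <- compare_samples(a, a)
  expect_equal(cmp$comparisons$delta_s, 0)
  expect_false(cmp$comparisons$is_elocus)

  b <- make_patterns(random_counts(60, 120))
  ab <- compare_samples(a, b)$comparisons$delta_s
  ba <- compare_samples(b, a)$comparisons$delta_s
  expect_equal(ab, -ba)

  cfg_abs <- epishift_config(elocus_on_absolute_delta_s = TRUE)
  ab2 <- compare_samples(a, b, cfg_abs)
  ba2 <- compare_samples(b, a, cfg_abs)
  star_ab <- -abs(ab2$comparisons$delta_s)
  star_ba <- -abs(ba2$comparisons$delta_s)
  expect_equal(star_ab, star_ba)
  expect_lte(star_ab, 0)
})

test_that("a single-pattern to uniform shift is an elocus at -70", {
  a <- make_patterns({ x <- numeric(16); x[1] <- 64; x })
  b <- make_patterns(rep(4, 16))
  cmp <- compare_samples(a, b)
  expect_equal(cmp$comparisons$delta_s, -100)
  expect_true(cmp$comparisons$is_elocus)
  # the reverse shift (entropy loss) only qualifies in absolute mode
  rev_signed <- compare_samples(b, a)
  expect_false(rev_signed$comparisons$is_elocus)
  rev_abs <- compare_samples(b, a,
                             epishift_config(elocus_on_absolute_delta_s = TRUE))
  expect_true(rev_abs$comparisons$is_elocus)
})

test_that("the elocus threshold is strict and monotone", {
  mk <- function(s_target) {
    # one dominant pattern at weight w, the rest uniform; solve for the
    # weight whose Shannon entropy matches s_target on the 25-per-bit scale
    h <- -s_target / 25
    f <- function(w)
      -(w * log2(w) + (1 - w) * log2((1 - w) / 15)) - h
    w <- uniroot(f, c(1 / 16 + 1e-9, 1 - 1e-9))$root
    p <- rep((1 - w) / 15, 16); p[1] <- w
    p
  }
  a <- make_patterns({ x <- numeric(16); x[1] <- 1000; x })
  # delta_s exactly -70: strict rule means not an elocus
  b70 <- patterns_from_dist(mk(-70), depth = 1e6)
  cmp70 <- compare_samples(a, b70)
  expect_equal(cmp70$comparisons$delta_s, -70, tolerance = 1e-3)
  # setting the threshold exactly at the observed shift exercises strictness
  expect_false(compare_samples(a, b70,
    epishift_config(elocus_delta_s_threshold =
                      cmp70$comparisons$delta_s))$comparisons$is_elocus)

  set.seed(9)
  loci <- make_patterns_multi(replicate(40, random_counts(60, 100),
                                        simplify = FALSE))
  loci2 <- make_patterns_multi(replicate(40, random_counts(60, 100),
                                         simplify = FALSE))
  el_at <- function(thr) {
    cfg <- epishift_config(elocus_delta_s_threshold = thr)
    cmp <- compare_samples(loci, loci2, cfg)
    cmp$comparisons$locus_id[cmp$comparisons$is_elocus]
  }
  e60 <- el_at(-60); e70 <- el_at(-70); e90 <- el_at(-90)
  expect_true(all(e70 %in% e60))
  expect_true(all(e90 %in% e70))
})

test_that("EPM is homogeneous and linear in E", {
  expect_equal(epm(0, 1e6), 0)
  expect_equal(epm(250, 1e6), 250)
  expect_equal(epm(1, 2e6), 0.5)
  expect_equal(epm(100, 5e4), epm(200, 1e5))
  expect_equal(epm(200, 1e5), 2 * epm(100, 1e5))
  expect_error(epm(1, 0), "C = 0")
  expect_error(epm(5, 3), "0 <= E <= C")
})

test_that("no shared loci gives C = 0 and a missing EPM, not zero", {
  a <- make_patterns(rep(4, 16), positions = c(100L, 110L, 120L, 130L))
  b <- make_patterns(rep(4, 16), positions = c(500L, 510L, 520L, 530L))
  cmp <- compare_samples(a, b)
  expect_equal(cmp$C, 0L)
  expect_true(is.na(cmp$epm))
})

test_that("methylation direction uses the 25% rule inclusively", {
  a <- patterns_from_dist(dist16(c(0, 1)))                      # meth 0
  hyper <- patterns_from_dist(dist16(c(0, 0.75), c(15, 0.25)))  # meth 0.25
  cmp <- compare_samples(a, hyper)
  expect_equal(cmp$comparisons$meth_diff, 0.25)
  expect_equal(cmp$comparisons$direction, "hyper")
  below <- patterns_from_dist(dist16(c(0, 0.76), c(15, 0.24)))
  expect_equal(compare_samples(a, below)$comparisons$direction, "none")
  hypo <- compare_samples(hyper, a)
  expect_equal(hypo$comparisons$direction, "hypo")
})

test_that("consensus eloci require the flag against every control", {
  single <- make_patterns({ x <- numeric(16); x[1] <- 64; x })
  uniform <- make_patterns(rep(4, 16))
  shifted <- compare_samples(single, uniform)     # elocus
  flat <- compare_samples(uniform, uniform)       # not an elocus
  expect_equal(consensus_eloci(list(shifted, shifted, shifted)),
               shifted$comparisons$locus_id)
  expect_equal(length(consensus_eloci(list(shifted, shifted, flat))), 0L)
  expect_equal(length(consensus_eloci(list(flat, flat, flat))), 0L)
  expect_error(consensus_eloci(list(shifted, shifted)), "exactly 3")
})

test_that("pattern-change classification follows the 30/70 definitions", {
  cfg <- epishift_config()
  uni <- rep(1 / 16, 16)
  single_a <- dist16(c(3, 1))
  single_b <- dist16(c(12, 1))
  expect_equal(classify_change(uni, single_a, cfg), "selection")
  expect_equal(classify_change(single_a, uni, cfg), "disorder")
  expect_equal(classify_change(single_a, single_b, cfg), "switch")
  expect_equal(classify_change(uni, uni, cfg), "disorder_maintenance")
  # same dominant pattern at both stages fails the switch definition
  expect_equal(classify_change(single_a, single_a, cfg), "unclassified")
})

test_that("classification thresholds are strict at 0.30 and 0.70", {
  cfg <- epishift_config()
  spread <- function(top) {
    p <- rep((1 - top) / 15, 16); p[1] <- top
    p
  }
  expect_equal(classify_change(spread(0.29), spread(0.29), cfg),
               "disorder_maintenance")
  # a 0.30 or 0.31 maximum is not "all patterns below 30%"
  expect_equal(classify_change(spread(0.30), spread(0.29), cfg),
               "unclassified")
  expect_equal(classify_change(spread(0.31), spread(0.29), cfg),
               "unclassified")
  # 0.70 is not "above 70%"
  expect_equal(classify_change(spread(0.29), spread(0.70), cfg),
               "unclassified")
  expect_equal(classify_change(spread(0.29), spread(0.71), cfg), "selection")
  expect_equal(classify_change(spread(0.71), spread(0.29), cfg), "disorder")
})

test_that("category fractions are computed over eloci and sum to one", {
  cmp <- data.frame(
    locus_id = paste0("l", 1:5),
    is_elocus = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    category = c("selection", "switch", "switch", "unclassified", "disorder"),
    stringsAsFactors = FALSE)
  fr <- category_fractions(cmp)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["selection"]), 0.25)
  expect_equal(unname(fr["switch"]), 0.5)
  expect_equal(unname(fr["disorder"]), 0)
  one <- category_fractions(data.frame(locus_id = "l1", is_elocus = TRUE,
                                       category = "disorder_maintenance"))
  expect_equal(unname(one["disorder_maintenance"]), 1)
  expect_error(category_fractions(cmp[5, ]), "no eloci")
})
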