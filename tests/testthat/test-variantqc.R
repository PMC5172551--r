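test_that("score thresholding is inclusive, monotone and validated", {
  calls <- data.frame(ss = c(0.1, 0.09, 0.5, 0.1), ts = c(100, 1e6, 99, 101))
  expect_equal(classify_wgs(calls), c("high", "low", "low", "high"))
  expect_error(classify_wgs(data.frame(ss = Inf, ts = 100)), "finite")
  expect_error(classify_wgs(data.frame(ts = 100)), "ss")

  # monotonicity: raising either score never turns high into low
  set.seed(1)
  base <- data.frame(ss = runif(50), ts = runif(50, 0, 200))
  before <- classify_wgs(base)
  for (bump in list(c(0.2, 0), c(0, 50), c(0.1, 10))) {
    after <- classify_wgs(data.frame(ss = base$ss + bump[1],
                                     ts = base$ts + bump[2]))
    expect_false(any(before == "high" & after == "low"))
  }
})

test_that("ROC rates agree with exhaustive quadrant counting", {
  calls <- gen_wgs_calls(sim_config(seed = 7))
  roc <- roc_curve(calls)
  for (i in sample(nrow(roc$roc_points), 50)) {
    pt <- roc$roc_points[i, ]
    high <- calls$ss >= pt$ss & calls$ts >= pt$ts
    expect_equal(pt$tpr, sum(high & calls$truth) / sum(calls$truth))
    expect_equal(pt$fpr, sum(high & !calls$truth) / sum(!calls$truth))
  }
  # separable clouds admit a perfect operating point
  sep <- gen_wgs_calls(sim_config(seed = 7, score_sd = 0))
  rs <- roc_curve(sep)
  expect_true(any(rs$roc_points$tpr == 1 & rs$roc_points$fpr == 0))
  # a one-pair grid yields one ROC point
  expect_equal(nrow(roc_curve(calls, grid = data.frame(ss = 0.1, ts = 100))$roc_points), 1L)
  expect_error(roc_curve(data.frame(ss = 1, ts = 1, truth = TRUE)), "both")
})

test_that("WGS somatic filtering removes polymorphisms, remission calls and synonymous calls", {
  calls <- data.frame(
    chrom = c("1", "1", "2", "3"), pos = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "T",
    consequence = c("non-synonymous", "non-synonymous", "synonymous",
                    "non-synonymous"),
    stringsAsFactors = FALSE
  )
  attr(calls, "genome_build") <- "36"
  poly <- polymorphism_index(data.frame(chrom = "1", pos = 200L,
                                        ref = "A", alt = "T"))
  remission <- data.frame(chrom = "3", pos = 400L, ref = "A", alt = "T")
  attr(remission, "genome_build") <- "36"
  out <- filter_wgs_somatic(calls, poly, remission)
  expect_equal(out$pos, 100L)

  wrong_build <- remission
  attr(wrong_build, "genome_build") <- "37"
  expect_error(filter_wgs_somatic(calls, poly, wrong_build), "build")
})

test_that("one-class boundary calibrates to the chi-square limit", {
  set.seed(99)
  pts <- make_points(matrix(rnorm(2 * 10000), ncol = 2),
                     matrix(rnorm(4, mean = 30), ncol = 2))
  b <- fit_one_class(pts, target_fnr = 0.10)
  expect_lt(abs(b$radius2 - qchisq(0.90, df = 2)) / qchisq(0.90, df = 2), 0.05)
  expect_lte(b$fnr, 0.10)
  expect_equal(b$fpr, 0)  # FP cluster 30 SDs away
})

test_that("one-class boundary never exceeds its target FNr on training data", {
  for (seed in 1:8) {
    for (target in c(0.05, 0.10, 0.25)) {
      pts <- gen_tes_quality(120, 80, sim_config(seed = seed))
      b <- fit_one_class(pts, target_fnr = target)
      expect_lte(b$fnr, target)
    }
  }
})

test_that("one-class boundary handles the degenerate identical-TP case", {
  pts <- make_points(matrix(5, nrow = 10, ncol = 2),
                     matrix(rnorm(20, 50), ncol = 2))
  b <- fit_one_class(pts, target_fnr = 0.10)
  expect_equal(b$radius2, 0)
  expect_equal(b$fnr, 0)
  expect_true(all(predict(b, pts[pts$label == "TP", ])))
})

test_that("rule boundary matches brute-force enumeration on small fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    pts <- make_points(cbind(rnorm(10, 30, 8), rnorm(10, 60, 15)),
                       cbind(rnorm(10, 18, 8), rnorm(10, 35, 15)))
    rb <- fit_rule_boundary(pts, target_fnr = 0.10)
    expect_equal(rb$fpr, rule_bruteforce_fpr(pts, 0.10))
    expect_lte(rb$fnr, 0.10)
  }
})

test_that("rule boundary separates separable clouds and degrades on overlap", {
  sep <- make_points(cbind(rnorm(40, 100, 2), rnorm(40, 100, 2)),
                     cbind(rnorm(40, 10, 2), rnorm(40, 10, 2)))
  expect_equal(fit_rule_boundary(sep, 0.10)$fpr, 0)
  # overlapping INDEL-like clouds: FPr well above the SNV setting
  snv <- fit_rule_boundary(gen_tes_quality(config = sim_config(seed = 1)), 0.10)
  indel <- fit_rule_boundary(gen_tes_quality(11, 41, sim_config(seed = 1),
                                             kind = "indel"), 0.10)
  expect_gt(indel$fpr, snv$fpr + 0.2)
})

test_that("TES filtering applies inclusive depth/VAF cutoffs with hotspot rescue", {
  calls <- data.frame(
    chrom = "1", pos = 1:6, ref = "A", alt = "T",
    class = c("snv", "snv", "ins", "del", "snv", "snv"),
    depth = c(9, 10, 5, 4, 50, 50),
    vaf = c(0.5, 0.30, 0.30, 0.5, 0.29, 0.6),
    gene = "JAK1", aa_pos = c(1, 1, 1, 1, 1, 724),
    stringsAsFactors = FALSE
  )
  out <- filter_tes(calls)
  expect_equal(out$pos, c(2L, 3L, 6L))  # 9x SNV, 4x INDEL, VAF 0.29 dropped

  # polymorphism hit dropped unless its amino acid is hotspot-annotated
  poly <- polymorphism_index(
    data.frame(chrom = "1", pos = c(2L, 6L), ref = "A", alt = "T"),
    cosmic = data.frame(gene = "JAK1", aa_pos = 724)
  )
  out2 <- filter_tes(calls, poly)
  expect_equal(out2$pos, c(3L, 6L))

  expect_error(filter_tes(transform(calls, class = "weird")), "unknown")
})

test_that("filtering is idempotent", {
  calls <- gen_wgs_calls(sim_config(seed = 12))
  calls$depth <- sample(1:60, nrow(calls), replace = TRUE)
  calls$vaf <- runif(nrow(calls))
  poly <- polymorphism_index(calls[1:5, c("chrom", "pos", "ref", "alt")])
  once <- filter_tes(calls, poly)
  expect_identical(filter_tes(once, poly), once)
  once_w <- filter_wgs_somatic(calls, poly)
  expect_identical(filter_wgs_somatic(once_w, poly), once_w)
})
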