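toy_cohort <- function() {
  data.frame(
    patient = c("A", "B", "C", "D"),
    subtype = c("ETP-ALL", "TLX", "TALLMO", "TALLMO"),
    lc50 = c(10, 20, 1, 2),
    time = c(12, 24, 60, 80),
    event = c(TRUE, TRUE, FALSE, FALSE),
    nr3c1_del = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

test_that("feature matrix aggregates lesions and masks missing aCGH", {
  cohort <- toy_cohort()
  mutations <- data.frame(patient = c("A", "A", "B"),
                          gene = c("JAK1", "JAK1", "PTEN"))
  cn <- data.frame(patient = c("B", "C"), gene = c("JAK1", "PTEN"),
                   direction = c("deletion", "amplification"))
  f <- build_features(mutations, cn, cohort,
                      cn_patients = c("A", "B", "C"))  # D lacks aCGH
  get <- function(g, p) f[f$gene == g & f$patient == p, ]

  # two JAK1 mutations in one patient collapse to one presence
  expect_true(get("JAK1", "A")$Mut)
  expect_false(get("JAK1", "A")$Del)
  expect_true(get("JAK1", "A")$MutAber)
  # deletion only
  jb <- get("JAK1", "B")
  expect_false(jb$Mut); expect_true(jb$Del); expect_true(jb$MutDel)
  expect_false(jb$MutAmp)
  # missing copy-number data: Del/Amp NA, unions follow three-valued logic
  jd <- get("JAK1", "D")
  expect_true(is.na(jd$Del) && is.na(jd$Amp) && is.na(jd$MutAber))
  pd <- get("PTEN", "B")
  expect_true(pd$Mut && pd$MutAber)  # TRUE even though Del is known FALSE

  # logical identities hold wherever defined
  ok <- !is.na(f$Del) & !is.na(f$Amp)
  expect_equal(f$MutAber[ok], (f$Mut | f$Del | f$Amp)[ok])
  expect_equal(f$MutDel[ok], (f$Mut | f$Del)[ok])
  expect_equal(f$MutAmp[ok], (f$Mut | f$Amp)[ok])

  expect_error(build_features(data.frame(patient = "Z", gene = "X"),
                              cn, cohort), "unknown patient")
})

test_that("Fisher association matches hypergeometric enumeration", {
  # the canonical 3/0 vs 0/3 split
  p <- assoc_subtype(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     c("a", "a", "a", "b", "b", "b"))$p
  expect_equal(p, 0.1, tolerance = 1e-12)
  # identical distribution across groups
  expect_equal(assoc_subtype(c(TRUE, FALSE, TRUE, FALSE),
                             c("a", "a", "b", "b"))$p, 1)
  # random small tables vs full enumeration
  set.seed(41)
  for (i in 1:40) {
    n <- sample(6:10, 1)
    feat <- sample(c(TRUE, FALSE), n, replace = TRUE)
    grp <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(feat)) < 2 || length(unique(grp)) < 2) next
    tab <- table(factor(feat, c(FALSE, TRUE)), factor(grp))
    expect_equal(assoc_subtype(feat, grp)$p, fisher_2x2_enum(tab),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis matches the hand rank formula and validates groups", {
  r <- assoc_lc50(factor(rep(c("g1", "g2"), each = 3)), c(1, 2, 3, 4, 5, 6))
  expect_equal(r$stat, 27 / 7, tolerance = 1e-12)  # fully separated ranks
  expect_error(assoc_lc50(factor(c("a", "a")), c(1, 2)), "two")
  expect_error(assoc_lc50(factor(c("a", "a", "b"), levels = c("a", "b")),
                          c(1, 2, NA)), "non-empty")
})

test_that("log-rank matches manual risk-set accounting", {
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  grp <- rep(c("a", "b"), each = 4)
  r <- assoc_survival(grp, time, event)
  expect_equal(r$stat, logrank_manual(time, event, grp), tolerance = 1e-10)
  # identical survival in both groups: chi-square 0, p 1
  same <- assoc_survival(rep(c("a", "b"), 4), rep(1:4, each = 2),
                         rep(TRUE, 8))
  expect_equal(same$stat, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(assoc_survival(grp, time, rep(FALSE, 8)), "event")
})

test_that("Mann-Whitney matches exact enumeration and the n=8 approximation", {
  expect_equal(group_compare(1:3, 4:6), 0.1, tolerance = 1e-12)
  expect_equal(group_compare(c(1, 2), c(1.5, 2.5)), mw_enum(c(1, 2), c(1.5, 2.5)),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    a <- round(rnorm(sample(3:8, 1)), 6)
    b <- round(rnorm(sample(3:8, 1), 0.5), 6)
    expect_equal(group_compare(a, b), mw_enum(a, b), tolerance = 1e-12)
  }
  # identical groups
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-6)
  # exact and normal approximation agree reasonably at n = 8
  a <- rnorm(8); b <- rnorm(8, 1)
  exact_p <- mw_enum(a, b)
  approx_p <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_lt(abs(exact_p - approx_p), 0.02)
  expect_error(group_compare(numeric(0), 1:3), "non-empty")
})

test_that("pathway grouping applies the precedence rule", {
  lesions <- data.frame(patient = c("A", "A", "B", "C"),
                        gene = c("JAK1", "PTEN", "PTEN", "NOTCH1"))
  g <- group_pathway(lesions, patients = c("A", "B", "C", "D"))
  expect_equal(as.character(g), c("pathway", "PTEN", "rest", "rest"))
  g2 <- group_pathway(lesions, patients = c("A", "B", "C", "D"),
                      precedence = "pten")
  expect_equal(as.character(g2)[1], "PTEN")
})

test_that("NR3C1-deleted patients are excluded with an audited count", {
  cohort <- toy_cohort()
  expect_message(out <- exclude_nr3c1_deleted(cohort), "1 of 4")
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_excluded"), 1L)
  none <- cohort[cohort$patient != "C", ]
  expect_identical(exclude_nr3c1_deleted(none, quiet = TRUE)$patient,
                   none$patient)
})

test_that("the association screen flags planted effects and reports test counts", {
  cfg <- sim_config(seed = 51, lc50_fold = 8, hazard_ratio = 3)
  co <- gen_cohort(120, prevalence = 0.4, config = cfg)
  lesions <- attr(co, "lesions")
  feats <- build_features(lesions, data.frame(patient = character(0),
                                              gene = character(0),
                                              direction = character(0)),
                          co, cn_patients = character(0))
  # collapse to pathway-level by testing the strongest single gene and the
  # pooled mutation indicator
  res <- screen_all(feats, co)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$flag, res$p < 0.05)
  expect_named(attr(res, "n_tests"))
  pooled_p <- assoc_lc50(co$pathway_mut, co$lc50)$p
  expect_lt(pooled_p, 0.001)  # planted 8-fold LC50 effect is detected

  empty <- screen_all(feats[0, ], co[0, ])
  expect_equal(nrow(empty), 0L)
})
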