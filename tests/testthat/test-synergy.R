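test_that("viability normalization switches denominator for combination wells", {
  expect_equal(normalize_viability(500, 500), 100)
  expect_equal(normalize_viability(0, 500), 0)
  # inhibitor-treated control at 80% of untreated changes results by 1/0.8
  expect_equal(normalize_viability(400, 500, inhibitor_control = 400),
               normalize_viability(400, 500) / 0.8)
  expect_error(normalize_viability(1, 0), "positive")
})

test_that("4PL fitting recovers exact curves and is scale-equivariant", {
  conc <- 100 * 10^seq(1, -2, length.out = 9)
  v <- 100 / (1 + (conc / 100))
  fit <- fit_dose_response(conc, v)
  expect_equal(fit$ic50, 100, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["slope"]]), 1, tolerance = 1e-6)
  expect_equal(fit$max_effect, 100, tolerance = 1e-6)
  # locked asymptotes preferred on data consistent with them
  expect_true(fit$params$locked_top && fit$params$locked_bottom)

  fit10 <- fit_dose_response(conc * 10, v)
  expect_equal(fit10$ic50, 1000, tolerance = 1e-5)

  expect_error(fit_dose_response(c(1, 10, 100), c(90, 50, 10)), "4 distinct")
  expect_error(fit_dose_response(c(-1, 1, 10, 100), c(99, 90, 50, 10)),
               "positive")
})

test_that("low-efficacy curves yield a not-determined IC50", {
  conc <- 100 * 10^seq(1, -2, length.out = 9)
  v <- 100 - 15 / (1 + (100 / conc))  # max effect 15% < 20%
  fit <- fit_dose_response(conc, v)
  expect_true(fit$nd)
  expect_true(is.na(fit$ic50))
  expect_lt(fit$max_effect, 20)
})

test_that("duplicate wells are averaged before fitting", {
  conc <- rep(100 * 10^seq(1, -2, length.out = 7), each = 2)
  v_true <- 100 / (1 + conc / 100)
  v <- v_true + rep(c(-3, 3), times = 7)  # duplicates straddle the curve
  fit <- fit_dose_response(conc, v)
  expect_equal(fit$ic50, 100, tolerance = 1e-4)
})

test_that("mixture designs follow the equipotent anchor composition", {
  des <- design_mixtures(100, 100)
  expect_equal(vapply(des, `[[`, character(1), "ratio"),
               c("1:1", "4:1", "1:4"))
  expect_equal(des[[1]]$anchor, 100)      # 50 + 50
  expect_equal(des[[1]]$frac_a, 0.5)
  expect_equal(des[[2]]$weight_a, 0.8)
  expect_equal(des[[3]]$weight_a, 0.2)
  # series endpoints at 10x and 0.01x in IC50-equivalent units
  expect_equal(max(des[[1]]$series) / des[[1]]$anchor, 10)
  expect_equal(min(des[[1]]$series) / des[[1]]$anchor, 0.01)

  des2 <- design_mixtures(40, 360, ratios = "4:1")[[1]]
  expect_equal(des2$anchor, 0.8 * 40 + 0.2 * 360)
  expect_error(design_mixtures(NA, 100), "determined")
})

test_that("the sham-combination identity holds for any curve and ratio", {
  cfg <- sim_config(seed = 61, viability_cv = 0)
  for (prm in list(c(100, 1), c(35, 0.7), c(800, 2.2))) {
    A <- hill_params(ic50 = prm[1], slope = prm[2])
    des <- design_mixtures(prm[1], prm[1])
    assay <- gen_dose_response(A, A, tau = 1, designs = des, config = cfg)
    res <- synergy_analysis(assay, des)
    expect_equal(unname(res$ci["ED50", ]), rep(1, 3), tolerance = 1e-6)
    expect_equal(unname(res$ci["ED75", ]), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("a mixture that is pure drug A at its own effect dose has CI 1", {
  A <- hill_params(ic50 = 100, slope = 1)
  B <- hill_params(ic50 = 250, slope = 1)
  conc <- 100 * 10^seq(1, -2, length.out = 9)
  fa <- fit_dose_response(conc, hill_viability(A, conc))
  fb <- fit_dose_response(250 * 10^seq(1, -2, length.out = 9),
                          hill_viability(B, 250 * 10^seq(1, -2, length.out = 9)))
  # "mixture" composed entirely of A behaves as A; frac_a = 1
  expect_equal(compute_ci(fa, fb, fa, design = 1, level = 0.5), 1,
               tolerance = 1e-6)
})

test_that("CI is NA with a reason when a curve cannot reach the effect level", {
  conc <- 100 * 10^seq(1, -2, length.out = 9)
  full <- fit_dose_response(conc, 100 / (1 + conc / 100))
  shallow <- fit_dose_response(conc, 100 - 60 / (1 + 100 / conc))  # 60% max
  ci <- compute_ci(full, full, shallow, design = 0.5, level = 0.75)
  expect_true(is.na(ci))
  expect_match(attr(ci, "reason"), "below 75")
  # but ED50 is still evaluable for the same curve
  expect_false(is.na(compute_ci(full, full, shallow, design = 0.5,
                                level = 0.5)))
})

test_that("unit rescaling leaves the combination index unchanged", {
  cfg <- sim_config(seed = 62, viability_cv = 0)
  A <- hill_params(ic50 = 100, slope = 1)
  B <- hill_params(ic50 = 250, slope = 1)
  des <- design_mixtures(100, 250)
  assay <- gen_dose_response(A, B, tau = 0.5, designs = des, config = cfg)
  res <- synergy_analysis(assay, des)
  scaled <- assay
  scaled$conc <- scaled$conc * 1000
  des_k <- design_mixtures(100 * 1000, 250 * 1000)
  res_k <- synergy_analysis(scaled, des_k)
  expect_equal(res$ci, res_k$ci, tolerance = 1e-5)
})

test_that("CI summaries follow the footnote conventions", {
  s <- summarize_ci(c(0.5, 0.6, 0.7))
  expect_equal(s$levels$mean[1], 0.6)
  expect_equal(s$levels$sd[1], 0.1)
  # fewer than three ratios: mean only, no SD
  s2 <- summarize_ci(c(0.5, 0.7))
  expect_equal(s2$levels$mean[1], 0.6)
  expect_true(is.na(s2$levels$sd[1]))
  # all NA: the level is NA
  s3 <- summarize_ci(c(NA_real_, NA_real_))
  expect_true(is.na(s3$levels$mean[1]))
  # bounds propagate
  s4 <- summarize_ci(c(0.1, 0.1), bounded_ed50 = c(TRUE, FALSE))
  expect_true(s4$levels$bounded[1])
})

test_that("synergy classification applies the published cut-offs", {
  # published rows: mean 0.13 sd 0.03 -> strong synergy
  strong <- classify_synergy(result_fixture(0.13, 0.03))
  expect_equal(strong$ed50, "strong synergy")
  expect_equal(strong$overall, "synergistic")
  # mean 0.90 sd 0.25 -> no synergy (0.9 + 0.25 >= 1)
  none <- classify_synergy(result_fixture(0.90, 0.25))
  expect_equal(none$ed50, "no synergy")
  expect_equal(none$overall, "not synergistic")
  # boundary: 0.98 + 0.01 = 0.99 < 1 -> synergy
  edge <- classify_synergy(result_fixture(0.98, 0.01))
  expect_equal(edge$ed50, "synergy")
  # antagonism is a flag, not a label
  ant <- classify_synergy(result_fixture(1.65, 0.05))
  expect_equal(ant$ed50, "no synergy")
  expect_true(ant$antagonism)
  # NA level propagates; evaluability needs one numeric or bounded CI
  na_all <- classify_synergy(summarize_ci(NA_real_, NA_real_))
  expect_true(is.na(na_all$overall))
  expect_false(na_all$evaluable)
})

test_that("the transcribed table reproduces the published per-inhibitor counts", {
  counts <- per_inhibitor_counts()
  row <- function(g) counts[counts$inhibitor == g, ]
  expect_equal(row("AZD8055")[, c("n_synergistic", "n_evaluable")],
               data.frame(n_synergistic = 10L, n_evaluable = 11L),
               ignore_attr = TRUE)
  expect_equal(row("Everolimus")[, c("n_synergistic", "n_evaluable")],
               data.frame(n_synergistic = 8L, n_evaluable = 8L),
               ignore_attr = TRUE)
  expect_equal(row("Trametinib")[, c("n_synergistic", "n_evaluable")],
               data.frame(n_synergistic = 9L, n_evaluable = 10L),
               ignore_attr = TRUE)
  expect_equal(row("MK2206")[, c("n_synergistic", "n_evaluable")],
               data.frame(n_synergistic = 8L, n_evaluable = 11L),
               ignore_attr = TRUE)
  expect_equal(row("NVPBEZ235")[, c("n_synergistic", "n_evaluable")],
               data.frame(n_synergistic = 10L, n_evaluable = 11L),
               ignore_attr = TRUE)
  expect_equal(row("Ruxolitinib")[, c("n_synergistic", "n_evaluable")],
               data.frame(n_synergistic = 0L, n_evaluable = 8L),
               ignore_attr = TRUE)
  expect_equal(unique(counts$n_samples), 11L)
})
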