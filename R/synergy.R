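# Curve-shift synergy analysis.
#
# Dose-response curves are four-parameter logistic (Hill) fits; IC50-matched
# drug mixtures are compared against the single-agent curves with the
# Chou-Talalay combination index in its mutually exclusive (two-term) form:
#   CI(x) = d_A / D_A(x) + d_B / D_B(x)
# where (d_A, d_B) is the composition of the mixture dose producing effect x
# and D_A(x), D_B(x) are the single-agent doses producing that effect. All
# effect levels are on the responding-fraction scale, i.e. normalized to each
# curve's maximal effect, so the IC50 of a 4PL fit is exactly its midpoint
# parameter. CI = 1 is additive, < 1 synergy, < 0.3 strong synergy, > 1.5
# antagonism.

#' Hill (four-parameter logistic) curve parameters
#'
#' @param top,bottom Upper and lower viability asymptotes (% of control);
#'   `top > bottom`.
#' @param ic50 Midpoint concentration (dose at 50% of the responding
#'   fraction), > 0, in the assay's declared units.
#' @param slope Hill slope, > 0.
#' @param locked_top,locked_bottom Whether the asymptote was locked rather
#'   than fitted.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(top = 100, bottom = 0, ic50, slope = 1,
                        locked_top = FALSE, locked_bottom = FALSE) {
  stopifnot(is.numeric(top), is.numeric(bottom), is.numeric(ic50),
            is.numeric(slope))
  if (!is.finite(ic50) || ic50 <= 0) stop("`ic50` must be > 0")
  if (!is.finite(slope) || slope <= 0) stop("`slope` must be > 0")
  if (top <= bottom) stop("`top` must exceed `bottom`")
  structure(list(top = top, bottom = bottom, ic50 = ic50, slope = slope,
                 max_effect = top - bottom,
                 locked_top = locked_top, locked_bottom = locked_bottom),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill curve: top %.4g%s, bottom %.4g%s, IC50 %.6g, slope %.4g (max effect %.4g%%)\n",
              x$top, if (x$locked_top) " (locked)" else "",
              x$bottom, if (x$locked_bottom) " (locked)" else "",
              x$ic50, x$slope, x$max_effect))
  invisible(x)
}

# Viability (% of control) at dose d under a 4PL curve.
hill_viability <- function(params, dose) {
  params$bottom + (params$top - params$bottom) /
    (1 + (dose / params$ic50)^params$slope)
}

# Dose producing responding fraction x in (0, 1) (effect-scale inverse).
effect_dose <- function(params, x) {
  stopifnot(x > 0, x < 1)
  params$ic50 * (x / (1 - x))^(1 / params$slope)
}

#' Normalize raw viability signal to percent of control
#'
#' Plain wells are normalized to the untreated control; combination wells
#' (drug plus a fixed inhibitor background) are normalized to the
#' inhibitor-treated control so the inhibitor's own toxicity does not enter
#' the drug's curve.
#'
#' @param raw Raw signal (e.g. luminescence).
#' @param control Untreated-control signal (> 0).
#' @param inhibitor_control Optional inhibitor-treated control signal (> 0);
#'   when supplied it replaces `control` as the denominator.
#' @return Viability in percent.
#' @export
normalize_viability <- function(raw, control, inhibitor_control = NULL) {
  denom <- inhibitor_control %||% control
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    stop("control signal must be positive", call. = FALSE)
  }
  100 * raw / denom
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit with automatic asymptote locking: variants with the
#' top locked to 100 and/or the bottom locked to 0 are preferred over the
#' fully free fit whenever the extra-sum-of-squares F-test does not reject
#' them at `alpha`. Duplicate wells at the same concentration are averaged
#' before fitting. The IC50 is the fitted midpoint, i.e. the concentration at
#' 50% of the responding fraction; when the fitted maximal effect is below
#' `min_effect` (default 20%) the IC50 is reported as not determined.
#'
#' @param conc Concentrations (> 0), or a data frame with columns `conc` and
#'   `viability`.
#' @param viability Viabilities in % of control (ignored when `conc` is a
#'   data frame).
#' @param alpha Significance level of the F-test used for asymptote locking.
#' @param min_effect Maximal-effect threshold (%) below which the IC50 is
#'   not determined.
#' @return An object of class `hill_fit` with elements `params`
#'   ([hill_params()]), `ic50` (NA when not determined), `max_effect`,
#'   `nd` (logical), `rss`, `data`, `status` ("ok" or "failed").
#' @export
fit_dose_response <- function(conc, viability = NULL, alpha = 0.05,
                              min_effect = 20) {
  if (is.data.frame(conc)) {
    viability <- conc$viability
    conc <- conc$conc
  }
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentrations must be positive and finite", call. = FALSE)
  }
  if (length(conc) != length(viability)) stop("length mismatch")
  mean_v <- tapply(viability, conc, mean)
  d <- data.frame(conc = as.numeric(names(mean_v)),
                  viability = as.numeric(mean_v))
  if (nrow(d) < 4L) stop("need at least 4 distinct concentrations")

  fit_variant <- function(top_fixed, bottom_fixed) {
    has_top <- is.null(top_fixed)
    has_bot <- is.null(bottom_fixed)
    # parameter vector: lic50, lslope, then free asymptotes
    unpack <- function(par) {
      list(top = if (has_top) par[["top"]] else top_fixed,
           bottom = if (has_bot) par[["bottom"]] else bottom_fixed,
           lic50 = par[["lic50"]], lslope = par[["lslope"]])
    }
    sse <- function(par) {
      p <- unpack(par)
      pred <- p$bottom + (p$top - p$bottom) /
        (1 + exp(exp(p$lslope) * (log(d$conc) - p$lic50)))
      sum((d$viability - pred)^2)
    }
    mid <- (max(d$viability) + min(d$viability)) / 2
    lic50_start <- log(d$conc[which.min(abs(d$viability - mid))])
    base <- c(lic50 = lic50_start, lslope = 0)
    if (has_top) base <- c(base, top = max(d$viability))
    if (has_bot) base <- c(base, bottom = min(d$viability))
    starts <- lapply(c(0, log(2), -log(2)), function(ls) {
      s <- base
      s[["lslope"]] <- ls
      s
    })
    best <- NULL
    for (s in starts) {
      fit <- tryCatch({
        form <- if (has_top && has_bot) {
          viability ~ bottom + (top - bottom) /
            (1 + exp(exp(lslope) * (log(conc) - lic50)))
        } else if (has_top) {
          viability ~ bottom_fixed + (top - bottom_fixed) /
            (1 + exp(exp(lslope) * (log(conc) - lic50)))
        } else if (has_bot) {
          viability ~ bottom + (top_fixed - bottom) /
            (1 + exp(exp(lslope) * (log(conc) - lic50)))
        } else {
          viability ~ bottom_fixed + (top_fixed - bottom_fixed) /
            (1 + exp(exp(lslope) * (log(conc) - lic50)))
        }
        minpack.lm::nlsLM(form, data = d, start = as.list(s),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        cand <- c(cf[intersect(names(base), names(cf))])
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(par = cand, rss = rss)
      }
    }
    if (is.null(best)) {
      # derivative-free fallback for starts where Levenberg-Marquardt stalls
      for (s in starts) {
        opt <- tryCatch({
          o1 <- stats::optim(s, sse, method = "Nelder-Mead",
                             control = list(maxit = 5000, reltol = 1e-15))
          stats::optim(o1$par, sse, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-15))
        }, error = function(e) NULL)
        if (!is.null(opt) && is.finite(opt$value) &&
            (is.null(best) || opt$value < best$rss)) {
          best <- list(par = opt$par, rss = opt$value)
        }
      }
    }
    if (is.null(best)) return(NULL)
    p <- unpack(best$par)
    list(top = p$top, bottom = p$bottom,
         ic50 = exp(p$lic50), slope = exp(p$lslope),
         rss = best$rss, npar = 2L + has_top + has_bot)
  }

  free <- fit_variant(NULL, NULL)
  locked <- list(both = fit_variant(100, 0),
                 top = fit_variant(100, NULL),
                 bottom = fit_variant(NULL, 0))
  n <- nrow(d)
  pick <- NULL
  lock_flags <- c(FALSE, FALSE)
  if (!is.null(free)) {
    df_free <- n - free$npar
    scale <- max(1, sum(d$viability^2))
    for (nm in c("both", "top", "bottom")) {
      v <- locked[[nm]]
      if (is.null(v)) next
      ok <- if (free$rss / scale < 1e-12) {
        # free fit is (numerically) perfect: accept the locked variant only
        # if it is perfect too
        v$rss / scale < 1e-10
      } else if (df_free <= 0) {
        FALSE
      } else {
        fstat <- ((v$rss - free$rss) / (free$npar - v$npar)) /
          (free$rss / df_free)
        p <- stats::pf(max(fstat, 0), free$npar - v$npar, df_free,
                       lower.tail = FALSE)
        p >= alpha
      }
      if (ok) {
        pick <- v
        lock_flags <- c(nm %in% c("both", "top"), nm %in% c("both", "bottom"))
        break
      }
    }
    if (is.null(pick)) pick <- free
  } else {
    for (nm in c("both", "top", "bottom")) {
      if (!is.null(locked[[nm]])) {
        pick <- locked[[nm]]
        lock_flags <- c(nm %in% c("both", "top"), nm %in% c("both", "bottom"))
        break
      }
    }
  }
  if (is.null(pick) || pick$top <= pick$bottom || !is.finite(pick$ic50)) {
    warning("dose-response fit failed", call. = FALSE)
    return(structure(list(params = NULL, ic50 = NA_real_,
                          max_effect = NA_real_, nd = TRUE, rss = NA_real_,
                          data = d, status = "failed"),
                     class = "hill_fit"))
  }
  params <- hill_params(top = pick$top, bottom = pick$bottom,
                        ic50 = pick$ic50, slope = pick$slope,
                        locked_top = lock_flags[1],
                        locked_bottom = lock_flags[2])
  nd <- params$max_effect < min_effect
  structure(list(params = params,
                 ic50 = if (nd) NA_real_ else params$ic50,
                 max_effect = params$max_effect, nd = nd, rss = pick$rss,
                 data = d, status = "ok"),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$status == "failed") {
    cat("4PL dose-response fit: FAILED\n")
    return(invisible(x))
  }
  cat("4PL dose-response fit\n")
  print(x$params)
  if (x$nd) {
    cat(sprintf("  IC50: not determined (max effect %.3g%% < 20%%)\n",
                x$max_effect))
  } else {
    cat(sprintf("  IC50: %.6g (responding-fraction scale), RSS %.4g\n",
                x$ic50, x$rss))
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  if (object$status == "failed") {
    return(c(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
             slope = NA_real_))
  }
  with(object$params, c(top = top, bottom = bottom, ic50 = ic50,
                        slope = slope))
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  if (object$status == "failed") stop("cannot predict from a failed fit")
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc else newdata
  hill_viability(object$params, conc)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$viability - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  if (x$status == "failed") stop("cannot plot a failed fit")
  rng <- range(x$data$conc)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = 200))
  plot(x$data$conc, x$data$viability, log = "x",
       xlab = "concentration", ylab = "viability (% of control)", ...)
  graphics::lines(grid, hill_viability(x$params, grid))
  if (!x$nd) graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}

#' IC50-matched mixture designs
#'
#' Builds the three standard equipotent mixture designs. The undiluted
#' (10^0) composition of the r_A:r_B ratio is
#' w_A x IC50_A + w_B x IC50_B with IC50-equivalent weights
#' (0.5, 0.5), (0.8, 0.2) and (0.2, 0.8) for the 1:1, 4:1 and 1:4 ratios;
#' the seven-point series spans 10x down to 0.01x in IC50-equivalent units.
#'
#' @param ic50_a,ic50_b Single-agent IC50s (> 0, determined).
#' @param ratios Character vector among `"1:1"`, `"4:1"`, `"1:4"`.
#' @param n_points Points in the dilution series (default 7).
#' @return A list of `mixture_design` objects with fields `ratio`,
#'   `weight_a`, `anchor` (the 10^0 total concentration), `frac_a` (fraction
#'   of total concentration that is drug A), `series`.
#' @export
design_mixtures <- function(ic50_a, ic50_b, ratios = c("1:1", "4:1", "1:4"),
                            n_points = 7L) {
  if (is.na(ic50_a) || is.na(ic50_b)) {
    stop("both IC50s must be determined to design mixtures", call. = FALSE)
  }
  stopifnot(ic50_a > 0, ic50_b > 0)
  weights <- c("1:1" = 0.5, "4:1" = 0.8, "1:4" = 0.2)
  ratios <- match.arg(ratios, names(weights), several.ok = TRUE)
  lapply(ratios, function(r) {
    wa <- weights[[r]]
    anchor <- wa * ic50_a + (1 - wa) * ic50_b
    structure(list(ratio = r, weight_a = wa, anchor = anchor,
                   frac_a = wa * ic50_a / anchor,
                   series = anchor * 10^seq(1, -2, length.out = n_points)),
              class = "mixture_design")
  })
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("Mixture design %s: 10^0 dose %.6g (%.0f%% drug A by concentration), %d points %.3g-%.3gx\n",
              x$ratio, x$anchor, 100 * x$frac_a, length(x$series),
              max(x$series) / x$anchor, min(x$series) / x$anchor))
  invisible(x)
}

#' Combination index at an effect level
#'
#' Two-term (mutually exclusive) Chou-Talalay combination index at effect
#' level `level` on the responding-fraction scale. The mixture dose
#' producing the effect comes from the fitted mixture curve; its composition
#' from the design; and the single-agent reference doses from the
#' single-agent fits of the same experiment.
#'
#' @param fit_a,fit_b Single-agent [fit_dose_response()] fits.
#' @param fit_mix Mixture-series fit.
#' @param design The [mixture_design()] of the mixture (supplies the
#'   composition fraction), or a number giving the fraction of total
#'   concentration that is drug A.
#' @param level Effect level x in (0, 1); 0.5 for ED50, 0.75 for ED75.
#' @return The CI (numeric); `NA` with attribute `reason` when any required
#'   curve does not reach the effect level or failed to fit.
#' @export
compute_ci <- function(fit_a, fit_b, fit_mix, design, level = 0.5) {
  stopifnot(level > 0, level < 1)
  frac_a <- if (inherits(design, "mixture_design")) design$frac_a
            else as.numeric(design)
  stopifnot(frac_a >= 0, frac_a <= 1)
  fits <- list(A = fit_a, B = fit_b, mixture = fit_mix)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    stopifnot(inherits(f, "hill_fit"))
    if (f$status == "failed") {
      return(structure(NA_real_, reason = sprintf("%s curve failed to fit", nm)))
    }
    if (f$max_effect < 100 * level) {
      return(structure(NA_real_,
                       reason = sprintf("%s curve max effect %.3g%% below %.0f%%",
                                        nm, f$max_effect, 100 * level)))
    }
  }
  d_total <- effect_dose(fit_mix$params, level)
  d_a <- frac_a * d_total
  d_b <- (1 - frac_a) * d_total
  d_a / effect_dose(fit_a$params, level) + d_b / effect_dose(fit_b$params, level)
}

#' Summarize per-ratio combination indices into a synergy result
#'
#' Mean CI per effect level over the evaluable ratios; the SD is reported
#' only when at least three ratios are evaluable at that level. Bounded
#' entries (upper bounds such as "<0.10") propagate as bounds: the summary
#' is flagged bounded when any contributing value is.
#'
#' @param ci_ed50,ci_ed75 Numeric per-ratio CI values (NA = not evaluable).
#' @param bounded_ed50,bounded_ed75 Logical flags marking upper-bound values.
#' @return An object of class `synergy_result`: a per-level table of mean,
#'   SD, number evaluable and bounded flag.
#' @export
summarize_ci <- function(ci_ed50, ci_ed75 = NA_real_,
                         bounded_ed50 = FALSE, bounded_ed75 = FALSE) {
  one <- function(vals, bounded) {
    bounded <- rep_len(bounded, length(vals))
    ok <- !is.na(vals)
    n <- sum(ok)
    list(mean = if (n) mean(vals[ok]) else NA_real_,
         sd = if (n >= 3L) stats::sd(vals[ok]) else NA_real_,
         n = n,
         bounded = any(bounded[ok]))
  }
  s50 <- one(ci_ed50, bounded_ed50)
  s75 <- one(ci_ed75, bounded_ed75)
  structure(list(levels = data.frame(
    level = c("ED50", "ED75"),
    mean = c(s50$mean, s75$mean),
    sd = c(s50$sd, s75$sd),
    n = c(s50$n, s75$n),
    bounded = c(s50$bounded, s75$bounded),
    stringsAsFactors = FALSE
  )), class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("Combination-index summary\n")
  lv <- x$levels
  for (i in seq_len(nrow(lv))) {
    if (is.na(lv$mean[i])) {
      cat(sprintf("  %s: NA (no evaluable ratio)\n", lv$level[i]))
    } else {
      cat(sprintf("  %s: mean CI %s%.3g%s (n = %d ratios)\n", lv$level[i],
                  if (lv$bounded[i]) "<=" else "", lv$mean[i],
                  if (is.na(lv$sd[i])) "" else sprintf(" +/- %.3g", lv$sd[i]),
                  lv$n[i]))
    }
  }
  invisible(x)
}

#' Classify a synergy result
#'
#' At each effect level: strong synergy when the mean CI is below 0.3;
#' synergy when mean CI + SD is below 1.0 (SD taken as 0 when absent, and an
#' upper bound such as "<0.10" read at its bound); otherwise no synergy.
#' Antagonism (mean CI - SD above 1.5) is reported as a separate flag, not a
#' label. The overall call is synergistic when either level is synergy or
#' strong synergy.
#'
#' @param result A [summarize_ci()] result.
#' @return A list with `ed50`, `ed75` (labels, `NA` when the level has no
#'   evaluable ratio), `overall` (`"synergistic"`/`"not synergistic"`/`NA`),
#'   `antagonism` (logical) and `evaluable` (logical).
#' @export
classify_synergy <- function(result) {
  stopifnot(inherits(result, "synergy_result"))
  lv <- result$levels
  label_one <- function(m, s) {
    if (is.na(m)) return(NA_character_)
    s <- if (is.na(s)) 0 else s
    if (m < 0.3) "strong synergy"
    else if (m + s < 1.0) "synergy"
    else "no synergy"
  }
  labels <- mapply(label_one, lv$mean, lv$sd)
  antag <- any(!is.na(lv$mean) &
                 (lv$mean - ifelse(is.na(lv$sd), 0, lv$sd)) > 1.5)
  evaluable <- any(!is.na(lv$mean))
  synergistic <- any(labels %in% c("synergy", "strong synergy"))
  list(ed50 = labels[[1]], ed75 = labels[[2]],
       overall = if (!evaluable) NA_character_
                 else if (synergistic) "synergistic" else "not synergistic",
       antagonism = antag, evaluable = evaluable)
}

#' Fit and score a complete synergy experiment
#'
#' Convenience wrapper over the module: fits the two single-agent series and
#' every mixture series of an assay table (as produced by
#' [gen_dose_response()] or read from a long-format plate file), computes
#' the combination index per ratio at the requested effect levels,
#' summarizes, and classifies.
#'
#' @param assay Long data frame with columns `agent`, `series`
#'   ("single"/"mixture"), `conc`, `viability`.
#' @param designs The [mixture_design()] list matching the mixture series
#'   (matched by ratio label in `agent`).
#' @param levels Effect levels, default ED50 and ED75.
#' @return A list with `fits`, per-ratio `ci` (matrix levels x ratios),
#'   `summary` ([summarize_ci()]) and `class` ([classify_synergy()]).
#' @export
synergy_analysis <- function(assay, designs, levels = c(0.5, 0.75)) {
  singles <- assay[assay$series == "single", ]
  fit_a <- fit_dose_response(singles$conc[singles$agent == "A"],
                             singles$viability[singles$agent == "A"])
  fit_b <- fit_dose_response(singles$conc[singles$agent == "B"],
                             singles$viability[singles$agent == "B"])
  ratio_labels <- vapply(designs, `[[`, character(1), "ratio")
  ci <- matrix(NA_real_, length(levels), length(designs),
               dimnames = list(sprintf("ED%.0f", 100 * levels), ratio_labels))
  fits_mix <- list()
  for (j in seq_along(designs)) {
    des <- designs[[j]]
    mix <- assay[assay$series == "mixture" & assay$agent == des$ratio, ]
    if (!nrow(mix)) next
    fm <- fit_dose_response(mix$conc, mix$viability)
    fits_mix[[des$ratio]] <- fm
    for (i in seq_along(levels)) {
      ci[i, j] <- compute_ci(fit_a, fit_b, fm, des, level = levels[i])
    }
  }
  summ <- summarize_ci(ci_ed50 = ci[1, ],
                       ci_ed75 = if (nrow(ci) > 1) ci[2, ] else NA_real_)
  list(fits = c(list(A = fit_a, B = fit_b), fits_mix), ci = ci,
       summary = summ, class = classify_synergy(summ))
}

# ---- published combination-index table ------------------------------------

parse_ci_entry <- function(x) {
  x <- trimws(x)
  if (x %in% c("NA", "ND", "")) {
    return(list(mean = NA_real_, sd = NA_real_, bounded = FALSE))
  }
  if (grepl("^<", x)) {
    return(list(mean = as.numeric(sub("^<", "", x)), sd = NA_real_,
                bounded = TRUE))
  }
  parts <- strsplit(x, "\\s*\\+/-\\s*")[[1]]
  list(mean = as.numeric(parts[1]),
       sd = if (length(parts) > 1) as.numeric(parts[2]) else NA_real_,
       bounded = FALSE)
}

#' Load the transcribed published combination-index table
#'
#' Reads the packaged transcription of the published per-patient,
#' per-inhibitor single-agent IC50s and ED50/ED75 combination indices for
#' prednisolone-inhibitor combinations in 11 primary T-ALL samples, and
#' parses the CI entries (`a +/- b`, bare means for fewer than three
#' evaluable ratios, `<0.10` bounds, `NA`, `ND`) into numeric columns.
#'
#' @param path Optional path to an alternative table in the same format.
#' @return A data frame with one row per (patient, inhibitor): the printed
#'   strings plus parsed `ci50_mean`, `ci50_sd`, `ci50_bounded`,
#'   `ci75_mean`, `ci75_sd`, `ci75_bounded`.
#' @export
load_table1 <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_ci.tsv",
                                package = "tallpipe", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  p50 <- lapply(tab$ed50, parse_ci_entry)
  p75 <- lapply(tab$ed75, parse_ci_entry)
  tab$ci50_mean <- vapply(p50, `[[`, numeric(1), "mean")
  tab$ci50_sd <- vapply(p50, `[[`, numeric(1), "sd")
  tab$ci50_bounded <- vapply(p50, `[[`, logical(1), "bounded")
  tab$ci75_mean <- vapply(p75, `[[`, numeric(1), "mean")
  tab$ci75_sd <- vapply(p75, `[[`, numeric(1), "sd")
  tab$ci75_bounded <- vapply(p75, `[[`, logical(1), "bounded")
  tab
}

# Build a synergy_result directly from already-summarized per-level CI
# means/SDs (as printed in the published table). `n` is inferred from the
# SD footnote convention: an SD implies >= 3 evaluable ratios.
result_from_summary <- function(m50, s50, b50, m75, s75, b75) {
  n_of <- function(m, s) if (is.na(m)) 0L else if (is.na(s)) 1L else 3L
  structure(list(levels = data.frame(
    level = c("ED50", "ED75"),
    mean = c(m50, m75), sd = c(s50, s75),
    n = c(n_of(m50, s50), n_of(m75, s75)),
    bounded = c(isTRUE(b50), isTRUE(b75)),
    stringsAsFactors = FALSE
  )), class = "synergy_result")
}

#' Per-inhibitor synergy counts from the published table
#'
#' Applies [classify_synergy()] to every (patient, inhibitor) cell of the
#' transcribed table. A cell is evaluable when at least one numeric or
#' bounded CI is present at ED50 or ED75.
#'
#' @param fixture A [load_table1()] data frame.
#' @return A data frame with one row per inhibitor: `inhibitor`,
#'   `n_synergistic`, `n_evaluable`, `n_samples`.
#' @export
per_inhibitor_counts <- function(fixture = load_table1()) {
  cls <- lapply(seq_len(nrow(fixture)), function(i) {
    r <- fixture[i, ]
    classify_synergy(result_from_summary(r$ci50_mean, r$ci50_sd,
                                         r$ci50_bounded, r$ci75_mean,
                                         r$ci75_sd, r$ci75_bounded))
  })
  evaluable <- vapply(cls, `[[`, logical(1), "evaluable")
  synergistic <- vapply(cls, function(x) {
    isTRUE(x$overall == "synergistic")
  }, logical(1))
  inhibitors <- unique(fixture$inhibitor)
  out <- data.frame(
    inhibitor = inhibitors,
    n_synergistic = vapply(inhibitors, function(g) {
      sum(synergistic[fixture$inhibitor == g])
    }, integer(1)),
    n_evaluable = vapply(inhibitors, function(g) {
      sum(evaluable[fixture$inhibitor == g])
    }, integer(1)),
    n_samples = vapply(inhibitors, function(g) {
      sum(fixture$inhibitor == g)
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}
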