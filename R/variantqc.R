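# Somatic variant confidence calibration and filtering.
#
# Whole-genome-style calls carry two platform scores: the total score TS
# (confidence in the called mutation) and the somatic score SS (confidence
# that the mutation is tumor-specific). High-confidence calling thresholds
# both jointly, by default at SS >= 0.1 and TS >= 100, with inclusive
# comparisons. Targeted-exome-style calls carry read depth and an overall
# quality score; their acceptance boundary is calibrated on validated
# true-positive calls only, either as a Gaussian one-class (Mahalanobis
# ellipse) boundary or as an exhaustive axis-aligned decision rule, both to
# a target false-negative rate.

#' Build a polymorphism index
#'
#' A lookup of known germline variants keyed by (chromosome, position,
#' reference, alternate) plus an optional somatic-hotspot rescue lookup
#' keyed by (gene, amino-acid position): database-listed variants touching a
#' hotspot-annotated amino acid are retained rather than filtered.
#'
#' @param polymorphisms Data frame with columns `chrom`, `pos`, `ref`,
#'   `alt` (or NULL for an empty index).
#' @param cosmic Optional data frame with columns `gene`, `aa_pos`.
#' @return An object of class `polymorphism_index`.
#' @export
polymorphism_index <- function(polymorphisms = NULL, cosmic = NULL) {
  poly_keys <- if (is.null(polymorphisms) || !nrow(polymorphisms)) {
    character(0)
  } else {
    unique(paste(polymorphisms$chrom, polymorphisms$pos,
                 polymorphisms$ref, polymorphisms$alt, sep = ":"))
  }
  cosmic_keys <- if (is.null(cosmic) || !nrow(cosmic)) {
    character(0)
  } else {
    unique(paste(cosmic$gene, cosmic$aa_pos, sep = ":"))
  }
  structure(list(poly = poly_keys, cosmic = cosmic_keys),
            class = "polymorphism_index")
}

#' @export
print.polymorphism_index <- function(x, ...) {
  cat(sprintf("Polymorphism index: %d variant keys, %d hotspot amino-acid keys\n",
              length(x$poly), length(x$cosmic)))
  invisible(x)
}

variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Joint-score ROC over (SS, TS) threshold pairs
#'
#' True/false-positive rates for calling a variant high-confidence at
#' SS >= ss and TS >= ts (inclusive on both axes), evaluated on a labeled
#' call table over a grid of threshold pairs.
#'
#' @param calls Variant-call data frame with numeric `ss`, `ts` and logical
#'   `truth` columns containing both classes.
#' @param grid Data frame of candidate pairs (columns `ss`, `ts`); defaults
#'   to the cross of observed score values, always including the pair
#'   (0.1, 100).
#' @param ss_min,ts_min The selected operating pair (defaults 0.1 and 100).
#' @return An object of class `wgs_thresholds` with the selected cutoffs and
#'   the `roc_points` table (`ss`, `ts`, `tpr`, `fpr`).
#' @export
roc_curve <- function(calls, grid = NULL, ss_min = 0.1, ts_min = 100) {
  stopifnot(is.numeric(calls$ss), is.numeric(calls$ts),
            is.logical(calls$truth))
  if (!any(calls$truth) || all(calls$truth)) {
    stop("need both true and false labels to compute a ROC", call. = FALSE)
  }
  if (is.null(grid)) {
    ss_cand <- sort(unique(c(calls$ss, ss_min)))
    ts_cand <- sort(unique(c(calls$ts, ts_min)))
    grid <- expand.grid(ss = ss_cand, ts = ts_cand,
                        KEEP.OUT.ATTRS = FALSE)
  }
  n_t <- sum(calls$truth)
  n_f <- sum(!calls$truth)
  rates <- t(vapply(seq_len(nrow(grid)), function(i) {
    high <- calls$ss >= grid$ss[i] & calls$ts >= grid$ts[i]
    c(tpr = sum(high & calls$truth) / n_t,
      fpr = sum(high & !calls$truth) / n_f)
  }, c(tpr = 0, fpr = 0)))
  structure(list(ss_min = ss_min, ts_min = ts_min,
                 roc_points = cbind(grid, rates)),
            class = "wgs_thresholds")
}

#' @export
print.wgs_thresholds <- function(x, ...) {
  at <- x$roc_points[x$roc_points$ss == x$ss_min &
                       x$roc_points$ts == x$ts_min, , drop = FALSE]
  cat(sprintf("WGS score thresholds: SS >= %g and TS >= %g (%d grid pairs)\n",
              x$ss_min, x$ts_min, nrow(x$roc_points)))
  if (nrow(at)) {
    cat(sprintf("  at the selected pair: TPR %.3f, FPR %.3f\n",
                at$tpr[1], at$fpr[1]))
  }
  invisible(x)
}

#' Classify calls as high or low confidence by the score thresholds
#'
#' High iff SS >= ss_min and TS >= ts_min; boundary values are high.
#'
#' @param calls Data frame with finite numeric `ss` and `ts` columns.
#' @param thresholds A [roc_curve()] result, or a list with `ss_min` and
#'   `ts_min`.
#' @return Character vector, "high" or "low", one per call.
#' @export
classify_wgs <- function(calls, thresholds = list(ss_min = 0.1, ts_min = 100)) {
  if (is.null(calls$ss) || is.null(calls$ts)) {
    stop("calls must carry `ss` and `ts` scores", call. = FALSE)
  }
  stopifnot_finite(calls$ss, "ss")
  stopifnot_finite(calls$ts, "ts")
  ifelse(calls$ss >= thresholds$ss_min & calls$ts >= thresholds$ts_min,
         "high", "low")
}

#' Somatic filtering of whole-genome calls
#'
#' Retains exonic non-synonymous calls that are absent from the polymorphism
#' index and absent from the matched remission sample, in stable input
#' order. Tables must declare the same genome build (attribute
#' `genome_build`) when both declare one.
#'
#' @param calls Tumor variant-call data frame.
#' @param polymorphisms A [polymorphism_index()].
#' @param remission_calls Variant calls from the matched remission sample
#'   (same coordinate convention).
#' @return The filtered call table.
#' @export
filter_wgs_somatic <- function(calls, polymorphisms = polymorphism_index(),
                               remission_calls = NULL) {
  build_t <- attr(calls, "genome_build")
  build_r <- if (is.null(remission_calls)) NULL
             else attr(remission_calls, "genome_build")
  if (!is.null(build_t) && !is.null(build_r) && !identical(build_t, build_r)) {
    stop("genome builds of tumor and remission tables differ", call. = FALSE)
  }
  keep <- calls$consequence == "non-synonymous"
  keep <- keep & !(variant_key(calls) %in% polymorphisms$poly)
  if (!is.null(remission_calls) && nrow(remission_calls)) {
    keep <- keep & !(variant_key(calls) %in% variant_key(remission_calls))
  }
  out <- calls[keep, , drop = FALSE]
  attr(out, "genome_build") <- build_t
  out
}

#' Fit a Gaussian one-class acceptance boundary
#'
#' The boundary is the Mahalanobis ellipse of the true-positive training
#' points: centre and shape are the TP sample mean and covariance
#' (ridge-regularized by `1e-8 x trace` when near-degenerate), and the
#' squared radius is the smallest empirical squared-Mahalanobis-distance
#' quantile leaving at most `target_fnr` of the TP points outside. Points
#' inside or on the boundary are accepted. The false-positive rate is
#' measured on the FP points of the training set.
#'
#' @param points A labeled point set (data frame with `depth`, `quality`,
#'   `label` in TP/FP) as from [gen_tes_quality()].
#' @param target_fnr Target training false-negative rate in (0, 1).
#' @return An object of class `one_class_boundary` with `center`, `shape`,
#'   `radius2`, achieved `fnr` and `fpr`.
#' @export
fit_one_class <- function(points, target_fnr = 0.10) {
  stopifnot(target_fnr > 0, target_fnr < 1)
  X <- as.matrix(points[points$label == "TP", c("depth", "quality")])
  if (nrow(X) < 3L) stop("need at least 3 TP points", call. = FALSE)
  center <- colMeans(X)
  S <- stats::cov(X)
  tr <- sum(diag(S))
  if (tr <= 0 || kappa(S) > 1e10 || det(S) <= 0) {
    S <- S + diag(2L) * max(1e-8 * tr, .Machine$double.eps)
  }
  if (sum(diag(S)) <= .Machine$double.eps) {
    # all TP identical: the degenerate boundary is the point itself
    d2 <- rep(0, nrow(X))
    radius2 <- 0
  } else {
    d2 <- stats::mahalanobis(X, center, S)
    n <- length(d2)
    m <- floor(n * target_fnr)           # points allowed outside
    radius2 <- unname(sort(d2)[n - m])
  }
  inside <- d2 <= radius2
  fnr <- mean(!inside)
  Xf <- as.matrix(points[points$label == "FP", c("depth", "quality")])
  fpr <- if (nrow(Xf)) {
    mean(stats::mahalanobis(Xf, center, S) <= radius2)
  } else {
    NA_real_
  }
  structure(list(center = center, shape = S, radius2 = radius2,
                 fnr = fnr, fpr = fpr, n_tp = nrow(X), n_fp = nrow(Xf)),
            class = "one_class_boundary")
}

#' @export
print.one_class_boundary <- function(x, ...) {
  cat("Gaussian one-class boundary (Mahalanobis ellipse)\n")
  cat(sprintf("  center: depth %.3g, quality %.3g; squared radius %.4g\n",
              x$center[1], x$center[2], x$radius2))
  cat(sprintf("  training FNr %.3f (n = %d TP), FPr %s (n = %d FP)\n",
              x$fnr, x$n_tp,
              if (is.na(x$fpr)) "NA" else sprintf("%.3f", x$fpr), x$n_fp))
  invisible(x)
}

#' @export
predict.one_class_boundary <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, c("depth", "quality")])
  if (object$radius2 == 0 && sum(diag(object$shape)) <= 1e-6) {
    return(apply(X, 1L, function(r) all(r == object$center)))
  }
  stats::mahalanobis(X, object$center, object$shape) <= object$radius2
}

#' Fit an axis-aligned decision-rule acceptance boundary
#'
#' Exhaustive search over one- and two-threshold accept rules of the form
#' depth >= t_d and/or quality >= t_q. Among rules whose training
#' false-negative rate does not exceed `target_fnr`, the rule minimizing the
#' false-positive rate is returned; ties are broken toward the higher
#' quality threshold, then the higher depth threshold.
#'
#' @inheritParams fit_one_class
#' @return An object of class `rule_boundary` with `depth_min`,
#'   `quality_min` (either may be `-Inf`), achieved `fnr` and `fpr`.
#' @export
fit_rule_boundary <- function(points, target_fnr = 0.10) {
  stopifnot(target_fnr > 0, target_fnr < 1)
  tp <- points[points$label == "TP", c("depth", "quality")]
  fp <- points[points$label == "FP", c("depth", "quality")]
  if (!nrow(tp) || !nrow(fp)) stop("need both TP and FP points", call. = FALSE)
  d_cand <- c(-Inf, sort(unique(c(tp$depth, fp$depth))))
  q_cand <- c(-Inf, sort(unique(c(tp$quality, fp$quality))))
  best <- NULL
  for (td in d_cand) {
    tp_d <- tp$depth >= td
    fp_d <- fp$depth >= td
    for (tq in q_cand) {
      acc_tp <- tp_d & tp$quality >= tq
      fnr <- 1 - mean(acc_tp)
      if (fnr > target_fnr) next
      fpr <- mean(fp_d & fp$quality >= tq)
      if (is.null(best) || fpr < best$fpr ||
          (fpr == best$fpr && (tq > best$quality_min ||
                                 (tq == best$quality_min &&
                                    td > best$depth_min)))) {
        best <- list(depth_min = td, quality_min = tq, fnr = fnr, fpr = fpr)
      }
    }
  }
  structure(c(best, list(n_tp = nrow(tp), n_fp = nrow(fp))),
            class = "rule_boundary")
}

#' @export
print.rule_boundary <- function(x, ...) {
  cat(sprintf("Decision-rule boundary: accept when depth >= %s and quality >= %s\n",
              format(x$depth_min), format(x$quality_min)))
  cat(sprintf("  training FNr %.3f, FPr %.3f (n = %d TP, %d FP)\n",
              x$fnr, x$fpr, x$n_tp, x$n_fp))
  invisible(x)
}

#' @export
predict.rule_boundary <- function(object, newdata, ...) {
  newdata$depth >= object$depth_min & newdata$quality >= object$quality_min
}

#' Filter targeted-exome calls
#'
#' Keeps calls with read depth of at least 10x for SNVs or 5x for INDELs
#' (insertions, deletions, substitutions) and a variant allele fraction of
#' at least 0.30, all boundaries inclusive. Polymorphism-index hits are
#' dropped unless the call's (gene, amino-acid position) is annotated in the
#' hotspot rescue lookup, in which case it is retained.
#'
#' @param calls Variant-call data frame with columns `class`
#'   (snv/ins/del/sub), `depth`, `vaf`, plus `chrom`, `pos`, `ref`, `alt`
#'   and optionally `gene`, `aa_pos` for the rescue.
#' @param polymorphisms A [polymorphism_index()].
#' @return The filtered call table (input order preserved).
#' @export
filter_tes <- function(calls, polymorphisms = polymorphism_index()) {
  if (is.null(calls$depth) || is.null(calls$vaf)) {
    stop("calls must carry `depth` and `vaf`", call. = FALSE)
  }
  known <- c("snv", "ins", "del", "sub")
  if (!all(calls$class %in% known)) {
    stop("unknown variant class: ",
         paste(setdiff(unique(calls$class), known), collapse = ", "),
         call. = FALSE)
  }
  min_depth <- ifelse(calls$class == "snv", 10, 5)
  keep <- calls$depth >= min_depth & calls$vaf >= 0.30
  is_poly <- variant_key(calls) %in% polymorphisms$poly
  rescued <- if (!is.null(calls$gene) && !is.null(calls$aa_pos)) {
    paste(calls$gene, calls$aa_pos, sep = ":") %in% polymorphisms$cosmic
  } else {
    rep(FALSE, nrow(calls))
  }
  keep <- keep & (!is_poly | rescued)
  calls[keep, , drop = FALSE]
}
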