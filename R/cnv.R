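# Array-CGH copy-number calling.
#
# Wave-corrected log10 ratios L are converted to copy number CN = 2 * 10^L
# and gene-level amplifications/deletions are called when at least three
# consecutive probes of a gene lie strictly beyond the per-probe
# cross-sample mean +/- 2 SD of CN, all in the same direction.

#' Probe x sample log10-ratio panel
#'
#' @param probes Data frame of probe annotation with columns `probe`,
#'   `chrom`, `pos`, `gene`, sorted by (chrom, pos).
#' @param samples Character vector of sample ids.
#' @param L Numeric matrix of wave-corrected log10 ratios, probes x samples,
#'   all finite.
#' @return An object of class `probe_panel`.
#' @export
probe_panel <- function(probes, samples, L) {
  stopifnot(is.data.frame(probes),
            all(c("probe", "chrom", "pos", "gene") %in% names(probes)))
  L <- as.matrix(L)
  if (nrow(L) != nrow(probes) || ncol(L) != length(samples)) {
    stop("matrix dimensions must match probe and sample lists", call. = FALSE)
  }
  if (any(!is.finite(L))) stop("log ratios must be finite", call. = FALSE)
  ord <- order(probes$chrom, probes$pos)
  if (!identical(ord, seq_len(nrow(probes)))) {
    probes <- probes[ord, , drop = FALSE]
    L <- L[ord, , drop = FALSE]
  }
  dimnames(L) <- list(probes$probe, samples)
  structure(list(probes = probes, samples = samples, L = L),
            class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("aCGH probe panel: %d probes (%d genes) x %d samples\n",
              nrow(x$L), length(unique(x$probes$gene)), ncol(x$L)))
  invisible(x)
}

#' Convert log10 ratio to copy number
#'
#' CN = 2 x 10^L; a log ratio of 0 is the diploid state CN = 2.
#'
#' @param L Finite log10 ratio(s).
#' @return Copy number, strictly positive.
#' @export
log_ratio_to_cn <- function(L) {
  if (any(!is.finite(L))) stop("log ratio must be finite", call. = FALSE)
  2 * 10^L
}

#' Call gene-level copy-number aberrations
#'
#' Per probe, the mean and standard deviation of copy number are computed
#' across all samples (including the tested sample, or excluding it with
#' `loo = TRUE`). A call is made for a (sample, gene) when at least
#' `min_run` consecutive probes of that gene have CN strictly beyond
#' mean + `sd_mult` x SD (amplification) or strictly below
#' mean - `sd_mult` x SD (deletion), all in the same direction; each maximal
#' qualifying run produces one call. Genes with fewer than `min_run` probes
#' can never be called.
#'
#' @param panel A [probe_panel()] with at least two samples.
#' @param sd_mult SD multiplier, default 2.
#' @param min_run Minimum consecutive-outlier-probe run, default 3.
#' @param loo Leave the tested sample out of the per-probe statistics.
#' @return A data frame of calls: `sample`, `gene`, `direction`
#'   ("amplification"/"deletion"), `n_probes`, `probes`
#'   (semicolon-separated ids of the supporting run).
#' @export
call_gene_cnv <- function(panel, sd_mult = 2, min_run = 3L, loo = FALSE) {
  stopifnot(inherits(panel, "probe_panel"))
  n_s <- ncol(panel$L)
  if (n_s < 2L) stop("need at least 2 samples to define the SD", call. = FALSE)
  CN <- log_ratio_to_cn(panel$L)
  calls <- list()
  gene_rows <- split(seq_len(nrow(CN)), panel$probes$gene)
  # population SD across samples: cohort-relative, so replicating every
  # sample leaves the per-probe statistics (and hence the calls) unchanged
  pop_sd <- function(M) {
    k <- ncol(M)
    apply(M, 1L, stats::sd) * sqrt((k - 1) / k)
  }
  mu_all <- rowMeans(CN)
  sd_all <- pop_sd(CN)
  for (j in seq_len(n_s)) {
    if (loo) {
      mu <- rowMeans(CN[, -j, drop = FALSE])
      sd_j <- pop_sd(CN[, -j, drop = FALSE])
    } else {
      mu <- mu_all
      sd_j <- sd_all
    }
    up <- CN[, j] > mu + sd_mult * sd_j
    dn <- CN[, j] < mu - sd_mult * sd_j
    state <- integer(nrow(CN))
    state[up] <- 1L
    state[dn] <- -1L
    for (g in names(gene_rows)) {
      rows <- gene_rows[[g]]
      if (length(rows) < min_run) next
      s <- state[rows]
      r <- rle(s)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (r$values[k] != 0L && r$lengths[k] >= min_run) {
          run <- rows[starts[k]:ends[k]]
          calls[[length(calls) + 1L]] <- data.frame(
            sample = panel$samples[j], gene = g,
            direction = if (r$values[k] > 0L) "amplification" else "deletion",
            n_probes = length(run),
            probes = paste(panel$probes$probe[run], collapse = ";"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(sample = character(0), gene = character(0),
                      direction = character(0), n_probes = integer(0),
                      probes = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}
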