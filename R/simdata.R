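# Synthetic-data generators.
#
# Each generator emulates the statistical structure one downstream stage
# assumes: two-class quality-score clouds for variant-call calibration,
# junction tables with planted pass/fail status, probe-level aCGH matrices
# with planted copy-number events, patient cohorts with a pathway-mutation
# effect on drug response and survival, and Hill-curve viability assays with
# a tunable Loewe interaction index. Planted truth travels as attributes of
# the returned table, never as columns a downstream caller would consume by
# accident.

#' Simulation configuration
#'
#' Bundles the seed, effect sizes and noise scales shared by the synthetic
#' data generators. A fixed configuration yields byte-identical output from
#' every generator.
#'
#' @param seed Integer seed driving all randomness of a generator call.
#' @param n_true,n_false Counts of true and false somatic calls for
#'   [gen_wgs_calls()]. Defaults follow the 46-mutation validation set split
#'   30 true / 16 false.
#' @param score_sd Noise scale (>= 0) multiplying the dispersion of the
#'   quality-score clouds; 0 collapses each cluster to a point.
#' @param cluster_sep Separation multiplier between the true- and false-call
#'   cluster centres (1 = default geometry).
#' @param lr_sd Standard deviation of baseline aCGH log10 ratios.
#' @param cn_shift Absolute log10-ratio shift of a planted copy-number event
#'   (deletions shift by \code{-cn_shift}, amplifications by \code{+cn_shift}).
#' @param lc50_fold Fold-change of prednisolone LC50 in pathway-mutant
#'   patients relative to wild-type.
#' @param hazard_ratio Event-hazard ratio of pathway-mutant patients.
#' @param tau Loewe interaction index used by [gen_dose_response()]; 1 is
#'   additive, < 1 synergistic, > 1 antagonistic.
#' @param viability_cv Coefficient of variation of the multiplicative
#'   (log-normal) plate-reader noise on viabilities.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, n_true = 30L, n_false = 16L,
                       score_sd = 1, cluster_sep = 1,
                       lr_sd = 0.02, cn_shift = 0.3,
                       lc50_fold = 3, hazard_ratio = 2.5,
                       tau = 1, viability_cv = 0.05) {
  seed <- stopifnot_scalar_count(seed, "seed", min = 0L)
  n_true <- stopifnot_scalar_count(n_true, "n_true")
  n_false <- stopifnot_scalar_count(n_false, "n_false")
  for (nm in c("score_sd", "cluster_sep", "lr_sd", "viability_cv")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single value >= 0", nm), call. = FALSE)
    }
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("`tau` must be a single value > 0", call. = FALSE)
  }
  if (lc50_fold <= 0 || hazard_ratio <= 0) {
    stop("`lc50_fold` and `hazard_ratio` must be > 0", call. = FALSE)
  }
  structure(list(seed = seed, n_true = n_true, n_false = n_false,
                 score_sd = score_sd, cluster_sep = cluster_sep,
                 lr_sd = lr_sd, cn_shift = cn_shift,
                 lc50_fold = lc50_fold, hazard_ratio = hazard_ratio,
                 tau = tau, viability_cv = viability_cv),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  score clouds: n_true %d, n_false %d, score_sd %.3g, sep %.3g\n",
              x$n_true, x$n_false, x$score_sd, x$cluster_sep))
  cat(sprintf("  aCGH: log-ratio SD %.3g, planted shift +/- %.3g\n",
              x$lr_sd, x$cn_shift))
  cat(sprintf("  cohort: LC50 fold %.3g, hazard ratio %.3g\n",
              x$lc50_fold, x$hazard_ratio))
  cat(sprintf("  synergy: interaction index tau %.3g, viability CV %.3g\n",
              x$tau, x$viability_cv))
  invisible(x)
}

random_bases <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate whole-genome somatic variant calls with quality scores
#'
#' True calls are drawn from a tight, high-score cluster in the
#' (somatic score, total score) plane and false calls from a dispersed
#' low-score distribution, so that the published score thresholds
#' (SS >= 0.1 and TS >= 100) separate the classes. The planted truth label is
#' carried in the `truth` column for calibration work.
#'
#' @param config A [sim_config()]; `n_true`, `n_false`, `score_sd` and
#'   `cluster_sep` control the clouds.
#' @return A data frame of variant calls with columns `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `gene`, `consequence`, `ss`, `ts`,
#'   `truth`.
#' @export
gen_wgs_calls <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_t <- config$n_true
  n_f <- config$n_false
  with_seed(config$seed, {
    # cluster centres; separation scales the true-call centre away from the
    # false-call centre along both score axes
    fp_c <- c(ss = 0.02, lts = log(40))
    tp_c <- fp_c + config$cluster_sep * c(0.58, log(400 / 40))
    sdv <- config$score_sd
    ss_t <- pmax(tp_c[["ss"]] + 0.15 * sdv * stats::rnorm(n_t), 0)
    ts_t <- exp(tp_c[["lts"]] + 0.40 * sdv * stats::rnorm(n_t))
    ss_f <- fp_c[["ss"]] + 0.08 * sdv * abs(stats::rnorm(n_f))
    ts_f <- exp(fp_c[["lts"]] + 0.90 * sdv * stats::rnorm(n_f))
    n <- n_t + n_f
    classes <- sample(c("snv", "ins", "del", "sub"), n, replace = TRUE,
                      prob = c(0.6, 0.15, 0.15, 0.1))
    calls <- data.frame(
      sample = sprintf("P%02d", sample(1:13, n, replace = TRUE)),
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(1e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      class = classes,
      gene = sprintf("GENE%03d", sample.int(150, n, replace = TRUE)),
      consequence = "non-synonymous",
      ss = c(ss_t, ss_f),
      ts = c(ts_t, ts_f),
      truth = rep(c(TRUE, FALSE), c(n_t, n_f)),
      stringsAsFactors = FALSE
    )
    attr(calls, "genome_build") <- "36"
    attr(calls, "seed") <- config$seed
    calls
  })
}

#' Simulate targeted-exome quality-score clouds
#'
#' True-positive points form an elliptical Gaussian cluster in
#' (read depth, overall quality); false positives are scattered with a
#' heavier low-quality tail. Defaults mirror a 570-point SNV training set of
#' 218 true against 352 false calls; `kind = "indel"` produces the smaller,
#' heavily overlapping clouds typical of platform-discordant INDEL calls.
#'
#' @param n_tp,n_fp Numbers of true- and false-positive points (>= 1).
#' @param config A [sim_config()].
#' @param kind `"snv"` (well-separated clouds) or `"indel"` (overlapping).
#' @return A data frame with columns `depth`, `quality`, `label`
#'   (factor TP/FP); the generating TP mean and covariance are attached as
#'   attributes `tp_mean` and `tp_cov`.
#' @export
gen_tes_quality <- function(n_tp = 218L, n_fp = 352L, config = sim_config(),
                            kind = c("snv", "indel")) {
  kind <- match.arg(kind)
  n_tp <- stopifnot_scalar_count(n_tp, "n_tp")
  n_fp <- stopifnot_scalar_count(n_fp, "n_fp")
  stopifnot(inherits(config, "sim_config"))
  s <- config$score_sd
  if (kind == "snv") {
    mu <- c(depth = 60, quality = 150)
    sds <- c(15, 30) * s
    rho <- 0.5
  } else {
    mu <- c(depth = 25, quality = 70)
    sds <- c(14, 45) * s
    rho <- 0.3
  }
  Sigma <- matrix(c(sds[1]^2, rho * sds[1] * sds[2],
                    rho * sds[1] * sds[2], sds[2]^2), 2, 2)
  with_seed(config$seed, {
    z <- matrix(stats::rnorm(2L * n_tp), n_tp, 2L)
    R <- if (all(sds > 0)) chol(Sigma) else matrix(0, 2, 2)
    tp <- sweep(z %*% R, 2L, mu, `+`)
    if (kind == "snv") {
      fp_depth <- exp(log(25) + 0.7 * s * stats::rnorm(n_fp))
      fp_quality <- 150 * stats::runif(n_fp)^2   # mass piled at low quality
    } else {
      fp_depth <- exp(log(18) + 0.8 * s * stats::rnorm(n_fp))
      fp_quality <- 110 * stats::runif(n_fp)^1.3
    }
    pts <- data.frame(
      depth = pmax(c(tp[, 1], fp_depth), 1),
      quality = pmax(c(tp[, 2], fp_quality), 0),
      label = factor(rep(c("TP", "FP"), c(n_tp, n_fp)), levels = c("TP", "FP"))
    )
    attr(pts, "tp_mean") <- mu
    attr(pts, "tp_cov") <- Sigma
    attr(pts, "seed") <- config$seed
    pts
  })
}

# Truncated-geometric insert lengths: mean about 18 nt, support [1, 221],
# matching the observed non-template insert distribution at junctions.
sample_insert_len <- function(n) {
  len <- stats::rgeom(n, prob = 1 / 18) + 1L
  pmin(len, 221L)
}

#' Simulate breakpoint-junction tables with planted pass/fail status
#'
#' Passing records satisfy all seven high-confidence criteria (mate pairs,
#' assembly, mapping-diversity span, repeat overlap, dbSNP, transposon
#' deletion, baseline genomes); each failing record violates exactly one
#' criterion chosen uniformly. Junction sequences are built as
#' flank A + non-template insert + flank B with insert lengths in [1, 221].
#'
#' @param n_pass,n_fail Numbers of passing / failing records (>= 0).
#' @param config A [sim_config()].
#' @param flank_len Length (nt) of each simulated reference flank.
#' @return A data frame of junction records; planted status and insert
#'   lengths travel in attribute `truth` (columns `planted_pass`,
#'   `insert_len`).
#' @export
gen_junctions <- function(n_pass, n_fail, config = sim_config(),
                          flank_len = 30L) {
  n_pass <- stopifnot_scalar_count(n_pass, "n_pass", min = 0L)
  n_fail <- stopifnot_scalar_count(n_fail, "n_fail", min = 0L)
  stopifnot(inherits(config, "sim_config"))
  n <- n_pass + n_fail
  with_seed(config$seed, {
    draw <- function(n) {
      data.frame(
        sample = sprintf("P%02d", sample(1:13, n, replace = TRUE)),
        chrom_a = as.character(sample(1:22, n, replace = TRUE)),
        pos_a = sample.int(1e8, n),
        strand_a = sample(c("+", "-"), n, replace = TRUE),
        chrom_b = as.character(sample(1:22, n, replace = TRUE)),
        pos_b = sample.int(1e8, n),
        strand_b = sample(c("+", "-"), n, replace = TRUE),
        mate_pairs = sample(10:60, n, replace = TRUE),
        assembled = TRUE,
        span = sample(71:2000, n, replace = TRUE),
        repeat_overlap = FALSE,
        in_dbsnp = FALSE,
        te_deletion = FALSE,
        in_baseline = FALSE,
        stringsAsFactors = FALSE
      )
    }
    rec <- if (n > 0) draw(n) else draw(0L)
    if (n_fail > 0) {
      idx <- n_pass + seq_len(n_fail)
      crit <- sample(7L, n_fail, replace = TRUE)
      for (k in seq_len(n_fail)) {
        i <- idx[k]
        switch(crit[k],
          rec$mate_pairs[i] <- sample(0:9, 1L),
          rec$assembled[i] <- FALSE,
          rec$span[i] <- sample(0:70, 1L),
          rec$repeat_overlap[i] <- TRUE,
          rec$in_dbsnp[i] <- TRUE,
          rec$te_deletion[i] <- TRUE,
          rec$in_baseline[i] <- TRUE
        )
      }
    }
    ins_len <- if (n > 0) sample_insert_len(n) else integer(0)
    flank_a <- random_bases(n, flank_len)
    flank_b <- random_bases(n, flank_len)
    insert <- vapply(ins_len, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    rec$flank_a <- flank_a
    rec$flank_b <- flank_b
    rec$junction_seq <- paste0(flank_a, insert, flank_b)
    attr(rec, "truth") <- data.frame(
      planted_pass = rep(c(TRUE, FALSE), c(n_pass, n_fail)),
      insert_len = ins_len
    )
    attr(rec, "seed") <- config$seed
    rec
  })
}

#' Simulate a probe-level aCGH log10-ratio panel with planted events
#'
#' Baseline log10 ratios are Normal(0, `lr_sd`); each planted event shifts a
#' run of consecutive probes of one gene in one sample by `+cn_shift`
#' (amplification) or `-cn_shift` (deletion). Probes are annotated to genes
#' in consecutive blocks of ten.
#'
#' @param n_samples,n_probes Panel dimensions (>= 1).
#' @param events Optional data frame with columns `sample` (index or id),
#'   `gene`, `direction` ("amplification"/"deletion") and `span`
#'   (>= 1 probes).
#' @param config A [sim_config()].
#' @return A [probe_panel()] with planted events recorded in attribute
#'   `truth`.
#' @export
gen_acgh <- function(n_samples, n_probes, events = NULL,
                     config = sim_config()) {
  n_samples <- stopifnot_scalar_count(n_samples, "n_samples")
  n_probes <- stopifnot_scalar_count(n_probes, "n_probes")
  stopifnot(inherits(config, "sim_config"))
  n_genes <- max(1L, n_probes %/% 10L)
  gene_of <- sprintf("GENE%03d", pmin(((seq_len(n_probes) - 1L) %/% 10L) + 1L,
                                      n_genes))
  probes <- data.frame(
    probe = sprintf("probe_%05d", seq_len(n_probes)),
    chrom = as.character(((seq_len(n_probes) - 1L) %/% 2000L) + 1L),
    pos = seq_len(n_probes) * 5000L,
    gene = gene_of,
    stringsAsFactors = FALSE
  )
  samples <- sprintf("S%03d", seq_len(n_samples))
  with_seed(config$seed, {
    L <- matrix(stats::rnorm(n_probes * n_samples, 0, config$lr_sd),
                n_probes, n_samples,
                dimnames = list(probes$probe, samples))
    if (!is.null(events) && nrow(events)) {
      for (k in seq_len(nrow(events))) {
        ev <- events[k, ]
        j <- if (is.numeric(ev$sample)) as.integer(ev$sample) else
          match(ev$sample, samples)
        rows <- which(probes$gene == ev$gene)
        if (is.na(j) || j < 1L || j > n_samples || !length(rows)) {
          stop("planted event outside the probe annotation", call. = FALSE)
        }
        span <- stopifnot_scalar_count(ev$span, "span")
        if (span > length(rows)) {
          stop("planted event span exceeds probes in gene", call. = FALSE)
        }
        shift <- if (identical(ev$direction, "deletion")) -config$cn_shift
                 else config$cn_shift
        L[rows[seq_len(span)], j] <- L[rows[seq_len(span)], j] + shift
      }
    }
    panel <- probe_panel(probes, samples, L)
    attr(panel, "truth") <- events
    attr(panel, "seed") <- config$seed
    panel
  })
}

#' Simulate a patient cohort with a pathway-mutation phenotype
#'
#' Pathway-mutant status is Bernoulli(`prevalence`); mutants receive
#' log-normal prednisolone LC50 shifted up by `lc50_fold` and exponential
#' event times accelerated by `hazard_ratio`, with uniform censoring over
#' the follow-up window. Subtype labels are assigned with mutation
#' enrichment in ETP-ALL and TLX.
#'
#' @param n_patients Cohort size (>= 0); 0 yields an empty table.
#' @param prevalence Pathway-mutation prevalence in [0, 1]; the default 0.32
#'   matches the 47/146 confirmation-cohort rate.
#' @param lc50_fold,hazard_ratio Effect sizes (> 0); defaults from `config`.
#' @param config A [sim_config()].
#' @param follow_up Maximum follow-up (months) for uniform censoring.
#' @return A data frame with columns `patient`, `subtype`, `pathway_mut`,
#'   `lc50`, `time`, `event`, `nr3c1_del`; a per-gene lesion table is
#'   attached as attribute `lesions`.
#' @export
gen_cohort <- function(n_patients = 146L, prevalence = 0.32,
                       lc50_fold = config$lc50_fold,
                       hazard_ratio = config$hazard_ratio,
                       config = sim_config(), follow_up = 120) {
  n_patients <- stopifnot_scalar_count(n_patients, "n_patients", min = 0L)
  stopifnot(inherits(config, "sim_config"))
  if (prevalence < 0 || prevalence > 1) stop("`prevalence` must be in [0, 1]")
  if (lc50_fold <= 0 || hazard_ratio <= 0) {
    stop("`lc50_fold` and `hazard_ratio` must be > 0")
  }
  pathway_genes <- c("IL7R", "JAK1", "JAK3", "NF1", "NRAS", "KRAS", "AKT")
  subtypes <- c("ETP-ALL", "TLX", "proliferative", "TALLMO")
  with_seed(config$seed, {
    mut <- stats::rbinom(n_patients, 1L, prevalence) == 1L
    subtype <- character(n_patients)
    if (n_patients) {
      subtype[mut] <- sample(subtypes, sum(mut), replace = TRUE,
                             prob = c(0.35, 0.35, 0.15, 0.15))
      subtype[!mut] <- sample(subtypes, sum(!mut), replace = TRUE,
                              prob = c(0.10, 0.20, 0.30, 0.40))
    }
    lc50 <- stats::rlnorm(n_patients, meanlog = log(0.5) +
                            log(lc50_fold) * mut, sdlog = 1)
    base_rate <- 1 / 60  # median event time about 42 months in wild-type
    t_event <- stats::rexp(n_patients, rate = base_rate * hazard_ratio^mut)
    t_cens <- stats::runif(n_patients, 0, follow_up)
    cohort <- data.frame(
      patient = sprintf("T%04d", seq_len(n_patients)),
      subtype = subtype,
      pathway_mut = mut,
      lc50 = lc50,
      time = pmin(t_event, t_cens),
      event = t_event <= t_cens,
      nr3c1_del = stats::rbinom(n_patients, 1L, 0.03) == 1L,
      stringsAsFactors = FALSE
    )
    lesions <- if (any(mut)) {
      data.frame(patient = cohort$patient[mut],
                 gene = sample(pathway_genes, sum(mut), replace = TRUE),
                 type = "mutation", stringsAsFactors = FALSE)
    } else {
      data.frame(patient = character(0), gene = character(0),
                 type = character(0), stringsAsFactors = FALSE)
    }
    attr(cohort, "lesions") <- lesions
    attr(cohort, "seed") <- config$seed
    cohort
  })
}

#' Simulate single-agent and mixture dose-response assays
#'
#' Single-agent viabilities follow their four-parameter Hill curves. For an
#' IC50-matched mixture at composition fractions (pA, pB) of total dose T,
#' the effect level x attained is defined by inverting the Loewe relation
#' pA*T / D_A(x) + pB*T / D_B(x) = tau, where D_A(x), D_B(x) are the
#' single-agent doses producing effect x. tau = 1 generates exact Loewe
#' additivity, tau < 1 synergy, tau > 1 antagonism; the combination index
#' estimated downstream recovers tau by construction. Multiplicative
#' log-normal noise with coefficient of variation `viability_cv` is applied
#' per well.
#'
#' @param curve_a,curve_b [hill_params()] for the two single agents
#'   (slopes > 0).
#' @param tau Interaction index (> 0); default from `config`.
#' @param designs List of [mixture_design()] objects; default the three
#'   standard ratios from [design_mixtures()].
#' @param config A [sim_config()].
#' @param replicates Wells per concentration (default 2, duplicate plating).
#' @return A long data frame with columns `agent` ("A", "B" or the ratio
#'   label), `series` ("single"/"mixture"), `conc` (total concentration),
#'   `replicate`, `viability` (% of control). Generating parameters are
#'   attached as attributes `tau`, `curve_a`, `curve_b`.
#' @export
gen_dose_response <- function(curve_a, curve_b, tau = config$tau,
                              designs = design_mixtures(curve_a$ic50,
                                                        curve_b$ic50),
                              config = sim_config(), replicates = 2L) {
  stopifnot(inherits(curve_a, "hill_params"), inherits(curve_b, "hill_params"))
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0")
  if (curve_a$slope <= 0 || curve_b$slope <= 0) stop("Hill slopes must be > 0")
  stopifnot(inherits(config, "sim_config"))
  single_mult <- 10^seq(1, -2, length.out = 9)  # nine-point dilution series
  cv <- config$viability_cv
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(config$seed, {
    noisy <- function(v, n) {
      if (cv == 0) return(rep(v, n))
      v * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    one_series <- function(agent, series, conc, viab) {
      do.call(rbind, lapply(seq_along(conc), function(i) {
        data.frame(agent = agent, series = series, conc = conc[i],
                   replicate = seq_len(replicates),
                   viability = noisy(viab[i], replicates),
                   stringsAsFactors = FALSE)
      }))
    }
    out <- rbind(
      one_series("A", "single", curve_a$ic50 * single_mult,
                 hill_viability(curve_a, curve_a$ic50 * single_mult)),
      one_series("B", "single", curve_b$ic50 * single_mult,
                 hill_viability(curve_b, curve_b$ic50 * single_mult))
    )
    for (des in designs) {
      stopifnot(inherits(des, "mixture_design"))
      if (any(des$series <= 0)) stop("design concentrations must be positive")
      pa <- des$frac_a
      pb <- 1 - pa
      x <- vapply(des$series, function(total) {
        loewe_effect(total, pa, pb, curve_a, curve_b, tau)
      }, numeric(1))
      top <- pa * curve_a$top + pb * curve_b$top
      bottom <- pa * curve_a$bottom + pb * curve_b$bottom
      viab <- top - x * (top - bottom)
      out <- rbind(out, one_series(des$ratio, "mixture", des$series, viab))
    }
    attr(out, "tau") <- tau
    attr(out, "curve_a") <- curve_a
    attr(out, "curve_b") <- curve_b
    attr(out, "seed") <- config$seed
    out
  })
}

# Effect level x in (0, 1) reached by a mixture of total dose `total` with
# composition fractions pa/pb, under a constant interaction index tau on the
# combination isobole.
loewe_effect <- function(total, pa, pb, curve_a, curve_b, tau) {
  f <- function(x) {
    pa * total / effect_dose(curve_a, x) +
      pb * total / effect_dose(curve_b, x) - tau
  }
  lo <- 1e-9
  hi <- 1 - 1e-9
  if (f(lo) < 0) return(lo)   # dose below any measurable effect
  if (f(hi) > 0) return(hi)   # dose beyond full effect
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
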