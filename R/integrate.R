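# Gene-level lesion integration and association testing.
#
# Per (gene, patient), six binary lesion features are derived -- Mut, Del,
# Amp and the unions MutDel, MutAmp, MutAber -- and tested against three
# endpoints: T-ALL subtype (Fisher's exact test), in vitro prednisolone LC50
# (Kruskal-Wallis) and survival (log-rank). All p-values are two-sided and
# nominal: no multiple-testing correction is applied, but the number of
# tests per endpoint is reported.

#' Build the gene x patient six-feature lesion matrix
#'
#' Features are presence/absence aggregated over lesions: at least one
#' qualifying lesion makes the feature present. Patients without copy-number
#' data get missing (NA), not absent, Del/Amp features; unions follow
#' three-valued logic, so Mut = TRUE makes MutAber TRUE even when the
#' copy-number side is missing.
#'
#' @param mutations Data frame with columns `patient`, `gene` (one row per
#'   mutation).
#' @param cn_calls Data frame with `patient` (or `sample`), `gene`,
#'   `direction` as from [call_gene_cnv()].
#' @param cohort Data frame with a `patient` column defining the patient
#'   universe.
#' @param cn_patients Patients with copy-number data; defaults to all
#'   cohort patients. Others get NA Del/Amp features.
#' @return A long data frame with one row per (gene, patient) and logical
#'   columns `Mut`, `Del`, `Amp`, `MutDel`, `MutAmp`, `MutAber`.
#' @export
build_features <- function(mutations, cn_calls, cohort,
                           cn_patients = cohort$patient) {
  if (!is.null(cn_calls$sample) && is.null(cn_calls$patient)) {
    cn_calls$patient <- cn_calls$sample
  }
  patients <- unique(cohort$patient)
  for (tab in list(mutations, cn_calls)) {
    bad <- setdiff(unique(tab$patient), patients)
    if (length(bad)) {
      stop("unknown patient id(s) in lesion table: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  genes <- sort(unique(c(mutations$gene, cn_calls$gene)))
  grid <- expand.grid(gene = genes, patient = patients,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(g, p) paste(g, p, sep = "\r")
  mut_set <- unique(key(mutations$gene, mutations$patient))
  del <- cn_calls[cn_calls$direction == "deletion", ]
  amp <- cn_calls[cn_calls$direction == "amplification", ]
  del_set <- unique(key(del$gene, del$patient))
  amp_set <- unique(key(amp$gene, amp$patient))
  k <- key(grid$gene, grid$patient)
  grid$Mut <- k %in% mut_set
  has_cn <- grid$patient %in% cn_patients
  grid$Del <- ifelse(has_cn, k %in% del_set, NA)
  grid$Amp <- ifelse(has_cn, k %in% amp_set, NA)
  grid$MutDel <- grid$Mut | grid$Del
  grid$MutAmp <- grid$Mut | grid$Amp
  grid$MutAber <- grid$Mut | grid$Del | grid$Amp
  grid
}

assoc_result <- function(gene, feature, endpoint, test, p, n) {
  data.frame(gene = gene, feature = feature, endpoint = endpoint,
             test = test, n = n, p = p, stringsAsFactors = FALSE)
}

#' Feature-subtype association (Fisher's exact test)
#'
#' Two-sided Fisher's exact test of the feature x subtype contingency table
#' over patients with a non-missing feature; r x c tables are handled by the
#' exact network algorithm.
#'
#' @param feature Logical feature vector (one per patient; NA = missing).
#' @param subtype Subtype labels (character or factor).
#' @param gene,feature_name Annotation carried into the result.
#' @return A one-row association-result data frame.
#' @export
assoc_subtype <- function(feature, subtype, gene = NA_character_,
                          feature_name = NA_character_) {
  ok <- !is.na(feature) & !is.na(subtype)
  if (!any(ok)) stop("feature is missing for all patients", call. = FALSE)
  f <- factor(feature[ok], levels = c(FALSE, TRUE))
  s <- factor(as.character(subtype[ok]))
  if (nlevels(droplevels(s)) < 2L) {
    stop("need at least two subtype levels", call. = FALSE)
  }
  tab <- table(f, droplevels(s))
  p <- stats::fisher.test(tab, workspace = 2e6)$p.value
  assoc_result(gene, feature_name, "subtype", "fisher", p, sum(ok))
}

#' Feature-LC50 association (Kruskal-Wallis)
#'
#' Tie-corrected Kruskal-Wallis rank test of LC50 across feature groups; in
#' the two-group case this equals the Wilcoxon rank-sum chi-square form.
#'
#' @param feature Group labels (logical feature or factor), one per patient.
#' @param lc50 Positive LC50 values (NA = unavailable).
#' @inheritParams assoc_subtype
#' @return A one-row association-result data frame with the H statistic in
#'   column `stat`.
#' @export
assoc_lc50 <- function(feature, lc50, gene = NA_character_,
                       feature_name = NA_character_) {
  ok <- !is.na(feature) & !is.na(lc50)
  g <- factor(feature[ok])
  if (nlevels(droplevels(g)) < 2L || any(table(droplevels(g)) == 0L)) {
    stop("need at least two non-empty groups with LC50 values",
         call. = FALSE)
  }
  kt <- stats::kruskal.test(lc50[ok], droplevels(g))
  out <- assoc_result(gene, feature_name, "lc50", "kruskal-wallis",
                      kt$p.value, sum(ok))
  out$stat <- unname(kt$statistic)
  out
}

#' Feature-survival association (log-rank)
#'
#' Log-rank chi-square test with standard risk-set accounting of censored
#' observations.
#'
#' @param feature Group labels, one per patient.
#' @param time Follow-up times (>= 0).
#' @param event Logical event indicator (FALSE = censored).
#' @inheritParams assoc_subtype
#' @return A one-row association-result data frame with the chi-square
#'   statistic in column `stat`.
#' @export
assoc_survival <- function(feature, time, event, gene = NA_character_,
                           feature_name = NA_character_) {
  ok <- !is.na(feature) & !is.na(time) & !is.na(event)
  g <- droplevels(factor(feature[ok]))
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (!any(event[ok])) stop("need at least one event", call. = FALSE)
  sd_fit <- survival::survdiff(
    survival::Surv(time[ok], event[ok]) ~ g)
  df <- length(sd_fit$n) - 1L
  p <- stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  out <- assoc_result(gene, feature_name, "survival", "log-rank", p, sum(ok))
  out$stat <- unname(sd_fit$chisq)
  out
}

#' Segregate patients into pathway / PTEN / rest groups
#'
#' Pathway when the patient carries at least one mutation in an IL7R
#' signaling pathway gene (this takes precedence), else PTEN when a
#' PTEN-inactivating lesion is present, else rest.
#'
#' @param lesions Data frame with `patient`, `gene` (and optionally `type`)
#'   rows for each lesion.
#' @param patients Patient universe (character vector).
#' @param pathway_genes IL7R signaling pathway gene set.
#' @param pten_genes PTEN gene set.
#' @param precedence `"pathway"` (default) or `"pten"` for doubly-lesioned
#'   patients.
#' @return Factor with levels pathway, PTEN, rest, one per patient.
#' @export
group_pathway <- function(lesions, patients,
                          pathway_genes = c("IL7R", "JAK1", "JAK3", "NF1",
                                            "NRAS", "KRAS", "AKT"),
                          pten_genes = "PTEN",
                          precedence = c("pathway", "pten")) {
  precedence <- match.arg(precedence)
  has_pathway <- patients %in% lesions$patient[lesions$gene %in% pathway_genes]
  has_pten <- patients %in% lesions$patient[lesions$gene %in% pten_genes]
  lab <- rep("rest", length(patients))
  if (precedence == "pathway") {
    lab[has_pten] <- "PTEN"
    lab[has_pathway] <- "pathway"
  } else {
    lab[has_pathway] <- "pathway"
    lab[has_pten] <- "PTEN"
  }
  factor(lab, levels = c("pathway", "PTEN", "rest"))
}

#' Exclude patients with NR3C1 deletions
#'
#' Removes patients flagged as carrying an NR3C1 deletion (a consequence of
#' chromosomal 5q deletion) before steroid-response and survival
#' association analyses, reporting the removal count.
#'
#' @param cohort Cohort data frame with a logical `nr3c1_del` column.
#' @param quiet Suppress the audit message.
#' @return The cohort without the flagged patients; the number removed is
#'   attached as attribute `n_excluded`.
#' @export
exclude_nr3c1_deleted <- function(cohort, quiet = FALSE) {
  if (is.null(cohort$nr3c1_del)) stop("`nr3c1_del` flag missing", call. = FALSE)
  drop <- isTRUE_vec(cohort$nr3c1_del)
  out <- cohort[!drop, , drop = FALSE]
  if (!quiet) {
    message(sprintf("excluded %d of %d patients with NR3C1 deletion",
                    sum(drop), nrow(cohort)))
  }
  attr(out, "n_excluded") <- sum(drop)
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Screen all (gene, feature, endpoint) associations
#'
#' Tests every gene's six features against each requested endpoint where
#' the data allow (at least two non-missing groups, both non-empty), flags
#' results below `alpha`, and reports the number of tests per endpoint.
#' P-values stay nominal.
#'
#' @param features A [build_features()] table.
#' @param cohort Cohort data frame with `patient`, `subtype`, `lc50`,
#'   `time`, `event`.
#' @param alpha Nominal flagging threshold, default 0.05.
#' @param endpoints Endpoints to test among subtype, lc50, survival.
#' @return A data frame of association results with a logical `flag`
#'   column; tests per endpoint in attribute `n_tests`.
#' @export
screen_all <- function(features, cohort, alpha = 0.05,
                       endpoints = c("subtype", "lc50", "survival")) {
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  feature_names <- c("Mut", "Del", "Amp", "MutDel", "MutAmp", "MutAber")
  res <- list()
  if (!nrow(cohort) || !nrow(features)) {
    out <- assoc_result(character(0), character(0), character(0),
                        character(0), numeric(0), integer(0))
    out$flag <- logical(0)
    attr(out, "n_tests") <- stats::setNames(rep(0L, length(endpoints)),
                                            endpoints)
    return(out)
  }
  for (g in unique(features$gene)) {
    fg <- features[features$gene == g, ]
    fg <- fg[match(cohort$patient, fg$patient), ]
    for (fn in feature_names) {
      f <- fg[[fn]]
      ok <- !is.na(f)
      if (sum(ok) < 2L || length(unique(f[ok])) < 2L) next
      for (ep in endpoints) {
        r <- tryCatch(switch(ep,
          subtype = assoc_subtype(f, cohort$subtype, g, fn),
          lc50 = assoc_lc50(f, cohort$lc50, g, fn),
          survival = assoc_survival(f, cohort$time, cohort$event, g, fn)
        ), error = function(e) NULL)
        if (!is.null(r)) res[[length(res) + 1L]] <- r
      }
    }
  }
  out <- if (length(res)) {
    r <- do.call(rbind, lapply(res, function(x) x[, c("gene", "feature",
                                                      "endpoint", "test",
                                                      "n", "p")]))
    r
  } else {
    assoc_result(character(0), character(0), character(0), character(0),
                 numeric(0), integer(0))
  }
  out$flag <- out$p < alpha
  attr(out, "n_tests") <- table(factor(out$endpoint, levels = endpoints))
  out
}

#' Two-group comparison (Mann-Whitney U)
#'
#' Exact two-sided Mann-Whitney test when both groups have at most 8
#' observations and no ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param a,b Numeric observation vectors, both non-empty.
#' @return Two-sided p-value.
#' @export
group_compare <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- max(length(a), length(b)) <= 8L && !ties
  stats::wilcox.test(a, b, exact = exact, correct = FALSE)$p.value
}
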