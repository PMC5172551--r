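---
title: "Methods: models, calibration and design choices in tallpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in tallpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`tallpipe` re-implements, as one tested package, the computational chain used
to dissect steroid resistance in pediatric T-ALL: somatic variant confidence
calibration, structural-variant junction filtering, aCGH copy-number calling,
lesion–phenotype association, and combination-index synergy analysis. This
vignette records the models behind each stage, the parameters that matter,
the numerical choices, and the design decisions taken where the procedure
left genuine freedom. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Variant confidence calibration

**Whole-genome calls.** Each call carries a total score TS (confidence in
the call) and a somatic score SS (confidence that it is tumor-specific).
High-confidence status is the conjunction SS ≥ 0.1 ∧ TS ≥ 100, with both
comparisons inclusive so that a call sitting exactly on a threshold is
accepted. `roc_curve()` evaluates the true/false-positive rates of every
candidate threshold pair on a validated call set by direct counting; the
default operating pair is exposed rather than optimized, because a fixed,
auditable cutoff is easier to reason about than a data-driven one, and the
grid lets a user inspect the trade-off themselves. `classify_wgs()` is
monotone by construction: raising either score can never demote a call.

**Targeted-exome calls.** The acceptance region in the (read depth, overall
quality) plane is calibrated on validated true positives only — a one-class
problem, since false positives from a different platform are not a random
sample of future errors. The Gaussian one-class boundary is the Mahalanobis
ellipse of the TP cloud: centre and shape are the TP sample mean and
covariance, and the squared radius is the smallest empirical squared-distance
quantile that keeps the training false-negative rate at or below the target
(default FNr 0.10). The empirical-quantile rule (rather than the χ²
quantile) guarantees the achieved FNr never exceeds the target on the
training set, which is the property the calibration is for; for large
Gaussian clouds the two coincide — with 10,000 standard-normal TP points the
fitted squared radius is within 5% of the χ²(2 df) 0.90 quantile (≈ 4.61),
which the test suite checks. Near-degenerate covariances are
ridge-regularized by `1e-8 × trace`; if all TP points coincide the boundary
degenerates to that point with radius 0 and FNr 0.

For INDEL-like calls, where the two platforms agree poorly and an elliptical
model is unconvincing, the boundary is instead an axis-aligned accept rule
(depth ≥ t_d ∧ quality ≥ t_q) found by exhaustive search over all candidate
thresholds: among rules meeting the FNr target, the one with minimal
false-positive rate wins, with ties broken toward the higher quality then
higher depth threshold. A depth-2 axis-aligned rule is exactly enumerable and
oracle-checkable, which an arbitrary induced decision tree is not. On the
package's default synthetic clouds the INDEL-setting FPr is far above the
SNV-setting FPr, mirroring the poor cross-platform INDEL concordance.

**Filtering.** Exome calls are kept at depth ≥ 10× for SNVs, ≥ 5× for
INDELs, and variant allele fraction ≥ 30%, all inclusive. Database
polymorphisms are dropped, except calls whose (gene, amino-acid position)
is hotspot-annotated, which are retained — a germline database can contain a
recurrently somatic position. The polymorphism index is an abstract lookup
loaded from a table, not a live database query, because database build drift
would make runs irreproducible. Coordinates are 1-based inclusive
throughout; a genome-build string travels as table metadata and must match
when tables are joined, since mixed builds are a classic silent-join hazard.

## Structural-variant junctions

A junction passes iff all seven criteria hold: mate pairs ≥ 10 (inclusive,
"at least ten"), successful de novo assembly, mapping-diversity span
strictly greater than 70 bp ("more than 70 bp"), no underrepresented-repeat
overlap, absent from dbSNP, not a transposable-element (AluY/L1) deletion
signature, and absent from the baseline normal genomes. The filter is a pure
conjunction: a record passes exactly when its failure-reason list is empty,
and the reasons enumerate every violated criterion, not just the first. The
repeat/dbSNP/transposon/baseline memberships are input flags rather than
recomputed annotations, because the underlying resources are not
redistributable with the package.

Rearrangement typing uses the standard orientation convention after ordering
the two breakpoints by position: inter-chromosomal junctions are
translocations; (+,−) strand pairs are deletion-type, (−,+) duplication-type
and same-strand pairs inversion-type. Junctions with any breakpoint within
1 kb of another junction's breakpoint in the same sample are merged into one
complex call; the window is configurable (`complex_window`) since no
published rule fixes it, and 1 kb is the scale at which independent simple
events are no longer plausible.

Non-template nucleotides at a junction are counted as the junction sequence
length minus the maximal exact prefix match against flank A and the maximal
exact suffix match against flank B, floored at zero so that micro-homology
(flank matches overlapping) reports no insert. Exact matching is
deterministic and recovers planted insert lengths identically on simulated
junctions, which the suite asserts.

## Copy number

Wave-corrected log10 ratios L convert to copy number as CN = 2·10^L (so
L = 0 means the diploid CN 2), and thresholding happens on the CN scale
after conversion, following the stated formula order. For each probe, the
mean and SD of CN are taken across all samples, including the tested sample
(`loo = TRUE` switches to leave-one-out). The SD is the population SD
(denominator n): it is a cohort-descriptive scale parameter, and with it the
calls are exactly invariant under duplicating every sample — the
cohort-relative property the test suite asserts. A (sample, gene) call needs
at least three consecutive probes strictly beyond mean ± 2·SD, all in the
same direction; strict inequality makes the degenerate constant-matrix case
(SD = 0) well-defined, with no calls. Each maximal qualifying run yields one
call, since gene-level status is the object of interest. "Average CN" is
read per probe, not per gene, matching "the corresponding probe sets".
Wave correction itself is an input contract: the module consumes corrected
ratios and does not reimplement the correction.

## Lesion–phenotype integration

The six features per (gene, patient) are Mut, Del, Amp and the unions
MutDel, MutAmp, MutAber, each a presence/absence bit aggregated over all
qualifying lesions. Patients without aCGH have Del/Amp missing (NA), not
absent; unions follow R's three-valued logic, so a known mutation makes
MutAber TRUE even when the copy-number side is unknown. Endpoint tests are
the field-standard ones, called from base R and `survival`: Fisher's exact
test for subtype (one-vs-rest 2×2 or r×c), Kruskal–Wallis for LC50 (equal to
the Wilcoxon rank-sum chi-square form in the two-group case), and the
log-rank test for survival. Two-group comparisons use the exact Mann–Whitney
distribution when both groups have ≤ 8 observations and no ties, and the
tie-corrected normal approximation otherwise. P-values are nominal by
design — the screen is for hypothesis prioritization — but
`screen_all()` reports the number of tests per endpoint so a reader can
judge multiplicity. Patients missing an endpoint are dropped per test, not
imputed.

Pathway grouping assigns "pathway" when a patient has at least one mutation
in the IL7R signaling set (IL7R, JAK1, JAK3, NF1, NRAS, KRAS, AKT), else
"PTEN", else "rest". For patients with both kinds of lesion the pathway
label takes precedence by default (the pathway lesion is the hypothesis
under test); `precedence = "pten"` flips it. Patients flagged for NR3C1
deletion are removed before steroid-response and survival analyses, with the
removal count audited.

## Synergy analysis

**Curve model.** Viability follows the four-parameter logistic
V(d) = bottom + (top − bottom) / (1 + (d/IC50)^h). Fits are least squares
(Levenberg–Marquardt via `minpack.lm`, with a derivative-free fallback for
starts where the exact-data Jacobian is numerically singular); IC50 and
slope are fitted on the log scale to enforce positivity. Variants with top
locked to 100 and/or bottom locked to 0 are preferred whenever the
extra-sum-of-squares F-test does not reject them at α = 0.05 — locking is
the default posture and the free fit the fallback, because asymptotes
outside the observed range are poorly identified from seven-point series.
Duplicate wells are averaged before fitting. All effect levels are on the
responding-fraction scale (normalized to each curve's maximal effect), so
the fitted midpoint *is* the IC50; when the maximal effect is below 20% the
IC50 is reported as not determined, and fit failures propagate as flagged
NA, never silently as zero.

**Combination index.** Mixtures are designed equipotently: the undiluted
composition of the r_A:r_B ratio is w_A·IC50_A + w_B·IC50_B with weights
(0.5, 0.5), (0.8, 0.2), (0.2, 0.8) for 1:1, 4:1, 1:4, and the seven-point
series spans 10× down to 0.01× in IC50-equivalent units. The CI at effect
level x is the mutually exclusive (two-term) Chou–Talalay form
CI = d_A/D_A(x) + d_B/D_B(x), with the mixture dose from the fitted mixture
curve, its composition from the design, and the reference doses from the
single-agent fits of the same experiment. The two-term form is the variant
under which the sham identity holds exactly: a drug combined with itself at
any ratio gives CI = 1 at every effect level, which the suite verifies to
1e-6 on noise-free curves. CI is NA, with a reason, whenever any required
curve does not reach the effect level — in particular ED75 is NA when a
maximal effect is below 75%.

**Classification.** At each level: strong synergy when mean CI < 0.3;
synergy when mean CI + SD < 1.0 (SD taken as 0 when absent, and "<0.10"
bounds read at the bound); otherwise no synergy. The overall call is
synergistic when either ED50 or ED75 qualifies. The SD-penalized rule is the
unique simple rule consistent with every labeled row and all six
reproducible per-inhibitor counts in the packaged table; antagonism
(mean CI − SD > 1.5) is a separate flag rather than a label, because rows
with mean CI up to 1.65 are labeled "No synergy" in the source table. The SD
is reported only when at least three ratios are evaluable. One inhibitor
column (AZD6244) is not reproducible from the printed values under any
simple rule tried — the transcribed table supports 6 synergistic of 8
evaluable — and is therefore reported but not treated as an anchor.

## The synthetic-data module

The generators emulate the statistical structure each stage assumes, with
planted truth carried in attributes that no downstream function reads:

* **Score clouds.** True WGS calls cluster tightly at high (SS, TS), false
  calls scatter at low scores with a heavy TS tail; the default 46-call set
  splits 30 true / 16 false. TES true positives are an elliptical Gaussian
  in (depth, quality) — defaults 218 TP vs 352 FP for SNV-like data, 11 vs
  41 heavily overlapping for INDEL-like data — and false positives have a
  heavier low-quality tail. The published material shows only scatterplots,
  so these distributions are chosen to make the published thresholds
  meaningful, and their dispersions are tunable (`score_sd`), not inferred.
* **Junctions.** Passing records satisfy all seven criteria; each failing
  record violates exactly one, chosen uniformly, so filter errors are
  attributable. Non-template inserts are truncated-geometric with mean about
  18 nt on [1, 221], matching the observed insert-length range.
* **aCGH.** Baseline log ratios are Normal(0, 0.02); planted events shift a
  probe run by ±0.3 log10 (about CN 1 for deletions, CN 4 for
  amplifications), the scale of single-copy events after wave correction.
* **Cohorts.** Pathway mutation is Bernoulli with default prevalence 0.32
  (the 47/146 rate); mutants' LC50 is log-normal shifted by a 3-fold
  default; event times are exponential with a default hazard ratio 2.5 and
  uniform censoring over 120 months — the simplest model supporting
  log-rank power and calibration checks. Subtypes are assigned with
  mutation enrichment in ETP-ALL and TLX.
* **Dose–response.** Single agents follow their Hill curves; for a mixture
  at composition (p_A, p_B) of total dose T, the attained effect x solves
  p_A·T/D_A(x) + p_B·T/D_B(x) = τ, a constant interaction index on the
  isobole. This is the minimal generative model under which the CI
  estimator has a known truth: by construction the estimated CI recovers τ.
  The default study conditions use Hill slope 1 for both agents; with equal
  slopes the mixture locus is itself exactly a 4PL curve, so noise-free
  recovery is exact, while with unequal slopes the locus deviates from the
  4PL family and recovery is approximate. Viability noise is multiplicative
  log-normal (plate-reader convention) with CV 5% by default, mean-corrected
  so expectation is preserved.

All randomness flows through one seed per generator call, restored on exit,
and the seed is recorded in the output attributes; a fixed `sim_config`
yields byte-identical output.

**What passing tests do and do not show.** The generators reproduce the
*statistical shape* each stage assumes — cluster geometry, criterion
violations, shift-plus-noise copy number, proportional hazards, constant-τ
isoboles. They do not simulate read-level error profiles, GC waves,
segmentation-scale correlation structure along chromosomes, informative
censoring, or inter-plate drift. Passing tests therefore demonstrate
correctness of the algorithms under their stated models, not performance on
raw instrument data.

## Problem sizes and runtime choices

The suite and acceptance script use desk-scale sizes chosen so the full run
completes in well under a minute per module: 570-point TES clouds (10,000
points for the χ² limit check), 20-sample × 200-probe aCGH panels with 60
planted-event and 200 null replicates, 60-patient cohorts over 500
calibration replicates (146 for power checks), and 50 replicates per
interaction index for noisy CI recovery. These sizes give the binomial and
Kolmogorov–Smirnov checks enough resolution at their stated tolerances;
larger runs change nothing structurally.

## Known limitations

* The junction module annotates and filters; it does not discover junctions
  from reads, and the published per-type rearrangement counts are not
  reproducible without the original genomes.
* The copy-number caller is the three-probe ±2 SD rule, deliberately not a
  segmentation algorithm (no CBS/HMM); allele-specific copy number is out of
  scope.
* Association screening is univariate by design: no Cox regression,
  multivariable adjustment, or multiplicity correction.
* Synergy is Loewe-based; Bliss independence, ZIP and response-surface
  models are out of scope, as is any pharmacokinetic extrapolation.
* Cohort-scale published associations (prevalence, LC50 and survival
  p-values) depend on patient-level data that are not redistributable; the
  package covers them with calibration and power properties on synthetic
  cohorts instead.
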