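---
title: "Community typing of gut microbiome profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community typing of gut microbiome profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Stool metagenomes vary enormously between people, which makes single-taxon
biomarkers fragile. A long-standing simplification is to collapse each
sample's genus-level composition into one of a small number of community
types ("enterotypes"): typically a *Bacteroides*-dominated, a
*Prevotella*-dominated, and a *Firmicutes*-diverse cluster, with finer
models splitting off the extreme *Bacteroides*/*Prevotella* tails. Whether
such clusters carry clinical signal — in prevalent disease, in disease
subtypes, in incident-disease risk — is an empirical question that requires
a full pipeline: clustering, cluster-number selection, phenotype screening
with multiplicity control, confounder handling, and survival analysis.
`commtype` implements that pipeline end to end, together with a synthetic
cohort generator with known ground truth, so every stage is testable
without access to restricted cohort data.

# The mixture model

Counts for sample $i$ over $G$ genera are modelled by a Dirichlet
multinomial mixture (DMM). Component $k$ has concentration vector
$\alpha_k \in \mathbb{R}_{>0}^G$ and weight $\pi_k$; conditional on
component $k$ and depth $n_i$ the counts follow the Dirichlet-multinomial

$$
P(x \mid \alpha) \;=\; \frac{n!}{\prod_j x_j!}\,
\frac{\Gamma(A)}{\Gamma(n+A)} \prod_j
\frac{\Gamma(x_j+\alpha_j)}{\Gamma(\alpha_j)}, \qquad A = \sum_j \alpha_j .
$$

`dm_log_pmf()` evaluates this entirely through `lgamma`, so depths of
$10^4$ or more are safe. The Dirichlet layer absorbs the overdispersion of
real taxon counts that a plain multinomial cannot represent; the component
mean composition is $m_{kj} = \alpha_{kj}/A_k$ and $A_k$ controls
within-cluster heterogeneity (small $A_k$ = loose cluster).

## Fitting

`fit_dmm()` runs expectation–maximisation:

* **E-step** — responsibilities $r_{ik} \propto \pi_k\,\mathrm{DM}(x_i \mid
  \alpha_k)$, computed on the log scale with a row-wise log-sum-exp.
* **M-step** — $\pi_k$ is the mean responsibility; each $\alpha_k$ is
  improved by a handful of box-constrained quasi-Newton (L-BFGS-B) steps on
  the $r$-weighted DM log-likelihood in $\log\alpha$ space, with the
  analytic digamma gradient. Partial M-steps make this a generalised EM, so
  the observed-data log-likelihood is still monotone (asserted in the test
  suite via the stored `ll_trace`).

Initialisation is a seeded k-means on the proportion vectors; additional
starts perturb a quarter of the assignments, and the best start by final
log-likelihood wins. Defaults: `n_starts = 5`, relative tolerance
`tol = 1e-6`, `max_iter = 1000`, `m_step_maxit = 8`. The box constraint
$\log\alpha \in [\log 10^{-6}, \log 10^{6}]$ exists purely to stop a dying
component (near-zero weights, flat objective) from running to numerical
infinity; a component whose weight falls below the floor $1/(10N)$, or a
start whose log-likelihood is not a finite negative number, is flagged and
can never win the multi-start.

Raw genus counts are modelled as-is — the DM conditions on the realised
sequencing depth, so no rescaling or rarefaction is applied first.

## Model evidence and choosing K

`laplace_evidence()` scores a fit by the negative log marginal likelihood
under a Laplace approximation taken in $\log\alpha$ space:

$$
-\Big[\log p(D\mid\hat\theta) + \log p(\hat\theta) +
\tfrac{d}{2}\log 2\pi - \tfrac12 \log\det H\Big],
$$

with $d = K\,G$ free concentration parameters, an independent
Exponential(rate $0.1$) shrinkage prior on every $\alpha_{kj}$ (weak — the
prior mean 10 is far above typical per-genus concentrations, so it mostly
regularises the integral), and $H$ the Hessian of the negative log
posterior at its mode. Three deliberate choices:

* **Mixing weights are conditioned on, not integrated.** $\pi$ is held at
  its maximum-likelihood value and contributes no parameters to $d$; the
  evidence compares concentration structures. Because every candidate $K$
  is treated identically, the comparison is fair, and the
  over-parameterisation penalty (duplicating a component always worsens
  the score — a tested invariant) still operates through the $\alpha$
  block.
* **Per-component Hessian with responsibilities fixed.** $H$ is block
  diagonal over components, each block the analytic (digamma/trigamma)
  Hessian of the responsibility-weighted DM log-posterior. The blocks have
  the cheap structure $cJ + \mathrm{diag}(d_j)$, so no numerical
  differentiation is needed.
* **A MAP polish before expanding.** EM maximises the likelihood, not the
  posterior, so each $\alpha_k$ is first pushed to the posterior mode (a
  few more quasi-Newton steps with the prior included, responsibilities
  fixed) before the quadratic expansion. On a small single-component
  instance the resulting evidence sits within one nat of brute-force grid
  integration of the marginal likelihood (tested).

Degenerate Hessians are handled by symmetric eigenvalue clipping at
$10^{-8}$ before the log-determinant, with a warning.

`fit_dmm_curve()` fits $K = 1..k_{\max}$ (default 10) and `select_k()`
formalises "stop when the fit stops improving": the elbow rule returns the
smallest $K$ whose gain to $K{+}1$ falls below `tau = 0.05` of the first
gain, with a global-minimum rule available for sensitivity analysis. The
rule is invariant to adding a constant to all scores. The enterotype model
is the fixed $K = 3$ fit from the same curve; the community-type model is
the selected-$K$ fit.

## Descriptors

* `driving_genera()` ranks genera per cluster by
  $|m_{kj} - \overline{m_{\cdot j}}|$ (ties alphabetical) — the genera that
  give a cluster its identity, including characteristic depletions.
* `gradient_score()` is the continuous alternative to discrete clusters:
  $g_i = \log\big((\text{Prevotella}_i + c)/(\text{Bacteroides}_i +
  c)\big)$ on genus counts, natural log, pseudocount $c = 0.5$ (half a
  count — the usual zero-guard; configurable). It is antisymmetric under
  swapping the two genera and strictly increasing in Prevotella.
* `alpha_diversity()` reports observed richness and the Shannon index
  (natural log); `bray_curtis_pcoa()` ordinates samples by classical
  metric scaling of Bray–Curtis dissimilarities on proportions, reporting
  negative eigenvalues rather than correcting them.

# Preprocessing

`drop_low_depth_samples()` takes either an explicit `min_reads` cutoff or
`n_lowest` (remove exactly the n shallowest samples — the form used when a
study reports removing "a few" outliers without publishing a threshold).
`filter_prevalent_taxa()` keeps a taxon when its per-sample relative
abundance reaches `rel_abund` (inclusive, default 0.001) in strictly more
than `prevalence_frac` (default 0.10) of samples; both inclusivity
conventions are configurable because published threshold wordings are
usually ambiguous. `aggregate_to_genus()` sums species to genera from the
lineage strings and pools genus-less species into `"unclassified"` rather
than dropping them, so per-sample depth — which the multinomial model
conditions on — is conserved exactly. `group_ehr_factors()` keeps disease
indicators with at least 20 carriers and rolls drug codes up the ATC
hierarchy (level 5 → 4 → 3) until the prefix group — all users of any code
under the prefix — reaches 20, dropping codes that never do.

# Association testing

The regression direction is phenotype-as-outcome, cluster-as-predictor:
it supports covariate adjustment and likelihood-ratio tests uniformly
across factor types. The cluster enters as a categorical term with the
largest cluster as reference; the gradient as one numeric column.

* binary factors: logistic regression, global cluster p from the LRT
  against the covariate-only model;
* continuous (and, by default, ordinal) factors: linear regression, LRT
  likewise;
* categorical factors: Pearson chi-squared on the factor × cluster table
  (no covariates — the test has no adjustment mechanism, and asking for
  one is an error).

Complete cases per test; missingness is never imputed. Benjamini–Hochberg
correction is applied within one representation's factor family
(`screen_factors()`), ET / CT / gradient separately, matching how
per-model significant counts are usually reported; `bh_fdr()` delegates to
`stats::p.adjust` and is cross-checked against the step-up definition in
the tests. `compare_representations()` refits the same model family with
each representation term and compares AICs — the 4 extra parameters of a
5-cluster term must buy their likelihood, so a genuinely cluster-specific
effect wins CT and a ratio-shaped effect wins the gradient (both tested as
discrimination properties).

For prevalent diseases, `adjusted_disease_test()` adds age, BMI, gender
and Bristol stool score (entered numerically; a categorical option exists)
and `drug_confounding_scan()` implements the post-hoc rule: a
disease–cluster association is confounded if at least one drug exists such
that the cluster no longer improves the model (cluster-term LRT p >
`alpha = 0.05`, a threshold the rule itself leaves open) once that drug is
in the model. Constant or disease-identical drug columns are skipped with
a note.

# Incident-disease screening

`screen_incident()` excludes each disease's prevalent cases, then fits
adjusted Cox proportional-hazards models (`survival::coxph`, Efron ties —
the safer default with registry-dated events) with the cluster as a
multi-level term. The headline p-value is the LRT of the cluster term
against the covariate-only model; per-level hazard ratios versus the
largest cluster are reported alongside for interpretation. The PH
assumption is checked with scaled Schoenfeld residuals
(`survival::cox.zph`, Kaplan–Meier time transform by default). BH runs
across diseases within each representation. Time origin is sample
collection; entry staggering, competing risks and time-varying covariates
are out of scope.

# The synthetic cohort generator

`generate_counts()` draws, per sample, a component from the mixing
weights, proportions from that component's Dirichlet, a depth from
LogNormal(log $10^4$, 0.3) — a round number near typical taxon-table
totals, chosen for test speed — and counts from the multinomial.
`alpha_preset_3()` encodes the canonical three roles
(Bacteroides-heavy, Prevotella-heavy, spread/Firmicutes-like with higher
diversity); `alpha_preset_5()` adds the extreme Bacteroides/Prevotella
tails so that collapsing 1,2 / 3 / 4,5 recovers the three roles. Default
mixing weights (0.40, 0.25, 0.35) make no cluster rare.

`generate_phenotypes()` draws covariates from plausible cohort
distributions — age truncated-Normal(50, 10) on [23, 89], 70% female, BMI
Normal(26, 4), Bristol score centred at 4 with a mild cluster shift — and
factors from logistic / Gaussian / thresholded-latent / tilted-multinomial
models on the cluster, gradient and covariate terms. A `drug_confounder`
can ride along in either causal direction: indication (disease → drug) or
full mediation (cluster → drug → factor), the structure the deconfounding
scan must flag. `generate_survival()` draws Weibull event times with
per-cluster log hazard ratios and administrative censoring at 3.1 years
with ±1 year uniform entry jitter, emulating a short-follow-up biobank
cohort.

What the generator deliberately does **not** emulate: real taxon
inventories and their correlation structure, zero-inflation beyond what
the DM produces, realistic disease prevalences and comorbidity, informative
censoring, or cohort selection effects. Passing tests therefore demonstrate
that the machinery is correct under its own model assumptions — not that
those assumptions hold in any particular cohort.

# Validation sizes and numerical choices

The test suite validates the pmf by exhaustive enumeration (all outcomes
of $n \le 6$ over 3 taxa) and $10^6$-draw Monte-Carlo sampling; parameter
recovery and K-selection on 600-sample, 40-genus cohorts at depth ≈ 5000
(20 seeds for selection, 5 for recovery); association calibration on 1000
null replicates; representation discrimination and deconfounding on 50–100
replicate cohorts; Cox behaviour against a grid-search oracle on 8-subject
instances, 500-replicate coverage at n = 2000, and a 100-replicate
piecewise-hazard power study for the PH test; and the full demo pipeline
(N = 1000, G = 50, `k_max = 4`, single start) twice for checksum-identical
determinism. These sizes are the package's chosen validation scale: large
enough for the stated statistical bands, small enough to run routinely.

Numerical details worth knowing: all log-likelihoods use `lgamma`
directly; responsibilities are normalised by log-sum-exp; EM convergence is
relative, $|\Delta\ell| < 10^{-6}(|\ell| + 1)$; posterior ties in
`assign_clusters()` break to the lowest component index; ranking ties in
`driving_genera()` break alphabetically; zero-depth samples are rejected
rather than patched.

# Limitations

* The Laplace evidence conditions on the mixing weights and uses a
  block-diagonal Hessian; it is a model-selection score, not a precise
  marginal likelihood for mixtures with overlapping components.
* Ordinal factors are treated as continuous by default; no ordinal
  logistic models.
* The confounding rule is the stated one-drug LRT criterion — it is not a
  mediation analysis and cannot distinguish confounding from mediation.
* Cluster assignments feed the association stage as hard labels; posterior
  uncertainty is reported (`max_posterior`) but not propagated.
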