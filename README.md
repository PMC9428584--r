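# commtype

Community typing of gut microbiome profiles with Dirichlet multinomial
mixtures, and a full downstream screen of what those community types are
worth clinically: phenotype associations with FDR control, cluster-versus-
gradient model comparison by AIC, drug-usage deconfounding of disease
associations, and incident-disease risk screening by Cox regression.

The package is aimed at microbiome epidemiologists who have a
taxon-by-sample count table plus per-sample phenotype / health-record
tables and want to ask, reproducibly: *do discrete community types exist in
my cohort, how many, what drives them, and do they associate with anything
after the obvious confounders are handled?* Because cohort microbiome data
are usually access-restricted, the package also ships a synthetic cohort
generator with known ground truth (cluster labels, effect sizes, hazard
ratios), so the entire pipeline is exercised and validated without any
external data.

## The model

Genus counts $x_i$ for sample $i$ follow a $K$-component Dirichlet
multinomial mixture: component $k$ has concentration vector $\alpha_k$ and
weight $\pi_k$, and

$$P(x \mid \alpha_k) = \frac{n!}{\prod_j x_j!}\,
\frac{\Gamma(A_k)}{\Gamma(n+A_k)}\prod_j
\frac{\Gamma(x_j+\alpha_{kj})}{\Gamma(\alpha_{kj})},\qquad A_k=\sum_j\alpha_{kj}.$$

The mixture is fitted by EM (quasi-Newton M-step in $\log\alpha$ space,
seeded k-means initialisation, multi-start). Each $K$ is scored by a
Laplace approximation of the negative log model evidence; the number of
community types is the smallest $K$ after which the score stops improving
appreciably (an elbow rule with threshold `tau = 0.05`), and the
three-cluster fit of the same curve is the enterotype model. A continuous
alternative — the gradient model, $g_i=\log\frac{P_i + c}{B_i + c}$ on
Prevotella and Bacteroides counts — is carried through every downstream
comparison.

Downstream, factors are tested against each representation by logistic /
linear regression with likelihood-ratio tests (chi-squared for categorical
factors), corrected by Benjamini–Hochberg within representation; disease
models are adjusted for age, BMI, gender and stool consistency; an
association is declared drug-confounded when at least one drug exists such
that the cluster term no longer improves the model once that drug is
included; incident diseases are screened with covariate-adjusted Cox
models (Efron ties, Schoenfeld PH diagnostics) after excluding prevalent
cases.

## A worked example

Simulate a 300-sample cohort from the three canonical community roles,
fit the model-fit curve, and pick the number of clusters:

```r
library(commtype)

spec  <- cohort_spec(n_samples = 300, n_genera = 30, seed = 42)
gen   <- generate_counts(spec)
curve <- fit_dmm_curve(gen$counts, k_max = 4, seed = 1, n_starts = 2)
curve$curve
#> # A tibble: 4 × 4
#>       k laplace_score log_likelihood converged
#>   <int>         <dbl>          <dbl> <lgl>
#> 1     1        49521.        -49354. TRUE
#> 2     2        48386.        -48085. TRUE
#> 3     3        46598.        -46185. TRUE
#> 4     4        46704.        -46162. TRUE
select_k(curve)
#> [1] 3
```

The score improves sharply up to the generative $K = 3$ and then turns
back up — four clusters buy 23 nats of likelihood but cost more than that
in parameter volume. The selected fit recovers the mixture:

```r
fit <- curve$fits[[select_k(curve)]]
fit
#> <dmm_fit> K=3, 300 samples x 30 genera
#>   log-likelihood -46184.85, converged in 2 iterations
#>   Laplace score 46598.25 (lower is better)
#>   mixing weights: 0.410 0.243 0.347
```

(the generator used weights 0.40 / 0.25 / 0.35). Its clusters are
labelled by their driving genera, and the assignments match the ground
truth exactly:

```r
head(driving_genera(fit, top_m = 3), 6)
#> # A tibble: 6 × 5
#>   cluster  rank genus       expected_prop deviation
#>     <int> <int> <chr>               <dbl>     <dbl>
#> 1       1     1 Bacteroides       0.777      0.493
#> 2       1     2 Prevotella        0.00475    0.247
#> 3       1     3 Clostridium       0.0230     0.0324
#> 4       2     1 Prevotella        0.743      0.491
#> 5       2     2 Bacteroides       0.0140     0.270
#> 6       2     3 Clostridium       0.0211     0.0342

asg <- assign_clusters(fit, gen$counts)
crosstab_models(asg$cluster, gen$truth$labels)
#>    B
#> A     1  2   3
#>   1 123  0   0
#>   2   0 73   0
#>   3   0  0 104

tapply(gradient_score(gen$counts)$gradient, asg$cluster, mean)
#>         1         2         3
#> -7.275752  5.172507 -3.582000
```

Cluster 1 is Bacteroides-dominated (mean log Prevotella/Bacteroides ratio
−7.3), cluster 2 Prevotella-dominated (+5.2), cluster 3 the diverse
middle. `run_pipeline()` chains the whole analysis — preprocessing, fit
curve, ET/CT/gradient assignment, factor screen, AIC comparison,
deconfounding, survival — into one deterministic artifact directory;
`make_demo()` builds a complete synthetic cohort (counts, phenotypes,
drugs, prevalent and incident tables) to run it on.

## Layout

| Where | What |
|---|---|
| `R/synthetic-data.R` | cohort / effect / survival specs and generators |
| `R/io-prep.R` | TSV I/O, depth and prevalence filters, genus aggregation, EHR grouping |
| `R/dmm.R` | DM log-pmf, EM fitting, Laplace evidence, posterior assignment |
| `R/community-models.R` | fit curve, K selection, driving genera, gradient, diversity, PCoA |
| `R/association.R` | factor screen, BH-FDR, adjusted LRTs, AIC comparison, drug scan |
| `R/survival.R` | prevalent exclusion, Cox screen, PH diagnostics |
| `R/pipeline.R` | `make_demo()`, `run_pipeline()` |
| `vignettes/community-typing.Rmd` | the methods vignette: models, choices, limitations |
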