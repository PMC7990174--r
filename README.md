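# dcmd — distance-based classification of microbiome counts using mixture distributions

`dcmd` classifies samples from sparse microbiome OTU count tables. Instead
of feeding raw counts or relative abundances into a classifier, it models
each OTU's counts with a zero-inflated Poisson-Gamma mixture, converts
every observed count into a *sample-specific distribution* — the posterior
over mixture components given the count and the sample's sequencing depth
— and classifies samples by squared-L2 distances between those
distributions. The package is aimed at researchers building disease
classifiers from 16S/metagenomic count data, where zero inflation and
skewness break the usual distance-based methods.

## The model

For OTU $j$ and sample $i$ with resolution $t_i = N_i/\bar N$ (depth
normalized by the cohort mean), counts follow
$n_i \mid t_i, r^*_i \sim \mathrm{Poisson}(r^*_i t_i)$ with the rate drawn
from a mixture

$$\Omega = (G_z,\; \Gamma(\alpha_1, \beta_1), \dots, \Gamma(\alpha_M, \beta_M),\; G_{C+}),$$

a structural-zero point mass, a ladder of Gamma components (so counts are
conditionally negative binomial,
$NB(\alpha_m, \beta_m/(t_i + \beta_m))$), and a point mass for counts above
the truncation $C$ (the 0.85 quantile of the positive counts). Component
weights $w$ solve the simplex-constrained least-squares problem

$$\hat w = \arg\min_{\sum w_m = 1,\, w \ge 0} \sum_{x=0}^{C+}
\left[y_x - I\textstyle\sum_m w_m \bar p_{xm}\right]^2,$$

where $y_x$ are aggregate count frequencies, and are averaged over nested
candidate models (dropping low-rate components) with nonparametric
bootstrap model probabilities $v(l)$: $w = \sum_l v(l) w_l$. Each sample's
posterior weights $w_i \propto w_m P_{NB}(n_i \mid \alpha_m,
\beta_m/(t_i+\beta_m))$ define its distribution, and two squared-L2
metrics compare samples: **D-L2**, $\sum_x [P_a(x) - P_b(x)]^2$ over the
discrete categories $z, 0, \dots, C, C+$, and **CC-L2**,
$\int_0^C [F_a - F_b]^2 dx$ over component CDFs — both quadratic forms
$(w_a - w_b) G (w_a - w_b)'$ in weight space. Classification is k-means
(nearest class-mean distribution) or k-NN on the total distance summed
over OTUs. See `vignettes/dcmd-methods.Rmd` for the full account,
including the calibrated synthetic-data generator and the baseline
classifiers (Euclidean/Manhattan k-means and k-NN, nearest shrunken
centroid, RF, GB, LASSO, ridge, SVM).

## Worked example

Simulate a strongly separated, highly sparse two-class community (the
hardest regime for abundance-based distances), train on 60%, predict the
held-out 40%:

```r
library(dcmd)
sim <- simulate_dataset(two_class_scenario(4, class_sizes = c(150, 150)), seed = 1)
sim$table
#> otu_table: 300 samples x 25 OTUs
#>   total reads: median 9452 (range 6743-12457)
#>   overall zero proportion: 0.696
#>   labels: class1=150, class2=150

split <- train_test_split(sim$table, prop = 0.6, seed = 2)
fit <- dcmd(split$train, B = 50, seed = 3)
fit
#> dcmd model
#>   25 OTUs, 180 training samples, 2 classes (class1, class2)
#>   default metric: d-l2, classifier: kmeans
#>   bootstrap: B = 50, 5 nested models

evaluate(split$test$labels, predict(fit, split$test, metric = "d-l2"))
#> prediction report (n = 120)
#>   accuracy : 0.8667
#>   precision: 0.8929  recall: 0.8333  F1: 0.8621  (positive = class2)
#>   TP 50  FP 6  FN 10
```

Despite 70% zeros, the distributional distance separates the classes with
87% accuracy on held-out samples. The fitted mixtures are inspectable —
for the first OTU roughly a third of samples are structural zeros
(`z` weight 0.32), with the rest split between a near-zero exponential and
moderate-rate components:

```r
head(coef(fit), 3)
#>   otu_id component    weight
#> 1   OTU1         z 0.3180827
#> 2   OTU1    G(1,2) 0.3650869
#> 3   OTU1    G(1,1) 0.0000000
```

`cv_evaluate()` runs the same machinery under stratified k-fold
cross-validation on a user-supplied table (`read_otu_table()` reads
TSV/CSV in either orientation), with optional Mann-Whitney/BH OTU
screening redone inside each training fold. A thin command-line front end
with `fit`, `classify`, `simulate` and `cv-evaluate` subcommands lives at
`inst/cli/dcmd.R`.

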