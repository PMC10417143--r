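# layerquant

Quantitative pipeline for 3-D tissue-imaging prognosis studies of a
membrane-associated tumour marker (the motivating case: elafin/PI3 in
esophageal squamous cell carcinoma). The package is aimed at imaging and
biostatistics groups who need the numeric half of such a study —
quantification, testing, cutpoint selection — as reusable, tested code
rather than a chain of one-off scripts.

It implements five stages, plus generators that produce every input class
with known ground truth:

* **Stack quantification.** A 3-channel confocal z-stack (marker, cell
  membrane, nuclei; 0.7 µm z-steps) is reduced to a per-layer *relative
  marker intensity* `r_z = #marker pixels / #membrane pixels`, after
  per-layer background subtraction and median filtering. Layers with
  `r > 0.01` are selected as the signal-bearing tissue block; sum
  z-projections and layer-count→µm conversions round out the geometry.
* **Exact paired permutation test.** Two subjects' profiles are clustered
  into K = 20 contiguous blocks, dichotomized at 0.05, and compared by
  enumerating all 2^K = 1,048,576 sign reallocations of the paired cluster
  scores. Ties are resolved exactly (integer arithmetic) and the p-value
  uses the midpoint of the tied ranks:
  `p = 1 − (rank + (ties − 1)/2) / 2^K`.
* **Survival cutpoint scan.** Expression cutoffs are scanned for the
  maximum Youden index `J = sensitivity + specificity − 1`, each with a
  covariate-adjusted Cox fit (age, sex, smoking, alcohol) and a
  Kaplan–Meier/log-rank comparison at the selected cutoff.
* **Paired score comparison.** Tumour vs normal ordinal IHC scores:
  paired t and Wilcoxon signed-rank, plus unpaired group summaries.
* **Concordance filter.** Genes with `log2FC > 1` in an overexpression
  contrast and `log2FC < −1` in a knockdown contrast.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; results have `tidy()`/`glance()`/`autoplot()`
methods.

## Worked example

```r
library(layerquant)

# two synthetic subjects: marker webbed through the stroma vs confined to
# tumour nests, identical marker density
web  <- simulate_stack(pattern = "stromal-web",   seed = 1)
nest <- simulate_stack(pattern = "nest-confined", seed = 2)
prof_web  <- quantify_stack(web$stack,  bg_method = "constant", bg_level = 0,
                            median_window = 1)
prof_nest <- quantify_stack(nest$stack, bg_method = "constant", bg_level = 0,
                            median_window = 1)

select_layers(prof_web, cutoff = 0.01)
#> # A tibble: 1 × 4
#>   first  last n_selected thickness_um
#> 1     1   200        200          140

compare_layer_profiles(prof_web, prof_nest, k = 20, cutoff = 0.05)
#> Paired sign-flip permutation test (exact, K = 20)
#>   mean score difference = 0.99
#>   rank 1,048,576 (ties 1) of 1,048,576 reallocations
#>   p (upper tail, midpoint ties) = 0
#>   p (two-sided) = 0
```

All 200 layers of the stromal-web subject carry signal (140 µm of tissue at
0.7 µm/layer). Its dichotomized cluster scores exceed the nest-confined
subject's in essentially every cluster, the observed mean difference of
0.99 ranks last among all 1,048,576 reallocations, and the permutation
p-value is 0 to machine precision — the two spatial phenotypes are cleanly
distinguished.

```r
surv <- simulate_survival_table(n = 400, true_cutoff = 25, hazard_ratio = 6,
                                seed = 1)
scan <- scan_cutoffs(surv, fit = "selected")
scan
#> Cutoff scan over 13 admissible cutoffs (outcome: event)
#>   selected cutoff = 24.5 (J = 0.3439, n_high = 192, n_low = 208)
#>   adjusted log HR = 1.404 (se 0.128), p = 3.47e-28

km_logrank(surv, surv$expression > scan$selected$cutoff)
#> Log-rank test: chisq = 137 on 1 df, p = 1.202e-31
```

The scan lands in the empty expression gap around the planted hazard step
at 25 (expression is integer-valued, so 24.5 and 25.5 are the two
candidates bracketing it), and the adjusted Cox fit at that cutoff gives a
strongly significant group effect; `autoplot(scan)` and
`autoplot(km_logrank(...))` draw the J-curve and the survival curves.

`run_pipeline(run_config(...))` runs all stages end to end on synthetic
data, writing every intermediate CSV plus a JSON run report with parameter
provenance and output hashes; reports are byte-identical for identical
configs.

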