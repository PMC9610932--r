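# bcfqsar

QSAR models for the fish bioconcentration factor (log BCF), for
environmental chemists and risk assessors who need structure-based
estimates of bioaccumulation potential under the REACH criteria
(bioaccumulative, B, when BCF > 2000, i.e. log BCF > 3.30).

The package implements, end to end:

- a **hydrogen-aware SMILES engine**: parsing with aromaticity perception,
  a deterministic canonical form, and the curation filter that excludes
  inorganics, metal-organics, salts/mixtures and ions;
- the **nine modelled molecular descriptors**: MWC4 = ln(1 + w4), the
  molecular walk count of order 4; IC0 and IC2, Shannon entropies (bits)
  of the atom partition by neighbourhood symmetry at orders 0 and 2;
  maxHBd, maxdO and MAXDP from the electrotopological-state framework
  (S = I + ΔI, with intrinsic state I = ((2/N)²δᵛ + 1)/δ and
  distance-damped perturbations ΔIᵢ = Σⱼ (Iᵢ − Iⱼ)/(dᵢⱼ + 1)²);
  TopoPSA, the fragment-based topological polar surface area; and the
  fingerprint counts SubFPC171 (`[Cl][c]`, aryl chloride) and SubFPC295
  (carbon-to-N/O/S bonds);
- the **published six-descriptor regression** with frozen coefficients

  ```
  log BCF = −1.44 + 0.80·MWC4 + 0.24·SubFPC171 − 0.10·SubFPC295
            − 1.19·maxHBd − 0.06·maxdO − 0.51·IC0
  ```

  and its Williams-plot applicability domain (h* = 3(p+1)/n; 0.023 at the
  published training size n = 920, p = 6);
- the **model-building machinery**: descriptor pre-reduction, step-up
  (forward-beam) variable subset selection, 5-fold cross-validation,
  Q²loo, Y-scrambling, response-ranked and Euclidean-distance splits;
- **B / not-B classification**: pooled-covariance LDA with proportional
  priors and genetic-algorithm variable selection, accuracy / precision /
  sensitivity / specificity, ROC/AUC, and a standardization-based
  applicability-domain check;
- a **resilient-backpropagation MLP** for the non-linear regression and
  classification variants;
- seeded **synthetic-data generators** and a command-line interface
  (`inst/cli/bcfqsar.R`, a thin Rscript over `run_cli()`).

## Worked example

```r
library(bcfqsar)

d <- compute_descriptors("Clc1ccccc1")   # chlorobenzene
round(d, 4)
#>      MWC4       IC0       IC2    maxHBd     maxdO     MAXDP   TopoPSA
#>    4.8903    1.3250    2.0546    0.0000    0.0000    1.4286    0.0000
#> SubFPC171 SubFPC295
#>    1.0000    0.0000

predict_published(d)
#> [1] 2.036955
```

Chlorobenzene has one aryl chloride (SubFPC171 = 1, pushing log BCF up),
no hydrogen-bond donor or carbonyl oxygen (maxHBd = maxdO = 0), and a
walk count MWC4 = ln(1 + 132) ≈ 4.89; the frozen equation yields
log BCF ≈ 2.04 — below the 3.30 regulatory cut-off, so the compound
screens as not-B. By contrast a strong donor drags the estimate down:

```r
predict_published(compute_descriptors("CCO"))  # ethanol, maxHBd = 7.57
#> [1] -9.120457
```

an extrapolation far outside the model's descriptor domain — exactly the
situation the Williams-plot leverage check (`williams()`, `h_star()`) is
there to flag.

A full synthetic modelling cycle:

```r
g     <- gen_regression(sim_spec(n = 920, noise_sd = 0.8, n_decoys = 14))
red   <- prereduce(g$X)
pop   <- step_up_vss(red$X, g$y, max_size = 6, keep_per_size = 50)
split <- response_ranked_split(g$y)
vars  <- best_model(pop, 6)$vars
validate_regression(g$X[split$train_idx, vars], g$y[split$train_idx],
                    g$X[split$pred_idx, vars],  g$y[split$pred_idx])
```

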