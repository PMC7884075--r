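# polyarch

Estimating the polygenic architecture of quantitative traits from GWAS
summary statistics — and testing every step of that estimation, end to end,
on synthetic data with known ground truth.

## Who this is for

Statistical geneticists who have per-variant association summaries
(effect, standard error, t, p) and want to know:

* **How many causal variants does the trait have?** The package estimates
  π₁, the fraction of variants with truly nonzero effects under a
  point-normal model (effects are exactly zero with probability 1 − π₁,
  otherwise drawn from a mean-zero normal).
* **Where does the heritability sit?** Block-wise local SNP-heritability,
  cumulative-heritability curves along the genome, and pathway sums.
* **Are trait-relevant pathways enriched for association signal?**
  Lead-SNP clumping, gene windows, Fisher/Poisson/matched-null enrichment.
* **Is there evidence of non-additivity?** Dominance, pairwise-epistasis
  and stratified paired-difference screens.

## The core statistic

Marginal GWAS tests mix causal signal with linkage disequilibrium. The LD
score ℓᵢ = Σⱼ r²ᵢⱼ measures how much variant *i* can tag, and under a
polygenic model E[χ²ᵢ] = 1 + N·h²·ℓᵢ/M. `polyarch` ranks variants by ℓ,
splits them into equal-count bins, and estimates within each bin the
proportion of *null* marginal effects π₀ with an empirical-Bayes
point-mass-plus-normal mixture (a from-scratch, SQUAREM-accelerated
penalized EM with an exact null-coordinate polish). The resulting curves
(π₀ versus ℓ, mean χ² versus ℓ) are then matched against forward
simulations over a grid of causal fractions π₁ and test-statistic
inflation values λ; the best-fitting grid point, refined by log-scale
interpolation, is the estimate. A parametric fit of the π₀ decay rate
provides an inflation-robust cross-check.

## Worked example

Simulate a trait with a known architecture, then recover it:

```r
library(polyarch)

profile <- make_ld_profile(20000, block_size = 100, seed = 7)
ldtab   <- profile_ldscores(profile)

truth <- architecture_spec(pi1 = 0.01, h2 = 0.3)
assoc <- simulate_summary_stats(truth, profile, n_individuals = 20000, seed = 42)

reg <- ldsc_regression(assoc, ldtab, n_individuals = 20000)
round(c(intercept = reg$intercept, h2 = reg$h2_implied), 3)
#> intercept        h2
#>     1.018     0.297

bins <- bin_and_summarize(assoc, ldtab, n_bins = 50, maf_range = c(0.01, 0.5))
lib  <- build_reference_curves(c(0.001, 0.003, 0.01, 0.03), 1, truth,
                               profile, 20000, n_reps = 2, seed = 1,
                               n_bins = 50, maf_range = c(0.01, 0.5))
fit <- estimate_pi1_matching(bins, lib, seed = 1)
fit
#> polygenicity_fit (matching): pi1_hat = 0.01293, best lambda = 1
```

The LD-score regression reads back the simulated heritability (0.3) and a
clean intercept (no inflation was injected); the matching estimator
recovers the simulated causal fraction 0.01 as ≈ 0.013. At this desk
scale the estimate is expected to land within a factor of two of truth;
the acceptance suite verifies exactly that at M = 100,000 variants,
N = 50,000, for π₁ ∈ {0.001, 0.003, 0.01}.

The same machinery runs on real files: `read_assoc()` consumes plink2
`.glm.linear` tables, `read_ldscore()` the ldsc `.l2.ldscore` dialect,
plus BED intervals and GMT gene sets. A small CLI
(`inst/cli/polyarch`, or `polyarch_main()`) wraps the common steps.

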