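# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; no data files are read.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

## small genotype panel with moderate LD
fix_panel <- function() memo("panel", {
  lay <- variant_layout_grid(300, n_chrom = 2, bp_step = 5000, cm_per_mb = 1)
  ## adjacent latent correlation 0.7 at 0.005 cM spacing
  simulate_genotypes(600, lay, ld_decay = 0.7^(1 / 0.005), seed = 101)
})

## independent-variant panel
fix_panel_indep <- function() memo("panel_indep", {
  lay <- variant_layout_grid(120, bp_step = 5000, cm_per_mb = 1)
  simulate_genotypes(800, lay, ld_decay = 0, seed = 102)
})

## modest LD profile for summary-level tests
fix_profile <- function() memo("profile", {
  make_ld_profile(20000, block_size = 50, seed = 103)
})

fix_gene_landscape <- function() memo("landscape", {
  simulate_gene_landscape(60, c(chr1 = 5e6, chr2 = 4e6),
                          pathway_sizes = c(8, 5), seed = 104)
})

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}

## acceptance-scale worlds, shared across test files (built once)
ACC_SEED <- 1L

acc_profile <- function() memo("acc_profile", {
  make_ld_profile(100000, block_size = 100, seed = child_seed(ACC_SEED, 11))
})

acc_lib1 <- function() memo("acc_lib1", {
  build_reference_curves(c(1e-4, 1e-3, 3e-3, 0.01, 0.03), 1,
                         architecture_spec(0.001, 0.3), acc_profile(), 50000,
                         n_reps = 3, seed = child_seed(ACC_SEED, 12),
                         n_bins = 100, maf_range = c(0.01, 0.5))
})

acc_profile50 <- function() memo("acc_profile50", {
  make_ld_profile(50000, block_size = 100, seed = child_seed(ACC_SEED, 14))
})

acc_lib3 <- function() memo("acc_lib3", {
  build_reference_curves(c(1e-4, 1e-3, 3e-3, 0.01, 0.03),
                         c(0.9, 1, 1.05, 1.1, 1.2),
                         architecture_spec(0.001, 0.3), acc_profile50(), 50000,
                         n_reps = 3, seed = child_seed(ACC_SEED, 15),
                         n_bins = 100, maf_range = c(0.01, 0.5))
})

## many small mixed-LD blocks: the world where the regression intercept is
## well identified (plenty of genuinely low-LD variants)
acc_profile_ldsc <- function() memo("acc_profile_ldsc", {
  make_ld_profile(400000, block_size = 50,
                  rho_sampler = function(n) sqrt(runif(n, 0, 0.98)),
                  seed = child_seed(ACC_SEED, 41))
})
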