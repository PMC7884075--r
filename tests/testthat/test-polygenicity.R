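# LD scores, binning, LD-score regression and the pi1 estimators
# (desk-scale unit tests; the full-scale recovery lives in test-acceptance).

test_that("compute_ld_scores: self-term, perfect block, and monotonicity", {
  ## independent variants at large n: ell ~ 1 (the bias adjustment must
  ## remove the 1/n noise floor)
  lay <- variant_layout_grid(60, bp_step = 5000, cm_per_mb = 1)
  pind <- simulate_genotypes(4000, lay, ld_decay = 0, seed = 105)
  l0 <- compute_ld_scores(pind)
  expect_true(all(abs(l0$ldscore - 1) < 0.05))

  ## block of k perfectly correlated variants: ell ~ k for each member
  n <- 500; k <- 4
  base <- rbinom(n, 2, 0.4)
  dos <- cbind(matrix(rep(base, k), n, k),
               matrix(rbinom(n * 2, 2, 0.3), n, 2))
  vm <- data.frame(variant_id = paste0("v", 1:6), chrom = "chr1",
                   pos_bp = 1:6 * 1000L, pos_cm = (1:6) * 0.001,
                   allele_ref = "A", allele_alt = "G",
                   maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2))
  panel <- structure(list(sample_ids = paste0("s", 1:n), variant_map = vm,
                          dosages = dos), class = "genotype_panel")
  lsc <- compute_ld_scores(panel)
  expect_equal(lsc$ldscore[1:k], rep(k, k), tolerance = 0.1)

  ## adding a correlated variant never decreases ell (noiseless construction)
  dos7 <- cbind(dos, base)
  vm7 <- rbind(vm, data.frame(variant_id = "v7", chrom = "chr1",
                              pos_bp = 7000L, pos_cm = 0.007,
                              allele_ref = "A", allele_alt = "G",
                              maf = vm$maf[1]))
  panel7 <- structure(list(sample_ids = panel$sample_ids, variant_map = vm7,
                           dosages = dos7), class = "genotype_panel")
  lsc7 <- compute_ld_scores(panel7)
  expect_true(all(lsc7$ldscore[1:6] >= lsc$ldscore - 1e-8))

  expect_error(compute_ld_scores(structure(list(
    sample_ids = c("a", "b"), variant_map = vm, dosages = dos[1:2, ]),
    class = "genotype_panel")), "at least 3")
})

test_that("bin_and_summarize follows ntile semantics and per-bin consistency", {
  set.seed(20)
  assoc <- data.frame(variant_id = paste0("v", 1:10), maf = 0.25,
                      beta = rnorm(10), se = 1, t_stat = rnorm(10))
  lds <- data.frame(variant_id = paste0("v", 1:10), ldscore = c(10:1))
  out <- bin_and_summarize(assoc, lds, n_bins = 2)
  expect_identical(out$n_variants, c(5L, 5L))
  expect_lt(out$mean_ld[1], out$mean_ld[2])  # split at the median
  expect_true(all(is.na(out$prop_null)))     # < 10 variants: flagged, no fit
  expect_false(any(out$usable))

  ## prop_null equals a direct fit on the bin's members
  set.seed(21)
  assoc2 <- data.frame(variant_id = paste0("w", 1:100), maf = runif(100, 0.1, 0.5),
                       beta = rnorm(100), se = rep(1, 100),
                       t_stat = rnorm(100))
  lds2 <- data.frame(variant_id = paste0("w", 1:100), ldscore = runif(100, 1, 20))
  out2 <- bin_and_summarize(assoc2, lds2, n_bins = 4)
  members <- attr(out2, "members")
  direct <- fit_ash(members[[2]]$beta, members[[2]]$se)$pi0
  expect_identical(out2$prop_null[2], direct)

  ## partition: sizes differ by at most one, all variants used
  out3 <- bin_and_summarize(assoc2, lds2, n_bins = 7, min_bin_n = 5)
  expect_lte(diff(range(out3$n_variants)), 1L)
  expect_identical(sum(out3$n_variants), 100L)
  ## small bins flagged unusable
  expect_true(all(out3$usable | out3$n_variants < 5))

  ## strict MAF range filter
  out4 <- bin_and_summarize(assoc2, lds2, n_bins = 2,
                            maf_range = c(0.2, 0.4), min_bin_n = 1)
  fold <- pmin(assoc2$maf, 1 - assoc2$maf)
  expect_identical(sum(out4$n_variants), sum(fold > 0.2 & fold < 0.4))
})

test_that("ntile_stable is deterministic under ties", {
  x <- c(1, 1, 1, 2, 2, 3)
  expect_identical(ntile_stable(x, 2), c(1L, 1L, 1L, 2L, 2L, 2L))
  ## larger bins first when uneven
  expect_identical(tabulate(ntile_stable(1:7, 3)), c(3L, 2L, 2L))
})

test_that("ldsc_regression recovers exact linear input and the null", {
  m <- 5000; n <- 10000
  set.seed(22)
  ell <- runif(m, 1, 50)
  lds <- data.frame(variant_id = paste0("v", 1:m), ldscore = ell)
  h2 <- 0.25
  chi2 <- 1 + n * h2 * ell / m
  assoc <- data.frame(variant_id = paste0("v", 1:m), t_stat = sqrt(chi2))
  reg <- ldsc_regression(assoc, lds, n)
  expect_equal(reg$slope, n * h2 / m, tolerance = 1e-10)
  expect_equal(reg$intercept, 1, tolerance = 1e-10)
  expect_equal(reg$h2_implied, h2, tolerance = 1e-8)

  ## all chi2 = 1: slope 0, intercept 1
  assoc1 <- data.frame(variant_id = paste0("v", 1:m), t_stat = 1)
  reg1 <- ldsc_regression(assoc1, lds, n)
  expect_equal(reg1$slope, 0, tolerance = 1e-12)
  expect_equal(reg1$intercept, 1, tolerance = 1e-12)

  expect_error(ldsc_regression(assoc[1:50, ], lds, n), "at least 100")
  const <- data.frame(variant_id = paste0("v", 1:m), ldscore = 2)
  expect_error(ldsc_regression(assoc, const, n), "degenerate")
})

test_that("inflation shifts the ldsc intercept as injected", {
  ## needs a world with abundant low-LD variants (small mixed-LD blocks)
  prof <- acc_profile_ldsc()
  ints <- vapply(30:32, function(s) {
    a <- simulate_summary_stats(architecture_spec(0, 0, inflation_lambda = 1.1),
                                prof, 50000, seed = s)
    ldsc_regression(a, profile_ldscores(prof), 50000)$intercept
  }, 0)
  expect_lt(abs(mean(ints) - 1.1), 0.03)
})

test_that("reference libraries are deterministic and self-matching", {
  prof <- memo("tiny_profile", make_ld_profile(6000, block_size = 50, seed = 40))
  tmpl <- architecture_spec(0.003, 0.3)
  grid <- c(0.001, 0.003, 0.01)
  dir <- withr::local_tempdir()
  lib <- build_reference_curves(grid, 1, tmpl, prof, 20000, n_reps = 2,
                                seed = 41, n_bins = 12,
                                maf_range = c(0.01, 0.5), cache_dir = dir)
  ## cache round-trip is identical
  f <- list.files(dir, full.names = TRUE)
  expect_length(f, 1)
  lib2 <- build_reference_curves(grid, 1, tmpl, prof, 20000, n_reps = 2,
                                 seed = 41, n_bins = 12,
                                 maf_range = c(0.01, 0.5), cache_dir = dir)
  expect_equal(lib2$curves, lapply(lib$curves, as.data.frame),
               tolerance = 1e-12, ignore_attr = TRUE)

  ## self-consistency: a library curve matches itself
  obs <- lib$curves[[polyarch:::grid_name(0.003, 1)]]
  class(obs) <- c("bin_summary", "data.frame")
  fit <- estimate_pi1_matching(obs, lib, n_boot = 10, seed = 1)
  expect_equal(fit$diagnostics$best_grid_pi1, 0.003)
  expect_equal(fit$best_lambda, 1)

  ## prop_null in the top bin nonincreasing in pi1 (high per-causal NCP)
  top_pn <- vapply(grid, function(p) {
    cv <- lib$curves[[polyarch:::grid_name(p, 1)]]
    tail(cv$prop_null[cv$usable], 1)
  }, 0)
  expect_true(all(diff(top_pn) <= 0.05))
})

test_that("parametric fit recovers the assumed form and handles the null", {
  ## curves generated exactly from the form pi1 = 0.005, c = 0.8
  ell <- seq(1, 60, length.out = 40)
  pn <- (1 - 0.005)^(0.8 * ell)
  obs <- data.frame(bin_index = 1:40, mean_ld = ell, se_ld = 0.01,
                    mean_chisq = 1, se_chisq = 0.01, mean_maf = 0.25,
                    prop_null = pn, n_variants = 100L, usable = TRUE)
  class(obs) <- c("bin_summary", "data.frame")
  fit <- estimate_pi1_parametric(obs, c_tag = 0.8)
  expect_equal(fit$pi1_hat, 0.005, tolerance = 5e-4)

  ## all-null curve
  obs0 <- obs; obs0$prop_null <- 1
  fit0 <- estimate_pi1_parametric(obs0, c_tag = 0.8)
  expect_equal(fit0$pi1_hat, 0)

  expect_error(estimate_pi1_parametric(obs), "library or a fixed c_tag")
  expect_error(estimate_pi1_parametric(obs[1:10, ], c_tag = 1), "20 usable")
})
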