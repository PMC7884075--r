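# Genotype, architecture and phenotype generators.

test_that("simulate_genotypes honors invariants, determinism and the independence limit", {
  lay <- variant_layout_grid(100, bp_step = 5000, cm_per_mb = 1)
  p1 <- simulate_genotypes(5000, lay, ld_decay = 0, seed = 1)
  p2 <- simulate_genotypes(5000, lay, ld_decay = 0, seed = 1)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% 0:2))
  expect_true(all(p1$variant_map$maf > 0 & p1$variant_map$maf <= 0.5))

  r_adj <- vapply(1:99, function(j) {
    abs(cor(p1$dosages[, j], p1$dosages[, j + 1]))
  }, 0)
  expect_lt(mean(r_adj), 0.05)

  expect_error(simulate_genotypes(100, lay[c(2, 1, 3:100), ], seed = 1),
               "non-increasing")
  expect_error(simulate_genotypes(100, lay, maf_sampler = function(n) rep(0.7, n)),
               "maf_sampler")
})

test_that("latent LD matches an independent thresholded-bivariate-normal oracle", {
  lay <- variant_layout_grid(60, bp_step = 5000, cm_per_mb = 1)
  rho <- 0.9
  panel <- simulate_genotypes(20000, lay, ld_decay = rho^(1 / 0.005), seed = 2)
  r_obs <- mean(vapply(1:59, function(j) {
    cor(panel$dosages[, j], panel$dosages[, j + 1])
  }, 0))
  ## oracle: direct simulation of the same two-haplotype threshold model
  set.seed(900)
  r_oracle <- mean(vapply(1:59, function(j) {
    m1 <- panel$variant_map$maf[j]; m2 <- panel$variant_map$maf[j + 1]
    x1 <- rnorm(40000); y1 <- rho * x1 + sqrt(1 - rho^2) * rnorm(40000)
    x2 <- rnorm(40000); y2 <- rho * x2 + sqrt(1 - rho^2) * rnorm(40000)
    d1 <- (x1 < qnorm(m1)) + (x2 < qnorm(m1))
    d2 <- (y1 < qnorm(m2)) + (y2 < qnorm(m2))
    cor(d1, d2)
  }, 0))
  expect_lt(abs(r_obs - r_oracle), 0.03)
})

test_that("draw_causal_effects boundaries and binomial sampling", {
  panel <- fix_panel_indep()
  s0 <- architecture_spec(pi1 = 0, h2 = 0)
  e0 <- draw_causal_effects(panel, s0, seed = 1)
  expect_true(all(!e0$causal_mask))
  expect_true(all(e0$true_effects == 0))

  s1 <- architecture_spec(pi1 = 1, h2 = 0.5, maf_floor = 0.05)
  e1 <- draw_causal_effects(panel, s1, seed = 1)
  eligible <- panel$variant_map$maf >= 0.05
  expect_identical(e1$causal_mask, eligible)
  expect_true(all(e1$true_effects[!eligible] == 0))
  expect_true(all(e1$true_effects[eligible] != 0))

  expect_error(draw_causal_effects(panel, architecture_spec(0.5, 0.3, maf_floor = 0.9)),
               "excludes all")

  ## binomial oracle for the causal fraction over 100 seeds
  sp <- architecture_spec(pi1 = 0.1, h2 = 0.3, maf_floor = 0)
  m <- nrow(panel$variant_map)
  fr <- vapply(1:100, function(s) {
    mean(draw_causal_effects(panel, sp, seed = s)$causal_mask)
  }, 0)
  se_bin <- sqrt(0.1 * 0.9 / (m * 100))
  expect_lt(abs(mean(fr) - 0.1), 3 * se_bin)
})

test_that("clumpy placement follows the Beta(alpha, alpha/rho) mean", {
  ## expected causal fraction is rho/(1+rho), the Beta mean taken literally
  lay <- variant_layout_grid(4000, bp_step = 2000, cm_per_mb = 1)
  panel <- list(sample_ids = "x",
                variant_map = data.frame(
                  variant_id = sprintf("v%d", 1:4000), chrom = lay$chrom,
                  pos_bp = lay$pos_bp, pos_cm = lay$pos_cm,
                  allele_ref = "A", allele_alt = "G", maf = 0.25),
                dosages = matrix(0L, 1, 4000))
  class(panel) <- "genotype_panel"
  sp <- architecture_spec(pi1 = 0.01, h2 = 0.3, placement = "clumpy",
                          alpha = 0.3, rho = 0.01, maf_floor = 0)
  fr <- vapply(1:200, function(s) {
    mean(polyarch:::draw_causal_mask(sp, panel$variant_map$chrom,
                                     panel$variant_map$pos_bp,
                                     rep(TRUE, 4000)))
  }, 0)
  target <- 0.01 / 1.01
  ## Monte-Carlo se of the mean fraction, dominated by the Beta spread
  mc_se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - target), 4 * mc_se + 0.001)
})

test_that("clumpy placement converges to uniform as alpha grows", {
  lay <- variant_layout_grid(20000, bp_step = 500, cm_per_mb = 1)
  chrom <- lay$chrom; bp <- lay$pos_bp
  mb <- (bp - 1) %/% 1000000
  count_var <- function(sp, seeds) {
    v <- vapply(seeds, function(s) {
      set.seed(s)
      mask <- polyarch:::draw_causal_mask(sp, chrom, bp, rep(TRUE, 20000))
      var(tapply(mask, mb, sum))
    }, 0)
    mean(v)
  }
  sp_unif <- architecture_spec(0.0099, 0.3)   # rho/(1+rho) to match clumpy
  sp_big <- architecture_spec(0.0099, 0.3, placement = "clumpy",
                              alpha = 1e6, rho = 0.01)
  v_u <- count_var(sp_unif, 1:50)
  v_c <- count_var(sp_big, 51:100)
  expect_lt(abs(v_c - v_u) / v_u, 0.10)
})

test_that("simulate_phenotype hits target h2 and conserves the variance identity", {
  lay <- variant_layout_grid(400, bp_step = 5000, cm_per_mb = 1)
  panel <- simulate_genotypes(20000, lay, ld_decay = 0.3^(1 / 0.005), seed = 3)
  eff <- draw_causal_effects(panel, architecture_spec(0.2, 0.3), seed = 4)
  tr <- simulate_phenotype(panel, eff, 0.3, seed = 5)

  expect_equal(mean(tr$phenotype), 0, tolerance = 1e-10)
  expect_equal(var(tr$phenotype), 1, tolerance = 1e-10)
  vm <- panel$variant_map
  lhs <- sum(2 * vm$maf * (1 - vm$maf) * tr$true_effects^2) / var(tr$phenotype)
  expect_equal(lhs, tr$realized_h2, tolerance = 1e-10)
  expect_between(tr$realized_h2, 0, 1)

  g <- as.vector(panel$dosages %*% tr$true_effects)
  r2 <- summary(lm(tr$phenotype ~ g))$r.squared
  expect_lt(abs(r2 - 0.3), 0.03)

  ## no-noise limit: phenotype is the standardized genetic value
  tr1 <- simulate_phenotype(panel, eff, 1, seed = 6)
  g1 <- as.vector(panel$dosages %*% tr1$true_effects)
  expect_equal(cor(tr1$phenotype, g1), 1, tolerance = 1e-12)

  ## independence limit
  tr0 <- simulate_phenotype(panel, eff, 0, seed = 7)
  expect_lt(cor(tr0$phenotype, g)^2, 0.01)

  expect_error(simulate_phenotype(panel, draw_causal_effects(
    panel, architecture_spec(0, 0), seed = 1), 0.3), "degenerate")
})

test_that("simulate_summary_stats is calibrated and follows the LD-score identity", {
  ## null calibration at the 100k-variant scale (dense LD leaves only
  ## ~1000 independent blocks, so the mean needs the full-width panel)
  prof_big <- acc_profile()
  a0 <- simulate_summary_stats(architecture_spec(0, 0), prof_big, 50000,
                               seed = 1)
  expect_lt(abs(mean(a0$t_stat^2) - 1), 0.02)
  a12 <- simulate_summary_stats(architecture_spec(0, 0, inflation_lambda = 1.2),
                                prof_big, 50000, seed = 1)
  expect_lt(abs(mean(a12$t_stat^2) - 1.2), 0.03)

  prof <- fix_profile()
  n <- 20000; m <- nrow(prof$variants)

  ## slope of the chi2-on-LD-score regression: average over replicates to
  ## beat the single-replicate sampling noise at this desk scale
  slopes <- vapply(2:7, function(s) {
    a1 <- simulate_summary_stats(architecture_spec(0.01, 0.4), prof, n,
                                 seed = s)
    ldsc_regression(a1, profile_ldscores(prof), n)$slope
  }, 0)
  expect_lt(abs(mean(slopes) - n * 0.4 / m) / (n * 0.4 / m), 0.15)

  ## determinism
  a1 <- simulate_summary_stats(architecture_spec(0.01, 0.4), prof, n, seed = 2)
  a1b <- simulate_summary_stats(architecture_spec(0.01, 0.4), prof, n, seed = 2)
  expect_identical(a1$t_stat, a1b$t_stat)
})

test_that("E[chi2] curve is invariant to pi1 at fixed h2", {
  prof <- fix_profile()
  ldt <- profile_ldscores(prof)
  bin <- ntile_stable(ldt$ldscore, 10)
  curves_of <- function(pi1, seeds) {
    sapply(seeds, function(s) {
      a <- simulate_summary_stats(architecture_spec(pi1, 0.3), prof, 20000,
                                  seed = s)
      tapply(a$t_stat^2, bin, mean)
    })
  }
  m1 <- curves_of(0.001, 1:12)
  m2 <- curves_of(0.01, 21:32)
  ## bin-by-bin agreement within the curves' own Monte-Carlo error
  se_diff <- sqrt(apply(m1, 1, var) / ncol(m1) + apply(m2, 1, var) / ncol(m2))
  z <- abs(rowMeans(m1) - rowMeans(m2)) / se_diff
  expect_lt(mean(z > 3), 0.2)
  expect_lt(max(z), 6)
})

test_that("simulate_gene_landscape packs genes and round-trips GMT", {
  land <- fix_gene_landscape()
  genes <- land$genes
  expect_true(all(genes$start < genes$end))
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(head(g$end, -1) <= tail(g$start, -1)))
  }
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(land$gene_sets, path)
  expect_identical(read_gmt(path), land$gene_sets)

  empty <- simulate_gene_landscape(10, c(chr1 = 1e6), integer(0), seed = 1)
  expect_length(empty$gene_sets, 0)
  expect_error(simulate_gene_landscape(10, c(chr1 = 1e4),
                                       gene_length = 50000, seed = 1),
               "exceeds")
})
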