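## LD-score computation, LD binning with per-bin null proportions, LD-score
## regression, and the two causal-fraction estimators (simulation matching
## and parametric fit).

#' Compute LD scores from a genotype panel
#'
#' For each variant, l_i = sum over variants j within `window_cm` (including
#' i itself) of the bias-adjusted squared correlation
#' r^2 - (1 - r^2)/(n - 2), each term floored at 0.
#'
#' @param panel a `genotype_panel` with at least 3 individuals.
#' @param window_cm window half-width in centimorgan (default 1).
#' @return data.frame (variant_id, ldscore, maf, chrom, pos_bp).
#' @export
compute_ld_scores <- function(panel, window_cm = 1) {
  validate_panel(panel)
  stopifnot(window_cm > 0)
  n <- length(panel$sample_ids)
  if (n < 3) stop_domain("need at least 3 individuals for adjusted r^2")
  vm <- panel$variant_map
  Z <- scale(panel$dosages)          # monomorphic would give NaN
  if (anyNA(Z)) {
    Z[, apply(is.na(Z), 2, any)] <- 0 # monomorphic: zero correlation with all
  }
  Z <- Z / sqrt(n - 1)               # crossprod(Z) is then the correlation
  ell <- numeric(nrow(vm))
  for (ch in unique(vm$chrom)) {
    idx <- which(vm$chrom == ch)
    cm <- vm$pos_cm[idx]
    ## chunked banded computation
    chunk <- 512L
    for (s in seq(1, length(idx), by = chunk)) {
      rows <- s:min(s + chunk - 1L, length(idx))
      lo <- findInterval(cm[rows[1]] - window_cm, cm) + 1L
      hi <- findInterval(cm[rows[length(rows)]] + window_cm, cm)
      win <- lo:hi
      r <- crossprod(Z[, idx[rows], drop = FALSE], Z[, idx[win], drop = FALSE])
      r2 <- r^2
      adj <- pmax(r2 - (1 - r2) / (n - 2), 0)
      ## mask pairs outside the per-variant cM window
      inwin <- abs(outer(cm[rows], cm[win], "-")) <= window_cm
      ell[idx[rows]] <- rowSums(adj * inwin)
    }
  }
  data.frame(variant_id = vm$variant_id, ldscore = ell, maf = vm$maf,
             chrom = vm$chrom, pos_bp = vm$pos_bp, stringsAsFactors = FALSE)
}

#' Bin variants by LD score and summarize association signal
#'
#' Filters to the MAF range (strict inequalities on folded MAF), ranks by LD
#' score, splits into `n_bins` equal-count bins (ntile semantics, ties broken
#' by input order), and per bin reports mean/se of LD score and chi-square
#' (t^2), mean MAF, and the null proportion from [fit_ash()] on that bin's
#' (beta, se). Bins with fewer than `min_bin_n` variants are flagged and get
#' no null proportion.
#'
#' @param assoc `assoc_result`.
#' @param ldscores data.frame (variant_id, ldscore) as from
#'   [compute_ld_scores()] or [profile_ldscores()].
#' @param n_bins number of equal-count bins (>= 2; 1000 in the reference
#'   pipeline, 200/5000 as sensitivity settings).
#' @param maf_range (min, max) folded-MAF bounds, strict.
#' @param min_bin_n minimum bin size for a null-proportion fit.
#' @param penalty passed to [fit_ash()].
#' @return data.frame of class `bin_summary` (bin_index, mean_ld, se_ld,
#'   mean_chisq, se_chisq, mean_maf, prop_null, n_variants, usable) with
#'   attribute "members" holding each bin's (beta, se) for bootstrap use.
#' @export
bin_and_summarize <- function(assoc, ldscores, n_bins = 1000,
                              maf_range = c(0, 0.5), min_bin_n = 10,
                              penalty = 10) {
  stopifnot(n_bins >= 2)
  assert_cols(assoc, c("variant_id", "maf", "beta", "se", "t_stat"), "assoc")
  assert_cols(ldscores, c("variant_id", "ldscore"), "ldscores")
  idx <- match(assoc$variant_id, ldscores$variant_id)
  d <- data.frame(variant_id = assoc$variant_id, maf = assoc$maf,
                  beta = assoc$beta, se = assoc$se, t_stat = assoc$t_stat,
                  ldscore = ldscores$ldscore[idx],
                  stringsAsFactors = FALSE)[!is.na(idx), , drop = FALSE]
  fold <- pmin(d$maf, 1 - d$maf)
  d <- d[fold > maf_range[1] & fold < maf_range[2], , drop = FALSE]
  if (!nrow(d)) stop_domain("no variants left after MAF filtering")
  bin <- ntile_stable(d$ldscore, n_bins)
  chisq <- d$t_stat^2
  members <- vector("list", n_bins)
  out <- data.frame(bin_index = seq_len(n_bins), mean_ld = NA_real_,
                    se_ld = NA_real_, mean_chisq = NA_real_,
                    se_chisq = NA_real_, mean_maf = NA_real_,
                    prop_null = NA_real_, n_variants = 0L, usable = FALSE)
  by_bin <- split(seq_along(bin), factor(bin, levels = seq_len(n_bins)))
  for (b in seq_len(n_bins)) {
    i <- by_bin[[b]]
    nb <- length(i)
    out$n_variants[b] <- nb
    if (!nb) next
    out$mean_ld[b] <- mean(d$ldscore[i])
    out$se_ld[b] <- sd(d$ldscore[i]) / sqrt(nb)
    cs <- chisq[i]
    out$mean_chisq[b] <- mean(cs, na.rm = TRUE)
    out$se_chisq[b] <- sd(cs, na.rm = TRUE) / sqrt(sum(!is.na(cs)))
    out$mean_maf[b] <- mean(pmin(d$maf[i], 1 - d$maf[i]))
    members[[b]] <- list(beta = d$beta[i], se = d$se[i])
    if (nb >= max(min_bin_n, 10)) {   # the mixture fit needs >= 10 points
      out$prop_null[b] <- fit_ash(d$beta[i], d$se[i], penalty = penalty)$pi0
      out$usable[b] <- TRUE
    }
  }
  class(out) <- c("bin_summary", "data.frame")
  attr(out, "members") <- members
  attr(out, "n_bins") <- n_bins
  attr(out, "maf_range") <- maf_range
  out
}

#' Univariate LD-score regression
#'
#' Weighted least squares of chi-square (t^2) on LD score with weights
#' 1/max(1, l)^2 (a simple heteroscedasticity proxy). The intercept
#' estimates test-statistic inflation; the slope implies
#' h2 = slope * M / N.
#'
#' @param assoc `assoc_result` (>= 100 variants).
#' @param ldscores data.frame (variant_id, ldscore).
#' @param n_individuals GWAS sample size N.
#' @return list (slope, intercept, se_slope, se_intercept, h2_implied,
#'   n_variants).
#' @export
ldsc_regression <- function(assoc, ldscores, n_individuals) {
  idx <- match(assoc$variant_id, ldscores$variant_id)
  d <- data.frame(t_stat = assoc$t_stat,
                  ldscore = ldscores$ldscore[idx])[!is.na(idx), , drop = FALSE]
  if (nrow(d) < 100) stop_domain("need at least 100 variants")
  ell <- d$ldscore
  if (sd(ell) == 0) stop_domain("constant LD score: degenerate design")
  chisq <- d$t_stat^2
  w <- 1 / pmax(1, ell)^2
  X <- cbind(1, ell)
  XtW <- t(X * w)
  A <- XtW %*% X
  coefs <- solve(A, XtW %*% chisq)
  resid <- chisq - X %*% coefs
  ## heteroscedasticity-robust (sandwich) standard errors
  meat <- t(X * (w^2 * as.vector(resid)^2)) %*% X
  V <- solve(A, meat) %*% solve(A)
  M <- nrow(d)
  list(slope = coefs[2], intercept = coefs[1],
       se_slope = sqrt(V[2, 2]), se_intercept = sqrt(V[1, 1]),
       h2_implied = coefs[2] * M / n_individuals, n_variants = M)
}

#' Build a reference curve library over a (pi1, lambda) grid
#'
#' For each grid point, simulates `n_reps` summary-statistic replicates via
#' [simulate_summary_stats()] (inflation applied by rescaling the same base
#' replicate, so lambda variation is noise-free), bins each with
#' [bin_and_summarize()], and averages the per-bin curves. Optionally cached
#' to disk as JSON keyed by a content hash of all parameters.
#'
#' @param pi1_grid causal-fraction grid (e.g. the reference grid
#'   c(1e-4, 1e-3, 3e-3, 0.01, 0.03)).
#' @param lambda_grid inflation grid (e.g. c(0.9, 1, 1.05, 1.1, 1.2)).
#' @param spec_template `architecture_spec` supplying h2, effect family,
#'   placement and maf_floor (pi1 and lambda are overridden per grid point).
#' @param ld_profile `ld_profile` shared by all simulations.
#' @param n_individuals sample size for the simulated GWAS.
#' @param n_reps replicates per grid point (>= 1).
#' @param seed master seed; every replicate draws a derived child seed.
#' @param n_bins,maf_range,penalty passed to [bin_and_summarize()].
#' @param cache_dir optional directory for JSON caching.
#' @return object of class `reference_library`: list with `curves` (named
#'   list per grid point of averaged bin tables), grids, and the binning
#'   metadata needed by [estimate_pi1_matching()].
#' @export
build_reference_curves <- function(pi1_grid, lambda_grid, spec_template,
                                   ld_profile, n_individuals, n_reps = 3,
                                   seed = 1, n_bins = 1000,
                                   maf_range = c(0, 0.5), penalty = 10,
                                   cache_dir = NULL) {
  stopifnot(length(pi1_grid) >= 1, length(lambda_grid) >= 1, n_reps >= 1)
  key <- content_key(list(pi1_grid, lambda_grid,
                          unclass(spec_template)[c("h2", "effect_family", "df",
                                                   "placement", "alpha", "rho",
                                                   "maf_floor")],
                          ld_profile$variants$ldscore, n_individuals, n_reps,
                          seed, n_bins, maf_range, penalty))
  if (!is.null(cache_dir)) {
    cache_file <- file.path(cache_dir, paste0("reflib_", key, ".json"))
    if (file.exists(cache_file)) {
      return(read_reference_library(cache_file))
    }
  }
  ldt <- profile_ldscores(ld_profile)
  curves <- list()
  for (i in seq_along(pi1_grid)) {
    pi1 <- pi1_grid[i]
    per_lambda <- lapply(lambda_grid, function(l) vector("list", n_reps))
    for (r in seq_len(n_reps)) {
      spec <- spec_template
      spec$pi1 <- pi1
      spec$inflation_lambda <- 1
      base <- simulate_summary_stats(spec, ld_profile, n_individuals,
                                     seed = child_seed(seed, i * 1000 + r))
      for (j in seq_along(lambda_grid)) {
        infl <- inflate_assoc(base, lambda_grid[j])
        bs <- bin_and_summarize(infl, ldt, n_bins = n_bins,
                                maf_range = maf_range, penalty = penalty)
        per_lambda[[j]][[r]] <- as.data.frame(bs)
      }
    }
    for (j in seq_along(lambda_grid)) {
      reps <- per_lambda[[j]]
      avg <- reps[[1]]
      num_cols <- c("mean_ld", "se_ld", "mean_chisq", "se_chisq", "mean_maf",
                    "prop_null")
      for (cc in num_cols) {
        avg[[cc]] <- rowMeans(do.call(cbind, lapply(reps, `[[`, cc)))
      }
      ## between-replicate spread: the library's own Monte-Carlo error,
      ## propagated into the matching objective
      if (n_reps > 1) {
        avg$rep_sd_prop_null <- apply(do.call(cbind, lapply(reps, `[[`,
                                                            "prop_null")), 1, sd)
        avg$rep_sd_chisq <- apply(do.call(cbind, lapply(reps, `[[`,
                                                        "mean_chisq")), 1, sd)
      } else {
        avg$rep_sd_prop_null <- 0
        avg$rep_sd_chisq <- 0
      }
      avg$usable <- Reduce(`&`, lapply(reps, `[[`, "usable"))
      curves[[grid_name(pi1, lambda_grid[j])]] <- avg
    }
  }
  lib <- structure(list(curves = curves, pi1_grid = pi1_grid,
                        lambda_grid = lambda_grid, n_bins = n_bins,
                        maf_range = maf_range, n_reps = n_reps,
                        n_individuals = n_individuals,
                        h2 = spec_template$h2, key = key),
                   class = "reference_library")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    write_reference_library(lib, cache_file)
  }
  lib
}

grid_name <- function(pi1, lambda) sprintf("pi1=%g|lambda=%g", pi1, lambda)

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("reference_library: pi1 grid {%s} x lambda grid {%s}, %d bins, %d reps, N=%d, h2=%g\n",
              paste(x$pi1_grid, collapse = ", "),
              paste(x$lambda_grid, collapse = ", "),
              x$n_bins, x$n_reps, x$n_individuals, x$h2))
  invisible(x)
}

#' Write / read a reference library as JSON
#' @param lib a `reference_library`.
#' @param path JSON file path.
#' @export
write_reference_library <- function(lib, path) {
  jsonlite::write_json(unclass(lib), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_library
#' @export
read_reference_library <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$curves <- lapply(x$curves, as.data.frame)
  structure(x, class = "reference_library")
}

## Running-median smoothing of per-bin variance estimates (window 11);
## replicate variances have very few degrees of freedom per bin and the
## underlying scale varies slowly along the LD-score axis.
smooth_var <- function(v, window = 11) {
  n <- length(v)
  if (n < 3) return(v)
  half <- window %/% 2
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::median(v[lo:hi], na.rm = TRUE)
  }, 0)
  out[!is.finite(out)] <- 0
  out
}

## Bootstrap standard error of a bin's null proportion: multinomial
## resampling of observations expressed as weighted EM refits.
boot_prop_null_se <- function(beta, se, n_boot = 50, penalty = 10, seed = 1) {
  n <- length(beta)
  grid <- default_sd_grid(beta, se)
  sd_tot <- sqrt(outer(se^2, grid^2, "+"))
  L <- dnorm(beta / sd_tot) / sd_tot
  ## bootstrap refits reuse the likelihood matrix, warm-start at the
  ## full-data solution, and skip the exact polish: only the spread of the
  ## refitted null weight is needed
  full <- em_mix_weights(L, rep(1, n), penalty, 1e-7, 2000L, FALSE)
  with_seed(seed, {
    counts <- rmultinom(n_boot, n, rep(1 / n, n))
    pis <- vapply(seq_len(n_boot), function(b) {
      em_mix_weights(L, counts[, b], penalty, 1e-6, 300L, FALSE,
                     polish = FALSE, init = full$weights)$weights[1]
    }, 0)
    sd(pis)
  })
}

#' Estimate the causal fraction by simulation matching
#'
#' Compares observed per-bin curves with a reference library and returns the
#' grid point minimizing
#'   sum over usable bins of (prop_null_obs - prop_null_sim)^2 / se_pn^2
#'                          + (mean_chisq_obs - mean_chisq_sim)^2 / se_chisq^2,
#' where se_pn is a within-bin multinomial bootstrap standard error of the
#' observed null proportion (floored to avoid division blow-ups) and
#' se_chisq the observed bin's chi-square standard error. The final estimate
#' interpolates between bracketing pi1 grid points by a quadratic fit of the
#' objective in log10(pi1) at the best lambda.
#'
#' @param observed `bin_summary` of the trait of interest. The library must
#'   have been built with identical n_bins and maf_range and at a matching
#'   sample size and heritability.
#' @param library a `reference_library`.
#' @param n_boot bootstrap replicates per bin for the null-proportion se.
#' @param seed seed for the bootstrap.
#' @return object of class `polygenicity_fit`: pi1_hat, method, lambda_grid,
#'   objective_by_lambda (pi1 x lambda matrix), best_lambda, diagnostics.
#' @export
estimate_pi1_matching <- function(observed, library, n_boot = 50, seed = 1) {
  stopifnot(inherits(library, "reference_library"))
  if (!is.null(attr(observed, "n_bins")) &&
      attr(observed, "n_bins") != library$n_bins) {
    stop_domain("observed bins and library built with different n_bins")
  }
  obs <- as.data.frame(observed)
  members <- attr(observed, "members")
  usable <- obs$usable & is.finite(obs$prop_null)

  ## per-bin bootstrap se for the observed null proportion
  se_pn <- rep(NA_real_, nrow(obs))
  if (!is.null(members)) {
    for (b in which(usable)) {
      se_pn[b] <- boot_prop_null_se(members[[b]]$beta, members[[b]]$se,
                                    n_boot = n_boot,
                                    seed = child_seed(seed, b))
    }
  }
  se_pn_floor <- max(1e-3, median(se_pn[usable], na.rm = TRUE) / 10,
                     na.rm = TRUE)
  se_pn <- pmax(se_pn, se_pn_floor)
  se_cs <- pmax(obs$se_chisq, 1e-6)

  np <- length(library$pi1_grid); nl <- length(library$lambda_grid)
  objective <- matrix(NA_real_, np, nl,
                      dimnames = list(paste0("pi1_", library$pi1_grid),
                                      paste0("lambda_", library$lambda_grid)))
  for (i in seq_len(np)) for (j in seq_len(nl)) {
    sim <- library$curves[[grid_name(library$pi1_grid[i],
                                     library$lambda_grid[j])]]
    if (nrow(sim) != nrow(obs)) stop_domain("bin count mismatch with library")
    ok <- usable & sim$usable & is.finite(sim$prop_null)
    ## Gaussian pseudo-likelihood per bin on (prop_null, log mean_chisq).
    ## Denominators combine the observed-bin uncertainty with the
    ## causal-draw variance estimated from the library replicates: the
    ## observed curve is one further draw from the same world, so the
    ## obs-minus-library-mean difference carries (1 + 1/n_reps) times the
    ## per-replicate variance. Replicate variances (df = n_reps - 1 per
    ## bin) are floored by a running-median smooth but never reduced, so
    ## isolated sparse-causal spikes keep their large variance. The
    ## log-variance term makes grid points comparable: without it, grid
    ## points with large modeled variance win by variance alone. The
    ## chi-square curve enters on the log scale, where its heavy per-bin
    ## skew at small pi1 is tamed.
    zero <- rep(0, nrow(sim))
    fac <- 1 + 1 / library$n_reps
    rep_v_pn <- if (is.null(sim$rep_sd_prop_null)) zero else
      pmax(sim$rep_sd_prop_null^2, smooth_var(sim$rep_sd_prop_null^2)) * fac
    rel_cs <- if (is.null(sim$rep_sd_chisq)) zero else
      (sim$rep_sd_chisq / sim$mean_chisq)^2
    rep_v_cs <- pmax(rel_cs, smooth_var(rel_cs)) * fac
    v_pn <- se_pn[ok]^2 + rep_v_pn[ok]
    v_cs <- (se_cs[ok] / obs$mean_chisq[ok])^2 + rep_v_cs[ok]
    objective[i, j] <- sum(
      (obs$prop_null[ok] - sim$prop_null[ok])^2 / v_pn + log(v_pn) +
        (log(obs$mean_chisq[ok]) - log(sim$mean_chisq[ok]))^2 / v_cs +
        log(v_cs))
  }
  best <- which(objective == min(objective), arr.ind = TRUE)[1, ]
  best_lambda <- library$lambda_grid[best[2]]

  ## log-scale quadratic interpolation between bracketing pi1 points
  i0 <- best[1]
  pi1_hat <- library$pi1_grid[i0]
  if (i0 > 1 && i0 < np) {
    lx <- log10(library$pi1_grid[(i0 - 1):(i0 + 1)])
    ly <- objective[(i0 - 1):(i0 + 1), best[2]]
    fit <- lm.fit(cbind(1, lx, lx^2), ly)
    a <- fit$coefficients
    if (is.finite(a[3]) && a[3] > 0) {
      vertex <- -a[2] / (2 * a[3])
      vertex <- min(max(vertex, lx[1]), lx[3])
      pi1_hat <- 10^vertex
    }
  }
  structure(list(pi1_hat = unname(pi1_hat), method = "matching",
                 lambda_grid = library$lambda_grid,
                 objective_by_lambda = objective,
                 best_lambda = unname(best_lambda),
                 diagnostics = list(se_prop_null = se_pn,
                                    usable_bins = sum(usable),
                                    best_grid_pi1 = library$pi1_grid[i0])),
            class = "polygenicity_fit")
}

#' @export
print.polygenicity_fit <- function(x, ...) {
  cat(sprintf("polygenicity_fit (%s): pi1_hat = %.4g", x$method, x$pi1_hat))
  if (!is.null(x$best_lambda)) cat(sprintf(", best lambda = %g", x$best_lambda))
  cat("\n")
  invisible(x)
}

## Weighted NLS fit of the exponential null-proportion decay
## prop_null(l) = a * exp(-k * l); returns the rate k, the multiplicative
## intercept a, and the objective value. The intercept absorbs uniform
## (inflation-style) depression of the null proportion, which is what makes
## the rate — and hence the pi1 estimate — robust to test-statistic
## inflation. Only the rate is identified as a causal-fraction signal: in
## the (pi1, c) parametrization prop_null = (1 - pi1)^(c*l) = exp(-k*l)
## with k = -c*log(1 - pi1), so (pi1, c) trade off exactly along a ridge.
parametric_decay_rate <- function(ell, pn, w) {
  a_for <- function(k) {
    e <- exp(-k * ell)
    min(max(sum(w * pn * e) / sum(w * e^2), 1e-6), 1.05)
  }
  obj <- function(logk) {
    k <- exp(logk)
    sum(w * (pn - a_for(k) * exp(-k * ell))^2)
  }
  fits <- lapply(log(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)), function(s0) {
    tryCatch(optim(s0, obj, method = "Brent", lower = log(1e-10),
                   upper = log(10)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop_domain("parametric fit failed to converge")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  k <- exp(best$par)
  list(k = k, a = a_for(k), value = best$value)
}

#' Estimate the causal fraction by a parametric fit to the null-proportion
#' curve
#'
#' Fits prop_null(l) = (1 - pi1)^(c * l) to the per-bin null proportions by
#' weighted nonlinear least squares (weights = bin sizes). Only the decay
#' rate k = -c * log(1 - pi1) is identified by the curve, so converting the
#' rate to pi1 requires fixing the tagging coefficient c (the effective
#' number of tagged variants per unit LD score). Two routes are offered:
#' supplying a `library` of reference curves calibrates the k-to-pi1 map by
#' fitting the same decay to each library curve and inverting by log-log
#' interpolation (self-calibrating, recommended); alternatively a numeric
#' `c_tag` applies pi1 = 1 - exp(-k / c_tag) directly.
#'
#' `lambda_assumed` deflates the observed statistics (beta / sqrt(lambda))
#' and refits the per-bin null proportions before fitting; because the rate
#' is driven by the high-LD decay rather than the intercept, the resulting
#' estimates are insensitive to modest misspecification of the inflation.
#'
#' The functional form is this package's construction (the single-c
#' exponential is a deliberate simplification), recorded as such in the
#' fit diagnostics.
#'
#' @param observed `bin_summary` with at least 20 usable bins (must carry
#'   the "members" attribute when `lambda_assumed != 1`).
#' @param lambda_assumed assumed test-statistic inflation.
#' @param library optional `reference_library` for rate calibration (its
#'   lambda grid must contain 1).
#' @param c_tag fixed tagging coefficient, used when no library is given.
#' @param penalty passed to the per-bin refits under `lambda_assumed`.
#' @return `polygenicity_fit` with pi1_hat, the fitted decay rate, and
#'   diagnostics; `method` is "parametric".
#' @export
estimate_pi1_parametric <- function(observed, lambda_assumed = 1,
                                    library = NULL, c_tag = NULL,
                                    penalty = 10) {
  if (is.null(library) && is.null(c_tag)) {
    stop_domain("supply a reference library or a fixed c_tag")
  }
  obs <- as.data.frame(observed)
  usable <- obs$usable & is.finite(obs$prop_null)
  if (sum(usable) < 20) stop_domain("need at least 20 usable bins")
  pn <- obs$prop_null
  if (lambda_assumed != 1) {
    members <- attr(observed, "members")
    if (is.null(members)) {
      stop_domain("lambda_assumed != 1 requires bin members for refitting")
    }
    s <- sqrt(lambda_assumed)
    for (b in which(usable)) {
      pn[b] <- fit_ash(members[[b]]$beta / s, members[[b]]$se,
                       penalty = penalty)$pi0
    }
  }
  fit <- parametric_decay_rate(obs$mean_ld[usable], pn[usable],
                               obs$n_variants[usable])
  k_hat <- fit$k
  if (!is.null(library)) {
    if (!1 %in% library$lambda_grid) {
      stop_domain("library lambda grid must contain 1 for rate calibration")
    }
    k_lib <- vapply(library$pi1_grid, function(p) {
      cv <- library$curves[[grid_name(p, 1)]]
      u <- cv$usable & is.finite(cv$prop_null)
      parametric_decay_rate(cv$mean_ld[u], cv$prop_null[u], cv$n_variants[u])$k
    }, 0)
    ## invert the monotone k(pi1) map by log-log interpolation
    ord <- order(k_lib)
    lk <- log(k_lib[ord]); lp <- log(library$pi1_grid[ord])
    lko <- log(max(k_hat, min(k_lib) * 1e-3))
    if (lko <= lk[1]) {
      pi1_hat <- exp(lp[1] + (lko - lk[1]))        # unit log-log slope tail
    } else if (lko >= lk[length(lk)]) {
      pi1_hat <- exp(lp[length(lp)] + (lko - lk[length(lk)]))
    } else {
      pi1_hat <- exp(stats::approx(lk, lp, xout = lko)$y)
    }
    pi1_hat <- min(pi1_hat, 1)
    c_used <- k_hat / max(-log(1 - pi1_hat), 1e-12)
  } else {
    pi1_hat <- 1 - exp(-k_hat / c_tag)
    c_used <- c_tag
  }
  if (all(pn[usable] >= 1 - 1e-12)) pi1_hat <- 0
  structure(list(pi1_hat = unname(pi1_hat), method = "parametric",
                 lambda_grid = lambda_assumed, objective_by_lambda = fit$value,
                 best_lambda = lambda_assumed,
                 diagnostics = list(decay_rate = k_hat, c_tag = c_used,
                                    calibration = if (is.null(library))
                                      "fixed-c" else "library",
                                    n_bins_used = sum(usable),
                                    functional_form = "prop_null = (1-pi1)^(c*l); package-defined form")),
            class = "polygenicity_fit")
}
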