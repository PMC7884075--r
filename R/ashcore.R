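## Empirical-Bayes point-mass-plus-normal mixture for (beta, se) pairs.
## The marginal model for observation i is
##   betahat_i ~ sum_k w_k Normal(0, sd_k^2 + se_i^2),
## with sd_1 = 0 (the point mass). The null weight w_1 is the quantity the
## LD-bin pipeline consumes as the per-bin proportion of null effects.

default_sd_grid <- function(betahat, se) {
  lo <- min(se) / 10
  hi <- 2 * max(abs(betahat))
  if (hi <= 0) return(c(0, lo))          # degenerate: all betahat zero
  if (hi <= lo) return(c(0, hi))
  n_steps <- ceiling(log(hi / lo) / log(sqrt(2)))
  c(0, lo * sqrt(2)^(0:n_steps))
}

#' Fit the point-mass-plus-normal mixture
#'
#' Maximizes the penalized marginal likelihood by EM over mixture weights on
#' a fixed standard-deviation grid (point mass first, then multiplicative
#' sqrt(2) spacing from min(se)/10 to 2*max|betahat|). A Dirichlet-style
#' penalty of strength `penalty` on the null weight makes the estimated
#' null proportion conservative, following the adaptive-shrinkage
#' convention. Deterministic given inputs.
#'
#' @param betahat effect estimates.
#' @param se standard errors (> 0), same length.
#' @param grid optional nondecreasing sd grid; first element must be 0.
#' @param penalty null-favoring penalty (>= 1; 10 by default).
#' @param tol absolute penalized log-likelihood convergence tolerance.
#' @param maxiter EM iteration cap.
#' @param obs_weights optional nonnegative per-observation weights
#'   (used internally for bootstrap refits).
#' @return object of class `ash_fit`: component_sds, weights, pi0, penalty,
#'   loglik, loglik_trace, n_iter, converged.
#' @export
fit_ash <- function(betahat, se, grid = NULL, penalty = 10, tol = 1e-7,
                    maxiter = 2000, obs_weights = NULL) {
  if (length(betahat) != length(se)) stop_domain("betahat/se length mismatch")
  if (length(betahat) < 10) stop_domain("need at least 10 observations")
  if (any(!is.finite(betahat)) || any(!is.finite(se))) {
    stop_domain("non-finite betahat or se")
  }
  if (any(se <= 0)) stop_domain("se must be positive")
  if (penalty < 1) stop_domain("penalty must be >= 1")
  if (is.null(grid)) grid <- default_sd_grid(betahat, se)
  if (grid[1] != 0 || is.unsorted(grid)) {
    stop_domain("grid must be nondecreasing with first element 0")
  }
  w_obs <- obs_weights %||% rep(1, length(betahat))

  ## n x K likelihood matrix, computed once
  sd_tot <- sqrt(outer(se^2, grid^2, "+"))
  L <- dnorm(betahat / sd_tot) / sd_tot
  fit <- em_mix_weights(L, w_obs, penalty, tol, as.integer(maxiter), TRUE)

  structure(list(component_sds = grid, weights = fit$weights,
                 pi0 = fit$weights[1], penalty = penalty,
                 loglik = fit$loglik, loglik_trace = fit$trace,
                 n_iter = fit$n_iter, converged = fit$converged),
            class = "ash_fit")
}

#' @export
print.ash_fit <- function(x, ...) {
  cat(sprintf("ash_fit: %d components, pi0 = %.4f, loglik = %.3f (%s in %d iter)\n",
              length(x$weights), x$pi0, x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Null proportion from an association table
#'
#' Thin wrapper applying [fit_ash()] to the BETA/SE columns of an
#' `assoc_result` and returning the fitted null weight.
#'
#' @param assoc `assoc_result` (columns beta, se).
#' @param ... passed to [fit_ash()].
#' @return numeric null proportion in \[0, 1\].
#' @export
prop_null <- function(assoc, ...) {
  fit_ash(assoc$beta, assoc$se, ...)$pi0
}

#' Posterior mean effects under a fitted mixture
#'
#' Conjugate-normal shrinkage: each component contributes
#' betahat * sd_k^2 / (sd_k^2 + se^2) weighted by its posterior
#' responsibility, so estimates are shrunk toward zero and never exceed
#' |betahat|.
#'
#' @param model fitted `ash_fit`.
#' @param betahat effect estimates.
#' @param se standard errors.
#' @return shrunken effect vector.
#' @export
posterior_mean_effects <- function(model, betahat, se) {
  if (!inherits(model, "ash_fit")) stop_domain("model is not a fitted ash_fit")
  if (length(betahat) != length(se)) stop_domain("betahat/se length mismatch")
  grid <- model$component_sds
  sd_tot2 <- outer(se^2, grid^2, "+")
  L <- dnorm(betahat / sqrt(sd_tot2)) / sqrt(sd_tot2)
  resp <- mix_responsibilities(L, model$weights)
  shrink <- sweep(1 / sd_tot2, 2, grid^2, "*")   # sd_k^2/(sd_k^2+se^2)
  rowSums(resp * shrink) * betahat
}

#' Serialize an ash fit to JSON
#'
#' @param model fitted `ash_fit`.
#' @param path output JSON path.
#' @export
write_ash_json <- function(model, path) {
  jsonlite::write_json(
    list(component_sds = model$component_sds, weights = model$weights,
         pi0 = model$pi0, penalty = model$penalty, loglik = model$loglik,
         loglik_trace = model$loglik_trace, n_iter = model$n_iter,
         converged = model$converged),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
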