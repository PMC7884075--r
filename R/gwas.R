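## Phenotype preparation and per-variant association at synthetic scale.

#' Log-transform and covariate-adjust a trait
#'
#' Regresses log(raw) on the covariate matrix (an intercept is prepended
#' unless `add_intercept = FALSE`) and returns the residuals, which are the
#' phenotype used by all downstream association and non-additivity tests.
#'
#' @param raw_values strictly positive trait measurements.
#' @param covariates data.frame or matrix of numeric covariates (may be
#'   NULL for intercept-only adjustment); must be full column rank.
#' @param add_intercept prepend an intercept column (default TRUE).
#' @return numeric residual vector, orthogonal to every covariate column.
#' @export
preprocess_trait <- function(raw_values, covariates = NULL,
                             add_intercept = TRUE) {
  bad <- which(!is.finite(raw_values) | raw_values <= 0)
  if (length(bad)) {
    stop_domain("non-positive or non-finite measurement at record ", bad[1])
  }
  y <- log(raw_values)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(X) && nrow(X) != length(y)) {
    stop_domain("covariates and measurements differ in length")
  }
  if (!is.null(X) && anyNA(X)) stop_domain("covariates contain missing values")
  if (add_intercept) X <- cbind(`(Intercept)` = rep(1, length(y)), X)
  if (is.null(X)) return(y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop_domain("covariate matrix is rank deficient (collinear columns)")
  }
  as.vector(qr.resid(qx, y))
}

#' Two-stage cleaning of repeated measurements
#'
#' Per-individual medians are taken; stage 1 drops individuals whose median
#' lies more than 10 x IQR (linear-interpolation quartiles) from the median
#' of medians, and stage 2 drops, among survivors, individuals more than 4
#' standard deviations (n-1 denominator) from the survivors' mean. When the
#' IQR of medians is zero the stage-1 filter is skipped entirely, since a
#' literal reading would discard every non-median individual.
#'
#' @param observations named list of numeric measurement vectors, one per
#'   individual (each non-empty).
#' @return data.frame (individual, median, n_obs, kept, stage) where stage
#'   is "ok", "stage1" or "stage2".
#' @export
clean_repeated_measures <- function(observations) {
  if (!length(observations)) stop_domain("empty input: no individuals")
  if (any(!lengths(observations))) {
    stop_domain("every individual needs at least one observation")
  }
  ids <- names(observations) %||% as.character(seq_along(observations))
  med <- vapply(observations, median, 0)
  n_obs <- lengths(observations)
  stage <- rep("ok", length(med))

  if (length(med) > 1) {
    iqr <- iqr_type7(med)
    if (iqr > 0) {
      ctr <- median(med)
      stage[abs(med - ctr) > 10 * iqr] <- "stage1"
    }
    surv <- stage == "ok"
    if (sum(surv) > 1) {
      mu <- mean(med[surv]); s <- sd(med[surv])
      if (s > 0) stage[surv & abs(med - mu) > 4 * s] <- "stage2"
    }
  }
  data.frame(individual = ids, median = med, n_obs = n_obs,
             kept = stage == "ok", stage = stage,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-variant linear association scan
#'
#' Simple linear regression of a prepared (residualized) phenotype on each
#' variant's dosage, with MAF and missingness filters. Covariates are
#' expected to have been removed beforehand by [preprocess_trait()];
#' dosage is the only regressor.
#'
#' @param panel a `genotype_panel` (dosages may contain NA).
#' @param phenotype numeric vector aligned to `panel$sample_ids`.
#' @param maf_min retain variants with observed MAF strictly greater
#'   (0 keeps all polymorphic variants).
#' @param missing_max drop variants with missingness above this fraction.
#' @param hwe_midp accepted for interface parity and logged; synthetic
#'   genotypes are Hardy-Weinberg by construction so no filter is applied.
#' @return `assoc_result` data.frame; attribute "n_filtered" counts
#'   exclusions by reason.
#' @export
run_gwas <- function(panel, phenotype, maf_min = 0, missing_max = 1,
                     hwe_midp = NULL) {
  validate_panel(panel)
  n <- length(panel$sample_ids)
  if (length(phenotype) != n) stop_domain("phenotype not aligned to panel")
  if (!is.null(hwe_midp)) {
    message("hwe_midp = ", hwe_midp,
            " accepted but not applied (pass-through flag)")
  }
  X <- panel$dosages
  obs <- !is.na(X)
  y <- phenotype
  n_obs <- colSums(obs)
  missing <- 1 - n_obs / n

  ## per-variant OLS with NA-aware closed forms
  Xz <- X; Xz[!obs] <- 0
  sum_x <- colSums(Xz)
  sum_y <- as.vector(crossprod(obs, y))
  sum_xy <- as.vector(crossprod(Xz, y))
  sum_x2 <- colSums(Xz^2)
  sum_y2 <- as.vector(crossprod(obs, y^2))
  mean_x <- sum_x / n_obs
  sxx <- sum_x2 - n_obs * mean_x^2
  sxy <- sum_xy - sum_x * sum_y / n_obs
  syy <- sum_y2 - sum_y^2 / n_obs

  freq <- sum_x / (2 * n_obs)
  maf <- pmin(freq, 1 - freq)
  poly <- sxx > 1e-12
  keep_maf <- maf > maf_min
  keep_miss <- missing <= missing_max
  keep <- poly & keep_maf & keep_miss & n_obs >= 3
  n_filtered <- c(monomorphic = sum(!poly),
                  maf = sum(poly & !keep_maf),
                  missingness = sum(poly & keep_maf & !keep_miss))
  if (n_filtered["monomorphic"] > 0) {
    message(n_filtered["monomorphic"], " zero-variance variant(s) skipped")
  }

  beta <- sxy / sxx
  rss <- syy - beta * sxy
  rss[rss < 0] <- 0
  sigma2 <- rss / (n_obs - 2)
  se <- sqrt(sigma2 / sxx)
  t_stat <- beta / se
  p <- pmax(2 * stats::pt(-abs(t_stat), df = n_obs - 2), 1e-300)

  vm <- panel$variant_map
  out <- data.frame(variant_id = vm$variant_id, chrom = vm$chrom,
                    pos_bp = vm$pos_bp, pos_cm = vm$pos_cm, maf = maf,
                    info = 1, n_obs = as.integer(n_obs), beta = beta,
                    se = se, t_stat = t_stat, p = p,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Filter association results on MAF and INFO
#'
#' Strict inequalities, as in the source filters "allele frequency greater
#' than" and "INFO score greater than"; row order is preserved.
#'
#' @param assoc `assoc_result`.
#' @param maf_min keep variants with maf strictly greater.
#' @param info_min keep variants with info strictly greater.
#' @return filtered `assoc_result`.
#' @export
filter_assoc <- function(assoc, maf_min = 0, info_min = 0) {
  assert_cols(assoc, c("maf"), "assoc")
  if (info_min > 0 && (!"info" %in% names(assoc) || all(is.na(assoc$info)))) {
    stop_domain("info_min > 0 but assoc carries no INFO column")
  }
  keep <- assoc$maf > maf_min
  if (info_min > 0) keep <- keep & assoc$info > info_min
  out <- assoc[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}
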