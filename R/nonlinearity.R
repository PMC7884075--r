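## Dominance, pairwise-epistasis, and stratified paired-difference screens.
## All tests take a residualized trait (see preprocess_trait) as outcome.

## Round dosage to the nearest genotype class in {0, 1, 2}; ties (x.5)
## round half-up.
round_genotype <- function(dosage) {
  pmin(2L, pmax(0L, as.integer(floor(dosage + 0.5))))
}

## RSS of least squares y ~ X (with intercept prepended), rank-aware.
rss_fit <- function(X, y) {
  qx <- qr(cbind(1, X))
  list(rss = sum(qr.resid(qx, y)^2), rank = qx$rank)
}

#' Test for non-additive (dominance-style) single-variant effects
#'
#' Nested-model F test of dosage-only against dosage plus indicators for
#' each rounded genotype class. With all three classes present this is a
#' 1-degree-of-freedom test for any departure from additivity.
#'
#' @param dosage dosage vector in \[0, 2\].
#' @param trait residualized trait, same length.
#' @param min_class_n genotype-class count below which the result is
#'   flagged `low_count` (default 5; flagged, not dropped).
#' @return object of class `nonadd_result`: variant-level F, df pair, p,
#'   class counts, low_count flag.
#' @export
dominance_test <- function(dosage, trait, min_class_n = 5) {
  stopifnot(length(dosage) == length(trait))
  ok <- is.finite(dosage) & is.finite(trait)
  dosage <- dosage[ok]; trait <- trait[ok]
  g <- round_genotype(dosage)
  counts <- table(factor(g, levels = 0:2))
  if (sum(counts > 0) < 2) stop_domain("fewer than 2 genotype classes")
  f0 <- rss_fit(cbind(dosage), trait)
  ind <- stats::model.matrix(~ factor(g))[, -1, drop = FALSE]
  f1 <- rss_fit(cbind(dosage, ind), trait)
  df1 <- f1$rank - f0$rank
  df2 <- length(trait) - f1$rank
  if (df1 <= 0) {
    F <- 0; p <- 1; df1 <- 0L
  } else {
    F <- max(0, (f0$rss - f1$rss) / df1 / (f1$rss / df2))
    p <- pf(F, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = F, df = c(df1, df2), p = p,
                 class_counts = as.vector(counts),
                 low_count = any(counts > 0 & counts < min_class_n)),
            class = "nonadd_result")
}

#' @export
print.nonadd_result <- function(x, ...) {
  cat(sprintf("dominance F(%d, %d) = %.3f, p = %.3g%s\n", x$df[1], x$df[2],
              x$F, x$p, if (x$low_count) " [low-count class]" else ""))
  invisible(x)
}

#' Pairwise epistasis test between two variants
#'
#' F test comparing the two-locus main-effects indicator model (factor(gA) +
#' factor(gB); 4 genotype degrees of freedom when both variants have three
#' classes) against the full interaction model factor(gA) * factor(gB)
#' (8 degrees of freedom), on rounded genotypes.
#'
#' @param dosage_a,dosage_b dosage vectors.
#' @param trait residualized trait.
#' @return object of class `epistasis_result` with F, df pair, p.
#' @export
epistasis_test <- function(dosage_a, dosage_b, trait) {
  stopifnot(length(dosage_a) == length(trait),
            length(dosage_b) == length(trait))
  ga <- round_genotype(dosage_a)
  gb <- round_genotype(dosage_b)
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2) {
    stop_domain("monomorphic variant after rounding")
  }
  if (identical(ga, gb)) stop_domain("collinear design: identical variants")
  A <- stats::model.matrix(~ factor(ga))[, -1, drop = FALSE]
  B <- stats::model.matrix(~ factor(gb))[, -1, drop = FALSE]
  f0 <- rss_fit(cbind(A, B), trait)
  full <- stats::model.matrix(~ factor(ga) * factor(gb))[, -1, drop = FALSE]
  f1 <- rss_fit(full, trait)
  df1 <- f1$rank - f0$rank
  df2 <- length(trait) - f1$rank
  if (df1 <= 0) {
    F <- 0; p <- 1; df1 <- 0L
  } else {
    F <- max(0, (f0$rss - f1$rss) / df1 / (f1$rss / df2))
    p <- pf(F, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = F, df = c(df1, df2), p = p,
                 main_df = f0$rank - 1L, full_df = f1$rank - 1L),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf("epistasis F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Paired-difference Z test between two association strata
#'
#' For every variant shared by two GWAS run in disjoint individual strata,
#' z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2) with a two-sided standard
#' normal p-value. Variants present in only one stratum are excluded with a
#' count; mismatched alleles raise a harmonization error.
#'
#' @param assoc_a,assoc_b `assoc_result` tables from disjoint strata.
#' @return data.frame (variant_id, beta_a, se_a, beta_b, se_b, z, p) with
#'   attribute "n_excluded".
#' @export
paired_difference_test <- function(assoc_a, assoc_b) {
  for (x in list(assoc_a, assoc_b)) {
    assert_cols(x, c("variant_id", "beta", "se"), "assoc")
  }
  shared <- intersect(assoc_a$variant_id, assoc_b$variant_id)
  n_excluded <- (nrow(assoc_a) - length(shared)) +
    (nrow(assoc_b) - length(shared))
  ia <- match(shared, assoc_a$variant_id)
  ib <- match(shared, assoc_b$variant_id)
  if (all(c("allele_ref", "allele_alt") %in% names(assoc_a)) &&
      all(c("allele_ref", "allele_alt") %in% names(assoc_b))) {
    if (any(assoc_a$allele_ref[ia] != assoc_b$allele_ref[ib]) ||
        any(assoc_a$allele_alt[ia] != assoc_b$allele_alt[ib])) {
      stop_domain("allele mismatch between strata: harmonize first")
    }
  }
  z <- (assoc_a$beta[ia] - assoc_b$beta[ib]) /
    sqrt(assoc_a$se[ia]^2 + assoc_b$se[ib]^2)
  out <- data.frame(variant_id = shared,
                    beta_a = assoc_a$beta[ia], se_a = assoc_a$se[ia],
                    beta_b = assoc_b$beta[ib], se_b = assoc_b$se[ib],
                    z = z, p = 2 * pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}
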