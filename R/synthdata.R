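## Synthetic genotype panels, causal architectures and phenotypes.
##
## The generator emulates a dense imputed panel: a latent Gaussian AR(1)
## process per chromosome is thresholded to diploid dosages at each
## variant's target MAF, which gives Hardy-Weinberg marginals and tunable
## local LD without any coalescent machinery.

#' Build a per-chromosome variant layout
#'
#' Convenience constructor for the variant grid consumed by
#' [simulate_genotypes()]: evenly spaced base-pair positions and a linear
#' genetic map.
#'
#' @param n_variants total number of variants.
#' @param n_chrom number of chromosomes (variants split as evenly as possible).
#' @param bp_step spacing between adjacent variants in bp.
#' @param cm_per_mb genetic-map density (centimorgan per megabase).
#' @return data.frame with columns chrom, pos_bp (1-based), pos_cm.
#' @export
variant_layout_grid <- function(n_variants, n_chrom = 1, bp_step = 5000,
                                cm_per_mb = 1) {
  stopifnot(n_variants >= 1, n_chrom >= 1, bp_step >= 1)
  per <- rep(n_variants %/% n_chrom, n_chrom)
  extra <- n_variants %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  out <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    idx <- seq_len(per[ch])
    data.frame(chrom = paste0("chr", ch),
               pos_bp = 1L + (idx - 1L) * as.integer(bp_step),
               pos_cm = (idx - 1L) * bp_step / 1e6 * cm_per_mb)
  }))
  rownames(out) <- NULL
  out
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  vm <- panel$variant_map
  assert_cols(vm, c("variant_id", "chrom", "pos_bp", "pos_cm",
                    "allele_ref", "allele_alt", "maf"), "variant_map")
  if (any(vm$maf <= 0 | vm$maf > 0.5)) {
    stop_domain("variant_map: maf must lie in (0, 0.5]")
  }
  for (ch in unique(vm$chrom)) {
    sub <- vm[vm$chrom == ch, ]
    if (is.unsorted(sub$pos_bp, strictly = TRUE) ||
        is.unsorted(sub$pos_cm, strictly = TRUE)) {
      stop_domain("positions must be strictly increasing within a chromosome")
    }
  }
  rng <- range(panel$dosages)
  if (rng[1] < 0 || rng[2] > 2) stop_domain("dosages must lie in [0, 2]")
  invisible(panel)
}

#' Simulate a genotype panel with local LD
#'
#' Draws two latent Gaussian haplotype processes per individual, AR(1)
#' within each chromosome with adjacent-variant correlation
#' `ld_decay^delta_cM`, and thresholds each at the per-variant MAF quantile.
#' The resulting dosage is Binomial(2, maf) marginally (Hardy-Weinberg by
#' construction) with LD controlled by `ld_decay`.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param variant_layout data.frame(chrom, pos_bp, pos_cm), e.g. from
#'   [variant_layout_grid()]; positions must be strictly increasing within
#'   chromosome.
#' @param ld_decay latent correlation per centimorgan, in \[0, 1).
#' @param maf_sampler function(n) returning MAFs in (0, 0.5]; default
#'   Uniform(0.01, 0.5).
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   panels.
#' @return object of class `genotype_panel`: list(sample_ids, variant_map,
#'   dosages) with dosages an individuals x variants integer matrix.
#' @export
simulate_genotypes <- function(n_individuals, variant_layout, ld_decay = 0,
                               maf_sampler = NULL, seed = 1) {
  stopifnot(n_individuals >= 2, nrow(variant_layout) >= 2,
            ld_decay >= 0, ld_decay < 1)
  assert_cols(variant_layout, c("chrom", "pos_bp", "pos_cm"), "variant_layout")
  for (ch in unique(variant_layout$chrom)) {
    sub <- variant_layout[variant_layout$chrom == ch, ]
    if (is.unsorted(sub$pos_bp, strictly = TRUE) ||
        is.unsorted(sub$pos_cm, strictly = TRUE)) {
      stop_domain("variant_layout: non-increasing positions on ", ch)
    }
  }
  maf_sampler <- maf_sampler %||% function(n) runif(n, 0.01, 0.5)
  m <- nrow(variant_layout)

  with_seed(seed, {
    maf <- maf_sampler(m)
    if (any(!is.finite(maf)) || any(maf <= 0 | maf > 0.5)) {
      stop_domain("maf_sampler returned values outside (0, 0.5]")
    }
    ## adjacent latent correlation per chromosome
    rho <- numeric(m)
    for (ch in unique(variant_layout$chrom)) {
      idx <- which(variant_layout$chrom == ch)
      d_cm <- c(NA, diff(variant_layout$pos_cm[idx]))
      rho[idx] <- ifelse(is.na(d_cm), 0, ld_decay^d_cm)
    }
    thr <- qnorm(maf)
    dos <- matrix(0L, n_individuals, m)
    for (hap in 1:2) {
      x <- rnorm(n_individuals)
      dos[, 1] <- dos[, 1] + (x < thr[1])
      for (j in 2:m) {
        r <- rho[j]
        x <- r * x + sqrt(1 - r^2) * rnorm(n_individuals)
        dos[, j] <- dos[, j] + (x < thr[j])
      }
    }
    vm <- data.frame(variant_id = sprintf("var%06d", seq_len(m)),
                     chrom = variant_layout$chrom,
                     pos_bp = as.integer(variant_layout$pos_bp),
                     pos_cm = variant_layout$pos_cm,
                     allele_ref = "A", allele_alt = "G",
                     maf = maf, stringsAsFactors = FALSE)
    colnames(dos) <- vm$variant_id
    panel <- structure(list(sample_ids = sprintf("id%06d", seq_len(n_individuals)),
                            variant_map = vm, dosages = dos),
                       class = "genotype_panel")
    validate_panel(panel)
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d variants on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$variant_map),
              length(unique(x$variant_map$chrom))))
  invisible(x)
}

#' Specify a causal architecture
#'
#' @param pi1 fraction of variants causal, in \[0, 1\].
#' @param h2 target SNP heritability, in \[0, 1\].
#' @param effect_family "normal" or "t"; `df` required (> 2) for "t".
#' @param df degrees of freedom for the t family.
#' @param placement "uniform" or "clumpy".
#' @param alpha,rho clumpy placement: the per-megabase causal probability is
#'   drawn as P ~ Beta(alpha, alpha/rho). Note that Beta's mean is
#'   rho/(1+rho), approximately rho for small rho.
#' @param maf_floor minimum MAF for causal eligibility.
#' @param inflation_lambda multiplicative chi-square inflation (>= 0).
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(pi1, h2, effect_family = c("normal", "t"),
                              df = NULL, placement = c("uniform", "clumpy"),
                              alpha = NULL, rho = NULL, maf_floor = 0.01,
                              inflation_lambda = 1) {
  effect_family <- match.arg(effect_family)
  placement <- match.arg(placement)
  stopifnot(pi1 >= 0, pi1 <= 1, h2 >= 0, h2 <= 1, inflation_lambda >= 0)
  if (effect_family == "t") {
    if (is.null(df) || df <= 2) stop_domain("t family requires df > 2")
  }
  if (placement == "clumpy") {
    if (is.null(alpha) || alpha <= 0) stop_domain("clumpy placement needs alpha > 0")
    if (is.null(rho) || rho <= 0 || rho >= 1) {
      stop_domain("clumpy placement needs rho in (0, 1)")
    }
  }
  structure(list(pi1 = pi1, h2 = h2, effect_family = effect_family, df = df,
                 placement = placement, alpha = alpha, rho = rho,
                 maf_floor = maf_floor, inflation_lambda = inflation_lambda),
            class = "architecture_spec")
}

## Draw raw (unit-scale) effect values for n causal variants.
draw_effect_values <- function(n, family, df) {
  if (n == 0) return(numeric(0))
  if (family == "normal") rnorm(n)
  else rt(n, df = df) / sqrt(df / (df - 2))   # unit variance
}

## Causal mask over variants given positions; shared by panel and fast path.
draw_causal_mask <- function(spec, chrom, pos_bp, eligible) {
  m <- length(pos_bp)
  mask <- logical(m)
  idx <- which(eligible)
  if (!length(idx)) stop_domain("maf_floor (or region) excludes all variants")
  if (spec$pi1 == 0) return(mask)
  if (spec$placement == "uniform") {
    mask[idx] <- runif(length(idx)) < spec$pi1
  } else {
    ## fixed 1-Mb tiles anchored at position 0 per chromosome
    ## P ~ Beta(alpha, alpha/rho) per tile, applied literally: the expected
    ## causal fraction is rho/(1+rho) (~ rho for small rho); pi1 is ignored
    ## in clumpy mode and rho governs the overall density.
    mb <- paste(chrom[idx], (pos_bp[idx] - 1L) %/% 1000000L)
    tiles <- unique(mb)
    p_mb <- rbeta(length(tiles), spec$alpha, spec$alpha / spec$rho)
    p <- p_mb[match(mb, tiles)]
    mask[idx] <- runif(length(idx)) < p
  }
  mask
}

#' Draw a causal architecture for a genotype panel
#'
#' Selects causal variants (uniformly or with clumpy per-megabase
#' probabilities P ~ Beta(alpha, alpha/rho)) among variants with
#' MAF >= maf_floor, and assigns mean-zero effect values from the chosen
#' family on the standardized-genotype scale. Effects are rescaled to the
#' target heritability by [simulate_phenotype()].
#'
#' @param panel a `genotype_panel`.
#' @param spec an `architecture_spec`.
#' @param seed integer seed.
#' @param region optional data.frame(chrom, start, end) of 0-based half-open
#'   intervals restricting causal eligibility (e.g. core-pathway windows).
#' @return object of class `simulated_trait` with causal_mask and
#'   true_effects (standardized scale, zero where non-causal); phenotype
#'   fields are filled by [simulate_phenotype()].
#' @export
draw_causal_effects <- function(panel, spec, seed = 1, region = NULL) {
  validate_panel(panel)
  stopifnot(inherits(spec, "architecture_spec"))
  vm <- panel$variant_map
  eligible <- vm$maf >= spec$maf_floor
  if (!is.null(region)) {
    assert_cols(region, c("chrom", "start", "end"), "region")
    inreg <- rep(FALSE, nrow(vm))
    for (k in seq_len(nrow(region))) {
      inreg <- inreg | (vm$chrom == region$chrom[k] &
                          point_in_interval(vm$pos_bp, region$start[k],
                                            region$end[k]))
    }
    eligible <- eligible & inreg
  }
  with_seed(seed, {
    mask <- draw_causal_mask(spec, vm$chrom, vm$pos_bp, eligible)
    eff <- numeric(nrow(vm))
    eff[mask] <- draw_effect_values(sum(mask), spec$effect_family, spec$df)
    structure(list(phenotype = NULL, causal_mask = mask, true_effects = eff,
                   realized_h2 = NA_real_, effect_scale = "standardized"),
              class = "simulated_trait")
  })
}

#' Simulate a phenotype from a panel and drawn effects
#'
#' Genetic values are formed on the standardized-dosage scale, effects are
#' rescaled so the theoretical genetic variance (sum of 2*maf*(1-maf)*beta^2
#' on the dosage scale) equals `h2`, Gaussian noise with variance 1 - h2 is
#' added, and the phenotype is standardized to mean 0, variance 1. The
#' returned `true_effects` are on the dosage scale of the standardized
#' phenotype, so sum(2*maf*(1-maf)*beta^2) / var(phenotype) equals the
#' reported `realized_h2` to machine precision.
#'
#' @param panel a `genotype_panel`.
#' @param effects a `simulated_trait` from [draw_causal_effects()].
#' @param h2 target heritability in \[0, 1\].
#' @param seed integer seed for the environmental noise.
#' @return completed `simulated_trait` with phenotype, dosage-scale
#'   true_effects, and realized_h2.
#' @export
simulate_phenotype <- function(panel, effects, h2, seed = 1) {
  validate_panel(panel)
  stopifnot(inherits(effects, "simulated_trait"),
            length(effects$true_effects) == nrow(panel$variant_map),
            h2 >= 0, h2 <= 1)
  if (h2 > 0 && all(effects$true_effects == 0)) {
    stop_domain("all effects are zero but h2 > 0: degenerate signal")
  }
  vm <- panel$variant_map
  n <- length(panel$sample_ids)
  with_seed(seed, {
    b <- effects$true_effects                    # standardized scale
    if (h2 > 0) {
      b <- b * sqrt(h2 / sum(b^2))               # sum of b^2 == h2 exactly
      sdx <- sqrt(2 * vm$maf * (1 - vm$maf))
      causal <- which(b != 0)
      g <- as.vector(panel$dosages[, causal, drop = FALSE] %*%
                       (b[causal] / sdx[causal]))
      g <- g - sum(2 * vm$maf[causal] * b[causal] / sdx[causal]) # center at HWE mean
    } else {
      b[] <- 0
      g <- numeric(n)
    }
    y0 <- g + rnorm(n, sd = sqrt(1 - h2))
    if (h2 == 1) y0 <- g
    s <- sd(y0)
    if (s == 0) stop_domain("degenerate phenotype: zero variance")
    y <- (y0 - mean(y0)) / s
    beta_dosage <- numeric(nrow(vm))
    if (h2 > 0) {
      sdx <- sqrt(2 * vm$maf * (1 - vm$maf))
      beta_dosage <- (b / sdx) / s
    }
    realized <- sum(2 * vm$maf * (1 - vm$maf) * beta_dosage^2)
    structure(list(phenotype = y, causal_mask = effects$causal_mask,
                   true_effects = beta_dosage, realized_h2 = realized,
                   effect_scale = "dosage"),
              class = "simulated_trait")
  })
}
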