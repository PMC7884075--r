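## Block-wise local SNP-heritability, cumulative curves, pathway sums, and
## interval subtraction.

#' Partition a panel into approximately independent LD blocks
#'
#' Places `target_n_blocks - 1` breakpoints at the largest inter-variant
#' genetic-map gaps (ties broken by bp order); chromosome boundaries always
#' separate blocks, and blocks tile each chromosome in 0-based half-open
#' coordinates.
#'
#' @param panel a `genotype_panel` (only the variant map is used); or any
#'   data.frame with chrom, pos_bp, pos_cm.
#' @param target_n_blocks desired number of gap-derived blocks (>= 1);
#'   `1` yields one block per chromosome.
#' @return data.frame of class `ld_block_set` (chrom, start, end, block_id).
#' @export
partition_ld_blocks <- function(panel, target_n_blocks) {
  vm <- if (inherits(panel, "genotype_panel")) panel$variant_map else panel
  assert_cols(vm, c("chrom", "pos_bp", "pos_cm"), "variant map")
  stopifnot(target_n_blocks >= 1)
  if (target_n_blocks > nrow(vm)) {
    stop_domain("target_n_blocks exceeds variant count")
  }
  ## candidate gaps: between adjacent variants within each chromosome
  gaps <- NULL
  for (ch in unique(vm$chrom)) {
    sub <- vm[vm$chrom == ch, ]
    if (nrow(sub) < 2) next
    gcm <- diff(sub$pos_cm)
    mid <- as.integer((head(sub$pos_bp, -1) + tail(sub$pos_bp, -1)) %/% 2)
    gaps <- rbind(gaps, data.frame(chrom = ch, cm = gcm, mid_bp = mid))
  }
  k <- target_n_blocks - 1
  cuts <- if (k > 0 && !is.null(gaps)) {
    gaps[order(-gaps$cm, gaps$chrom, gaps$mid_bp), ][seq_len(min(k, nrow(gaps))), ]
  } else NULL
  out <- NULL
  bid <- 0L
  for (ch in unique(vm$chrom)) {
    sub <- vm[vm$chrom == ch, ]
    chrom_end <- max(sub$pos_bp)           # 1-based last position -> end = pos
    bp_cuts <- sort(cuts$mid_bp[cuts$chrom == ch])
    starts <- c(0L, bp_cuts)
    ends <- c(bp_cuts, as.integer(chrom_end))
    out <- rbind(out, data.frame(chrom = ch, start = as.integer(starts),
                                 end = as.integer(ends),
                                 block_id = bid + seq_along(starts)))
    bid <- bid + length(starts)
  }
  rownames(out) <- NULL
  class(out) <- c("ld_block_set", "data.frame")
  out
}

## assign each variant (1-based point) to its block
assign_blocks <- function(blocks, chrom, pos_bp) {
  out <- rep(NA_integer_, length(pos_bp))
  for (ch in unique(chrom)) {
    b <- blocks[blocks$chrom == ch, ]
    if (!nrow(b)) next
    i <- which(chrom == ch)
    idx <- findInterval(pos_bp[i] - 1L, b$start)
    idx[idx < 1 | (pos_bp[i] - 1L) >= b$end[pmax(idx, 1)]] <- NA
    out[i] <- b$block_id[idx]
  }
  out
}

#' Local SNP-heritability per LD block
#'
#' Summary-statistic quadratic-form estimator per block:
#'   h2_b = (N * betahat' Rq+ betahat - q) / ((N - q) * f_q),
#' where betahat are standardized marginal effects (z / sqrt(N)), Rq+ is the
#' pseudoinverse of the block LD matrix truncated to the top q eigenvalues
#' (components covering 99 percent of LD variance, capped at 50), and f_q is
#' the fraction of LD variance those components explain. Dividing by f_q
#' corrects the downward truncation bias under an isotropic causal prior
#' (without it, signal in discarded eigendirections is lost). Negative
#' estimates are retained, preserving additivity of sums.
#'
#' @param assoc `assoc_result` covering the panel variants.
#' @param block_ld list of LD (correlation) matrices, one per block, aligned
#'   to the assoc variants falling in that block (in position order).
#' @param blocks `ld_block_set`.
#' @param n_individuals GWAS sample size N.
#' @param var_frac eigenvalue-truncation variance fraction (default 0.99).
#' @param max_rank eigenvalue cap per block (default 50).
#' @return data.frame of class `local_h2` (block_id, h2, se, n_snps, rank)
#'   with attribute "total" (the genome-wide sum).
#' @export
local_h2 <- function(assoc, block_ld, blocks, n_individuals,
                     var_frac = 0.99, max_rank = 50) {
  stopifnot(inherits(blocks, "ld_block_set") || is.data.frame(blocks))
  bid <- assign_blocks(blocks, assoc$chrom, assoc$pos_bp)
  N <- n_individuals
  res <- data.frame(block_id = blocks$block_id, h2 = 0, se = Inf,
                    n_snps = 0L, rank = 0L)
  for (r in seq_len(nrow(blocks))) {
    b <- blocks$block_id[r]
    i <- which(bid == b)
    res$n_snps[r] <- length(i)
    if (!length(i)) { res$se[r] <- 0; next }
    R <- block_ld[[r]]
    if (is.null(R) || nrow(R) != length(i)) {
      stop_domain("block_ld[[", r, "]] not aligned to block membership")
    }
    beta <- assoc$t_stat[i] / sqrt(N)
    eg <- eigen(R, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    if (sum(ev) <= 0) { res$se[r] <- Inf; next }   # zero retained rank
    csum <- cumsum(ev) / sum(ev)
    q <- min(which(csum >= var_frac)[1], max_rank, length(ev))
    if (N <= q) stop_domain("n_individuals must exceed block rank")
    f_q <- sum(ev[seq_len(q)]) / sum(ev)
    proj <- crossprod(eg$vectors[, seq_len(q), drop = FALSE], beta)
    quad <- sum(proj^2 / ev[seq_len(q)])
    est <- (N * quad - q) / ((N - q) * f_q)
    res$h2[r] <- est
    res$se[r] <- sqrt(2 * q + 4 * N * max(est, 0)) / ((N - q) * f_q)
    res$rank[r] <- as.integer(q)
  }
  class(res) <- c("local_h2", "data.frame")
  attr(res, "total") <- sum(res$h2)
  res
}

#' Cumulative heritability curve across the genome
#'
#' Blocks ordered by genome position; cumulative bp fraction against
#' cumulative h2 fraction (normalized by the genome-wide total). Negative
#' local estimates are retained, so the curve may dip below the diagonal.
#'
#' @param local `local_h2` table.
#' @param blocks matching `ld_block_set`.
#' @return data.frame (genome_frac, h2_frac) starting at (0, 0) and ending
#'   at (1, 1).
#' @export
cumulative_h2_curve <- function(local, blocks) {
  d <- merge(as.data.frame(blocks), as.data.frame(local), by = "block_id")
  d <- d[order(d$chrom, d$start), ]
  total <- sum(d$h2)
  if (total == 0) stop_domain("zero genome-wide total: cannot normalize")
  len <- d$end - d$start
  data.frame(genome_frac = c(0, cumsum(len) / sum(len)),
             h2_frac = c(0, cumsum(d$h2) / total))
}

#' Pathway heritability by block overlap
#'
#' Sums local estimates over every block containing at least one base of a
#' pathway gene window (binary overlap, exactly the block-sum rule); the
#' fraction is relative to the genome-wide total. Overlapping pathways can
#' double-count genome, so fractions are reported per pathway and never
#' summed across pathways.
#'
#' @param local `local_h2` table.
#' @param blocks `ld_block_set`.
#' @param gene_windows data.frame (chrom, start, end, name) of per-gene
#'   windows from [gene_windows()].
#' @param pathway character vector of gene ids.
#' @return list (pathway_h2, fraction, n_blocks, total) of class
#'   `pathway_h2`.
#' @export
pathway_h2 <- function(local, blocks, gene_windows, pathway) {
  total <- sum(local$h2)
  win <- gene_windows[gene_windows$name %in% pathway, , drop = FALSE]
  if (!nrow(win)) {
    out <- list(pathway_h2 = 0, fraction = 0, n_blocks = 0L, total = total)
    class(out) <- "pathway_h2"
    return(out)
  }
  hit_blocks <- integer(0)
  for (ch in unique(win$chrom)) {
    b <- blocks[blocks$chrom == ch, ]
    w <- win[win$chrom == ch, ]
    if (!nrow(b)) next
    ir_b <- IRanges::IRanges(start = b$start + 1L, end = b$end)
    ir_w <- IRanges::IRanges(start = w$start + 1L, end = w$end)
    ov <- IRanges::findOverlaps(ir_b, ir_w)
    hit_blocks <- c(hit_blocks, b$block_id[unique(S4Vectors::queryHits(ov))])
  }
  hit_blocks <- unique(hit_blocks)
  s <- sum(local$h2[local$block_id %in% hit_blocks])
  frac <- if (total != 0) s / total else NA_real_
  if (is.finite(frac) && (frac < -0.05 || frac > 1.05)) {
    warning("pathway h2 fraction outside [-0.05, 1.05]: noisy local estimates",
            call. = FALSE)
  }
  out <- list(pathway_h2 = s, fraction = frac,
              n_blocks = length(hit_blocks), total = total)
  class(out) <- "pathway_h2"
  out
}

#' @export
print.pathway_h2 <- function(x, ...) {
  cat(sprintf("pathway_h2: %.4f (%.1f%% of genome-wide %.4f) over %d blocks\n",
              x$pathway_h2, 100 * x$fraction, x$total, x$n_blocks))
  invisible(x)
}

#' Subtract one interval set from another
#'
#' Set difference A \\ B on 0-based half-open intervals, per chromosome;
#' output is sorted and non-overlapping, and total length satisfies
#' |A| = |A \\ B| + |A intersect B| exactly.
#'
#' @param intervals_a,intervals_b data.frames (chrom, start, end).
#' @return data.frame (chrom, start, end).
#' @export
subtract_annotation <- function(intervals_a, intervals_b) {
  for (x in list(intervals_a, intervals_b)) {
    assert_cols(x, c("chrom", "start", "end"), "intervals")
    if (nrow(x) && any(x$start >= x$end)) {
      stop_domain("malformed interval: start >= end")
    }
  }
  out <- NULL
  for (ch in unique(intervals_a$chrom)) {
    a <- intervals_a[intervals_a$chrom == ch, ]
    b <- intervals_b[intervals_b$chrom == ch, ]
    ir_a <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    ir_d <- if (nrow(b)) {
      IRanges::setdiff(ir_a, IRanges::IRanges(b$start + 1L, b$end))
    } else ir_a
    if (length(ir_d)) {
      out <- rbind(out, data.frame(chrom = ch,
                                   start = IRanges::start(ir_d) - 1L,
                                   end = IRanges::end(ir_d)))
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}
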