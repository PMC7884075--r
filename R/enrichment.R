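## Lead-SNP definition (greedy clumping + cM merging), gene windows, and
## the three pathway-enrichment procedures: Fisher 2x2, Poisson hit-rate,
## and matched-SNP null sets.

## Normalize an LD lookup to a fast query function(id_a, id_b) -> r2.
## Accepts a symmetric matrix with dimnames, a long data.frame
## (id_a, id_b, r2), or a function.
make_ld_lookup <- function(ld) {
  if (is.function(ld)) return(ld)
  if (is.matrix(ld)) {
    ids <- rownames(ld)
    return(function(a, b) {
      i <- match(a, ids); j <- match(b, ids)
      ifelse(is.na(i) | is.na(j), NA_real_, ld[cbind(i, j)])
    })
  }
  if (is.data.frame(ld)) {
    assert_cols(ld, c("id_a", "id_b", "r2"), "ld table")
    key <- c(paste(ld$id_a, ld$id_b), paste(ld$id_b, ld$id_a))
    val <- c(ld$r2, ld$r2)
    env <- new.env(hash = TRUE, size = length(key))
    for (i in seq_along(key)) assign(key[i], val[i], envir = env)
    return(function(a, b) {
      vapply(paste(a, b), function(k) {
        v <- get0(k, envir = env, ifnotfound = NA_real_); v
      }, 0, USE.NAMES = FALSE)
    })
  }
  stop_domain("unsupported LD lookup type")
}

#' Greedy LD clumping of association results
#'
#' Index variants are processed in ascending p-value among variants with
#' p <= p1 (ties broken by chromosome and position); each not-yet-assigned
#' variant with p <= p2, squared correlation >= r2_min with the index, and
#' within `kb_window` kb joins the index's clump. Indices become lead SNPs.
#' Missing LD for a required pair is treated as r2 = 0 with one summary
#' warning.
#'
#' @param assoc `assoc_result` (a pos_cm column, if present, is carried
#'   through for [merge_leads_cm()]).
#' @param ld LD lookup: symmetric r2 matrix with variant ids as dimnames, a
#'   long data.frame (id_a, id_b, r2), or a function(id_a, id_b).
#' @param p1 index p-value threshold (default 1e-4).
#' @param p2 clump-membership p-value threshold (default 1e-4).
#' @param r2_min LD threshold (default 0.01).
#' @param kb_window maximum distance in kb (default 10000).
#' @return data.frame of class `lead_snp_set` (variant_id, chrom, pos_bp,
#'   pos_cm, p, n_members, members).
#' @export
clump_assoc <- function(assoc, ld, p1 = 1e-4, p2 = 1e-4, r2_min = 0.01,
                        kb_window = 10000) {
  assert_cols(assoc, c("variant_id", "chrom", "pos_bp", "p"), "assoc")
  lookup <- make_ld_lookup(ld)
  d <- as.data.frame(assoc)
  if (!"pos_cm" %in% names(d)) d$pos_cm <- NA_real_
  cand <- d[d$p <= p2, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos_bp), , drop = FALSE]
  assigned <- rep(FALSE, nrow(cand))
  n_missing_ld <- 0L
  leads <- list()
  for (i in seq_len(nrow(cand))) {
    if (assigned[i] || cand$p[i] > p1) next
    assigned[i] <- TRUE
    near <- which(!assigned & cand$chrom == cand$chrom[i] &
                    abs(cand$pos_bp - cand$pos_bp[i]) <= kb_window * 1000)
    memb <- character(0)
    if (length(near)) {
      r2 <- lookup(rep(cand$variant_id[i], length(near)),
                   cand$variant_id[near])
      n_missing_ld <- n_missing_ld + sum(is.na(r2))
      r2[is.na(r2)] <- 0
      take <- near[r2 >= r2_min]
      assigned[take] <- TRUE
      memb <- cand$variant_id[take]
    }
    leads[[length(leads) + 1L]] <-
      data.frame(variant_id = cand$variant_id[i], chrom = cand$chrom[i],
                 pos_bp = cand$pos_bp[i], pos_cm = cand$pos_cm[i],
                 p = cand$p[i], n_members = length(memb),
                 members = paste(memb, collapse = ","),
                 stringsAsFactors = FALSE)
  }
  if (n_missing_ld > 0) {
    warning(n_missing_ld, " variant pair(s) without LD treated as r2 = 0",
            call. = FALSE)
  }
  out <- if (length(leads)) do.call(rbind, leads) else
    data.frame(variant_id = character(0), chrom = character(0),
               pos_bp = integer(0), pos_cm = numeric(0), p = numeric(0),
               n_members = integer(0), members = character(0))
  out <- out[order(out$chrom, out$pos_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lead_snp_set", "data.frame")
  out
}

#' Merge lead SNPs within a genetic-map window
#'
#' Anchor-greedy semantics: the remaining lead with the smallest p-value
#' absorbs every other remaining lead within `window_cm` of it (keeping its
#' own position and p), and the procedure repeats on the remainder. This
#' matches "take the SNP with the minimum p-value across all merged leads"
#' and prevents unbounded chains; `chain = TRUE` instead merges transitively
#' within the window.
#'
#' @param leads `lead_snp_set` with pos_cm.
#' @param window_cm merge window in centimorgan (default 0.1).
#' @param chain use transitive chaining instead of anchor-greedy.
#' @return merged `lead_snp_set`; pairwise separation of the output exceeds
#'   `window_cm` (anchor mode).
#' @export
merge_leads_cm <- function(leads, window_cm = 0.1, chain = FALSE) {
  if (!nrow(leads)) return(leads)
  if (any(is.na(leads$pos_cm))) stop_domain("leads need pos_cm for merging")
  d <- as.data.frame(leads)
  if (chain) {
    d <- d[order(d$chrom, d$pos_cm), ]
    grp <- cumsum(c(1, (d$chrom[-1] != head(d$chrom, -1)) |
                      (diff(d$pos_cm) > window_cm)))
    keep <- unlist(lapply(split(seq_len(nrow(d)), grp), function(i) {
      i[which.min(d$p[i])]
    }))
    out <- d[sort(keep), ]
  } else {
    d <- d[order(d$p, d$chrom, d$pos_bp), ]
    taken <- rep(FALSE, nrow(d))
    keep <- integer(0)
    for (i in seq_len(nrow(d))) {
      if (taken[i]) next
      taken[i] <- TRUE
      keep <- c(keep, i)
      ab <- which(!taken & d$chrom == d$chrom[i] &
                    abs(d$pos_cm - d$pos_cm[i]) <= window_cm)
      taken[ab] <- TRUE
      if (length(ab)) {
        extra <- unlist(strsplit(d$members[ab], ",", fixed = TRUE))
        memb <- unique(c(strsplit(d$members[i], ",", fixed = TRUE)[[1]],
                         d$variant_id[ab], extra))
        memb <- memb[nzchar(memb)]
        d$members[i] <- paste(memb, collapse = ",")
        d$n_members[i] <- length(memb)
      }
    }
    out <- d[keep, ]
    out <- out[order(out$chrom, out$pos_bp), ]
  }
  rownames(out) <- NULL
  class(out) <- c("lead_snp_set", "data.frame")
  out
}

#' Extend gene bodies into flanking windows
#'
#' \[start - flank, end + flank) clipped to \[0, chromosome length).
#'
#' @param genes data.frame (chrom, start, end, gene_id) in 0-based
#'   half-open coordinates.
#' @param flank_bp flank size (default 100000, i.e. 100 kb).
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @return data.frame (chrom, start, end, name).
#' @export
gene_windows <- function(genes, flank_bp = 100000, chrom_sizes) {
  assert_cols(genes, c("chrom", "start", "end", "gene_id"), "genes")
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop_domain("gene on unknown chromosome: ", unknown[1])
  }
  lim <- unname(chrom_sizes[genes$chrom])
  data.frame(chrom = genes$chrom,
             start = as.integer(pmax(0, genes$start - flank_bp)),
             end = as.integer(pmin(lim, genes$end + flank_bp)),
             name = genes$gene_id, stringsAsFactors = FALSE)
}

#' Flag genes with a genome-wide-significant lead SNP in their window
#'
#' A gene is flagged when at least one lead with p < `p_max` falls inside
#' its window (1-based SNP position against 0-based half-open window).
#'
#' @param windows data.frame (chrom, start, end, name) from
#'   [gene_windows()].
#' @param leads `lead_snp_set`.
#' @param p_max lead significance threshold (default 5e-8, strict <).
#' @return named logical vector per gene; attribute "n_hit_genes".
#' @export
genes_near_hits <- function(windows, leads, p_max = 5e-8) {
  sig <- leads[leads$p < p_max, , drop = FALSE]
  hit <- setNames(rep(FALSE, nrow(windows)), windows$name)
  for (k in seq_len(nrow(sig))) {
    inwin <- windows$chrom == sig$chrom[k] &
      point_in_interval(sig$pos_bp[k], windows$start, windows$end)
    hit[inwin] <- TRUE
  }
  attr(hit, "n_hit_genes") <- sum(hit)
  hit
}

## Two-sided Fisher p by the minimum-likelihood rule: sum of hypergeometric
## probabilities of tables no more probable than the observed one (with the
## customary 1e-7 relative tolerance guard against ties lost to rounding).
fisher_p_two_sided <- function(k, K, m, N) {
  support <- max(0, K + m - N):min(K, m)
  probs <- dhyper(support, m, N - m, K)
  p_obs <- dhyper(k, m, N - m, K)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher 2x2 pathway enrichment of hit genes
#'
#' Tabulates genes in/out of the pathway against hit/not (from
#' [genes_near_hits()]) and reports the two-sided exact p (minimum-
#' likelihood rule) and the fold enrichment of hit rates against the
#' non-pathway background, (k/K) / (m_out/N_out).
#'
#' @param hit_indicator named logical vector per gene.
#' @param pathway character vector of gene ids (subset of universe).
#' @param universe character vector of gene ids; defaults to
#'   names(hit_indicator).
#' @return object of class `enrichment_result`.
#' @export
fisher_pathway_enrichment <- function(hit_indicator, pathway,
                                      universe = names(hit_indicator)) {
  if (!length(pathway)) stop_domain("empty pathway: fold undefined")
  if (!all(pathway %in% universe)) {
    stop_domain("pathway contains genes outside the universe")
  }
  hits <- names(hit_indicator)[hit_indicator]
  N <- length(universe)
  K <- length(unique(pathway))
  m <- sum(universe %in% hits)
  k <- sum(unique(pathway) %in% hits)
  m_out <- m - k
  N_out <- N - K
  fold <- if (m_out == 0 && k > 0) Inf
          else if (k == 0) 0
          else (k / K) / (m_out / N_out)
  if (N_out == 0) fold <- 1   # pathway == universe: single possible table
  p <- fisher_p_two_sided(k, K, m, N)
  structure(list(method = "fisher",
                 counts = c(k = k, K = K, m = m, N = N),
                 fold = fold, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result (%s): fold = %.3g, p = %.3g\n",
              x$method, x$fold, x$p))
  invisible(x)
}

merged_mb <- function(windows) {
  tot <- 0
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(w$start + 1L, w$end))
    tot <- tot + sum(IRanges::width(ir))
  }
  tot / 1e6
}

count_leads_in <- function(leads, windows) {
  n <- 0L
  for (k in seq_len(nrow(leads))) {
    w <- windows[windows$chrom == leads$chrom[k], , drop = FALSE]
    if (nrow(w) &&
        any(point_in_interval(leads$pos_bp[k], w$start, w$end))) {
      n <- n + 1L
    }
  }
  n
}

#' Poisson rate comparison of hits per megabase
#'
#' Counts lead SNPs inside merged pathway windows versus merged background
#' windows and compares the two hit/Mb rates with the exact conditional
#' binomial test (hits in pathway ~ Binomial(total hits,
#' Mb_pathway / total Mb) under rate equality).
#'
#' @param leads `lead_snp_set`.
#' @param pathway_windows,background_windows data.frames (chrom, start,
#'   end); total Mb of each must be positive.
#' @return `enrichment_result` with rates, rate ratio and p (1 when no hits
#'   fall in either class).
#' @export
poisson_rate_enrichment <- function(leads, pathway_windows,
                                    background_windows) {
  mb_in <- merged_mb(pathway_windows)
  mb_out <- merged_mb(background_windows)
  if (mb_in <= 0 || mb_out <= 0) stop_domain("zero Mb in a window class")
  k_in <- count_leads_in(leads, pathway_windows)
  k_out <- count_leads_in(leads, background_windows)
  rate_in <- k_in / mb_in
  rate_out <- k_out / mb_out
  ratio <- if (k_in == 0 && k_out == 0) NA_real_
           else if (rate_out == 0) Inf else rate_in / rate_out
  p <- if (k_in + k_out == 0) 1 else
    binom.test(k_in, k_in + k_out, mb_in / (mb_in + mb_out))$p.value
  structure(list(method = "poisson",
                 counts = c(hits_in = k_in, hits_out = k_out,
                            mb_in = mb_in, mb_out = mb_out),
                 fold = if (is.na(ratio)) 1 else ratio,
                 rate_ratio = ratio, p = p),
            class = "enrichment_result")
}

#' Matched null SNP sets for lead variants
#'
#' For each lead, draws a random non-lead variant from the same
#' (MAF decile x LD-score decile x gene-distance decile) cell of the
#' variant table, without replacement within a set; `n_sets` independent
#' sets are returned. Empty cells fall back to the nearest cell by decile
#' distance, with the relaxation count recorded.
#'
#' @param leads `lead_snp_set`.
#' @param variant_table data.frame (variant_id, maf, ldscore, gene_dist)
#'   covering the genome-wide variant pool.
#' @param n_sets number of matched sets.
#' @param seed integer seed.
#' @return list of character vectors (variant ids), one per set, each the
#'   size of the lead set; attribute "n_relaxed" counts fallback draws.
#' @export
matched_null_sets <- function(leads, variant_table, n_sets, seed = 1) {
  assert_cols(variant_table, c("variant_id", "maf", "ldscore", "gene_dist"),
              "variant_table")
  vt <- variant_table
  vt$d_maf <- ntile_stable(vt$maf, 10)
  vt$d_ld <- ntile_stable(vt$ldscore, 10)
  vt$d_gd <- ntile_stable(vt$gene_dist, 10)
  lead_idx <- match(leads$variant_id, vt$variant_id)
  if (anyNA(lead_idx)) stop_domain("leads missing from variant_table")
  pool <- !(vt$variant_id %in% leads$variant_id)
  n_relaxed <- 0L
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(s) {
      used <- rep(FALSE, nrow(vt))
      out <- character(length(lead_idx))
      for (j in seq_along(lead_idx)) {
        li <- lead_idx[j]
        cand <- which(pool & !used & vt$d_maf == vt$d_maf[li] &
                        vt$d_ld == vt$d_ld[li] & vt$d_gd == vt$d_gd[li])
        if (!length(cand)) {
          n_relaxed <<- n_relaxed + 1L
          dist <- abs(vt$d_maf - vt$d_maf[li]) + abs(vt$d_ld - vt$d_ld[li]) +
            abs(vt$d_gd - vt$d_gd[li])
          avail <- which(pool & !used)
          if (!length(avail)) stop_domain("variant pool exhausted")
          cand <- avail[dist[avail] == min(dist[avail])]
        }
        pick <- cand[sample.int(length(cand), 1)]
        used[pick] <- TRUE
        out[j] <- vt$variant_id[pick]
      }
      out
    })
    attr(sets, "n_relaxed") <- n_relaxed
    sets
  })
}
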