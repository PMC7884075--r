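#' Simulate a gene annotation and gene-set collection
#'
#' Places non-overlapping gene intervals on the given chromosomes and
#' assembles gene sets of requested sizes, optionally marking one set as the
#' "core pathway" whose 100-kb windows can be used to plant causal variants
#' via the `region` argument of [draw_causal_effects()].
#'
#' @param n_genes number of genes (>= 1).
#' @param chromosome_lengths named numeric vector of chromosome lengths (bp).
#' @param pathway_sizes integer vector of gene-set sizes (possibly empty).
#' @param gene_length mean gene length in bp (lengths drawn +/- 50%).
#' @param seed integer seed.
#' @return list with `genes` (data.frame chrom, start, end, gene_id in
#'   0-based half-open BED coordinates) and `gene_sets` (named list of
#'   character vectors).
#' @export
simulate_gene_landscape <- function(n_genes, chromosome_lengths,
                                    pathway_sizes = integer(0),
                                    gene_length = 20000, seed = 1) {
  stopifnot(n_genes >= 1, all(chromosome_lengths > 0))
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  }
  if (any(pathway_sizes > n_genes)) {
    stop_domain("pathway size exceeds number of genes")
  }
  with_seed(seed, {
    ## apportion genes to chromosomes proportionally to length
    share <- chromosome_lengths / sum(chromosome_lengths)
    per <- diff(round(cumsum(c(0, share * n_genes))))
    per[length(per)] <- n_genes - sum(per[-length(per)])
    genes <- NULL
    gid <- 0L
    for (ci in seq_along(chromosome_lengths)) {
      ng <- per[ci]
      if (ng == 0) next
      clen <- chromosome_lengths[ci]
      lens <- pmax(1, round(runif(ng, 0.5, 1.5) * gene_length))
      if (sum(lens) > clen) {
        stop_domain("requested gene span exceeds chromosome ",
                    names(chromosome_lengths)[ci])
      }
      gap_total <- clen - sum(lens)
      gaps <- floor(gap_total * diff(sort(c(0, runif(ng), 1))))[seq_len(ng)]
      starts <- cumsum(c(0, head(lens, -1))) + cumsum(gaps)
      genes <- rbind(genes, data.frame(
        chrom = names(chromosome_lengths)[ci],
        start = as.integer(starts), end = as.integer(starts + lens),
        gene_id = sprintf("GENE%05d", gid + seq_len(ng)),
        stringsAsFactors = FALSE))
      gid <- gid + ng
    }
    gene_sets <- list()
    if (length(pathway_sizes)) {
      for (k in seq_along(pathway_sizes)) {
        gene_sets[[sprintf("PATHWAY_%03d", k)]] <-
          sort(sample(genes$gene_id, pathway_sizes[k]))
      }
    }
    list(genes = genes, gene_sets = gene_sets)
  })
}
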