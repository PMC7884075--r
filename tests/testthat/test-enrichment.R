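# Clumping, cM merging, gene windows, and the three enrichment procedures.

test_that("clump_assoc hand-traced greedy behavior", {
  assoc <- data.frame(variant_id = c("A", "B", "C"), chrom = "chr1",
                      pos_bp = c(1e6, 2e6, 3e6),
                      p = c(1e-10, 1e-6, 1e-5))
  ld <- matrix(0.001, 3, 3, dimnames = list(c("A", "B", "C"),
                                            c("A", "B", "C")))
  diag(ld) <- 1
  ld["A", "B"] <- ld["B", "A"] <- 0.5
  cl <- clump_assoc(assoc, ld)
  expect_identical(cl$variant_id, c("A", "C"))
  expect_identical(cl$members[cl$variant_id == "A"], "B")

  ## vacuous and singleton cases
  weak <- assoc; weak$p <- c(0.5, 0.2, 0.9)
  expect_identical(nrow(clump_assoc(weak, ld)), 0L)
  single <- assoc[1, ]
  expect_identical(clump_assoc(single, ld)$variant_id, "A")

  ## missing LD treated as zero with a warning
  ld_part <- data.frame(id_a = "A", id_b = "B", r2 = 0.5)
  expect_warning(cl2 <- clump_assoc(assoc, ld_part), "without LD")
  expect_identical(cl2$variant_id, c("A", "C"))

  ## determinism with tied p: ties broken by position
  tied <- data.frame(variant_id = c("D", "E"), chrom = "chr1",
                     pos_bp = c(2e6, 1e6), p = c(1e-8, 1e-8))
  ld0 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("D", "E"), c("D", "E")))
  cl3 <- clump_assoc(tied, ld0)
  expect_identical(cl3$variant_id[1], "E")
})

test_that("merge_leads_cm anchor-greedy semantics", {
  leads <- data.frame(variant_id = c("x", "y", "z"), chrom = "chr1",
                      pos_bp = c(1L, 2L, 3L), pos_cm = c(0, 0.05, 0.12),
                      p = c(1e-10, 1e-30, 1e-9), n_members = 0L,
                      members = "")
  class(leads) <- c("lead_snp_set", "data.frame")
  m <- merge_leads_cm(leads)
  expect_identical(m$variant_id, "y")   # min-p anchor absorbs both
  expect_identical(m$p, 1e-30)

  ## no-op when all gaps exceed the window
  spread <- leads; spread$pos_cm <- c(0, 0.5, 1.0)
  expect_identical(merge_leads_cm(spread)$variant_id, c("x", "y", "z"))
  ## singleton unchanged
  expect_identical(merge_leads_cm(leads[2, ])$variant_id, "y")

  ## output pairwise separation > window (anchor mode), random cases
  set.seed(60)
  for (r in 1:10) {
    ls <- data.frame(variant_id = paste0("v", 1:20), chrom = "chr1",
                     pos_bp = 1:20, pos_cm = sort(runif(20, 0, 1)),
                     p = 10^-runif(20, 4, 30), n_members = 0L, members = "")
    class(ls) <- c("lead_snp_set", "data.frame")
    mm <- merge_leads_cm(ls, 0.1)
    if (nrow(mm) > 1) expect_gt(min(diff(sort(mm$pos_cm))), 0.1)
  }

  ## chain mode merges transitively
  chain <- data.frame(variant_id = c("a", "b", "c"), chrom = "chr1",
                      pos_bp = 1:3, pos_cm = c(0, 0.09, 0.18),
                      p = c(1e-5, 1e-6, 1e-7), n_members = 0L, members = "")
  class(chain) <- c("lead_snp_set", "data.frame")
  expect_identical(merge_leads_cm(chain, chain = TRUE)$variant_id, "c")
  expect_identical(nrow(merge_leads_cm(chain, chain = FALSE)), 2L)
})

test_that("gene_windows flanks and truncates", {
  genes <- data.frame(chrom = "chr1", start = c(50000L, 500000L),
                      end = c(60000L, 520000L), gene_id = c("g1", "g2"))
  w <- gene_windows(genes, 100000, c(chr1 = 1000000))
  expect_identical(w$start, c(0L, 400000L))
  expect_identical(w$end, c(160000L, 620000L))
  ## zero flank: gene bodies
  w0 <- gene_windows(genes, 0, c(chr1 = 1000000))
  expect_identical(w0$start, genes$start)
  expect_identical(w0$end, genes$end)
  expect_error(gene_windows(data.frame(chrom = "chrX", start = 1L, end = 2L,
                                       gene_id = "g"), 0, c(chr1 = 10)),
               "unknown chromosome")
})

test_that("genes_near_hits respects the half-open boundary convention", {
  windows <- data.frame(chrom = "chr1", start = c(100L, 500L),
                        end = c(200L, 600L), name = c("g1", "g2"))
  mk_leads <- function(pos, p = 1e-10) {
    d <- data.frame(variant_id = paste0("l", seq_along(pos)), chrom = "chr1",
                    pos_bp = pos, pos_cm = 0, p = p, n_members = 0L,
                    members = "")
    class(d) <- c("lead_snp_set", "data.frame"); d
  }
  ## 1-based position 101 occupies 0-based coordinate 100 = window start
  h1 <- genes_near_hits(windows, mk_leads(101L))
  expect_true(h1[["g1"]])
  ## position 201 occupies coordinate 200 = window end -> outside
  h2 <- genes_near_hits(windows, mk_leads(201L))
  expect_false(h2[["g1"]])
  ## below-threshold leads are ignored
  h3 <- genes_near_hits(windows, mk_leads(150L, p = 1e-4))
  expect_false(any(h3))

  ## brute-force 5-gene/3-lead layout
  set.seed(61)
  win5 <- data.frame(chrom = "chr1", start = c(0L, 300L, 600L, 900L, 1200L),
                     end = c(250L, 550L, 850L, 1150L, 1450L),
                     name = paste0("G", 1:5))
  pos <- c(120L, 580L, 1460L)
  got <- genes_near_hits(win5, mk_leads(pos))
  want <- vapply(seq_len(5), function(g) {
    any((pos - 1) >= win5$start[g] & (pos - 1) < win5$end[g])
  }, TRUE)
  expect_identical(as.logical(got), want)
})

test_that("fisher_pathway_enrichment matches enumeration and handles boundaries", {
  ## enumeration oracle for one concrete table: k=4, K=5, m=6, N=15
  hits <- setNames(rep(FALSE, 15), paste0("g", 1:15))
  hits[paste0("g", 1:4)] <- TRUE       # pathway hits (pathway g1..g5)
  hits[paste0("g", 6:7)] <- TRUE       # background hits
  res <- fisher_pathway_enrichment(hits, paste0("g", 1:5))
  supp <- max(0, 5 + 6 - 15):min(5, 6)
  pr <- exp(lchoose(6, supp) + lchoose(9, 5 - supp) - lchoose(15, 5))
  p_or <- sum(pr[pr <= pr[supp == 4] * (1 + 1e-7)])
  expect_equal(res$p, p_or, tolerance = 1e-12)
  expect_equal(res$fold, (4 / 5) / (2 / 10))

  ## all genes hit: single possible table
  all_hit <- setNames(rep(TRUE, 10), paste0("g", 1:10))
  r1 <- fisher_pathway_enrichment(all_hit, paste0("g", 1:5))
  expect_equal(r1$fold, 1)
  expect_equal(r1$p, 1)

  ## zero pathway hits with background hits
  none <- setNames(c(rep(FALSE, 5), rep(TRUE, 5)), paste0("g", 1:10))
  expect_equal(fisher_pathway_enrichment(none, paste0("g", 1:5))$fold, 0)

  expect_error(fisher_pathway_enrichment(all_hit, character(0)), "empty")
  expect_error(fisher_pathway_enrichment(all_hit, "nope"), "outside")
})

test_that("poisson_rate_enrichment equals the conditional binomial oracle", {
  mk_leads <- function(pos) {
    d <- data.frame(variant_id = paste0("l", seq_along(pos)), chrom = "chr1",
                    pos_bp = pos, pos_cm = 0, p = 1e-10, n_members = 0L,
                    members = "")
    class(d) <- c("lead_snp_set", "data.frame"); d
  }
  pw <- data.frame(chrom = "chr1", start = 0L, end = 2000000L)
  bw <- data.frame(chrom = "chr1", start = 10000000L, end = 210000000L)
  pos <- c(as.integer(seq(1e5, 1.9e6, length.out = 10)),
           as.integer(seq(11e6, 209e6, length.out = 100)))
  res <- poisson_rate_enrichment(mk_leads(pos), pw, bw)
  expect_equal(res$rate_ratio, 10)
  expect_equal(res$p, binom.test(10, 110, 2 / 202)$p.value, tolerance = 1e-12)

  ## parity and the no-information convention
  pos_eq <- c(as.integer(seq(1e5, 1.9e6, length.out = 2)),
              as.integer(seq(11e6, 209e6, length.out = 200)))
  res_eq <- poisson_rate_enrichment(mk_leads(pos_eq), pw, bw)
  expect_equal(res_eq$rate_ratio, 1)
  res0 <- poisson_rate_enrichment(mk_leads(5000000L), pw, bw)
  expect_equal(res0$p, 1)

  expect_error(poisson_rate_enrichment(mk_leads(1L), pw[0, ], bw), "zero Mb")
})

test_that("matched_null_sets honors size, exclusion and bin equality", {
  set.seed(62)
  m <- 2000
  vt <- data.frame(variant_id = paste0("v", 1:m), maf = runif(m, 0.01, 0.5),
                   ldscore = rexp(m, 0.2), gene_dist = rexp(m, 1e-5))
  leads <- data.frame(variant_id = paste0("v", sample(m, 15)), chrom = "chr1",
                      pos_bp = 1:15, pos_cm = 0, p = 1e-10, n_members = 0L,
                      members = "")
  class(leads) <- c("lead_snp_set", "data.frame")
  sets <- matched_null_sets(leads, vt, n_sets = 20, seed = 63)
  expect_length(sets, 20)
  expect_true(all(lengths(sets) == 15))
  expect_false(any(unlist(sets) %in% leads$variant_id))

  if (attr(sets, "n_relaxed") == 0) {
    d10 <- function(x) ntile_stable(x, 10)
    vt$d_maf <- d10(vt$maf); vt$d_ld <- d10(vt$ldscore)
    vt$d_gd <- d10(vt$gene_dist)
    li <- match(leads$variant_id, vt$variant_id)
    for (s in sets[1:3]) {
      mi <- match(s, vt$variant_id)
      expect_identical(vt$d_maf[mi], vt$d_maf[li])
      expect_identical(vt$d_ld[mi], vt$d_ld[li])
      expect_identical(vt$d_gd[mi], vt$d_gd[li])
    }
  }
  ## determinism
  sets2 <- matched_null_sets(leads, vt, n_sets = 20, seed = 63)
  expect_identical(sets, sets2)
})

test_that("planted pathway signal is recovered by Fisher enrichment", {
  ## plant all causal variants inside one pathway's windows and check that
  ## the enrichment p-value is extreme for nearly every seed
  chrom_sizes <- c(chr1 = 6e6, chr2 = 6e6)
  land <- simulate_gene_landscape(150, chrom_sizes, c(10, 5),
                                  gene_length = 15000, seed = 104)
  win <- gene_windows(land$genes, 30000, chrom_sizes)
  core <- land$gene_sets[[1]]
  core_win <- win[win$name %in% core, ]

  lay <- variant_layout_grid(4000, n_chrom = 2, bp_step = 3000)
  panel <- simulate_genotypes(1200, lay, ld_decay = 0, seed = 64)
  ps <- vapply(1:20, function(s) {
    eff <- draw_causal_effects(panel, architecture_spec(0.08, 0.7, maf_floor = 0),
                               seed = s, region = core_win)
    tr <- simulate_phenotype(panel, eff, 0.7, seed = s + 100)
    a <- run_gwas(panel, tr$phenotype)
    sig <- a[a$p < 1e-4, , drop = FALSE]
    if (!nrow(sig)) return(1)
    leads <- structure(data.frame(variant_id = sig$variant_id,
                                  chrom = sig$chrom, pos_bp = sig$pos_bp,
                                  pos_cm = sig$pos_cm, p = sig$p,
                                  n_members = 0L, members = ""),
                       class = c("lead_snp_set", "data.frame"))
    hits <- genes_near_hits(win, leads, p_max = 1e-4)
    fisher_pathway_enrichment(hits, core)$p
  }, 0)
  expect_gte(mean(ps < 1e-3), 0.95)
})
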