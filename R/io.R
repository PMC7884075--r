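## File dialects. Association results travel in the plink2 ".glm.linear"
## column layout; LD scores in the ldsc ".l2.ldscore" layout; intervals as
## BED3+name (0-based half-open); gene sets as GMT.

GLM_COLS <- c("#CHROM", "POS", "ID", "REF", "ALT", "A1_FREQ", "OBS_CT",
              "BETA", "SE", "T_STAT", "P")

#' Write association results as plink2-style TSV
#'
#' @param assoc `assoc_result` data.frame.
#' @param path output file.
#' @export
write_assoc <- function(assoc, path) {
  assert_cols(assoc, c("variant_id", "chrom", "pos_bp", "maf", "n_obs",
                       "beta", "se", "t_stat", "p"), "assoc")
  out <- data.table::data.table(
    `#CHROM` = sub("^chr", "", assoc$chrom), POS = assoc$pos_bp,
    ID = assoc$variant_id, REF = "A", ALT = "G",
    A1_FREQ = assoc$maf, OBS_CT = assoc$n_obs, BETA = assoc$beta,
    SE = assoc$se, T_STAT = assoc$t_stat, P = assoc$p)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read association results from plink2-style TSV
#'
#' @param path input file in the `.glm.linear` column dialect.
#' @param info_default INFO value to attach (the dialect carries none).
#' @return `assoc_result` data.frame.
#' @export
read_assoc <- function(path, info_default = NA_real_) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  miss <- setdiff(setdiff(GLM_COLS, "#CHROM"),
                  union(names(dt), "CHROM"))
  if (!("#CHROM" %in% names(dt) || "CHROM" %in% names(dt)) || length(miss)) {
    stop_domain("not a .glm.linear table: missing column(s) ",
                paste(c(if (!any(c("#CHROM", "CHROM") %in% names(dt))) "#CHROM",
                        miss), collapse = ", "))
  }
  chrom_col <- if ("#CHROM" %in% names(dt)) dt[["#CHROM"]] else dt[["CHROM"]]
  out <- data.frame(variant_id = dt$ID,
                    chrom = paste0("chr", sub("^chr", "", chrom_col)),
                    pos_bp = as.integer(dt$POS), maf = dt$A1_FREQ,
                    info = info_default, n_obs = as.integer(dt$OBS_CT),
                    beta = dt$BETA, se = dt$SE, t_stat = dt$T_STAT, p = dt$P,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Write an LD-score table in ldsc `.l2.ldscore` layout
#'
#' @param ldscores data.frame (variant_id, ldscore, maf) plus optional
#'   chrom/pos_bp.
#' @param path output file.
#' @export
write_ldscore <- function(ldscores, path) {
  assert_cols(ldscores, c("variant_id", "ldscore"), "ldscores")
  out <- data.table::data.table(
    CHR = sub("^chr", "", ldscores$chrom %||% ldscores$CHR %||% rep("1", nrow(ldscores))),
    SNP = ldscores$variant_id,
    BP = ldscores$pos_bp %||% seq_len(nrow(ldscores)),
    L2 = ldscores$ldscore)
  if (!is.null(ldscores$maf)) out$MAF <- ldscores$maf
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an LD-score table in ldsc `.l2.ldscore` layout
#'
#' @param path input file with columns CHR, SNP, BP, L2 (MAF optional).
#' @return data.frame (variant_id, ldscore, maf, chrom, pos_bp).
#' @export
read_ldscore <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  assert_cols(dt, c("CHR", "SNP", "BP", "L2"), "ldscore file")
  data.frame(variant_id = dt$SNP, ldscore = dt$L2,
             maf = if ("MAF" %in% names(dt)) dt$MAF else NA_real_,
             chrom = paste0("chr", dt$CHR), pos_bp = as.integer(dt$BP),
             stringsAsFactors = FALSE)
}

#' Read a BED3(+name) interval file
#'
#' Intervals are 0-based half-open. Malformed rows (start >= end or
#' non-numeric coordinates) raise an error naming the line.
#'
#' @param path BED file path.
#' @return data.frame (chrom, start, end\[, name\]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop_domain("BED parse error at line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
  if (length(bad)) {
    stop_domain("BED parse error at line ", bad[1],
                ": start must be a number < end")
  }
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(parts, `[`, "", 4)
  out
}

#' Write intervals as BED3(+name)
#'
#' @param intervals data.frame (chrom, start, end\[, name\]).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  assert_cols(intervals, c("chrom", "start", "end"), "intervals")
  if (any(intervals$start >= intervals$end)) {
    stop_domain("malformed interval: start >= end")
  }
  cols <- c("chrom", "start", "end", if ("name" %in% names(intervals)) "name")
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Duplicate genes within one set are dropped with a warning.
#'
#' @param path GMT file (set name, description, member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop_domain("GMT parse error at line ", i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes deduplicated", f[1]),
              call. = FALSE)
      genes <- unique(genes)
    }
    out[[f[1]]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], description, gene_sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Round-trip validation for the package's file dialects
#'
#' Reads each file, writes it back through the package writer, re-reads, and
#' checks field identity. Dialect is inferred from the extension
#' (.tsv/.linear = association, .ldscore = LD scores, .bed, .gmt).
#'
#' @param paths character vector of files.
#' @return data.frame (path, dialect, ok).
#' @export
io_roundtrips <- function(paths) {
  res <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    tmp <- tempfile(fileext = paste0(".", ext))
    on.exit(unlink(tmp), add = TRUE)
    ok <- switch(ext,
      "bed" = {
        a <- read_bed(p); write_bed(a, tmp); identical(a, read_bed(tmp))
      },
      "gmt" = {
        a <- read_gmt(p); write_gmt(a, tmp); identical(a, read_gmt(tmp))
      },
      "ldscore" = {
        a <- read_ldscore(p); write_ldscore(a, tmp)
        isTRUE(all.equal(a, read_ldscore(tmp), tolerance = 1e-12))
      },
      {
        a <- read_assoc(p); write_assoc(a, tmp)
        isTRUE(all.equal(a, read_assoc(tmp), tolerance = 1e-12))
      })
    data.frame(path = p, dialect = if (ext %in% c("bed", "gmt", "ldscore"))
      ext else "assoc", ok = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
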