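## Orchestration: experiment configuration, the end-to-end synthetic
## architecture report, and a thin command-line dispatcher.

#' Build an experiment configuration
#'
#' A plain list validated and serialized as human-readable JSON; round-trip
#' through [write_config()]/[read_config()] is identity.
#'
#' @param pi1_truth vector of true causal fractions to simulate.
#' @param h2 SNP heritability of the simulated traits.
#' @param n_individuals GWAS sample size.
#' @param n_variants panel size M.
#' @param block_size LD-block size for the fast-path profile.
#' @param n_bins LD-score bins.
#' @param pi1_grid,lambda_grid reference-library grids.
#' @param n_reps library replicates per grid point.
#' @param effect_family,placement,alpha,rho architecture options (see
#'   [architecture_spec()]).
#' @param maf_range folded-MAF filter for binning.
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir report directory (NULL for none).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(pi1_truth = c(0.001, 0.01), h2 = 0.3,
                              n_individuals = 10000, n_variants = 20000,
                              block_size = 100, n_bins = 50,
                              pi1_grid = c(1e-4, 1e-3, 3e-3, 0.01, 0.03),
                              lambda_grid = 1, n_reps = 2,
                              effect_family = "normal",
                              placement = "uniform", alpha = NULL, rho = NULL,
                              maf_range = c(0.01, 0.5), seed = 1,
                              output_dir = NULL) {
  cfg <- list(pi1_truth = pi1_truth, h2 = h2, n_individuals = n_individuals,
              n_variants = n_variants, block_size = block_size,
              n_bins = n_bins, pi1_grid = pi1_grid,
              lambda_grid = lambda_grid, n_reps = n_reps,
              effect_family = effect_family, placement = placement,
              alpha = alpha, rho = rho, maf_range = maf_range, seed = seed,
              output_dir = output_dir)
  stopifnot(all(cfg$pi1_truth >= 0), cfg$h2 >= 0, cfg$h2 <= 1,
            cfg$n_individuals >= 2, cfg$n_variants >= 2, cfg$n_bins >= 2)
  class(cfg) <- "experiment_config"
  cfg
}

#' Write / read an experiment configuration as JSON
#' @param config an `experiment_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, x[!vapply(x, is.null, TRUE)])
}

#' Run the end-to-end synthetic architecture report
#'
#' Builds an LD profile, simulates one trait per true pi1, bins the summary
#' statistics, runs LD-score regression, builds a shared reference library,
#' and estimates pi1 by simulation matching (and the parametric fit). When
#' `output_dir` is set, writes report.json and a pi1 recovery TSV, stamped
#' with the configuration hash and seed.
#'
#' @param config an `experiment_config`.
#' @return list of class `architecture_report`: config hash, per-trait
#'   recovery table, ldsc fits, and the bin curves.
#' @export
run_architecture_report <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  profile <- make_ld_profile(cfg$n_variants, block_size = cfg$block_size,
                             seed = child_seed(cfg$seed, 1))
  ldt <- profile_ldscores(profile)
  lib_spec <- architecture_spec(pi1 = 0.001, h2 = cfg$h2,
                                effect_family = cfg$effect_family,
                                placement = "uniform",
                                df = if (cfg$effect_family == "t") 5 else NULL)
  library <- build_reference_curves(cfg$pi1_grid, cfg$lambda_grid, lib_spec,
                                    profile, cfg$n_individuals,
                                    n_reps = cfg$n_reps,
                                    seed = child_seed(cfg$seed, 2),
                                    n_bins = cfg$n_bins,
                                    maf_range = cfg$maf_range)
  rows <- list(); curves <- list(); ldsc <- list()
  for (i in seq_along(cfg$pi1_truth)) {
    spec <- architecture_spec(pi1 = cfg$pi1_truth[i], h2 = cfg$h2,
                              effect_family = cfg$effect_family,
                              placement = cfg$placement,
                              alpha = cfg$alpha, rho = cfg$rho,
                              df = if (cfg$effect_family == "t") 5 else NULL)
    assoc <- simulate_summary_stats(spec, profile, cfg$n_individuals,
                                    seed = child_seed(cfg$seed, 100 + i))
    bins <- bin_and_summarize(assoc, ldt, n_bins = cfg$n_bins,
                              maf_range = cfg$maf_range)
    reg <- ldsc_regression(assoc, ldt, cfg$n_individuals)
    fit_m <- estimate_pi1_matching(bins, library,
                                   seed = child_seed(cfg$seed, 200 + i))
    fit_p <- tryCatch(estimate_pi1_parametric(bins),
                      error = function(e) NULL)
    rows[[i]] <- data.frame(pi1_true = cfg$pi1_truth[i],
                            pi1_matching = fit_m$pi1_hat,
                            best_lambda = fit_m$best_lambda,
                            pi1_parametric = fit_p$pi1_hat %||% NA_real_,
                            ldsc_intercept = reg$intercept,
                            ldsc_h2 = reg$h2_implied)
    curves[[i]] <- as.data.frame(bins)
    ldsc[[i]] <- reg
  }
  ## hash covers the scientific configuration, not where output lands
  hash_cfg <- unclass(cfg)
  hash_cfg$output_dir <- NULL
  report <- list(config = unclass(cfg), config_hash = content_key(hash_cfg),
                 seed = cfg$seed, recovery = do.call(rbind, rows),
                 ldsc = ldsc, curves = curves)
  class(report) <- "architecture_report"
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(config = unclass(cfg), config_hash = report$config_hash,
           recovery = report$recovery, ldsc = ldsc),
      file.path(cfg$output_dir, "report.json"), digits = NA,
      auto_unbox = TRUE, pretty = TRUE, null = "null")
    data.table::fwrite(report$recovery,
                       file.path(cfg$output_dir, "recovery.tsv"), sep = "\t")
    for (i in seq_along(curves)) {
      data.table::fwrite(curves[[i]],
                         file.path(cfg$output_dir,
                                   sprintf("bins_pi1_%g.tsv", cfg$pi1_truth[i])),
                         sep = "\t")
    }
  }
  report
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("architecture_report (config", x$config_hash, ")\n")
  print(x$recovery)
  invisible(x)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `polyarch` script in `inst/cli`. Subcommands:
#' `report` (run [run_architecture_report()] from a JSON config),
#' `roundtrip` (validate file dialects), `ldscore`, `bins`, `ldsc`,
#' `estimate` operate on files in the package dialects.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
polyarch_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: polyarch <subcommand> [options]",
    "  report    --config cfg.json",
    "  roundtrip <files...>",
    "  ldscore   --assoc x.tsv --ldscore out.l2.ldscore  (from profile TSVs)",
    "  bins      --assoc x.tsv --ldscore l2.tsv --bins N --out bins.tsv",
    "  ldsc      --assoc x.tsv --ldscore l2.tsv --n N", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  positional <- character(0)
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      opts[[substring(rest[i], 3)]] <- rest[i + 1]; i <- i + 2
    } else {
      positional <- c(positional, rest[i]); i <- i + 1
    }
  }
  status <- 0L
  switch(sub,
    report = {
      cfg <- read_config(opts$config)
      rep <- run_architecture_report(cfg)
      print(rep)
    },
    roundtrip = {
      print(io_roundtrips(positional))
    },
    bins = {
      assoc <- read_assoc(opts$assoc)
      ldt <- read_ldscore(opts$ldscore)
      bins <- bin_and_summarize(assoc, ldt,
                                n_bins = as.integer(opts$bins %||% 1000))
      data.table::fwrite(as.data.frame(bins), opts$out %||% "bins.tsv",
                         sep = "\t")
    },
    ldsc = {
      assoc <- read_assoc(opts$assoc)
      ldt <- read_ldscore(opts$ldscore)
      reg <- ldsc_regression(assoc, ldt, as.integer(opts$n))
      cat(jsonlite::toJSON(reg, auto_unbox = TRUE, digits = NA), "\n")
    },
    {
      message("unknown subcommand: ", sub, "\n", usage)
      status <- 1L
    })
  invisible(status)
}
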