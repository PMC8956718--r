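#' Pipeline run configuration
#'
#' Defaults follow the baseline analysis settings: killability ratio
#' ratio 2, kill bounds `lb = 0.8` / `ub = 0.1`, fairness slack
#' `alpha = 0`, 20 replicates of 500 sampled cells, 50 sampled optima.
#'
#' @param cohort an `oncohit_cohort`, or a manifest path readable by
#'   [read_cohort()].
#' @param gene_pool character vector of candidate targets, or a path
#'   readable by [read_gene_pool()]; `NULL` uses the cohort's gene universe.
#' @param r,lb,ub,alpha model parameters (see [killability_params()],
#'   [fair_params()]).
#' @param mode `"ratio"` or `"presence"` killability.
#' @param full_coverage require every tumor cell hit (drops `lb`/`ub`
#'   handling as in [fair_params()]).
#' @param cells,replicates sampling protocol (see [replicate_spec()]).
#' @param num_sol optimal solutions to sample per replicate (0 disables the
#'   multiple-optima analysis).
#' @param min_cell_fraction low-coverage cell filter threshold.
#' @param tissue_tables optional list of two tissue tables for
#'   [filter_by_normal_tissue_expression()].
#' @param tissue_threshold TPM threshold for the tissue filter.
#' @param greedy also run the greedy baseline per patient.
#' @param seed base seed controlling every random draw.
#' @param out_dir output directory.
#' @export
run_config <- function(cohort, gene_pool = NULL, r = 2, lb = 0.8, ub = 0.1,
                       alpha = 0, mode = "ratio", full_coverage = FALSE,
                       cells = 500, replicates = 20, num_sol = 50,
                       min_cell_fraction = 0.10, tissue_tables = NULL,
                       tissue_threshold = NULL, greedy = FALSE, seed = 1,
                       out_dir = "oncohit_run") {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full target-selection pipeline
#'
#' Executes read, cell filtering, gene-pool restriction, per-replicate
#' sampling, incidence construction, per-patient ITS solves, H(i)
#' computation, the fair CTS solve, optional multiple-optima sampling with
#' frequency tables, and replicate summaries. All randomness is controlled
#' by `config$seed`. Per-patient failures are logged with context and do
#' not abort the run; partial results are preserved. Outputs (solution TSV,
#' cohort JSON, frequency TSVs, summary TSV, plain-text log, and a
#' machine-readable run manifest) are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with `its` (per-replicate tidy tibble), `cts`
#'   (per-replicate glance tibble), `summary`, `frequencies`
#'   (a `cooccurrence_report` or `NULL`), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), paste0(...), "\n",
                            file = log_path, append = TRUE)
  cat("", file = log_path)

  coh <- if (inherits(config$cohort, "oncohit_cohort")) config$cohort else
    read_cohort(config$cohort, on_error = "skip")
  pool <- config$gene_pool
  if (is.character(pool) && length(pool) == 1 && file.exists(pool)) {
    pool <- read_gene_pool(pool)
  }
  if (!is.null(config$tissue_tables)) {
    pool <- filter_by_normal_tissue_expression(
      config$tissue_tables[[1]], config$tissue_tables[[2]],
      pool %||% coh$gene_universe, config$tissue_threshold)
    logf("tissue filter retained ", length(pool), " genes")
  }

  # cell filter before any gene-pool reduction
  counts <- list()
  filtered <- lapply(coh$patients, function(p) {
    tum <- tryCatch(filter_low_coverage_cells(p$tumor, config$min_cell_fraction),
                    oncohit_error_empty_sample = function(e) {
                      stop_empty_sample(paste0("patient ", p$patient_id, ": ",
                                               conditionMessage(e)))
                    })
    nt <- p$nontumor
    if (!is.null(nt)) {
      nt <- filter_low_coverage_cells(nt, config$min_cell_fraction)
    }
    counts[[p$patient_id]] <<- c(tumor_removed = ncol(p$tumor) - ncol(tum),
                                 nontumor_removed =
                                   if (is.null(nt)) 0L else ncol(p$nontumor) - ncol(nt))
    patient_sample(p$patient_id, tum, nt)
  })
  coh <- cohort(filtered, gene_pool = NULL)
  pool <- (pool %||% coh$gene_universe)
  pool <- pool[pool %in% coh$gene_universe]
  if (length(pool) == 0) stop_config("gene pool is disjoint from the cohort universe")
  logf("cohort: ", length(coh$patients), " patients, pool of ", length(pool), " genes")

  kparams <- killability_params(r = config$r, mode = config$mode)
  fair <- fair_params(alpha = config$alpha, lb = config$lb, ub = config$ub,
                      full_coverage = config$full_coverage)
  iparams <- fair_its_params(fair)
  spec <- replicate_spec(c = config$cells, n_replicates = config$replicates,
                         seed = config$seed)

  its_rows <- list()
  cts_rows <- list()
  freq_tables <- list()
  for (rep_i in seq_len(spec$n_replicates)) {
    instances <- list()
    for (p in coh$patients) {
      res <- tryCatch({
        samp <- sample_replicate(p, spec, rep_i)
        if (is.null(samp)) NULL else build_incidence(samp, kparams, pool)
      }, error = function(e) {
        logf("replicate ", rep_i, " patient ", p$patient_id, ": ",
             conditionMessage(e))
        NULL
      })
      if (!is.null(res)) instances[[p$patient_id]] <- res
    }
    if (length(instances) == 0) next
    h <- compute_h_values(instances, fair)
    for (inst in instances) {
      r <- solve_its(inst, iparams)
      its_rows[[length(its_rows) + 1]] <-
        dplyr::mutate(tidy(r), replicate = rep_i)
      if (isTRUE(config$greedy)) {
        g <- greedy_its(inst, iparams)
        its_rows[[length(its_rows) + 1]] <-
          dplyr::mutate(tidy(g), replicate = rep_i)
      }
    }
    cts <- solve_fair_cts(instances, fair, h = h)
    cts_rows[[length(cts_rows) + 1]] <- dplyr::mutate(glance(cts), replicate = rep_i)
    if (config$num_sol > 0 && cts$status == "optimal") {
      opt <- enumerate_optima(unname(instances), fair, k_draws = config$num_sol,
                              seed = derive_seed(config$seed, "optima", rep_i))
      freq_tables[[length(freq_tables) + 1]] <- gene_frequencies(opt)
    }
    logf("replicate ", rep_i, ": CTS ", cts$status, " size ", cts$cts_size)
  }
  its_tbl <- dplyr::bind_rows(its_rows)
  cts_tbl <- dplyr::bind_rows(cts_rows)

  exact <- dplyr::filter(its_tbl, .data$method == "branch-and-bound")
  summary <- summarize_replicates(
    dplyr::left_join(exact, dplyr::select(cts_tbl, "replicate", "cts_size"),
                     by = "replicate"))
  freqs <- if (length(freq_tables) > 0) cooccurrence_report(freq_tables) else NULL

  write_solution(its_tbl, file.path(config$out_dir, "its_solutions.tsv"))
  write_solution(cts_tbl, file.path(config$out_dir, "cts_solutions.json"),
                 format = "json")
  readr::write_tsv(summary$per_patient, file.path(config$out_dir, "summary.tsv"),
                   progress = FALSE)
  if (!is.null(freqs)) {
    write_frequency_tables(freqs,
                           file.path(config$out_dir, "gene_frequencies.tsv"),
                           file.path(config$out_dir, "pair_frequencies.tsv"))
  }
  manifest <- list(
    parameters = config[c("r", "lb", "ub", "alpha", "mode", "full_coverage",
                          "cells", "replicates", "num_sol",
                          "min_cell_fraction", "seed")],
    package_version = as.character(utils::packageVersion("oncohit")),
    n_patients = length(coh$patients),
    pool_size = length(pool),
    cells_removed_by_filter = counts,
    replicates_run = length(cts_rows)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done")
  invisible(list(its = its_tbl, cts = cts_tbl, summary = summary,
                 frequencies = freqs, out_dir = config$out_dir))
}
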