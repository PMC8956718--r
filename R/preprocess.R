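#' Remove cells expressing fewer than a fraction of all genes
#'
#' Low-coverage cell filter applied before any gene-pool reduction: a cell
#' is kept iff its number of strictly positive entries is at least
#' `min_fraction` times the number of genes in the matrix (strict
#' "fewer than" removal). Idempotent.
#'
#' @param matrix an expression matrix (genes x cells).
#' @param min_fraction minimum expressed-gene fraction (default 0.10; raise
#'   to 0.20 for lightly filtered data such as blood cancers).
#' @return the filtered expression matrix.
#' @export
filter_low_coverage_cells <- function(matrix, min_fraction = 0.10) {
  if (min_fraction < 0 || min_fraction > 1) stop_config("min_fraction must lie in [0, 1]")
  keep <- colSums(matrix > 0) >= min_fraction * nrow(matrix) - 1e-9
  if (!any(keep)) {
    stop_empty_sample("all cells removed by the low-coverage filter")
  }
  matrix[, keep, drop = FALSE]
}

#' Restrict an expression matrix to a gene pool
#'
#' Keeps the rows in `pool` (in pool order); pool genes absent from the data
#' are reported via the `missing_genes` attribute and a message.
#'
#' @param matrix an expression matrix.
#' @param pool character vector of candidate target genes.
#' @return the restricted matrix with attribute `missing_genes`.
#' @export
restrict_gene_pool <- function(matrix, pool) {
  present <- pool[pool %in% rownames(matrix)]
  missing_genes <- setdiff(pool, present)
  if (length(present) == 0) {
    stop_config("gene pool is disjoint from the data")
  }
  if (length(missing_genes) > 0) {
    message(length(missing_genes), " pool gene(s) absent from the data")
  }
  out <- matrix[present, , drop = FALSE]
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Filter a gene pool by low expression across normal tissues
#'
#' Keeps pool genes whose arithmetic mean TPM across tissues is strictly
#' below `threshold_tpm` in *both* tissue tables (e.g. two independent
#' normal-tissue atlases). Genes absent from either table are excluded
#' (conservative for off-tumor toxicity) and reported via the
#' `excluded_missing` attribute.
#'
#' @param table_a,table_b long-format tissue expression tables: data frames
#'   with columns `gene`, `tissue`, `tpm` (see [read_tissue_table()]).
#' @param pool character vector of candidate genes.
#' @param threshold_tpm positive TPM threshold (e.g. 0.25, 0.5, 1, 2, 5, 10).
#' @return character vector of retained genes (pool order), with attribute
#'   `excluded_missing`. Empty results are allowed, with a warning.
#' @export
filter_by_normal_tissue_expression <- function(table_a, table_b, pool,
                                               threshold_tpm) {
  if (!is.numeric(threshold_tpm) || threshold_tpm <= 0) {
    stop_config("threshold_tpm must be positive")
  }
  gene_means <- function(tbl) {
    tbl |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(mean_tpm = mean(.data$tpm), .groups = "drop")
  }
  ma <- gene_means(table_a)
  mb <- gene_means(table_b)
  in_both <- pool[pool %in% ma$gene & pool %in% mb$gene]
  excluded_missing <- setdiff(pool, in_both)
  low <- in_both[
    ma$mean_tpm[match(in_both, ma$gene)] < threshold_tpm &
      mb$mean_tpm[match(in_both, mb$gene)] < threshold_tpm
  ]
  if (length(low) == 0) warn("tissue-expression filter removed every pool gene")
  attr(low, "excluded_missing") <- excluded_missing
  low
}

#' Replicate sampling specification
#'
#' @param c cells per replicate (m'); default 500.
#' @param n_replicates number of replicates (default 20).
#' @param seed base RNG seed; per-(patient, replicate) streams are derived
#'   by stable hashing so adding patients never perturbs others' draws.
#' @export
replicate_spec <- function(c = 500, n_replicates = 20, seed = 1) {
  if (c < 1 || n_replicates < 1) stop_config("c and n_replicates must be >= 1")
  structure(list(c = as.integer(c), n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "replicate_spec")
}

#' Sample one replicate of a patient's cells
#'
#' Draws `min(c, m)` cells uniformly at random without replacement from the
#' union of the patient's tumor and non-tumor cells, then partitions them
#' back into the two compartments. Deterministic given
#' `(spec$seed, patient_id, replicate_index)`. When `c >= m` all cells are
#' returned unchanged. A replicate with zero tumor cells (or zero non-tumor
#' cells when the patient has a non-tumor compartment) is degenerate:
#' `NULL` is returned with a warning so callers can skip it.
#'
#' @param patient a [patient_sample()].
#' @param spec a [replicate_spec()].
#' @param replicate_index 1-based replicate number.
#' @return a [patient_sample()] or `NULL` for a degenerate replicate.
#' @export
sample_replicate <- function(patient, spec, replicate_index = 1L) {
  m_t <- ncol(patient$tumor)
  m_n <- if (is.null(patient$nontumor)) 0L else ncol(patient$nontumor)
  m <- m_t + m_n
  if (spec$c >= m) return(patient)
  s <- derive_seed(spec$seed, patient$patient_id, replicate_index)
  pick <- withr::with_seed(s, sample.int(m, spec$c, replace = FALSE))
  t_idx <- pick[pick <= m_t]
  n_idx <- pick[pick > m_t] - m_t
  if (length(t_idx) == 0) {
    warn(paste0("replicate ", replicate_index, " of patient ", patient$patient_id,
                " has no tumor cells; skipping"))
    return(NULL)
  }
  if (m_n > 0 && length(n_idx) == 0) {
    warn(paste0("replicate ", replicate_index, " of patient ", patient$patient_id,
                " has no non-tumor cells; skipping"))
    return(NULL)
  }
  patient_sample(
    patient$patient_id,
    patient$tumor[, sort(t_idx), drop = FALSE],
    if (m_n > 0) patient$nontumor[, sort(n_idx), drop = FALSE] else NULL
  )
}

#' Summarize solver results over replicates
#'
#' Arithmetic means (and median/quartiles) of ITS size per patient over
#' feasible replicates, plus the mean CTS size when a `cts_size` column is
#' present. Infeasible replicates are counted separately; a patient (or
#' cohort) with no feasible replicate is marked infeasible.
#'
#' @param results tibble with at least `patient_id`, `status`, `its_size`
#'   (e.g. row-bound [tidy()] outputs of per-replicate solves); a `cts_size`
#'   column triggers the cohort summary.
#' @return list with `per_patient` tibble (mean/median/q25/q75 ITS size,
#'   `n_feasible`, `n_infeasible`, `feasible` flag) and `cohort` tibble
#'   (mean CTS size) when available.
#' @export
summarize_replicates <- function(results) {
  if (nrow(results) == 0) stop_config("no replicate results to summarize")
  per_patient <- results |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_feasible = sum(!is.na(.data$its_size)),
      n_infeasible = sum(is.na(.data$its_size)),
      mean_its = mean(.data$its_size, na.rm = TRUE),
      median_its = median(.data$its_size, na.rm = TRUE),
      q25_its = quantile(.data$its_size, 0.25, na.rm = TRUE, names = FALSE),
      q75_its = quantile(.data$its_size, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(feasible = .data$n_feasible > 0,
                  mean_its = ifelse(.data$feasible, .data$mean_its, NA_real_))
  out <- list(per_patient = per_patient)
  if ("cts_size" %in% names(results)) {
    cts <- results |>
      dplyr::distinct(.data$replicate, .data$cts_size)
    out$cohort <- tibble::tibble(
      mean_cts = mean(cts$cts_size, na.rm = TRUE),
      n_feasible = sum(!is.na(cts$cts_size)),
      n_infeasible = sum(is.na(cts$cts_size))
    )
  }
  out
}
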