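#' Tidy an individual target set result
#'
#' @param x an `its_result`.
#' @param ... unused.
#' @return one-row tibble: `patient_id`, `status`, `selected_genes`
#'   (semicolon-joined), `its_size`, `tumor_kill_frac`,
#'   `nontumor_kill_frac`, `method`.
#' @export
tidy.its_result <- function(x, ...) {
  tibble::tibble(
    patient_id = x$patient_id,
    status = x$status,
    selected_genes = paste(x$selected, collapse = ";"),
    its_size = x$its_size,
    tumor_kill_frac = x$tumor_kill_frac,
    nontumor_kill_frac = x$nontumor_kill_frac,
    method = x$method
  )
}

#' @rdname tidy.its_result
#' @export
glance.its_result <- function(x, ...) tidy(x)

#' Tidy a cohort target set result
#'
#' @param x a `cts_result`.
#' @param ... unused.
#' @return per-patient assignment tibble with the global solution attached
#'   (`cts_genes`, `cts_size`, `status`, `alpha`).
#' @export
tidy.cts_result <- function(x, ...) {
  if (is.null(x$assignments)) {
    return(tibble::tibble(patient_id = character(0)))
  }
  dplyr::mutate(x$assignments,
                status = x$status,
                alpha = x$alpha,
                cts_genes = paste(x$cts, collapse = ";"),
                cts_size = x$cts_size)
}

#' One-row summary of a cohort target set result
#'
#' @param x a `cts_result`.
#' @param ... unused.
#' @export
glance.cts_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    alpha = x$alpha,
    cts_size = x$cts_size,
    cts_genes = paste(x$cts, collapse = ";"),
    max_slack = if (is.null(x$assignments)) NA_integer_ else max(x$assignments$slack),
    mean_its = if (is.null(x$assignments)) NA_real_ else mean(x$assignments$its_size),
    n_patients = if (is.null(x$assignments)) 0L else nrow(x$assignments),
    n_dropped = length(x$dropped_patients),
    method = x$method
  )
}

#' Tidy a frequency table
#'
#' @param x a `frequency_table`.
#' @param ... unused.
#' @return the gene-frequency tibble.
#' @export
tidy.frequency_table <- function(x, ...) x$genes

#' Tidy a single-gene coverage report
#'
#' @param x a `gene_coverage` object.
#' @param ... unused.
#' @export
tidy.gene_coverage <- function(x, ...) x$per_patient

#' @rdname tidy.gene_coverage
#' @export
glance.gene_coverage <- function(x, ...) {
  tibble::tibble(cohort_mean = x$cohort_mean, n_patients = nrow(x$per_patient))
}
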