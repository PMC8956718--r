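#' Gene and gene-pair frequencies over sampled optimal solutions
#'
#' For a list of (sampled) optimal gene sets, the frequency of a gene is the
#' fraction of solutions containing it, and likewise for unordered gene
#' pairs jointly. The sum of gene frequencies equals the mean solution size.
#'
#' @param solutions non-empty list of character vectors (gene sets), e.g.
#'   `enumerate_optima(...)$solutions`.
#' @return list of class `frequency_table`: `genes` tibble
#'   (`gene`, `frequency`), `pairs` tibble (`gene1`, `gene2`, `frequency`,
#'   all unordered pairs over the observed genes incl. zero pairs), and
#'   `n_solutions`.
#' @export
gene_frequencies <- function(solutions) {
  if (inherits(solutions, "optima_sample")) solutions <- solutions$solutions
  if (length(solutions) == 0) stop_config("no solutions supplied")
  n <- length(solutions)
  all_genes <- sort(unique(unlist(solutions)))
  genes <- tibble::tibble(
    gene = all_genes,
    frequency = vapply(all_genes, function(g) {
      mean(vapply(solutions, function(s) g %in% s, logical(1)))
    }, numeric(1), USE.NAMES = FALSE)
  )
  pairs <- if (length(all_genes) >= 2) {
    pr <- combn(all_genes, 2)
    tibble::tibble(
      gene1 = pr[1, ], gene2 = pr[2, ],
      frequency = vapply(seq_len(ncol(pr)), function(j) {
        mean(vapply(solutions, function(s) all(pr[, j] %in% s), logical(1)))
      }, numeric(1))
    )
  } else {
    tibble::tibble(gene1 = character(0), gene2 = character(0),
                   frequency = numeric(0))
  }
  structure(list(genes = genes, pairs = pairs, n_solutions = n),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> over", x$n_solutions, "solutions\n")
  print(dplyr::arrange(x$genes, dplyr::desc(.data$frequency)))
  invisible(x)
}

#' Aggregate gene (co-)occurrence across replicates
#'
#' Given one [gene_frequencies()] table per replicate, reports for each gene
#' the number of replicates whose sampled optima include it at all
#' (maximum = number of replicates), its mean within-replicate frequency,
#' and the analogous aggregation for gene pairs.
#'
#' @param tables list of `frequency_table` objects sharing a gene pool.
#' @return list of class `cooccurrence_report` with `genes` tibble
#'   (`gene`, `replicate_count`, `mean_frequency`), `pairs` tibble
#'   (`gene1`, `gene2`, `replicate_count`, `mean_frequency`), and
#'   `n_replicates`.
#' @export
cooccurrence_report <- function(tables) {
  stopifnot(length(tables) > 0,
            all(vapply(tables, inherits, logical(1), "frequency_table")))
  nrep <- length(tables)
  gene_rows <- purrr::imap_dfr(tables, function(t, i) {
    dplyr::mutate(t$genes, replicate = i)
  })
  genes <- gene_rows |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      replicate_count = sum(.data$frequency > 0),
      mean_frequency = sum(.data$frequency) / nrep,
      .groups = "drop"
    )
  pair_rows <- purrr::imap_dfr(tables, function(t, i) {
    dplyr::mutate(t$pairs, replicate = i)
  })
  pairs <- pair_rows |>
    dplyr::group_by(.data$gene1, .data$gene2) |>
    dplyr::summarise(
      replicate_count = sum(.data$frequency > 0),
      mean_frequency = sum(.data$frequency) / nrep,
      .groups = "drop"
    )
  structure(list(genes = genes, pairs = pairs, n_replicates = nrep),
            class = "cooccurrence_report")
}

#' @export
print.cooccurrence_report <- function(x, ...) {
  cat("<cooccurrence_report> over", x$n_replicates, "replicates\n")
  print(dplyr::arrange(x$genes, dplyr::desc(.data$replicate_count)))
  invisible(x)
}

#' Write frequency / co-occurrence tables as TSV
#'
#' Writes a gene table (`gene`, `frequency` or `replicate_count`) and a pair
#' table (`gene1`, `gene2`, ...) suitable as input to circular co-occurrence
#' plotting tools.
#'
#' @param x a `frequency_table` or `cooccurrence_report`.
#' @param gene_path,pair_path output paths.
#' @export
write_frequency_tables <- function(x, gene_path, pair_path) {
  readr::write_tsv(x$genes, gene_path, progress = FALSE)
  readr::write_tsv(x$pairs, pair_path, progress = FALSE)
  invisible(c(gene_path, pair_path))
}
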