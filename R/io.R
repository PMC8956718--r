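#' Read an expression matrix from disk
#'
#' Two plain-text formats are supported. `dense_tsv`: tab-separated, first
#' column gene symbols, header row of cell identifiers.
#' `matrix_market_triplet`: a standard coordinate `.mtx` file plus side
#' files listing gene symbols and cell identifiers, one per line. Duplicate
#' gene rows collapse to the row with the larger total (with a message).
#'
#' @param path path to the dense TSV or `.mtx` file.
#' @param format `"dense_tsv"` or `"matrix_market_triplet"`.
#' @param genes_path,cells_path side files for the sparse format; default to
#'   `genes.txt` / `barcodes.txt` next to the `.mtx` file.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("dense_tsv", "matrix_market_triplet"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
    ct <- do.call(readr::cols, c(
      stats::setNames(list(readr::col_character()), hdr[1]),
      list(.default = readr::col_double())
    ))
    df <- readr::read_tsv(path, col_types = ct, progress = FALSE)
    genes <- df[[1]]
    vals <- as.matrix(df[, -1, drop = FALSE])
    cells <- colnames(df)[-1]
  } else {
    dir <- dirname(path)
    genes_path <- genes_path %||% file.path(dir, "genes.txt")
    cells_path <- cells_path %||% file.path(dir, "barcodes.txt")
    sm <- Matrix::readMM(path)
    genes <- readr::read_lines(genes_path, progress = FALSE)
    cells <- readr::read_lines(cells_path, progress = FALSE)
    if (nrow(sm) != length(genes) || ncol(sm) != length(cells)) {
      stop_format("matrix dimensions do not match the gene/cell side files")
    }
    vals <- as.matrix(sm)
  }
  if (anyNA(vals)) stop_format("non-numeric expression values in file")
  if (any(vals < 0)) stop_format("negative expression values in file")
  rownames(vals) <- genes
  colnames(vals) <- cells
  if (anyDuplicated(genes)) {
    message("collapsing duplicate gene rows (keeping the larger total)")
    tot <- rowSums(vals)
    keep <- vapply(split(seq_along(genes), genes),
                   function(ix) ix[which.max(tot[ix])], integer(1))
    vals <- vals[sort(unname(keep)), , drop = FALSE]
  }
  expression_matrix(vals)
}

#' Write an expression matrix as dense TSV
#'
#' Inverse of [read_expression()] for the dense format: first column `gene`,
#' one column per cell. A write-then-read round trip reproduces the values.
#'
#' @param matrix an expression matrix.
#' @param path output path.
#' @export
write_expression <- function(matrix, path) {
  df <- tibble::as_tibble(matrix, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a gene pool (one symbol per line)
#'
#' Lines starting with `#` are comments; symbols are whitespace-stripped and
#' matched case-sensitively. Order is preserved; duplicates are dropped with
#' a warning.
#'
#' @param path path to the list file.
#' @param name pool name (defaults to the file name).
#' @return character vector of unique gene symbols with attribute `pool_name`.
#' @export
read_gene_pool <- function(path, name = basename(path)) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_config(paste0("empty gene pool file: ", path))
  if (anyDuplicated(lines)) {
    warn(paste0("dropping ", sum(duplicated(lines)), " duplicate gene symbol(s)"))
    lines <- lines[!duplicated(lines)]
  }
  structure(lines, pool_name = name)
}

#' Read a long-format tissue expression table
#'
#' Expects tab-separated columns `gene`, `tissue`, `tpm` (mean TPM of the
#' gene in the tissue).
#'
#' @param path path to the TSV file.
#' @return tibble with columns `gene`, `tissue`, `tpm`.
#' @export
read_tissue_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(tbl) <- c("gene", "tissue", "tpm")
  if (any(tbl$tpm < 0)) stop_format("negative TPM values in tissue table")
  tbl
}

#' Read a cohort from a manifest
#'
#' The manifest is a TSV with columns `patient_id`, `tumor_path`,
#' `nontumor_path` (empty non-tumor path = tumor-only patient); one tumor
#' file and one non-tumor file per patient. Relative paths resolve against
#' the manifest's directory.
#'
#' @param path manifest path.
#' @param format expression file format passed to [read_expression()].
#' @param on_error `"stop"` aborts on the first unreadable patient;
#'   `"skip"` warns with the patient's id and processes the others.
#' @return an `oncohit_cohort`.
#' @export
read_cohort <- function(path, format = "dense_tsv", on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  man <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  if (!all(c("patient_id", "tumor_path", "nontumor_path") %in% names(man))) {
    stop_format("manifest needs columns patient_id, tumor_path, nontumor_path")
  }
  dir <- dirname(path)
  resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(dir, p))
  patients <- purrr::pmap(man, function(patient_id, tumor_path, nontumor_path) {
    read_one <- function() {
      nt <- if (is.na(nontumor_path) || !nzchar(nontumor_path)) NULL else
        read_expression(resolve(nontumor_path), format)
      patient_sample(patient_id, read_expression(resolve(tumor_path), format), nt)
    }
    if (on_error == "stop") return(read_one())
    tryCatch(read_one(), error = function(e) {
      warn(paste0("patient ", patient_id, ": ", conditionMessage(e), "; skipping"))
      NULL
    })
  })
  patients <- purrr::compact(patients)
  if (length(patients) == 0) stop_config("no readable patients in manifest")
  cohort(patients)
}

#' Write a cohort to per-patient dense TSV files plus a manifest
#'
#' @param x an `oncohit_cohort`.
#' @param dir output directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(x$patients, function(p) {
    tf <- paste0(p$patient_id, "_tumor.tsv")
    write_expression(p$tumor, file.path(dir, tf))
    nf <- ""
    if (!is.null(p$nontumor)) {
      nf <- paste0(p$patient_id, "_nontumor.tsv")
      write_expression(p$nontumor, file.path(dir, nf))
    }
    tibble::tibble(patient_id = p$patient_id, tumor_path = tf, nontumor_path = nf)
  })
  manifest <- file.path(dir, "manifest.tsv")
  readr::write_tsv(rows, manifest, progress = FALSE)
  invisible(manifest)
}

#' Write solver results to disk
#'
#' TSV output has one row per solve with columns `patient_id`, `replicate`,
#' `selected_genes` (semicolon-joined), `its_size`, `tumor_kill_frac`,
#' `nontumor_kill_frac`, `status`. JSON output mirrors the full result
#' object (used for cohort results).
#'
#' @param x an `its_result`, `cts_result`, or a tibble of tidied results.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_solution <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  tbl <- if (inherits(x, c("its_result", "cts_result"))) tidy(x) else tibble::as_tibble(x)
  if (!"replicate" %in% names(tbl)) tbl$replicate <- 1L
  if ("genes" %in% names(tbl) && !"selected_genes" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, selected_genes = "genes")
  }
  cols <- c("patient_id", "replicate", "selected_genes", "its_size",
            "tumor_kill_frac", "nontumor_kill_frac", "status")
  tbl <- tbl[, intersect(cols, names(tbl)), drop = FALSE]
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

# strip classes so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    if (!is.data.frame(x)) x <- unclass(x)
  }
  if (!is.null(attr(x, "class")) && !is.data.frame(x)) attr(x, "class") <- NULL
  x
}
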