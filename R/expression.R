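#' Construct a validated gene-by-cell expression matrix
#'
#' Expression values are taken as provided (counts, TPM, or normalized
#' units); no library-size normalization is applied. Rows are genes, columns
#' are cells. Values must be non-negative and identifiers unique.
#'
#' @param values numeric matrix, rows = genes, columns = cells.
#' @param gene_ids character vector of gene symbols (defaults to rownames).
#' @param cell_ids character vector of cell identifiers (defaults to colnames).
#' @return the matrix with validated dimnames.
#' @examples
#' m <- expression_matrix(matrix(c(0, 2, 4, 1, 0, 3), nrow = 2),
#'                        gene_ids = c("EGFR", "MET"),
#'                        cell_ids = c("c1", "c2", "c3"))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop_format("expression matrix needs gene and cell identifiers")
  }
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop_format("dimensions of values do not match gene/cell identifiers")
  }
  if (anyDuplicated(gene_ids)) stop_format("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop_format("duplicate cell identifiers")
  if (!is.numeric(values) || anyNA(values)) {
    stop_format("expression values must be numeric and non-missing")
  }
  if (any(values < 0)) stop_format("expression values must be non-negative")
  dimnames(values) <- list(as.character(gene_ids), as.character(cell_ids))
  values
}

#' Bundle a patient's tumor and non-tumor expression matrices
#'
#' @param patient_id patient identifier.
#' @param tumor expression matrix of the patient's tumor cells.
#' @param nontumor optional expression matrix of non-tumor cells from the
#'   same patient's tumor microenvironment, over the same ordered gene set.
#' @return an object of class `patient_sample`.
#' @export
patient_sample <- function(patient_id, tumor, nontumor = NULL) {
  tumor <- expression_matrix(tumor)
  if (ncol(tumor) < 1) stop_format("tumor matrix must contain at least one cell")
  if (!is.null(nontumor)) {
    nontumor <- expression_matrix(nontumor)
    if (!identical(rownames(tumor), rownames(nontumor))) {
      stop_format("tumor and non-tumor matrices must share an identical ordered gene set")
    }
  }
  structure(
    list(patient_id = as.character(patient_id), tumor = tumor, nontumor = nontumor),
    class = "patient_sample"
  )
}

#' @export
print.patient_sample <- function(x, ...) {
  cat("<patient_sample>", x$patient_id, "-", nrow(x$tumor), "genes,",
      ncol(x$tumor), "tumor cells,",
      if (is.null(x$nontumor)) 0L else ncol(x$nontumor), "non-tumor cells\n")
  invisible(x)
}

#' Assemble a cohort of patient samples over a harmonized gene universe
#'
#' The gene universe is the intersection of all per-patient gene sets,
#' further intersected with `gene_pool` when supplied (kept in pool order).
#' Each patient's matrices are restricted to the universe.
#'
#' @param patients list of [patient_sample()] objects.
#' @param gene_pool optional character vector restricting the universe.
#' @return an object of class `oncohit_cohort` with elements `patients` and
#'   `gene_universe`.
#' @export
cohort <- function(patients, gene_pool = NULL) {
  if (length(patients) < 1) stop_config("a cohort needs at least one patient")
  stopifnot(all(vapply(patients, inherits, logical(1), "patient_sample")))
  universe <- Reduce(intersect, lapply(patients, function(p) rownames(p$tumor)))
  if (!is.null(gene_pool)) universe <- gene_pool[gene_pool %in% universe]
  if (length(universe) == 0) stop_config("empty gene universe after intersection")
  patients <- lapply(patients, function(p) {
    patient_sample(
      p$patient_id,
      p$tumor[universe, , drop = FALSE],
      if (is.null(p$nontumor)) NULL else p$nontumor[universe, , drop = FALSE]
    )
  })
  names(patients) <- vapply(patients, function(p) p$patient_id, character(1))
  structure(list(patients = patients, gene_universe = universe),
            class = "oncohit_cohort")
}

#' @export
print.oncohit_cohort <- function(x, ...) {
  cat("<oncohit_cohort>", length(x$patients), "patients,",
      length(x$gene_universe), "genes in universe\n")
  invisible(x)
}

#' Killability parameters
#'
#' In `ratio` mode a gene can kill a cell when the cell's expression is both
#' strictly positive and at least `r` times the gene's reference expression
#' (mean of non-zero values in the patient's non-tumor cells). In `presence`
#' mode any strictly positive expression suffices.
#'
#' @param r expression-ratio threshold factor (> 0); baseline 2.
#' @param mode `"ratio"` or `"presence"`.
#' @export
killability_params <- function(r = 2, mode = c("ratio", "presence")) {
  mode <- match.arg(mode)
  if (!is.numeric(r) || length(r) != 1 || r <= 0) stop_config("r must be a positive number")
  structure(list(r = r, mode = mode), class = "killability_params")
}

#' Reference expression of a gene in non-tumor cells
#'
#' The arithmetic mean of the strictly positive entries of the gene's row;
#' zeros are ignored as likely dropouts. Returns 0 for an all-zero row (such
#' a gene is then treated as killing exactly the cells that express it).
#'
#' @param nontumor expression matrix of non-tumor cells.
#' @param gene gene symbol.
#' @return non-negative scalar.
#' @examples
#' m <- expression_matrix(matrix(c(0, 2, 4), nrow = 1),
#'                        gene_ids = "EGFR", cell_ids = c("c1", "c2", "c3"))
#' reference_expression(m, "EGFR")  # 3
#' @export
reference_expression <- function(nontumor, gene) {
  if (!gene %in% rownames(nontumor)) {
    stop_gene(paste0("unknown gene symbol: ", gene))
  }
  row <- nontumor[gene, ]
  pos <- row[row > 0]
  if (length(pos) == 0) return(0)
  mean(pos)
}

# vectorized over all genes; returns named vector of E(g)
reference_expression_all <- function(nontumor) {
  pos <- nontumor > 0
  n_pos <- rowSums(pos)
  tot <- rowSums(nontumor)
  e <- ifelse(n_pos > 0, tot / pmax(n_pos, 1), 0)
  names(e) <- rownames(nontumor)
  e
}

#' Build a hitting-set incidence instance for one patient
#'
#' For every cell the set of pool genes that can kill it is computed under
#' the killability rule. In ratio mode gene `g` is in cell `C`'s set iff
#' `E(g,C) > 0` and `E(g,C) >= r * E(g)` with `E(g)` the patient's non-tumor
#' reference expression (threshold comparison inclusive); in presence mode
#' iff `E(g,C) > 0`. Sets are computed for tumor and non-tumor cells alike.
#'
#' @param patient a [patient_sample()].
#' @param params [killability_params()].
#' @param gene_pool character vector of candidate target genes; must be a
#'   subset of the patient's gene universe.
#' @return an object of class `incidence` holding per-cell killability as
#'   logical gene-by-cell matrices (`tumor_hits`, `nontumor_hits`), the gene
#'   pool, and the patient id. Use [incidence_sets()] for the per-cell sets.
#' @export
build_incidence <- function(patient, params = killability_params(), gene_pool) {
  stopifnot(inherits(patient, "patient_sample"))
  if (length(gene_pool) == 0) stop_config("empty gene pool")
  missing_genes <- setdiff(gene_pool, rownames(patient$tumor))
  if (length(missing_genes) > 0) {
    stop_gene(paste0("gene pool members absent from patient ", patient$patient_id,
                     ": ", paste(head(missing_genes, 5), collapse = ", ")))
  }
  has_nt <- !is.null(patient$nontumor) && ncol(patient$nontumor) > 0
  if (params$mode == "ratio" && !has_nt) {
    stop_mode("ratio mode requires non-tumor cells for the reference expression")
  }
  tum <- patient$tumor[gene_pool, , drop = FALSE]
  nt <- if (has_nt) patient$nontumor[gene_pool, , drop = FALSE] else
    matrix(0, nrow = length(gene_pool), ncol = 0,
           dimnames = list(gene_pool, NULL))
  if (params$mode == "presence") {
    thr <- rep(0, length(gene_pool))
  } else {
    eg <- reference_expression_all(nt)
    thr <- params$r * eg
  }
  # kill iff expression > 0 AND expression >= threshold (the strict
  # positivity guard makes all-zero reference genes target only expressing cells)
  hit <- function(m) (m > 0) & (m >= thr)
  structure(
    list(patient_id = patient$patient_id,
         gene_pool = gene_pool,
         tumor_hits = hit(tum),
         nontumor_hits = hit(nt)),
    class = "incidence"
  )
}

#' @export
print.incidence <- function(x, ...) {
  cat("<incidence>", x$patient_id, "-", length(x$gene_pool), "pool genes,",
      ncol(x$tumor_hits), "tumor cells,", ncol(x$nontumor_hits),
      "non-tumor cells\n")
  invisible(x)
}

#' Per-cell killability sets of an incidence instance
#'
#' @param instance an [build_incidence()] result.
#' @param compartment `"tumor"` or `"nontumor"`.
#' @return named list: for each cell, the character vector of pool genes
#'   that can kill it.
#' @export
incidence_sets <- function(instance, compartment = c("tumor", "nontumor")) {
  compartment <- match.arg(compartment)
  m <- if (compartment == "tumor") instance$tumor_hits else instance$nontumor_hits
  lapply(seq_len(ncol(m)), function(j) instance$gene_pool[m[, j]]) |>
    stats::setNames(colnames(m))
}

#' Realized kill fractions of a gene selection
#'
#' Direct simulation of a selection against an incidence instance: the
#' fraction of tumor (resp. non-tumor) cells whose killability set
#' intersects the selection. Used to verify solver outputs.
#'
#' @param instance an incidence instance.
#' @param selected character vector of selected genes (subset of the pool).
#' @return one-row tibble with `tumor_kill_frac` and `nontumor_kill_frac`
#'   (0 when there are no non-tumor cells).
#' @export
kill_report <- function(instance, selected) {
  extra <- setdiff(selected, instance$gene_pool)
  if (length(extra) > 0) {
    stop_gene(paste0("selected genes outside the pool: ",
                     paste(extra, collapse = ", ")))
  }
  frac <- function(m) {
    if (ncol(m) == 0) return(0)
    if (length(selected) == 0) return(0)
    mean(colSums(m[selected, , drop = FALSE]) > 0)
  }
  tibble::tibble(tumor_kill_frac = frac(instance$tumor_hits),
                 nontumor_kill_frac = frac(instance$nontumor_hits))
}

#' Fraction of tumor cells a single gene can kill, per patient
#'
#' For each patient, the fraction of tumor cells killed by targeting `gene`
#' alone under `params`; in presence mode this is the fraction of tumor
#' cells with any expression of the gene. Also reports the unweighted mean
#' across patients.
#'
#' @param x an `oncohit_cohort`, a list of incidence instances, or a single
#'   incidence instance.
#' @param gene gene symbol.
#' @param params [killability_params()] (used when `x` holds expression data).
#' @return list of class `gene_coverage`: `per_patient` tibble
#'   (`patient_id`, `fraction`) and `cohort_mean`.
#' @export
single_gene_coverage <- function(x, gene, params = killability_params()) {
  instances <- if (inherits(x, "incidence")) {
    list(x)
  } else if (inherits(x, "oncohit_cohort")) {
    if (!gene %in% x$gene_universe) stop_gene(paste0("gene not in universe: ", gene))
    lapply(x$patients, build_incidence, params = params, gene_pool = x$gene_universe)
  } else {
    x
  }
  per <- purrr::map_dfr(instances, function(inst) {
    if (!gene %in% inst$gene_pool) stop_gene(paste0("gene not in pool: ", gene))
    tibble::tibble(patient_id = inst$patient_id,
                   fraction = kill_report(inst, gene)$tumor_kill_frac)
  })
  structure(list(per_patient = per, cohort_mean = mean(per$fraction)),
            class = "gene_coverage")
}

#' @export
print.gene_coverage <- function(x, ...) {
  print(x$per_patient)
  cat("cohort mean:", format(x$cohort_mean, digits = 4), "\n")
  invisible(x)
}
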