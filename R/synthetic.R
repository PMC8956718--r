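#' Three-patient demonstration cohort
#'
#' Builds the small worked example used throughout the documentation: three
#' patients with two tumor cells each over the genes
#' `{APP, MET, Target1, Target2, Target3}`. Patient `i`'s first tumor cell
#' is killable by `{APP, Target i}` and the second by `{MET, Target i}`;
#' non-tumor cells express none of the five target genes (a ubiquitous
#' housekeeping gene keeps cells above the low-coverage filter but is not in
#' the pool). The incidence is identical under presence mode and ratio mode
#' at ratio 2. Each patient's optimal ITS has size 1 (their private
#' `Target i`), so the fair cohort solution is `{Target1,Target2,Target3}`
#' (size 3) at `alpha = 0` and `{APP, MET}` (size 2) at `alpha = 1`.
#'
#' @param mode killability mode used to build the shipped incidence.
#' @return list with `cohort`, `instances` (per-patient incidence over the
#'   five-gene pool), and `gene_pool`.
#' @export
make_demo_cohort <- function(mode = c("ratio", "presence")) {
  mode <- match.arg(mode)
  targets <- c("APP", "MET", "Target1", "Target2", "Target3")
  genes <- c(targets, "ACTB")
  patients <- lapply(1:3, function(i) {
    tum <- matrix(0, nrow = 6, ncol = 2,
                  dimnames = list(genes, paste0("P", i, "_t", 1:2)))
    tum["APP", 1] <- 10
    tum["MET", 2] <- 10
    tum[paste0("Target", i), ] <- 10
    tum["ACTB", ] <- 5
    nt <- matrix(0, nrow = 6, ncol = 2,
                 dimnames = list(genes, paste0("P", i, "_n", 1:2)))
    nt["ACTB", ] <- 5
    patient_sample(paste0("patient", i), tum, nt)
  })
  coh <- cohort(patients)
  params <- killability_params(r = 2, mode = mode)
  instances <- lapply(coh$patients, build_incidence, params = params,
                      gene_pool = targets)
  list(cohort = coh, instances = unname(instances), gene_pool = targets)
}

#' Specification for a planted synthetic cohort
#'
#' Describes a cohort with a known ground-truth cohort target set: `k_star`
#' planted genes, each tumor cell assigned one of them (round-robin) and
#' expressing it at `rho` times the gene's non-zero background mean.
#' Background expression is log-normal with per-gene scale spread and
#' independent dropout zeroing, emulating the non-negative, zero-inflated
#' look of single-cell counts without claiming a specific noise model.
#'
#' @param n_patients number of patients (default 5).
#' @param n_genes genes in the universe (default 100).
#' @param n_tumor,n_nontumor cells per patient and compartment (default
#'   150 + 150 = 300 cells per patient).
#' @param k_star planted cohort target set size (default 4).
#' @param rho overexpression ratio of planted genes in their assigned tumor
#'   cells, relative to the gene's non-zero background mean (default 4).
#' @param dropout probability of independently zeroing a background entry
#'   (default 0.3).
#' @param meanlog,sdlog log-normal background parameters (defaults 0, 0.3;
#'   the narrow spread keeps non-planted genes weak decoys).
#' @param scale_spread sd of the per-gene log-scale factor (default 0.25).
#' @param seed RNG seed.
#' @export
plant_spec <- function(n_patients = 5, n_genes = 100, n_tumor = 150,
                       n_nontumor = 150, k_star = 4, rho = 4, dropout = 0.3,
                       meanlog = 0, sdlog = 0.3, scale_spread = 0.25,
                       seed = 1) {
  if (k_star > n_genes) stop_config("k_star cannot exceed n_genes")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must lie in [0, 1)")
  if (rho <= 0) stop_config("rho must be positive")
  structure(as.list(environment()), class = "plant_spec")
}

#' Generate a synthetic cohort with a planted cohort target set
#'
#' Draws log-normal background expression for every gene and cell, applies
#' dropout, then plants `k_star` genes: each tumor cell is assigned one
#' planted gene (round-robin within each patient, so each planted gene
#' covers about `1/k_star` of every patient's tumor cells) and expresses it
#' at `rho` times that gene's expected non-zero background mean. The
#' planted set is therefore feasible at the baseline killability ratio
#' whenever `rho >= 2 r`, and no strict subset reaches a 0.8 coverage
#' target when `k_star = 4`. Deterministic given `spec$seed`.
#'
#' @param spec a [plant_spec()].
#' @return list with `cohort` and `truth` (planted genes, per-cell
#'   assignments, per-gene expected non-zero background mean).
#' @export
generate_planted_cohort <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "plant_spec"))
  withr::with_seed(spec$seed, {
    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    planted <- sample(genes, spec$k_star)
    scale <- exp(rnorm(spec$n_genes, 0, spec$scale_spread))
    names(scale) <- genes
    # expected mean of the non-zero background values per gene
    e_bg <- scale * exp(spec$meanlog + spec$sdlog^2 / 2)
    names(e_bg) <- genes
    draw <- function(ncell, prefix) {
      v <- matrix(rlnorm(spec$n_genes * ncell, spec$meanlog, spec$sdlog) * scale,
                  nrow = spec$n_genes)
      v[matrix(runif(length(v)) < spec$dropout, nrow = spec$n_genes)] <- 0
      dimnames(v) <- list(genes, paste0(prefix, seq_len(ncell)))
      v
    }
    assignments <- list()
    patients <- lapply(seq_len(spec$n_patients), function(i) {
      pid <- paste0("patient", i)
      tum <- draw(spec$n_tumor, paste0("p", i, "_t"))
      nt <- draw(spec$n_nontumor, paste0("p", i, "_n"))
      assign_gene <- planted[(seq_len(spec$n_tumor) - 1L) %% spec$k_star + 1L]
      for (j in seq_len(spec$n_tumor)) {
        tum[assign_gene[j], j] <- spec$rho * e_bg[assign_gene[j]]
      }
      assignments[[pid]] <<- assign_gene
      patient_sample(pid, tum, nt)
    })
    list(cohort = cohort(patients),
         truth = list(planted_genes = sort(planted),
                      assignments = assignments,
                      background_mean = e_bg,
                      spec = spec))
  })
}

#' Generate paired tissue-expression tables with known pass/fail labels
#'
#' Builds two long-format tissue tables such that a known `low_fraction` of
#' genes has mean TPM strictly below `threshold` in *both* tables (the rest
#' exceed it in at least one). Ground-truth labels are returned so tests of
#' the tissue filter never re-derive them.
#'
#' @param n_genes,n_tissues table dimensions.
#' @param low_fraction fraction of genes labelled low in both tables.
#' @param threshold TPM threshold the labels refer to.
#' @param seed RNG seed.
#' @return list with `table_a`, `table_b` (tibbles `gene`, `tissue`, `tpm`)
#'   and `labels` tibble (`gene`, `low_in_both`).
#' @export
generate_tissue_tables <- function(n_genes = 100, n_tissues = 10,
                                   low_fraction = 0.3, threshold = 1,
                                   seed = 1) {
  if (low_fraction < 0 || low_fraction > 1) stop_config("low_fraction must lie in [0, 1]")
  withr::with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    n_low <- round(low_fraction * n_genes)
    low <- rep(c(TRUE, FALSE), c(n_low, n_genes - n_low))[sample.int(n_genes)]
    one_table <- function(force_high_half) {
      purrr::map_dfr(seq_along(genes), function(i) {
        if (low[i]) {
          center <- threshold * runif(1, 0.1, 0.6)
        } else if (force_high_half && runif(1) < 0.5) {
          # half the non-low genes fail only in the other table
          center <- threshold * runif(1, 0.1, 0.6)
        } else {
          center <- threshold * runif(1, 1.5, 4)
        }
        tpm <- pmax(center * exp(rnorm(n_tissues, 0, 0.1)), 0)
        # clamp so the mean lands on the intended side of the threshold
        if (center < threshold) tpm <- tpm * min(1, 0.9 * threshold / mean(tpm))
        else tpm <- tpm * max(1, 1.1 * threshold / mean(tpm))
        tibble::tibble(gene = genes[i], tissue = tissues, tpm = tpm)
      })
    }
    list(table_a = one_table(TRUE), table_b = one_table(FALSE),
         labels = tibble::tibble(gene = genes, low_in_both = low))
  })
}
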