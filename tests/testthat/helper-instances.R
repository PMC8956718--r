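# fixture builders used across the suite; everything is generated in code

# incidence instance straight from per-cell killability sets
incidence_from_sets <- function(tumor_sets, nontumor_sets = list(), pool,
                                patient_id = "pX") {
  as_hits <- function(sets, prefix) {
    m <- matrix(FALSE, nrow = length(pool), ncol = length(sets),
                dimnames = list(pool, if (length(sets)) paste0(prefix, seq_along(sets))))
    for (j in seq_along(sets)) m[sets[[j]], j] <- TRUE
    m
  }
  structure(
    list(patient_id = patient_id, gene_pool = pool,
         tumor_hits = as_hits(tumor_sets, "t"),
         nontumor_hits = as_hits(nontumor_sets, "n")),
    class = "incidence"
  )
}

# random incidence instance with given pool/cell sizes and hit densities
random_incidence <- function(seed, n_genes, n_tumor, n_nontumor,
                             density = 0.25, nt_density = density * 0.5,
                             patient_id = paste0("r", seed)) {
  set.seed(seed)
  pool <- sprintf("g%02d", seq_len(n_genes))
  tum <- matrix(runif(n_genes * n_tumor) < density, nrow = n_genes,
                dimnames = list(pool, paste0(patient_id, "_t", seq_len(n_tumor))))
  nt <- matrix(runif(n_genes * n_nontumor) < nt_density, nrow = n_genes,
               dimnames = list(pool, if (n_nontumor)
                 paste0(patient_id, "_n", seq_len(n_nontumor))))
  structure(list(patient_id = patient_id, gene_pool = pool,
                 tumor_hits = tum, nontumor_hits = nt),
            class = "incidence")
}

# random multi-patient cohort of incidence instances over a shared pool
random_cohort_instances <- function(seed, n_patients = 3, n_genes = 8) {
  set.seed(seed)
  sizes_t <- sample(5:15, n_patients, replace = TRUE)
  sizes_n <- sample(3:8, n_patients, replace = TRUE)
  dens <- runif(n_patients, 0.2, 0.45)
  lapply(seq_len(n_patients), function(p) {
    random_incidence(seed * 10 + p, n_genes, sizes_t[p], sizes_n[p],
                     density = dens[p], patient_id = paste0("p", p))
  })
}

# exhaustive list of ALL feasible gene sets of exactly size k (test oracle
# for optima enumeration); independent of the solvers
all_feasible_sets <- function(instance, params, k) {
  th <- oncohit:::its_thresholds(instance, params)
  pool <- instance$gene_pool
  if (k == 0) return(if (th$T <= 0) list(character(0)) else list())
  out <- list()
  subsets <- combn(length(pool), k)
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    cov <- sum(colSums(instance$tumor_hits[idx, , drop = FALSE]) > 0)
    if (cov < th$T) next
    kills <- if (ncol(instance$nontumor_hits) == 0) 0 else
      sum(colSums(instance$nontumor_hits[idx, , drop = FALSE]) > 0)
    if (kills <= th$B) out[[length(out) + 1]] <- sort(pool[idx])
  }
  out
}

# small expression fixture: 3 genes x 4 cells with controlled values
toy_patient <- function() {
  genes <- c("A", "B", "C")
  tum <- expression_matrix(
    matrix(c(6, 0, 1,
             0, 8, 1,
             6, 8, 1,
             0, 0, 1), nrow = 3,
           dimnames = list(genes, paste0("t", 1:4))))
  nt <- expression_matrix(
    matrix(c(3, 2, 1,
             0, 2, 1,
             3, 0, 1), nrow = 3,
           dimnames = list(genes, paste0("n", 1:3))))
  patient_sample("toy", tum, nt)
}
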