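#' Individual target set parameters
#'
#' @param lb lower bound on the fraction of tumor cells killed (baseline 0.8).
#' @param ub upper bound on the fraction of non-tumor cells whose killing is
#'   tolerated (baseline 0.1).
#' @param require_full_coverage when `TRUE`, `lb` is ignored and every tumor
#'   cell must be hit (the stricter full-coverage formulation; the non-tumor
#'   bound still applies).
#' @export
its_params <- function(lb = 0.8, ub = 0.1, require_full_coverage = FALSE) {
  if (lb < 0 || lb > 1 || ub < 0 || ub > 1) stop_config("lb and ub must lie in [0, 1]")
  structure(list(lb = lb, ub = ub,
                 require_full_coverage = isTRUE(require_full_coverage)),
            class = "its_params")
}

# integer thresholds for one instance under params; full coverage -> T = m
its_thresholds <- function(instance, params) {
  m <- ncol(instance$tumor_hits)
  q <- ncol(instance$nontumor_hits)
  T_ <- if (params$require_full_coverage) m else coverage_target(params$lb, m)
  list(T = T_, B = kill_allowance(params$ub, q), m = m, q = q)
}

its_result <- function(instance, status, selected, method,
                       infeasible_cells = NULL) {
  kr <- if (status %in% c("optimal", "feasible")) {
    kill_report(instance, selected)
  } else {
    tibble::tibble(tumor_kill_frac = NA_real_, nontumor_kill_frac = NA_real_)
  }
  structure(
    list(patient_id = instance$patient_id,
         status = status,
         selected = sort(selected),
         its_size = if (status %in% c("optimal", "feasible")) length(selected) else NA_integer_,
         tumor_kill_frac = kr$tumor_kill_frac,
         nontumor_kill_frac = kr$nontumor_kill_frac,
         method = method,
         infeasible_cells = infeasible_cells),
    class = "its_result"
  )
}

#' @export
print.its_result <- function(x, ...) {
  cat("<its_result>", x$patient_id, "-", x$status, "\n")
  if (!is.na(x$its_size)) {
    cat("  size", x$its_size, ":", paste(x$selected, collapse = ", "), "\n")
    cat(sprintf("  tumor killed %.3f | non-tumor killed %.3f\n",
                x$tumor_kill_frac, x$nontumor_kill_frac))
  }
  invisible(x)
}

#' Solve the basic minimum hitting-set problem (full coverage, no side bound)
#'
#' The unconstrained formulation: find the minimum-cardinality gene set
#' intersecting every tumor cell's killability set. Intended for
#' presence-mode incidence. Infeasible exactly when some cell has an empty
#' set; those cells are reported.
#'
#' @param instance an incidence instance.
#' @param node_limit search-node budget before giving up with status
#'   `"timeout"`.
#' @return an `its_result` (proven optimal when status is `"optimal"`).
#' @export
solve_basic_hitting_set <- function(instance, node_limit = 1e8) {
  empty <- colnames(instance$tumor_hits)[colSums(instance$tumor_hits) == 0]
  if (ncol(instance$tumor_hits) > 0 && is.null(colnames(instance$tumor_hits))) {
    empty <- which(colSums(instance$tumor_hits) == 0)
  }
  if (length(empty) > 0) {
    return(its_result(instance, "infeasible", character(0),
                      "branch-and-bound", infeasible_cells = empty))
  }
  m <- ncol(instance$tumor_hits)
  q <- ncol(instance$nontumor_hits)
  res <- cpp_solve_its(instance$tumor_hits, instance$nontumor_hits,
                       min_kill = m, max_side_kill = max(q, 1L),
                       node_limit = node_limit)
  its_result(instance, res$status, instance$gene_pool[res$selected],
             "branch-and-bound")
}

#' Solve the individual target set problem to proven optimality
#'
#' Finds a minimum-cardinality gene set killing at least `ceil(lb * m)` of
#' the patient's `m` tumor cells while killing at most `floor(ub * q)` of
#' the `q` non-tumor cells. Solved by exact branch-and-bound (iterative
#' deepening on set size with submodular coverage bounds); feasibility is
#' not guaranteed and is reported via `status`.
#'
#' @inheritParams solve_basic_hitting_set
#' @param params [its_params()].
#' @return an `its_result` with `status` one of `"optimal"`, `"infeasible"`,
#'   `"timeout"`.
#' @examples
#' fix <- make_demo_cohort()
#' solve_its(fix$instances[[1]], its_params(require_full_coverage = TRUE))
#' @export
solve_its <- function(instance, params = its_params(), node_limit = 1e8) {
  th <- its_thresholds(instance, params)
  res <- cpp_solve_its(instance$tumor_hits, instance$nontumor_hits,
                       min_kill = th$T, max_side_kill = th$B,
                       node_limit = node_limit)
  its_result(instance, res$status, instance$gene_pool[res$selected],
             "branch-and-bound")
}

#' Brute-force individual target set oracle
#'
#' Enumerates all gene subsets in increasing cardinality and returns the
#' first one satisfying both bounds; certifies infeasibility by exhausting
#' every subset. Deliberately independent of the branch-and-bound solver so
#' it can serve as a test oracle; refuses pools above `max_genes`.
#'
#' @inheritParams solve_its
#' @param max_genes refusal cap on pool size (default 20).
#' @return an `its_result` with method `"brute-force"`.
#' @export
brute_force_its <- function(instance, params = its_params(), max_genes = 20) {
  n <- length(instance$gene_pool)
  if (n > max_genes) {
    stop_config(paste0("brute-force oracle refuses pools larger than ", max_genes))
  }
  th <- its_thresholds(instance, params)
  if (th$T <= 0) return(its_result(instance, "optimal", character(0), "brute-force"))
  tum <- instance$tumor_hits
  nt <- instance$nontumor_hits
  for (k in 1:n) {
    subsets <- combn(n, k)
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      cov <- sum(colSums(tum[idx, , drop = FALSE]) > 0)
      if (cov < th$T) next
      kills <- if (ncol(nt) == 0) 0 else sum(colSums(nt[idx, , drop = FALSE]) > 0)
      if (kills <= th$B) {
        return(its_result(instance, "optimal", instance$gene_pool[idx], "brute-force"))
      }
    }
  }
  its_result(instance, "infeasible", character(0), "brute-force")
}

#' Greedy baseline for the individual target set problem
#'
#' A heuristic control: iteratively adds the single gene (or, in pair mode,
#' also the gene pair) that maximizes newly covered tumor cells among
#' candidates keeping cumulative non-tumor kills within the allowance. Ties
#' break by fewer new non-tumor kills, then fewer genes added, then
#' lexicographic gene order. Stops when the coverage target is met; if no
#' admissible candidate remains the status is `"infeasible"` (greedy could
#' not certify anything — the exact solver may still find a solution).
#'
#' @inheritParams solve_its
#' @param pair_mode also consider gene pairs at every step (default `TRUE`).
#' @return an `its_result` with method `"greedy"`; successful runs have
#'   status `"feasible"` since greedy solutions carry no optimality proof.
#' @export
greedy_its <- function(instance, params = its_params(), pair_mode = TRUE) {
  th <- its_thresholds(instance, params)
  if (th$T <= 0) return(its_result(instance, "feasible", character(0), "greedy"))
  tum <- instance$tumor_hits
  nt <- instance$nontumor_hits
  pool <- instance$gene_pool
  n <- length(pool)
  covered <- rep(FALSE, ncol(tum))
  killed <- rep(FALSE, ncol(nt))
  chosen <- integer(0)
  cand_sets <- lapply(seq_len(n), identity)
  if (pair_mode && n > 1) {
    pairs <- combn(n, 2)
    cand_sets <- c(cand_sets, lapply(seq_len(ncol(pairs)), function(j) pairs[, j]))
  }
  # candidates in lexicographic order of their (sorted) gene names so that
  # which.max-style selection realizes the documented tie-break
  key <- vapply(cand_sets, function(s) paste(sort(pool[s]), collapse = "\r"), character(1))
  cand_sets <- cand_sets[order(lengths(cand_sets), key)]
  repeat {
    if (sum(covered) >= th$T) {
      return(its_result(instance, "feasible", pool[chosen], "greedy"))
    }
    best <- NULL
    best_score <- c(-1, Inf, Inf) # new coverage (max), new kills (min), size (min)
    for (s in cand_sets) {
      if (any(s %in% chosen)) next
      new_cov <- sum(colSums(tum[s, !covered, drop = FALSE]) > 0)
      if (new_cov <= 0) next
      new_kill <- if (ncol(nt) == 0) 0 else
        sum(colSums(nt[s, !killed, drop = FALSE]) > 0)
      if (sum(killed) + new_kill > th$B) next
      better <- (new_cov > best_score[1]) ||
        (new_cov == best_score[1] && new_kill < best_score[2]) ||
        (new_cov == best_score[1] && new_kill == best_score[2] &&
           length(s) < best_score[3])
      if (better) {
        best <- s
        best_score <- c(new_cov, new_kill, length(s))
      }
    }
    if (is.null(best)) {
      return(its_result(instance, "infeasible", character(0), "greedy"))
    }
    chosen <- c(chosen, best)
    covered <- covered | colSums(tum[best, , drop = FALSE]) > 0
    if (ncol(nt) > 0) killed <- killed | colSums(nt[best, , drop = FALSE]) > 0
  }
}
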