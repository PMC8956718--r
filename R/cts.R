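#' Fair cohort target set parameters
#'
#' @param alpha unfairness slack: the maximum number of targets any patient
#'   may receive beyond their individually optimal ITS size (non-negative
#'   integer, default 0 = every patient gets a minimum-size ITS).
#' @param lb,ub per-patient tumor/non-tumor kill bounds as in [its_params()].
#' @param full_coverage when `TRUE`, every tumor cell of every patient must
#'   be hit and the non-tumor bound is dropped (the basic formulation).
#' @export
fair_params <- function(alpha = 0, lb = 0.8, ub = 0.1, full_coverage = FALSE) {
  if (alpha < 0 || alpha != round(alpha)) stop_config("alpha must be a non-negative integer")
  if (lb < 0 || lb > 1 || ub < 0 || ub > 1) stop_config("lb and ub must lie in [0, 1]")
  structure(list(alpha = as.integer(alpha), lb = lb, ub = ub,
                 full_coverage = isTRUE(full_coverage)),
            class = "fair_params")
}

# per-instance integer thresholds under fair params; full coverage drops ub
fair_thresholds <- function(instance, fair) {
  m <- ncol(instance$tumor_hits)
  q <- ncol(instance$nontumor_hits)
  if (fair$full_coverage) {
    list(T = m, B = q, m = m, q = q)
  } else {
    list(T = coverage_target(fair$lb, m), B = kill_allowance(fair$ub, q),
         m = m, q = q)
  }
}

fair_its_params <- function(fair) {
  its_params(lb = fair$lb, ub = if (fair$full_coverage) 1 else fair$ub,
             require_full_coverage = fair$full_coverage)
}

#' Optimal individual target set size H(i) for every patient
#'
#' Solves each patient's ITS problem in isolation under the bounds carried
#' by `fair`. Infeasibility is data here, not an error: infeasible patients
#' get `h = NA`.
#'
#' @param instances list of incidence instances built over a common pool.
#' @param fair [fair_params()].
#' @param node_limit per-patient search budget.
#' @return tibble with `patient_id`, `h`, `status`.
#' @export
compute_h_values <- function(instances, fair = fair_params(), node_limit = 1e8) {
  p <- fair_its_params(fair)
  purrr::map_dfr(instances, function(inst) {
    r <- solve_its(inst, p, node_limit = node_limit)
    tibble::tibble(patient_id = inst$patient_id, h = r$its_size, status = r$status)
  })
}

cts_result <- function(status, cts, instances, h_tbl, fair, dropped,
                       method = "branch-and-bound") {
  assignments <- NULL
  cts_size <- NA_integer_
  if (status == "optimal") {
    cts_size <- length(cts)
    p <- fair_its_params(fair)
    assignments <- purrr::map_dfr(instances, function(inst) {
      sub <- restrict_incidence(inst, cts)
      r <- solve_its(sub, p)
      h <- h_tbl$h[match(inst$patient_id, h_tbl$patient_id)]
      tibble::tibble(patient_id = inst$patient_id,
                     genes = paste(r$selected, collapse = ";"),
                     its_size = r$its_size,
                     h = h,
                     slack = r$its_size - h,
                     tumor_kill_frac = r$tumor_kill_frac,
                     nontumor_kill_frac = r$nontumor_kill_frac)
    })
  }
  structure(
    list(status = status, cts = sort(cts), cts_size = cts_size,
         assignments = assignments, h = h_tbl, dropped_patients = dropped,
         alpha = fair$alpha, method = method),
    class = "cts_result"
  )
}

#' @export
print.cts_result <- function(x, ...) {
  cat("<cts_result>", x$status, "| alpha =", x$alpha, "\n")
  if (!is.na(x$cts_size)) {
    cat("  CTS size", x$cts_size, ":", paste(x$cts, collapse = ", "), "\n")
    print(x$assignments)
  }
  if (length(x$dropped_patients) > 0) {
    cat("  dropped (ITS-infeasible):", paste(x$dropped_patients, collapse = ", "), "\n")
  }
  invisible(x)
}

# restrict an incidence instance to a subset of its pool
restrict_incidence <- function(instance, genes) {
  genes <- genes[genes %in% instance$gene_pool]
  structure(
    list(patient_id = instance$patient_id, gene_pool = genes,
         tumor_hits = instance$tumor_hits[genes, , drop = FALSE],
         nontumor_hits = instance$nontumor_hits[genes, , drop = FALSE]),
    class = "incidence"
  )
}

#' Solve the fair cohort target set problem to proven optimality
#'
#' Minimizes the size of a global gene set from which every patient can draw
#' an individual target set of size at most `H(i) + alpha` that satisfies
#' that patient's kill bounds. Patients infeasible at the ITS level are
#' dropped with a warning when `drop_infeasible` (the cohort answer then
#' covers the remaining patients), else they make the cohort infeasible.
#'
#' @inheritParams compute_h_values
#' @param h optional precomputed tibble from [compute_h_values()]; computed
#'   when missing. Recompute per replicate: sampling changes the instances.
#' @param drop_infeasible drop patients with no feasible ITS (default `TRUE`).
#' @return a `cts_result`: global set, per-patient assignments (each the
#'   minimum-size feasible subset of the global set), slacks, and kill
#'   fractions.
#' @examples
#' fix <- make_demo_cohort()
#' solve_fair_cts(fix$instances, fair_params(alpha = 1, full_coverage = TRUE))
#' @export
solve_fair_cts <- function(instances, fair = fair_params(), h = NULL,
                           drop_infeasible = TRUE, node_limit = 2e8) {
  if (is.null(h)) h <- compute_h_values(instances, fair, node_limit = node_limit)
  bad <- h$patient_id[is.na(h$h)]
  if (length(bad) > 0 && !drop_infeasible) {
    return(cts_result("infeasible", character(0), instances, h, fair, bad))
  }
  if (length(bad) > 0) {
    warn(paste0("dropping ITS-infeasible patients: ", paste(bad, collapse = ", ")))
  }
  keep <- instances[vapply(instances, function(i) !(i$patient_id %in% bad), logical(1))]
  if (length(keep) == 0) {
    return(cts_result("infeasible", character(0), instances, h, fair, bad))
  }
  pool <- keep[[1]]$gene_pool
  th <- lapply(keep, fair_thresholds, fair = fair)
  caps <- vapply(keep, function(inst) {
    as.integer(h$h[match(inst$patient_id, h$patient_id)] + fair$alpha)
  }, integer(1))
  res <- cpp_solve_cts(
    lapply(keep, `[[`, "tumor_hits"),
    lapply(keep, `[[`, "nontumor_hits"),
    vapply(th, function(x) as.integer(x$T), integer(1)),
    vapply(th, function(x) as.integer(x$B), integer(1)),
    caps, node_limit
  )
  if (res$status != "optimal") {
    return(cts_result(res$status, character(0), keep, h, fair, bad))
  }
  cts_result("optimal", pool[res$selected], keep, h, fair, bad)
}

#' Sweep the unfairness slack and track the cohort target set size
#'
#' Solves the fair CTS problem for `alpha = 0..alpha_max` and reports, per
#' alpha, the CTS size and the worst per-patient slack actually used. The
#' attribute `best_alpha` is the first alpha attaining the minimum observed
#' CTS size — the point past which extra unfairness buys nothing.
#'
#' @inheritParams solve_fair_cts
#' @param alpha_max largest slack to try.
#' @return tibble of class `alpha_sweep` with columns `alpha`, `cts_size`,
#'   `max_slack`, `status`; attribute `best_alpha`.
#' @export
alpha_sweep <- function(instances, fair = fair_params(), alpha_max = 5,
                        drop_infeasible = TRUE, node_limit = 2e8) {
  h <- compute_h_values(instances, fair, node_limit = node_limit)
  rows <- purrr::map_dfr(0:alpha_max, function(a) {
    f <- fair_params(alpha = a, lb = fair$lb, ub = fair$ub,
                     full_coverage = fair$full_coverage)
    r <- solve_fair_cts(instances, f, h = h, drop_infeasible = drop_infeasible,
                        node_limit = node_limit)
    tibble::tibble(alpha = a, cts_size = r$cts_size,
                   max_slack = if (r$status == "optimal") max(r$assignments$slack) else NA_integer_,
                   status = r$status)
  })
  ok <- !is.na(rows$cts_size)
  best <- if (any(ok)) rows$alpha[ok][which.min(rows$cts_size[ok])] else NA_integer_
  structure(tibble::new_tibble(rows, class = "alpha_sweep"), best_alpha = best)
}

#' Brute-force fair cohort target set oracle
#'
#' Exhaustive global search, independent of the branch-and-bound path:
#' enumerates every gene subset in increasing cardinality and accepts the
#' first one from which each patient can draw a feasible assignment of size
#' at most `H(i) + alpha` (assignments checked by subset enumeration).
#'
#' @inheritParams solve_fair_cts
#' @param max_genes refusal cap on pool size (default 12).
#' @return a `cts_result` with method `"brute-force"`.
#' @export
brute_force_cts <- function(instances, fair = fair_params(), h = NULL,
                            drop_infeasible = TRUE, max_genes = 12) {
  pool <- instances[[1]]$gene_pool
  n <- length(pool)
  if (n > max_genes) {
    stop_config(paste0("brute-force oracle refuses pools larger than ", max_genes))
  }
  p <- fair_its_params(fair)
  if (is.null(h)) {
    h <- purrr::map_dfr(instances, function(inst) {
      r <- brute_force_its(inst, p, max_genes = max_genes)
      tibble::tibble(patient_id = inst$patient_id, h = r$its_size, status = r$status)
    })
  }
  bad <- h$patient_id[is.na(h$h)]
  if (length(bad) > 0 && !drop_infeasible) {
    return(cts_result("infeasible", character(0), instances, h, fair, bad,
                      method = "brute-force"))
  }
  keep <- instances[vapply(instances, function(i) !(i$patient_id %in% bad), logical(1))]
  if (length(keep) == 0) {
    return(cts_result("infeasible", character(0), instances, h, fair, bad,
                      method = "brute-force"))
  }
  th <- lapply(keep, fair_thresholds, fair = fair)
  caps <- vapply(keep, function(inst) {
    as.integer(h$h[match(inst$patient_id, h$patient_id)] + fair$alpha)
  }, integer(1))
  feasible_for <- function(i, genes_idx) {
    # does some subset of genes_idx of size <= caps[i] meet patient i's bounds?
    tum <- keep[[i]]$tumor_hits
    nt <- keep[[i]]$nontumor_hits
    if (th[[i]]$T <= 0) return(TRUE)
    kmax <- min(caps[i], length(genes_idx))
    if (kmax < 1) return(FALSE)
    for (k in 1:kmax) {
      subs <- combn(length(genes_idx), k)
      for (j in seq_len(ncol(subs))) {
        idx <- genes_idx[subs[, j]]
        if (sum(colSums(tum[idx, , drop = FALSE]) > 0) < th[[i]]$T) next
        kills <- if (ncol(nt) == 0) 0 else sum(colSums(nt[idx, , drop = FALSE]) > 0)
        if (kills <= th[[i]]$B) return(TRUE)
      }
    }
    FALSE
  }
  for (k in 0:n) {
    subsets <- if (k == 0) matrix(integer(0), nrow = 0, ncol = 1) else combn(n, k)
    for (j in seq_len(ncol(subsets))) {
      s <- subsets[, j]
      if (all(vapply(seq_along(keep), feasible_for, logical(1), genes_idx = s))) {
        return(cts_result("optimal", pool[s], keep, h, fair, bad,
                          method = "brute-force"))
      }
    }
  }
  cts_result("infeasible", character(0), keep, h, fair, bad, method = "brute-force")
}

#' Sample optimal solutions of an ITS or CTS problem
#'
#' Enumerates the distinct optimal solutions at the proven optimal size
#' (capped at `max_distinct`) and draws `k_draws` of them uniformly with
#' replacement under `seed`. Every returned set attains the optimum and
#' satisfies all constraints; when fewer distinct optima exist than draws,
#' sets repeat. Feeds the gene frequency / co-occurrence statistics.
#'
#' @param x a single incidence instance (ITS problem) or a list of instances
#'   (fair CTS problem).
#' @param params [its_params()] for an instance, [fair_params()] for a list.
#' @param k_draws number of sampled solutions (default 50).
#' @param seed RNG seed for the draw.
#' @param max_distinct enumeration cap on distinct optima.
#' @param node_limit search budget.
#' @return list of class `optima_sample`: `solutions` (list of character
#'   vectors), `optimum` (size), `n_distinct`, `truncated`.
#' @export
enumerate_optima <- function(x, params = NULL, k_draws = 50, seed = 1,
                             max_distinct = 10000, node_limit = 2e8) {
  if (inherits(x, "incidence")) {
    params <- params %||% its_params()
    base <- solve_its(x, params, node_limit = node_limit)
    if (base$status != "optimal") stop_config("base ITS problem is not solvable")
    th <- its_thresholds(x, params)
    enum <- cpp_enumerate_its(x$tumor_hits, x$nontumor_hits, th$T, th$B,
                              base$its_size, max_distinct, node_limit)
    pool <- x$gene_pool
  } else {
    params <- params %||% fair_params()
    h <- compute_h_values(x, params, node_limit = node_limit)
    base <- solve_fair_cts(x, params, h = h, node_limit = node_limit)
    if (base$status != "optimal") stop_config("base CTS problem is not solvable")
    keep <- x[vapply(x, function(i) !(i$patient_id %in% base$dropped_patients),
                     logical(1))]
    th <- lapply(keep, fair_thresholds, fair = params)
    caps <- vapply(keep, function(inst) {
      as.integer(h$h[match(inst$patient_id, h$patient_id)] + params$alpha)
    }, integer(1))
    enum <- cpp_enumerate_cts(
      lapply(keep, `[[`, "tumor_hits"),
      lapply(keep, `[[`, "nontumor_hits"),
      vapply(th, function(t) as.integer(t$T), integer(1)),
      vapply(th, function(t) as.integer(t$B), integer(1)),
      caps, base$cts_size, max_distinct, node_limit
    )
    pool <- keep[[1]]$gene_pool
  }
  distinct <- lapply(enum$solutions, function(idx) sort(pool[idx]))
  if (length(distinct) == 0) stop_config("no optima enumerated")
  draws <- withr::with_seed(seed,
    sample.int(length(distinct), k_draws, replace = TRUE))
  structure(
    list(solutions = distinct[draws],
         optimum = length(distinct[[1]]),
         n_distinct = length(distinct),
         truncated = isTRUE(enum$truncated)),
    class = "optima_sample"
  )
}

#' @export
print.optima_sample <- function(x, ...) {
  cat("<optima_sample>", length(x$solutions), "draws from", x$n_distinct,
      "distinct optima of size", x$optimum,
      if (x$truncated) "(enumeration truncated)" else "", "\n")
  invisible(x)
}
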