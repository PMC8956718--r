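fix <- make_demo_cohort()
full <- fair_params(full_coverage = TRUE)

test_that("three-patient fixture: per-patient optima are singletons", {
  h <- compute_h_values(fix$instances, full)
  expect_equal(h$h, c(1L, 1L, 1L))
  expect_equal(h$status, rep("optimal", 3))
})

test_that("fixture cohort solution trades fairness slack for cohort size", {
  r1 <- solve_fair_cts(fix$instances, fair_params(alpha = 1, full_coverage = TRUE))
  expect_equal(r1$status, "optimal")
  expect_equal(r1$cts_size, 2L)
  expect_equal(r1$cts, c("APP", "MET"))
  expect_equal(max(r1$assignments$slack), 1L)
  expect_true(all(r1$assignments$its_size == 2L))

  r0 <- solve_fair_cts(fix$instances, fair_params(alpha = 0, full_coverage = TRUE))
  expect_equal(r0$cts_size, 3L)
  expect_equal(r0$cts, c("Target1", "Target2", "Target3"))
  expect_true(all(r0$assignments$slack == 0L))

  sw <- alpha_sweep(fix$instances, full, alpha_max = 3)
  expect_equal(sw$cts_size, c(3L, 2L, 2L, 2L))
  expect_equal(attr(sw, "best_alpha"), 1L)
})

test_that("single-patient cohort at alpha 0 reduces to that patient's ITS", {
  inst <- random_incidence(78, n_genes = 8, n_tumor = 10, n_nontumor = 5,
                           density = 0.35)
  p <- fair_params(alpha = 0, lb = 0.8, ub = 0.2)
  cts <- solve_fair_cts(list(inst), p)
  its <- solve_its(inst, its_params(lb = 0.8, ub = 0.2))
  expect_equal(its$status, "optimal")
  expect_equal(cts$cts_size, its$its_size)
})

test_that("fairness bound and union bound hold on random cohorts", {
  for (seed in c(11, 23, 35)) {
    insts <- random_cohort_instances(seed, n_patients = 3, n_genes = 8)
    for (a in 0:2) {
      f <- fair_params(alpha = a, lb = 0.8, ub = 0.2)
      r <- suppressWarnings(solve_fair_cts(insts, f))
      if (r$status != "optimal") next
      expect_true(all(r$assignments$slack <= a))
      expect_lte(r$cts_size, sum(r$assignments$h) )
      expect_true(all(r$cts %in% insts[[1]]$gene_pool))
      # every assignment is drawn from the global set and meets its bounds
      for (i in seq_len(nrow(r$assignments))) {
        genes <- strsplit(r$assignments$genes[i], ";")[[1]]
        expect_true(all(genes %in% r$cts))
      }
    }
  }
})

test_that("patients infeasible at the ITS level are dropped or sink the cohort", {
  feas <- incidence_from_sets(list("a", "b"), pool = c("a", "b", "c"),
                              patient_id = "ok")
  infeas <- incidence_from_sets(
    tumor_sets = list("c"),
    nontumor_sets = list("c"),
    pool = c("a", "b", "c"), patient_id = "stuck")
  f <- fair_params(alpha = 1, lb = 1, ub = 0)
  expect_warning(r <- solve_fair_cts(list(feas, infeas), f), "stuck")
  expect_equal(r$status, "optimal")
  expect_equal(r$dropped_patients, "stuck")
  expect_setequal(r$cts, c("a", "b"))
  r2 <- solve_fair_cts(list(feas, infeas), f, drop_infeasible = FALSE)
  expect_equal(r2$status, "infeasible")
})

test_that("optima sampling returns only verified optima with stable support", {
  # exactly two singleton optima
  inst <- incidence_from_sets(list(c("a", "b"), c("a", "b")), pool = c("a", "b", "c"))
  p <- its_params(lb = 1, ub = 1)
  s <- enumerate_optima(inst, p, k_draws = 50, seed = 4)
  expect_length(s$solutions, 50)
  expect_true(all(lengths(s$solutions) == 1))
  expect_true(all(unlist(s$solutions) %in% c("a", "b")))
  expect_equal(s$n_distinct, 2L)

  # unique optimum -> 50 identical sets
  uniq <- incidence_from_sets(list("a", c("a", "b")), pool = c("a", "b"))
  su <- enumerate_optima(uniq, p, k_draws = 50, seed = 4)
  expect_equal(unique(su$solutions), list("a"))

  # sampled support is contained in the exhaustive list of all optima
  for (seed in c(5, 17, 29)) {
    ri <- random_incidence(seed + 40, n_genes = 7, n_tumor = 9, n_nontumor = 5,
                           density = 0.35)
    pp <- its_params(lb = 0.8, ub = 0.25)
    base <- solve_its(ri, pp)
    if (base$status != "optimal") next
    samp <- enumerate_optima(ri, pp, k_draws = 30, seed = seed)
    oracle <- all_feasible_sets(ri, pp, base$its_size)
    expect_true(all(vapply(samp$solutions, function(s)
      any(vapply(oracle, identical, logical(1), y = s)), logical(1))))
    expect_equal(s <- samp$optimum, base$its_size)
  }
})

test_that("optima sampling draws are reproducible under the seed", {
  inst <- random_incidence(501, n_genes = 8, n_tumor = 10, n_nontumor = 4,
                           density = 0.4)
  p <- its_params(lb = 0.8, ub = 0.3)
  a <- enumerate_optima(inst, p, k_draws = 20, seed = 9)
  b <- enumerate_optima(inst, p, k_draws = 20, seed = 9)
  expect_identical(a$solutions, b$solutions)
})

test_that("cohort-level optima sampling respects the fairness constraints", {
  s <- enumerate_optima(fix$instances, fair_params(alpha = 1, full_coverage = TRUE),
                        k_draws = 25, seed = 3)
  expect_true(all(lengths(s$solutions) == 2))
  expect_equal(unique(s$solutions), list(c("APP", "MET")))
})
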