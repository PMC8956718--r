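test_that("basic hitting set: forced genes, universal genes, empty-set infeasibility", {
  inst <- incidence_from_sets(list("g1", "g2", c("g1", "g2")),
                              pool = c("g1", "g2", "g3"))
  r <- solve_basic_hitting_set(inst)
  expect_equal(r$status, "optimal")
  expect_equal(r$its_size, 2L)
  expect_setequal(r$selected, c("g1", "g2"))

  universal <- incidence_from_sets(list(c("g1", "g2"), c("g1"), c("g1", "g3")),
                                   pool = c("g1", "g2", "g3"))
  expect_equal(solve_basic_hitting_set(universal)$its_size, 1L)

  hole <- incidence_from_sets(list("g1", character(0)), pool = c("g1", "g2"))
  rh <- solve_basic_hitting_set(hole)
  expect_equal(rh$status, "infeasible")
  expect_equal(rh$infeasible_cells, "t2")
})

test_that("basic hitting set matches brute force on random presence instances", {
  for (seed in 1:20) {
    inst <- random_incidence(seed, n_genes = 10, n_tumor = 8, n_nontumor = 0,
                             density = 0.35)
    a <- solve_basic_hitting_set(inst)
    b <- brute_force_its(inst, its_params(lb = 1, ub = 1))
    expect_equal(a$status, b$status)
    expect_equal(a$its_size, b$its_size)
  }
})

test_that("solve_its honors partial coverage and the non-tumor kill budget", {
  # lb = 0.66 over 3 cells -> must hit ceil(1.98) = 2; g1 alone suffices
  inst <- incidence_from_sets(list("g1", "g1", "g2"), pool = c("g1", "g2"))
  r <- solve_its(inst, its_params(lb = 0.66, ub = 1))
  expect_equal(r$status, "optimal")
  expect_equal(r$selected, "g1")

  # the only gene killing the tumor cell kills 2 of 10 non-tumor cells but
  # floor(0.1 * 10) = 1 is allowed -> infeasible
  inst2 <- incidence_from_sets(
    tumor_sets = list("g"),
    nontumor_sets = c(list("g", "g"), rep(list(character(0)), 8)),
    pool = c("g", "h"))
  expect_equal(solve_its(inst2, its_params(lb = 1, ub = 0.1))$status, "infeasible")
  # relaxing ub to 0.2 admits it
  expect_equal(solve_its(inst2, its_params(lb = 1, ub = 0.2))$status, "optimal")
})

test_that("every optimal solution verifies against kill_report bounds", {
  for (seed in 1:25) {
    inst <- random_incidence(seed + 300, n_genes = 9, n_tumor = 12, n_nontumor = 8,
                             density = 0.3)
    p <- its_params(lb = 0.8, ub = 0.25)
    r <- solve_its(inst, p)
    if (r$status != "optimal") next
    kr <- kill_report(inst, r$selected)
    m <- ncol(inst$tumor_hits); q <- ncol(inst$nontumor_hits)
    expect_gte(kr$tumor_kill_frac, ceiling(p$lb * m - 1e-9) / m)
    expect_lte(kr$nontumor_kill_frac, floor(p$ub * q + 1e-9) / q)
  }
})

test_that("brute-force oracle handles degenerate cases and refuses big pools", {
  empty <- incidence_from_sets(list(), pool = c("a", "b"))
  r <- brute_force_its(empty, its_params())
  expect_equal(r$its_size, 0L)
  expect_equal(r$selected, character(0))

  nohope <- incidence_from_sets(
    tumor_sets = list("a"),
    nontumor_sets = list("a", "a"),
    pool = c("a", "b"))
  expect_equal(brute_force_its(nohope, its_params(lb = 1, ub = 0))$status,
               "infeasible")

  big <- random_incidence(1, n_genes = 25, n_tumor = 5, n_nontumor = 0)
  expect_error(brute_force_its(big, its_params()), class = "oncohit_error_config")
})

test_that("ITS size is monotone under pool reduction and bound tightening", {
  for (seed in 1:10) {
    inst <- random_incidence(seed + 600, n_genes = 10, n_tumor = 15, n_nontumor = 8,
                             density = 0.35)
    p <- its_params(lb = 0.8, ub = 0.25)
    full <- solve_its(inst, p)
    # nested sub-pools never shrink the optimum
    sub <- oncohit:::restrict_incidence(inst, inst$gene_pool[1:6])
    subr <- solve_its(sub, p)
    if (full$status == "optimal" && subr$status == "optimal") {
      expect_gte(subr$its_size, full$its_size)
    }
    if (full$status == "infeasible") expect_equal(subr$status, "infeasible")
    # raising lb or lowering ub never decreases the optimum
    harder_lb <- solve_its(inst, its_params(lb = 0.95, ub = 0.25))
    if (full$status == "optimal" && harder_lb$status == "optimal") {
      expect_gte(harder_lb$its_size, full$its_size)
    }
    harder_ub <- solve_its(inst, its_params(lb = 0.8, ub = 0.1))
    if (full$status == "optimal" && harder_ub$status == "optimal") {
      expect_gte(harder_ub$its_size, full$its_size)
    }
  }
})

test_that("greedy baseline follows its selection rule and never beats the optimum", {
  fix <- make_demo_cohort()
  g <- greedy_its(fix$instances[[1]], its_params(require_full_coverage = TRUE))
  expect_equal(g$status, "feasible")
  expect_equal(g$selected, "Target1")

  # when the unique optimum is the whole pool, greedy must find it
  allneeded <- incidence_from_sets(list("a", "b", "c"), pool = c("a", "b", "c"))
  ga <- greedy_its(allneeded, its_params(lb = 1, ub = 1), pair_mode = FALSE)
  expect_setequal(ga$selected, c("a", "b", "c"))

  for (seed in 1:40) {
    inst <- random_incidence(seed + 900, n_genes = 8, n_tumor = 12, n_nontumor = 6,
                             density = 0.3)
    p <- its_params(lb = 0.8, ub = 0.3)
    opt <- solve_its(inst, p)
    for (pm in c(TRUE, FALSE)) {
      gr <- greedy_its(inst, p, pair_mode = pm)
      if (opt$status == "optimal" && gr$status == "feasible") {
        expect_gte(gr$its_size, opt$its_size)
        kr <- kill_report(inst, gr$selected)
        m <- ncol(inst$tumor_hits)
        expect_gte(kr$tumor_kill_frac, ceiling(p$lb * m - 1e-9) / m)
      }
      # greedy can fail only on instances the exact solver also finds hard,
      # never the converse direction of a false positive
      if (opt$status == "infeasible") expect_equal(gr$status, "infeasible")
    }
  }
})
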