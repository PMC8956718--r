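test_that("reference expression is the mean of non-zero entries, 0 when all-zero", {
  m <- expression_matrix(matrix(c(0, 2, 4,
                                  5, 0, 0,
                                  0, 0, 0), nrow = 3, byrow = TRUE,
                                dimnames = list(c("g1", "g2", "g3"),
                                                c("c1", "c2", "c3"))))
  expect_equal(reference_expression(m, "g1"), 3.0)
  expect_equal(reference_expression(m, "g2"), 5.0)
  expect_equal(reference_expression(m, "g3"), 0.0)
  expect_error(reference_expression(m, "nope"), class = "oncohit_error_gene")
})

test_that("expression matrix validation rejects malformed input", {
  vals <- matrix(1:4, nrow = 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_silent(expression_matrix(vals))
  bad <- vals; bad[1, 1] <- -1
  expect_error(expression_matrix(bad), class = "oncohit_error_format")
  expect_error(expression_matrix(vals, gene_ids = c("a", "a"),
                                 cell_ids = c("c1", "c2")),
               class = "oncohit_error_format")
  expect_error(expression_matrix(vals, gene_ids = "a", cell_ids = c("c1", "c2")),
               class = "oncohit_error_format")
})

test_that("killability rule: inclusive ratio threshold with strict-positivity guard", {
  p <- toy_patient()
  inst <- build_incidence(p, killability_params(r = 2), c("A", "B", "C"))
  sets <- incidence_sets(inst, "tumor")
  # E(A)=3: tumor value 6 is exactly 2*E and counts (inclusive boundary)
  expect_equal(sets[["t1"]], "A")
  expect_equal(sets[["t2"]], "B")
  expect_equal(sort(sets[["t3"]]), c("A", "B"))
  expect_equal(sets[["t4"]], character(0))
  # value just below the boundary does not count
  p2 <- p
  p2$tumor["A", "t1"] <- 5.9
  inst2 <- build_incidence(p2, killability_params(r = 2), c("A", "B", "C"))
  expect_equal(incidence_sets(inst2, "tumor")[["t1"]], character(0))
})

test_that("all-zero reference rows target exactly the cells expressing the gene", {
  genes <- c("x", "y")
  tum <- expression_matrix(matrix(c(7, 0, 0, 1), nrow = 2,
                                  dimnames = list(genes, c("t1", "t2"))))
  nt <- expression_matrix(matrix(0, nrow = 2, ncol = 2,
                                 dimnames = list(genes, c("n1", "n2"))))
  inst <- build_incidence(patient_sample("p", tum, nt),
                          killability_params(r = 2), genes)
  sets <- incidence_sets(inst, "tumor")
  expect_equal(sets[["t1"]], "x")
  expect_equal(sets[["t2"]], "y")
  expect_equal(incidence_sets(inst, "nontumor")[["n1"]], character(0))
})

test_that("ratio mode without non-tumor cells is a mode error; empty pool a config error", {
  p <- toy_patient()
  p$nontumor <- NULL
  expect_error(build_incidence(p, killability_params(r = 2), c("A", "B")),
               class = "oncohit_error_mode")
  expect_silent(build_incidence(p, killability_params(mode = "presence"), c("A", "B")))
  expect_error(build_incidence(toy_patient(), killability_params(), character(0)),
               class = "oncohit_error_config")
})

test_that("incidence is monotone in r and presence mode is the zero-reference limit", {
  for (seed in 1:5) {
    set.seed(seed)
    genes <- sprintf("g%d", 1:6)
    tum <- expression_matrix(matrix(rexp(6 * 10), nrow = 6,
                                    dimnames = list(genes, paste0("t", 1:10))))
    nt <- expression_matrix(matrix(rexp(6 * 8) * rbinom(48, 1, 0.7), nrow = 6,
                                   dimnames = list(genes, paste0("n", 1:8))))
    p <- patient_sample("m", tum, nt)
    i1 <- build_incidence(p, killability_params(r = 1.5), genes)
    i2 <- build_incidence(p, killability_params(r = 3), genes)
    # every membership at the stricter ratio also holds at the looser one
    expect_true(all(i1$tumor_hits[i2$tumor_hits]))
    expect_true(all(i1$nontumor_hits[i2$nontumor_hits]))
    # presence mode = ratio mode with all reference expressions forced to 0
    pres <- build_incidence(p, killability_params(mode = "presence"), genes)
    p0 <- p
    p0$nontumor[] <- 0
    zero_ref <- build_incidence(p0, killability_params(r = 2), genes)
    expect_identical(pres$tumor_hits, zero_ref$tumor_hits)
  }
})

test_that("kill_report counts intersecting cells and flags foreign genes", {
  inst <- incidence_from_sets(
    tumor_sets = list(c("a"), c("b"), c("a", "b")),
    nontumor_sets = list(c("a"), character(0)),
    pool = c("a", "b", "c"))
  expect_equal(kill_report(inst, character(0)),
               tibble::tibble(tumor_kill_frac = 0, nontumor_kill_frac = 0))
  expect_equal(kill_report(inst, c("a", "b", "c"))$tumor_kill_frac, 1.0)
  expect_equal(kill_report(inst, "a"),
               tibble::tibble(tumor_kill_frac = 2 / 3, nontumor_kill_frac = 0.5))
  expect_error(kill_report(inst, "zzz"), class = "oncohit_error_gene")
})

test_that("single-gene coverage reports per-patient fractions and cohort mean", {
  i1 <- incidence_from_sets(list("a", "a", "a", character(0), "b"),
                            pool = c("a", "b"), patient_id = "p1")
  i2 <- incidence_from_sets(list("a", "a"), pool = c("a", "b"), patient_id = "p2")
  cov <- single_gene_coverage(list(i1, i2), "a")
  expect_equal(cov$per_patient$fraction, c(0.6, 1.0))
  expect_equal(cov$cohort_mean, 0.8)
  expect_error(single_gene_coverage(list(i1), "zzz"), class = "oncohit_error_gene")
})
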