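test_that("low-coverage cell filter uses a strict fewer-than rule and is idempotent", {
  genes <- sprintf("g%03d", 1:100)
  vals <- matrix(0, nrow = 100, ncol = 3,
                 dimnames = list(genes, c("poor", "edge", "rich")))
  vals[1:9, "poor"] <- 1     # 9 < 10% of 100 -> removed
  vals[1:10, "edge"] <- 1    # exactly 10% -> kept
  vals[1:60, "rich"] <- 1
  m <- expression_matrix(vals)
  f <- filter_low_coverage_cells(m, 0.10)
  expect_equal(colnames(f), c("edge", "rich"))
  expect_identical(filter_low_coverage_cells(f, 0.10), f)
  # blood-cancer style 20% threshold on a 50-gene file
  vals50 <- matrix(0, nrow = 50, ncol = 2,
                   dimnames = list(genes[1:50], c("nine", "ten")))
  vals50[1:9, "nine"] <- 1
  vals50[1:10, "ten"] <- 1
  f50 <- filter_low_coverage_cells(expression_matrix(vals50), 0.20)
  expect_equal(colnames(f50), "ten")
  expect_error(filter_low_coverage_cells(expression_matrix(vals50[, 1, drop = FALSE]), 0.5),
               class = "oncohit_error_empty_sample")
})

test_that("gene-pool restriction keeps pool order and reports missing genes", {
  m <- expression_matrix(matrix(1, nrow = 3, ncol = 2,
                                dimnames = list(c("b", "a", "c"), c("x", "y"))))
  expect_message(r <- restrict_gene_pool(m, c("a", "b", "q", "z")), "2 pool gene")
  expect_equal(rownames(r), c("a", "b"))
  expect_equal(attr(r, "missing_genes"), c("q", "z"))
  expect_error(restrict_gene_pool(m, c("q", "z")), class = "oncohit_error_config")
  sup <- restrict_gene_pool(m, c("a", "b", "c"))
  expect_setequal(rownames(sup), rownames(m))
})

test_that("tissue filter requires low mean in both tables and excludes absentees", {
  ta <- tibble::tibble(gene = rep(c("g1", "g2", "g3"), each = 2),
                       tissue = rep(c("t1", "t2"), 3),
                       tpm = c(0.2, 0.2, 0.1, 0.1, 0.1, 0.1))
  tb <- tibble::tibble(gene = rep(c("g1", "g2"), each = 2),
                       tissue = rep(c("t1", "t2"), 2),
                       tpm = c(0.3, 0.3, 0.2, 0.2))
  out <- filter_by_normal_tissue_expression(ta, tb, c("g1", "g2", "g3"), 0.25)
  expect_equal(as.character(out), "g2")          # g1 fails table B, g3 absent from B
  expect_equal(attr(out, "excluded_missing"), "g3")
  expect_error(filter_by_normal_tissue_expression(ta, tb, "g1", -1),
               class = "oncohit_error_config")
})

test_that("tissue filter recovers generator labels and is monotone in threshold", {
  gen <- generate_tissue_tables(n_genes = 100, n_tissues = 8, low_fraction = 0.3,
                                threshold = 1, seed = 7)
  pool <- gen$labels$gene
  out <- filter_by_normal_tissue_expression(gen$table_a, gen$table_b, pool, 1)
  expect_setequal(as.character(out), gen$labels$gene[gen$labels$low_in_both])
  thresholds <- c(0.25, 0.5, 1, 2, 5, 10)
  pools <- lapply(thresholds, function(th) suppressWarnings(
    as.character(filter_by_normal_tissue_expression(gen$table_a, gen$table_b, pool, th))))
  for (i in seq_along(pools)[-1]) {
    expect_true(all(pools[[i - 1]] %in% pools[[i]]))
  }
})

test_that("replicate sampling is deterministic, without replacement, and pass-through", {
  gen <- generate_planted_cohort(plant_spec(n_patients = 1, n_genes = 20,
                                            n_tumor = 40, n_nontumor = 30, k_star = 2,
                                            seed = 3))
  p <- gen$cohort$patients[[1]]
  spec <- replicate_spec(c = 30, n_replicates = 2, seed = 11)
  s1 <- sample_replicate(p, spec, 1)
  s2 <- sample_replicate(p, spec, 1)
  expect_identical(colnames(s1$tumor), colnames(s2$tumor))
  expect_identical(colnames(s1$nontumor), colnames(s2$nontumor))
  ids <- c(colnames(s1$tumor), colnames(s1$nontumor))
  expect_equal(length(ids), 30)
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(ids %in% c(colnames(p$tumor), colnames(p$nontumor))))
  # different replicate index -> different draw (with overwhelming probability)
  s3 <- sample_replicate(p, spec, 2)
  expect_false(identical(colnames(s3$tumor), colnames(s1$tumor)))
  # c >= m returns the patient unchanged
  expect_identical(sample_replicate(p, replicate_spec(c = 500, seed = 11), 1), p)
})

test_that("replicate summaries average feasible solves and flag infeasible ones", {
  res <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 4),
    replicate = rep(1:4, 2),
    status = c(rep("optimal", 4), "optimal", "optimal", "infeasible", "optimal"),
    its_size = c(2, 2, 3, 3, 1, 2, NA, 3))
  s <- summarize_replicates(res)
  expect_equal(s$per_patient$mean_its[s$per_patient$patient_id == "p1"], 2.5)
  expect_equal(s$per_patient$n_infeasible, c(0L, 1L))
  one <- summarize_replicates(res[1, ])
  expect_equal(one$per_patient$mean_its, 2)
  res$cts_size <- rep(c(2, 2, 2, 2), 2)
  expect_equal(summarize_replicates(res)$cohort$mean_cts, 2)
})
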