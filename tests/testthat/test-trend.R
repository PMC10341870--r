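test_that("single-timepoint labels follow the threshold rules with ties to Same", {
  expect_identical(trend_at_3h(0.6), "Up")
  expect_identical(trend_at_3h(-0.6), "Down")
  expect_identical(trend_at_3h(0.5), "Same")   # boundary
  expect_identical(trend_at_3h(-0.5), "Same")  # boundary
  expect_identical(trend_at_3h(0), "Same")
  expect_identical(trend_at_8h(0.6, 1.2), "Up")
  expect_identical(trend_at_8h(-0.6, 0.0), "Up")    # return to baseline
  expect_identical(trend_at_8h(1.7, 1.7), "Same")   # any (x, x)
  expect_identical(trend_at_8h(0.3, 0.8), "Same")   # difference exactly tau
  expect_error(trend_at_3h(NaN), "non-finite")
  expect_error(trend_at_8h(0, Inf), "non-finite")
})

test_that("combined trends match the examples", {
  expect_identical(as.character(combined_trend(0.6, 0.6)), "Up-Same")
  expect_identical(as.character(combined_trend(0, 0)), "Same-Same")
  expect_identical(as.character(combined_trend(0.6, 1.2)), "Up-Up")
  expect_identical(as.character(combined_trend(-0.6, 0)), "Down-Up")
})

test_that("classifier agrees with the rule-table oracle on a threshold-straddling grid", {
  grid <- c(-1.2, -0.6, -0.5, 0, 0.5, 0.6, 1.2)
  for (f1 in grid) for (f2 in grid) {
    expect_identical(as.character(combined_trend(f1, f2)),
                     trend_rule_table_oracle(f1, f2),
                     info = sprintf("f1=%g f2=%g", f1, f2))
  }
})

test_that("both readings of the late fold change give identical labels", {
  # thresholding (logFC_8h - logFC_3h), both vs baseline, equals
  # thresholding the 8h-vs-3h fold change directly: the baseline cancels
  set.seed(12)
  expr <- matrix(runif(900, 0, 200), ncol = 9,
                 dimnames = list(paste0("g", 1:100),
                                 c(paste0("nt", 1:3), paste0("t3_", 1:3),
                                   paste0("t8_", 1:3))))
  nt <- paste0("nt", 1:3); g3 <- paste0("t3_", 1:3); g8 <- paste0("t8_", 1:3)
  fc1 <- group_fold_change(expr, g3, nt)
  fc2 <- group_fold_change(expr, g8, nt)
  fc_8v3 <- group_fold_change(expr, g8, g3)
  expect_identical(trend_at_8h(fc1, fc2), trend_at_3h(fc_8v3))
})

test_that("trend labels obey symmetry and monotonicity", {
  set.seed(3)
  f1 <- runif(300, -3, 3); f2 <- runif(300, -3, 3)
  a <- as.character(combined_trend(f1, f2))
  b <- as.character(combined_trend(-f1, -f2))
  flip <- c("Up-Up" = "Down-Down", "Up-Same" = "Down-Same",
            "Up-Down" = "Down-Up", "Same-Up" = "Same-Down",
            "Same-Same" = "Same-Same", "Same-Down" = "Same-Up",
            "Down-Up" = "Up-Down", "Down-Same" = "Up-Same",
            "Down-Down" = "Up-Up")
  expect_identical(b, unname(flip[a]))
  # increasing f1 never moves the 3 h label downward
  lv <- c(Down = 1, Same = 2, Up = 3)
  x <- sort(runif(100, -2, 2))
  expect_true(all(diff(lv[trend_at_3h(x)]) >= 0))
})

test_that("partition summaries count every gene exactly once", {
  one_each <- combined_trend(c(1, 1, 1, 0, 0, 0, -1, -1, -1),
                             c(2, 1, 0, 1, 0, -1, 0, -1, -2))
  expect_identical(sort(as.character(one_each)),
                   sort(c("Up-Up", "Up-Same", "Up-Down", "Same-Up",
                          "Same-Same", "Same-Down", "Down-Up", "Down-Same",
                          "Down-Down")))
  part <- partition_summary(one_each)
  expect_true(all(part$table$count == 1L))
  expect_equal(sum(part$table$fraction), 1, tolerance = 1e-9)
  expect_identical(sum(part$table$count), part$n)
  expect_identical(unname(part$marginal_3h["Up"]), 3L)
  expect_error(partition_summary(character(0)), "empty")
})

test_that("a flat simulation is almost entirely Same-Same", {
  # at phi = 0.05, n = 3 the log2-FC noise floor is sd ~ 0.26 even for
  # abundant genes, so the joint Same-Same probability cannot exceed ~0.90;
  # the fraction approaches 1 as the dispersion shrinks
  sim <- simulate_experiment(n_genes = 1000, class_fractions = c(flat = 1),
                             seed = 19)
  fit <- wave_fit(sim, condition = "bzATP")
  frac <- with(fit$partition, table$fraction[table$trend == "Same-Same"])
  expect_gt(frac, 0.8)
  sim2 <- simulate_experiment(n_genes = 1000, class_fractions = c(flat = 1),
                              dispersion = 0.01, seed = 19)
  fit2 <- wave_fit(sim2, condition = "bzATP")
  frac2 <- with(fit2$partition, table$fraction[table$trend == "Same-Same"])
  expect_gt(frac2, 0.95)
})

test_that("monotonic gene lists honor strict q and expression filters", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   mean_tmm = c(50, 50, 5, 50),
                   log2fc_3h = c(2, 2, 2, -2), p_3h = c(1e-5, 0.04, 1e-5, 1e-5),
                   q_3h = c(1e-4, 0.05, 1e-4, 1e-4),
                   log2fc_8h = c(4, 4, 4, -4), p_8h = c(1e-6, 1e-6, 1e-6, 1e-6),
                   q_8h = c(1e-5, 1e-5, 1e-5, 1e-5))
  trends <- setNames(c("Up-Up", "Up-Up", "Up-Up", "Down-Down"), de$gene_id)
  got <- monotonic_de_genes(trends, de)
  expect_identical(got$up$gene_id, "a")      # b: q == 0.05 excluded; c: low TMM
  expect_identical(got$down$gene_id, "d")
  # single-timepoint mode readmits the gene failing only at 3 h
  got2 <- monotonic_de_genes(trends, de, both_timepoints = FALSE)
  expect_identical(sort(got2$up$gene_id), c("a", "b"))
  # empty table gives empty lists
  empty <- de[0, ]
  got3 <- monotonic_de_genes(setNames(character(0), character(0)), empty)
  expect_identical(nrow(got3$up), 0L)
  # mismatched universes error
  expect_error(monotonic_de_genes(trends[1:3], de), "different gene sets")
})

test_that("planted monotonic and slow-kinetic genes are recovered", {
  sim <- shared_sim()
  fit <- shared_fit()
  truth <- sim$truth[sim$truth$gene_id %in% fit$de$gene_id, ]
  mono <- monotonic_de_genes(fit$trends, fit$de)
  planted_up <- truth$gene_id[truth$planted_class == "up_up"]
  expect_gte(mean(planted_up %in% mono$up$gene_id), 0.9)
  slow <- slow_kinetic_genes(fit$trends, fit$de)
  planted_slow <- truth$gene_id[truth$planted_class == "same_up"]
  expect_gt(mean(planted_slow %in% slow$gene_id), 0.5)
  expect_true(all(slow$direction[slow$gene_id %in% planted_slow] == "up"))
  # an impossible q threshold empties the list
  expect_identical(nrow(slow_kinetic_genes(fit$trends, fit$de, q_max = 0)), 0L)
})

test_that("a flat simulation yields no slow-kinetic calls", {
  sim <- simulate_experiment(n_genes = 800, class_fractions = c(flat = 1),
                             seed = 29)
  fit <- wave_fit(sim, condition = "bzATP_LPS")
  expect_identical(nrow(slow_kinetic_genes(fit$trends, fit$de)), 0L)
})
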