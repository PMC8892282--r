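# Differential expression: log2 fold change, Welch tests with BH
# adjustment, the up-regulation partition, relative abundance to the
# minimum sample.

test_that("log2 fold change is the difference of mean log2 abundances", {
  am <- tiny_matrix(matrix(c(8, 8, 4, 4), 1, 4,
                           dimnames = list("P1", NULL)))
  fc <- log2_fold_change(am, c(TRUE, TRUE, FALSE, FALSE),
                         c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(fc), 1.0)  # log2(8) - log2(4)

  same <- log2_fold_change(am, c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(same), 0)

  zero <- tiny_matrix(matrix(c(0, 2, 2, 2), 1, 4,
                             dimnames = list("P1", NULL)))
  expect_error(log2_fold_change(zero, 1:2, 3:4), "preprocess")
})

test_that("fold change is antisymmetric in the groups", {
  set.seed(21)
  am <- tiny_matrix(matrix(2^rnorm(60, 10, 1), 10, 6))
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(log2_fold_change(am, a, !a), -log2_fold_change(am, !a, a))
})

test_that("degenerate groups get the documented sentinel p-values", {
  am <- tiny_matrix(matrix(c(2, 2, 2, 2), 1, 4,
                           dimnames = list("P1", NULL)))
  dep <- dep_test(am, 1:2, 3:4)
  expect_equal(dep$p_value, 1)
  expect_equal(dep$log2fc, 0)

  sep <- tiny_matrix(matrix(c(4, 4, 2, 2), 1, 4,
                            dimnames = list("P1", NULL)))
  dsep <- dep_test(sep, 1:2, 3:4)
  expect_equal(dsep$p_value, .Machine$double.xmin)
  expect_equal(dsep$flag, "zero-variance-separated")

  one <- tiny_matrix(matrix(c(4, 2), 1, 2, dimnames = list("P1", NULL)))
  d1 <- dep_test(one, 1, 2)
  expect_true(is.na(d1$p_value))
  expect_equal(d1$log2fc, 1)
  expect_equal(d1$flag, "insufficient-replicates")
})

test_that("per-protein p-values match a direct Welch t-test", {
  set.seed(22)
  am <- tiny_matrix(matrix(2^rnorm(48, 12, 1), 8, 6))
  dep <- dep_test(am, 1:3, 4:6)
  for (i in 1:8) {
    ref <- t.test(log2(am$values[i, 1:3]), log2(am$values[i, 4:6]),
                  var.equal = FALSE)$p.value
    expect_equal(dep$p_value[i], ref)
  }
  expect_equal(dep$q_value, p.adjust(dep$p_value, "BH"))
})

test_that("the Welch null is calibrated near the nominal level", {
  # identically distributed groups (n = 10 per side; at very small n the
  # Welch approximation is conservative) over 2000 null proteins
  set.seed(23)
  m <- 2000
  am <- tiny_matrix(matrix(2^rnorm(m * 20, 15, 0.5), m, 20))
  dep <- dep_test(am, 1:10, 11:20)
  rate <- mean(dep$p_value <= 0.05)
  half <- 1.96 * sqrt(0.05 * 0.95 / m)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("planted log2 effects are recovered at the 0.5 cutoff", {
  # delta = 1.0 on 50 of 500 proteins, n = 3, within-group sd 0.3
  sim <- simulate_abundance_experiment(
    n_proteins = 500, conditions = c("TWO_D", "THREE_D"),
    fractions = "SURFACE", n_replicates = 3, base_log2_sd = 0.3,
    planted_effects = data.frame(accession = sprintf("SYN%05d", 1:50),
                                 condition = "THREE_D", fraction = "*",
                                 delta = 1.0),
    missing_intercept = -Inf, seed = 24)
  fc <- log2_fold_change(sim$matrix, "condition:THREE_D", "condition:TWO_D")
  planted <- names(fc) %in% sprintf("SYN%05d", 1:50)
  sensitivity <- mean(fc[planted] >= 0.5)
  fpr <- mean(fc[!planted] >= 0.5)
  expect_gte(sensitivity, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("the up-regulation partition enumerates disjoint sets at an inclusive cutoff", {
  part <- upregulated_partition(c(A = 0.6, B = 0.6, C = 0.1),
                                c(A = 0.1, B = 0.7, C = 0.7))
  expect_equal(part$surface_only, "A")
  expect_equal(part$both, "B")
  expect_equal(part$endocytosed_only, "C")

  none <- upregulated_partition(c(A = 0, B = 0), c(A = 0, B = 0))
  expect_length(c(none$surface_only, none$both, none$endocytosed_only), 0)

  # cutoff is inclusive: exactly 0.5 counts as up-regulated
  edge <- upregulated_partition(c(A = 0.5), c(A = 0.49999))
  expect_equal(edge$surface_only, "A")

  # a protein missing from one fraction is not up-regulated there
  partial <- upregulated_partition(c(A = 1.0), c(B = 1.0))
  expect_equal(partial$surface_only, "A")
  expect_equal(partial$endocytosed_only, "B")
})

test_that("partition sets are disjoint and cover all above-cutoff proteins", {
  set.seed(25)
  for (rep in 1:10) {
    ids <- sprintf("P%02d", 1:40)
    s <- setNames(rnorm(40, 0, 0.7), ids)
    e <- setNames(rnorm(40, 0, 0.7), ids)
    part <- upregulated_partition(s, e)
    sets <- list(part$surface_only, part$both, part$endocytosed_only)
    expect_equal(sum(lengths(sets)), length(unique(unlist(sets))))
    expect_setequal(unlist(sets), ids[s >= 0.5 | e >= 0.5])
  }
})

test_that("relative abundance to the minimum sample is a nonnegative log2 ratio", {
  am <- tiny_matrix(matrix(c(2, 4, 16), 1, 3, dimnames = list("P1", NULL)))
  expect_equal(unname(relative_abundance_to_min(am)[1, ]), c(0, 1, 3))

  const <- tiny_matrix(matrix(5, 1, 3, dimnames = list("P1", NULL)))
  expect_equal(unname(relative_abundance_to_min(const)[1, ]), c(0, 0, 0))

  tie <- tiny_matrix(matrix(c(2, 2, 8), 1, 3, dimnames = list("P1", NULL)))
  expect_equal(unname(relative_abundance_to_min(tie)[1, ]), c(0, 0, 2))

  set.seed(26)
  big <- tiny_matrix(matrix(2^rnorm(50, 10, 2), 10, 5))
  rel <- relative_abundance_to_min(big)
  expect_true(all(rel >= 0))
  expect_true(all(apply(rel, 1, function(r) any(r == 0))))
})
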