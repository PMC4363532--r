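test_that("planted blocks control the population correlation structure", {
  # perfectly collinear pair: target 1, no noise
  ds <- simulate_expression(n_genes = 3, n_disease = 8, n_normal = 8,
                            blocks = list(correlation_block(1:2, 1.0)),
                            seed = 7)
  expect_equal(cor(ds$values["g01", ], ds$values["g02", ]), 1.0)

  # planted values recovered within sampling error at n = 200 per group
  blocks <- list(correlation_block(1:2, 0.9, "normal"),
                 correlation_block(3:4, -0.8, "disease"),
                 correlation_block(5:7, 0.95))
  ds <- simulate_expression(n_genes = 8, n_disease = 200, n_normal = 200,
                            blocks = blocks, seed = 11)
  v_n <- ds$values[, ds$groups == "normal"]
  v_d <- ds$values[, ds$groups == "disease"]
  expect_equal(cor(v_n["g01", ], v_n["g02", ]), 0.9, tolerance = 0.1)
  expect_lt(abs(cor(v_d["g01", ], v_d["g02", ])), 0.3)
  expect_equal(cor(v_d["g03", ], v_d["g04", ]), -0.8, tolerance = 0.1)
  expect_equal(cor(v_n["g05", ], v_n["g06", ]), 0.95, tolerance = 0.1)
  expect_equal(cor(v_d["g06", ], v_d["g07", ]), 0.95, tolerance = 0.1)
  expect_true(all(is.finite(ds$values)))
})

test_that("unplanted genes stay uncorrelated (Fisher-z bound at n = 5000)", {
  ds <- simulate_expression(n_genes = 10, n_disease = 5000, n_normal = 5000,
                            seed = 42)
  for (g in c("disease", "normal")) {
    cm <- cor(t(ds$values[, ds$groups == g]))
    expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)
  }
})

test_that("simulation is bit-reproducible for a fixed seed", {
  b <- list(correlation_block(1:3, 0.5))
  a1 <- simulate_expression(blocks = b, seed = 123, noise_sd = 0.5)
  a2 <- simulate_expression(blocks = b, seed = 123, noise_sd = 0.5)
  expect_identical(a1$values, a2$values)
  a3 <- simulate_expression(blocks = b, seed = 124, noise_sd = 0.5)
  expect_false(identical(a1$values, a3$values))
})

test_that("degenerate configurations are rejected with clear errors", {
  # non-PSD uniform block: 3 genes at r = -0.9
  expect_error(correlation_block(1:3, -0.9), "positive semi-definite")
  # overlapping blocks within one group
  expect_error(
    simulate_expression(blocks = list(correlation_block(1:3, 0.5),
                                      correlation_block(3:4, 0.5)),
                        seed = 1),
    "overlap")
  # the same gene may appear in different groups' blocks
  expect_s3_class(
    simulate_expression(blocks = list(correlation_block(1:2, 0.5, "normal"),
                                      correlation_block(2:3, 0.5, "disease")),
                        seed = 1),
    "expression_dataset")
  expect_error(simulate_expression(n_disease = 2, seed = 1), "at least 3")
  expect_error(correlation_block(c(1, 1), 0.5), "distinct")
  expect_error(correlation_block(1:2, 1.2), "\\[-1, 1\\]")
})

test_that("noise_sd attenuates planted correlations by 1/(1 + sd^2)", {
  ds <- simulate_expression(n_genes = 2, n_disease = 4000, n_normal = 3,
                            blocks = list(correlation_block(1:2, 0.9)),
                            noise_sd = 1, seed = 5)
  v <- ds$values[, ds$groups == "disease"]
  expect_equal(cor(v[1, ], v[2, ]), 0.45, tolerance = 0.05)
})

test_that("the planted fixture has the study dimensions and labelled truth", {
  fx <- simulate_planted_fixture(seed = 99)
  expect_equal(dim(fx$dataset$values), c(20, 24))
  expect_equal(sum(fx$dataset$groups == "disease"), 16)
  expect_equal(sum(fx$dataset$groups == "normal"), 8)
  expect_setequal(unique(fx$planted$category),
                  c("normal_specific", "common", "disease_specific",
                    "absent"))
  counts <- table(fx$planted$category)
  expect_equal(as.integer(counts[c("normal_specific", "common",
                                   "disease_specific", "absent")]),
               c(66L, 3L, 1L, 3L))
  # a negative correlation is planted (sign must be erased downstream)
  tab <- coexpression_table(fx$dataset)
  pair <- tab[tab$gene_a == "g16" & tab$gene_b == "g17", ]
  expect_lt(pair$r_d, 0)
  expect_equal(pair$C_d, abs(pair$r_d))
})
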