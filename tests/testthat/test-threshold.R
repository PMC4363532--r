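test_that("survival fractions use an inclusive >= and the exact grid", {
  tab <- counted_pair_table(3, 0, 0)
  tab$C_d <- c(0.2, 0.6, 0.8); tab$C_n <- c(0.5, 0.5, 0.5)
  cv <- survival_curves(tab)
  at <- function(t) cv$F_d[match(t, cv$thresholds)]
  expect_equal(at(0), 1.0)              # every C >= 0
  expect_equal(at(0.6), 2 / 3)          # direct count, inclusive
  expect_equal(at(0.8), 1 / 3)
  expect_equal(cv$F_n[match(0.5, cv$thresholds)], 1.0)  # all at 0.5, >= 0.5
  expect_equal(cv$F_d[match(1, cv$thresholds)], 0)

  # monotone non-increasing, multiples of 1/n_pairs
  expect_true(all(diff(cv$F_d) <= 0))
  expect_true(all(diff(cv$F_n) <= 0))
  expect_equal(cv$F_d * cv$n_pairs, round(cv$F_d * cv$n_pairs))
})

test_that("survival curves are monotone on random tables (property)", {
  for (seed in 1:20) {
    cv <- survival_curves(random_pair_table(n_genes = 8, seed = seed))
    expect_true(all(diff(cv$F_d) <= 0))
    expect_true(all(diff(cv$F_n) <= 0))
    expect_equal(cv$F_d[1], 1)
    expect_equal(cv$F_n[1], 1)
    expect_equal(cv$F_d[length(cv$thresholds)], 0)
  }
})

test_that("optimal_threshold finds the maximum deviation", {
  # published strong-pair fractions: |98/190 - 45/190| = 0.2789
  tab <- counted_pair_table(190, 45, 98, n_common = 27)
  opt <- optimal_threshold(survival_curves(tab))
  expect_equal(round(opt$D, 4), 0.2789)
  expect_equal(opt$C_star, 0.9)

  # identical distributions -> D = 0
  same <- random_pair_table(n_genes = 6, seed = 2)
  same$C_n <- same$C_d
  expect_equal(optimal_threshold(survival_curves(same))$D, 0)

  # complete separation -> D = 1
  sep <- counted_pair_table(10, 0, 10, n_common = 0,
                            strong = 0.9, weak = 0.1)
  opt2 <- optimal_threshold(survival_curves(sep))
  expect_equal(opt2$D, 1.0)
  expect_equal(opt2$C_star, 0.9)
})

test_that("optimal_threshold agrees with a brute-force scan (oracle)", {
  brute <- function(tab) {
    cand <- sort(unique(c(0, tab$C_d, tab$C_n, 1)))
    best <- list(D = -1, C = NA)
    for (t in cand) {
      d <- abs(mean(tab$C_d >= t) - mean(tab$C_n >= t))
      if (d > best$D || (d == best$D && t > best$C))
        best <- list(D = d, C = t)
    }
    best
  }
  for (seed in 1:50) {
    tab <- random_pair_table(n_genes = sample(3:10, 1), seed = seed)
    opt <- optimal_threshold(survival_curves(tab))
    ref <- brute(tab)
    expect_equal(opt$D, ref$D)
    expect_equal(opt$C_star, ref$C)
  }
})

test_that("asymptotic KS p-value matches the Kolmogorov tail", {
  expect_equal(ks_pvalue(0, 190, 190), 1)
  # lambda = 1.358 is the classical 5% critical point
  expect_equal(ks_pvalue(1.358 / sqrt(190 / 2), 190, 190), 0.05,
               tolerance = 2e-3)
  expect_lt(ks_pvalue(0.2789, 190, 190), 0.01)
  expect_lt(ks_pvalue(1, 190, 190), 1e-10)

  # cross-check against stats::ks.test's asymptotic two-sample p-value
  set.seed(1)
  x <- rnorm(300); y <- rnorm(300, 0.15)
  ref <- suppressWarnings(ks.test(x, y, exact = FALSE))
  D <- unname(ref$statistic)
  expect_equal(ks_pvalue(D, 300, 300), ref$p.value, tolerance = 1e-4)
})

test_that("dichotomize counts are inclusive and consistent with the curves", {
  tab <- counted_pair_table(190, 45, 98, n_common = 27)
  ct <- dichotomize(tab, 0.9)
  expect_equal(unname(ct), matrix(c(45, 145, 98, 92), 2))
  expect_equal(colSums(ct), c(disease = 190, normal = 190))

  # C_star = 0 -> everything strong
  ct0 <- dichotomize(tab, 0)
  expect_equal(unname(ct0["strong", ]), c(190, 190))

  # a pair exactly at the threshold counts as strong
  one <- counted_pair_table(1, 1, 0, n_common = 0, strong = 0.7)
  expect_equal(unname(dichotomize(one, 0.7)["strong", "disease"]), 1)

  # identity with the survival fractions at the fitted threshold
  rt <- random_pair_table(n_genes = 9, seed = 5)
  cv <- survival_curves(rt)
  opt <- optimal_threshold(cv)
  ct2 <- dichotomize(rt, opt$C_star)
  i <- match(opt$C_star, cv$thresholds)
  expect_equal(ct2["strong", "disease"], cv$n_pairs * cv$F_d[i])
  expect_equal(ct2["strong", "normal"], cv$n_pairs * cv$F_n[i])
})

test_that("chi-square is uncorrected Pearson on 2x2 counts", {
  # closed-form oracle: N (ad - bc)^2 / (r1 r2 c1 c2)
  closed_form <- function(m) {
    sum(m) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m), colSums(m))
  }
  m1 <- matrix(c(45, 145, 98, 92), 2)
  expect_equal(round(chi_square(m1)$chi2, 4), 31.4957)
  expect_equal(chi_square(m1)$chi2, closed_form(m1), tolerance = 1e-12)
  expect_lt(chi_square(m1)$p, 0.01)

  expect_equal(chi_square(matrix(c(50, 50, 50, 50), 2))$chi2, 0)
  m3 <- matrix(c(10, 30, 20, 40), 2)
  expect_equal(round(chi_square(m3)$chi2, 4), 0.7937)
  expect_equal(chi_square(m3)$chi2, closed_form(m3), tolerance = 1e-12)

  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "marginals")
})

test_that("undefined pairs are dropped from curves and counts", {
  tab <- random_pair_table(n_genes = 5, seed = 6)
  tab$C_d[1] <- NA; tab$r_d[1] <- NA
  expect_message(cv <- survival_curves(tab), "dropped")
  expect_equal(cv$n_pairs, 9)
  expect_equal(unname(colSums(dichotomize(tab, 0.5))), c(9, 9))
})
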