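test_that("noise-free linear data returns the exact intercept", {
  set.seed(81)
  g <- runif(3000, 0, 100)
  expect_equal(null_model_llg(g, 2 * g + 50), 50, tolerance = 1e-6)
  expect_equal(null_model_llg(g, -1.3 * g + 120), 120, tolerance = 1e-6)
})

test_that("the trimmed-bin fit recovers the intercept on noisy data", {
  # The iterative one-sided trim (drop points 1 sigma below the bin mean,
  # repeat to stability) shifts every bin mean up by a fixed amount on pure
  # Gaussian noise; compute that offset with an independent inline oracle and
  # check the fitted intercept equals true intercept + offset.
  trim_oracle <- function(x) {
    repeat {
      m <- mean(x); s <- sd(x)
      if (is.na(s) || s == 0) break
      keep <- x >= m - s
      if (all(keep)) break
      x <- x[keep]
    }
    mean(x)
  }
  set.seed(82)
  bias <- trim_oracle(rnorm(2e5, 0, 5))
  g <- runif(2000, 0, 100)
  l <- 2 * g + 50 + rnorm(2000, 0, 5)
  expect_equal(null_model_llg(g, l), 50 + bias, tolerance = 2)
  # on the realistic pattern -- a tight line plus sparse low outliers, which
  # the trim exists to reject -- the intercept comes back nearly unbiased
  l2 <- 2 * g + 50 + rnorm(2000, 0, 0.5)
  low <- sample(2000, 100)
  l2[low] <- l2[low] - runif(100, 20, 80)
  expect_equal(null_model_llg(g, l2), 50, tolerance = 1.5)
})

test_that("data confined to high GDT_HA cannot define a null model", {
  set.seed(83)
  g <- runif(500, 40, 100)
  expect_error(null_model_llg(g, 2 * g + 50), class = "rellg_null_undefined")
})

test_that("dLLG subtracts the null and floors at zero", {
  expect_equal(dllg(100, 40), 60)
  expect_equal(dllg(30, 40), 0)
  expect_equal(dllg(40, 40), 0)
  expect_equal(dllg(c(-5, 45, 200), 40), c(0, 5, 160))
})

test_that("two-pass Z-scores match the hand-computed population-SD case", {
  tab <- data.frame(group = c("a", "b", "c", "d"), target = "T1", model = 1,
                    score = c(10, 10, 10, 0))
  r <- zscore_ranking(tab)
  # pass-1 Z of the zero scorer is -1.732 (population SD 4.330): NOT an
  # outlier, so pass 2 changes nothing and the floor never engages
  expect_equal(unname(r$z["T1", ]), c(0.5773503, 0.5773503, 0.5773503, -1.7320508),
               tolerance = 1e-6)
})

test_that("equal scores give zero Z-scores and are flagged degenerate", {
  tab <- data.frame(group = c("a", "b", "c"), target = "T1", model = 1, score = 5)
  r <- zscore_ranking(tab)
  expect_equal(unname(r$z["T1", ]), c(0, 0, 0))
  expect_identical(r$degenerate_targets, "T1")
})

test_that("a genuine outlier is excluded and floored at -2", {
  tab <- data.frame(group = letters[1:6], target = "T1", model = 1,
                    score = c(10, 11, 9, 10, 10, -200))
  r <- zscore_ranking(tab)
  expect_equal(unname(r$z["T1", "f"]), -2)
  # after exclusion the others are scored against their own spread
  expect_true(all(abs(r$z["T1", letters[1:5]]) < 2))
})

test_that("Z-scores are invariant under positive affine score transforms", {
  tab <- make_score_table(n_groups = 6, n_targets = 4, noise_sd = 3, seed = 84)
  r1 <- zscore_ranking(tab)
  tab2 <- tab; tab2$score <- 3.7 * tab2$score + 11
  r2 <- zscore_ranking(tab2)
  expect_equal(r1$z, r2$z, tolerance = 1e-9)
})

test_that("ranking recovers a planted skill order and penalizes missing models", {
  tab <- make_score_table(n_groups = 8, n_targets = 6, noise_sd = 0, seed = 85)
  r <- zscore_ranking(tab)
  expect_identical(r$groups$group, sprintf("G%02d", 1:8))  # planted order
  miss <- data.frame(group = "G03", target = c("T01", "T02", "T03"))
  rm_ <- zscore_ranking(make_score_table(n_groups = 8, n_targets = 6,
                                         noise_sd = 0, missing = miss, seed = 85))
  expect_equal(rm_$groups$n_missing[rm_$groups$group == "G03"], 3)
  # the penalty is exactly -2 per missing target
  z_present <- sum(rm_$z[c("T04", "T05", "T06"), "G03"])
  expect_equal(rm_$groups$sum_z[rm_$groups$group == "G03"], z_present - 6)
  expect_error(zscore_ranking(data.frame(group = "a", target = "T", model = 1,
                                         score = 1)),
               class = "rellg_ranking")
})
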