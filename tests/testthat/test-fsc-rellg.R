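# synthetic E-value sets on a fake shell layout, for testing the FSC / eLLG
# accumulation in isolation from the structure-factor machinery
fake_E <- function(Et, Em, n_per_shell) {
  shell <- rep(seq_along(n_per_shell), n_per_shell)
  list(Et = Et, Em = Em, shell = shell,
       shells = data.frame(n = n_per_shell,
                           s_mean = seq(0.1, 0.5, length.out = length(n_per_shell))))
}

test_that("self-correlation gives FSC = 1 in every shell", {
  set.seed(51)
  E <- complex(real = rnorm(3000), imaginary = rnorm(3000))
  fc <- fsc_curve(fake_E(E, E, c(1000, 1000, 1000)))
  expect_equal(fc$fsc, rep(1, 3), tolerance = 1e-12)
})

test_that("independent random phases give near-zero FSC", {
  set.seed(52)
  n <- 4000
  Et <- complex(modulus = 1, argument = runif(n, -pi, pi))
  Em <- complex(modulus = 1, argument = runif(n, -pi, pi))
  fc <- fsc_curve(fake_E(Et, Em, c(2000, 2000)))
  expect_true(all(abs(fc$fsc_raw) < 0.1))
})

test_that("negative raw FSC is clamped to zero for scoring", {
  set.seed(53)
  E <- complex(real = rnorm(500), imaginary = rnorm(500))
  fc <- fsc_curve(fake_E(E, -E, 500))
  expect_equal(fc$fsc_raw, -1, tolerance = 1e-12)
  expect_equal(fc$fsc, 0)
  expect_equal(ellg_from_fsc(fc), 0)
})

test_that("eLLG accumulates n FSC^4 / 2 over shells", {
  expect_equal(ellg_from_fsc(data.frame(n = c(50, 70), fsc = 0)), 0)
  expect_equal(ellg_from_fsc(data.frame(n = c(50, 70), fsc = 1)), 60)  # N/2
  expect_equal(ellg_from_fsc(data.frame(n = c(100, 200), fsc = c(0.5, 0.8))),
               44.085)
  # monotone in any shell's FSC
  base <- data.frame(n = c(100, 200), fsc = c(0.5, 0.8))
  up <- base; up$fsc[1] <- 0.6
  expect_gt(ellg_from_fsc(up), ellg_from_fsc(base))
})

test_that("the ideal eLLG matches sigmaA(0.4)^4 / 2 accumulation", {
  expect_equal(ideal_ellg(rep(0, 10)), 5)                  # sigmaA = 1 at s = 0
  expect_equal(ideal_ellg(rep(0.5, 100)), 17.4487, tolerance = 1e-4)
  s <- runif(500, 0, 0.5)
  expect_lt(ideal_ellg(s), 250)                            # < N/2 for rmsd > 0
})

test_that("a model identical to the target scores FSC 1 and the exact ratio", {
  tgt <- make_toy_structure(15, "helix", seed = 55)
  # identical B profiles too: constant-B weighting sets the model's B to 25,
  # and the target keeps its file B-factors, so give it the same constant
  tgt$atoms$bfield <- 25
  fit <- rellg(tgt, tgt, weighting = "constant")
  expect_true(all(fit$fsc$fsc > 1 - 1e-6))
  expect_equal(fit$ellg, sum(fit$fsc$n) / 2, tolerance = 1e-5)
  expect_equal(fit$rellg, (fit$n_terms / 2) / fit$ellg_ideal, tolerance = 1e-5)
  expect_gt(fit$rellg, 1)
})

test_that("an unrelated structure scores essentially zero", {
  tgt <- make_toy_structure(40, "random-coil", seed = 56)
  un <- make_toy_structure(40, "random-coil", seed = 57)
  un <- apply_pose(un, trans = tgt$center - un$center)
  fit <- rellg(tgt, un, weighting = "constant", refine_pose = FALSE)
  expect_lt(fit$rellg, 0.05)
})

test_that("scoring failures are mapped to zero-score results with reasons", {
  tgt <- make_toy_structure(20, "helix", seed = 58)
  # unfolded-chain stand-in: one atom flung out so the grid explodes
  wide <- tgt$atoms; wide$x[1] <- 900
  fit <- rellg(tgt, rellg:::new_model(wide, "b_factor"), weighting = "as_is",
               max_grid_points = 1e5)
  expect_s3_class(fit, "rellg")
  expect_equal(fit$rellg, 0)
  expect_match(fit$failure, "memory bound")
  # error estimates so large every atom is downweighted to nothing
  dead <- degrade(tgt, 0.2, seed = 59)
  dead$atoms$bfield <- rep(100, nrow(dead$atoms))
  fit2 <- rellg(tgt, dead, weighting = "error")
  expect_equal(fit2$rellg, 0)
  expect_false(is.null(fit2$failure))
})

test_that("rellg objects expose the standard fitted-model methods", {
  tgt <- make_toy_structure(12, "helix", seed = 60)
  mdl <- degrade(tgt, 0.5, seed = 61)
  fit <- rellg(tgt, mdl, weighting = "error")
  expect_named(coef(fit), c("rmsd", "rot_x", "rot_y", "rot_z",
                            "trans_x", "trans_y", "trans_z"))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$llg)
  expect_output(print(fit), "reLLG")
  expect_output(print(summary(fit)), "Fourier shell correlation")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
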