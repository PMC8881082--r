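test_that("the virtual cell encloses both structures with padding, deterministically", {
  a <- make_toy_structure(10, "helix", seed = 1)
  b <- apply_pose(a, trans = c(3, 0, 0))
  cell <- build_cell(a, b, pad = 10)
  span <- apply(rbind(model_xyz(a), model_xyz(b)), 2, function(v) diff(range(v)))
  expect_true(all(cell$abc >= span + 20))
  expect_identical(cell, build_cell(a, b, pad = 10))
  expect_true(all(cell$abc / cell$ngrid <= cell$d_min / 3))
  expect_error(build_cell(a, b, max_grid_points = 1000), class = "rellg_oversize")
})

test_that("direct summation matches a plain R oracle on a small system", {
  set.seed(11)
  m <- tiny_model(matrix(runif(15, 0, 8), ncol = 3),
                  bfield = runif(5, 0, 30), element = c("C", "N", "O", "C", "S"),
                  occ = c(1, 1, 0.5, 1, 0.3))
  cell <- build_cell(m, m, pad = 6)
  terms <- rellg:::make_hkl(cell)
  F_cpp <- compute_structure_factors(m, cell, terms, method = "direct")$F
  # independent oracle: literal sum in R
  frac <- sweep(model_xyz(m), 2, cell$origin) / rep(cell$abc, each = 5)
  F_r <- vapply(seq_along(terms$s), function(i) {
    s <- terms$s[i]
    ph <- 2 * pi * as.numeric(frac %*% terms$hkl[i, ])
    f <- vapply(m$atoms$element, rellg:::form_factor, numeric(1), s = s)
    sum(m$atoms$occ * f * exp(-m$atoms$bfield * s^2 / 4) * exp(1i * ph))
  }, complex(1))
  expect_lt(max(Mod(F_cpp - F_r)) / sqrt(mean(Mod(F_r)^2)), 1e-10)
})

test_that("a single atom at the origin has zero phase everywhere", {
  m <- tiny_model(matrix(c(0, 0, 0), 1), bfield = 5)
  cell <- rellg:::build_cell(m, m, pad = 8)
  # put the cell origin at the atom so fractional coordinates are zero
  cell$origin <- c(0, 0, 0)
  F <- compute_structure_factors(m, cell, method = "direct")$F
  expect_lt(max(abs(Arg(F))), 1e-12)
  expect_true(all(Mod(F) > 0))
})

test_that("translation shifts phases by exactly 2 pi h.t (Fourier shift theorem)", {
  m <- make_toy_structure(6, "helix", seed = 2)
  t_vec <- c(1.7, -0.9, 0.4)
  ms <- apply_pose(m, trans = t_vec)
  cell <- build_cell(m, ms)
  terms <- rellg:::make_hkl(cell)
  w <- apply_error_weighting(degrade(m, 0, seed = 1), "constant")
  ws <- apply_error_weighting(degrade(ms, 0, seed = 1), "constant")
  F1 <- compute_structure_factors(w, cell, terms)$F
  F2 <- compute_structure_factors(ws, cell, terms)$F
  phase <- exp(1i * 2 * pi * as.numeric(terms$hkl %*% (t_vec / cell$abc)))
  expect_lt(max(Mod(F2 - F1 * phase) / Mod(F1)), 1e-9)
  expect_equal(Mod(F2), Mod(F1), tolerance = 1e-12)  # |F| unchanged
})

test_that("B damping multiplies amplitudes by exp(-B s^2 / 4)", {
  xyz <- matrix(runif(9, 0, 5), ncol = 3)
  m0 <- tiny_model(xyz, bfield = 0)
  mb <- tiny_model(xyz, bfield = 18)
  cell <- build_cell(m0, m0, pad = 8)
  terms <- rellg:::make_hkl(cell)
  F0 <- compute_structure_factors(m0, cell, terms)$F
  Fb <- compute_structure_factors(mb, cell, terms)$F
  expect_equal(Fb, F0 * exp(-18 * terms$s^2 / 4), tolerance = 1e-12)
})

test_that("FFT and direct-summation paths agree to the 0.5% contract", {
  tgt <- make_toy_structure(40, "random-coil", seed = 3)   # 200 atoms
  m <- apply_error_weighting(degrade(tgt, 0.3, seed = 4), "error")
  cell <- build_cell(tgt, tgt)
  terms <- rellg:::make_hkl(cell)
  Fd <- compute_structure_factors(m, cell, terms, method = "direct")$F
  Ff <- compute_structure_factors(m, cell, terms, method = "fft")$F
  # scale-relative (R-factor style) error, overall and in the outermost data
  expect_lt(sqrt(sum(Mod(Ff - Fd)^2) / sum(Mod(Fd)^2)), 0.005)
  hi <- terms$s > 0.45
  expect_lt(sqrt(sum(Mod(Ff[hi] - Fd[hi])^2) / sum(Mod(Fd[hi])^2)), 0.005)
})

test_that("E-normalization gives unit mean-squared amplitude per shell", {
  tgt <- make_toy_structure(25, "random-coil", seed = 5)
  mdl <- degrade(tgt, 0.5, seed = 6)
  cell <- build_cell(tgt, mdl)
  terms <- rellg:::make_hkl(cell)
  ft <- compute_structure_factors(tgt, cell, terms)
  fm <- compute_structure_factors(apply_error_weighting(mdl, "constant"), cell, terms)
  E <- normalize_to_E(ft, fm)
  for (k in unique(E$shell)) {
    expect_equal(mean(Mod(E$Et[E$shell == k])^2), 1, tolerance = 1e-6)
    expect_equal(mean(Mod(E$Em[E$shell == k])^2), 1, tolerance = 1e-6)
  }
  # identical inputs normalize identically; scaling leaves E unchanged
  E2 <- normalize_to_E(ft, ft)
  expect_equal(E2$Et, E2$Em)
  ft_scaled <- ft; ft_scaled$F <- 7.3 * ft$F
  E3 <- normalize_to_E(ft_scaled, fm)
  expect_equal(E3$Et, E$Et, tolerance = 1e-12)
})
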