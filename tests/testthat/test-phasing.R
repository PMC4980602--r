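test_that("heavy-atom structure factors match the direct oracle", {
  cell <- rubredoxin_cell()
  site <- c(0.21, 0.37, 0.08)
  b <- complex(real = -8, imaginary = 8.4615)
  hkl <- rbind(c(1, 2, 3), c(2, 1, 4), c(3, 3, 1), c(0, 1, 2))
  fh <- heavy_atom_sf(rbind(site), hkl, b, cell, B = 12)
  model <- structure(list(
    cell = cell, ops = p212121_ops(),
    atoms = data.frame(isotope = "site", x = site[1], y = site[2],
                       z = site[3], occ = 1, B = 12,
                       b_real = Re(b), b_imag = Im(b))),
    class = "nsad_model")
  expect_lt(max(Mod(fh$plus - sf_direct(model, hkl))) /
              max(Mod(fh$plus)), 1e-10)
  expect_lt(max(Mod(fh$minus - sf_direct(model, -hkl))) /
              max(Mod(fh$minus)), 1e-10)
})

test_that("real-b substructure factors obey Friedel conjugation", {
  cell <- rubredoxin_cell()
  hkl <- rbind(c(1, 2, 3), c(2, 1, 4), c(4, 2, 2))
  fh <- heavy_atom_sf(rbind(c(0.1, 0.2, 0.3)), hkl,
                      complex(real = -8, imaginary = 0), cell)
  expect_lt(max(Mod(fh$minus - Conj(fh$plus))) / max(Mod(fh$plus)), 1e-10)
  # and with b'' > 0 the law is broken
  fh2 <- heavy_atom_sf(rbind(c(0.1, 0.2, 0.3)), hkl,
                       complex(real = -8, imaginary = 8), cell)
  expect_gt(max(Mod(fh2$minus - Conj(fh2$plus))), 1e-3)
})

# shared noiseless phasing fixture at reduced scale
phasing_fixture <- function(seed = 3, noise_frac = 0, multiplicity = 1,
                            sim_seed = seed + 100) {
  model <- generate_toy_structure(120, seed = seed)
  obs <- simulate_unmerged(model, d_min = 2.3, multiplicity = multiplicity,
                           noise_frac = noise_frac,
                           floor_frac = if (noise_frac == 0) 0 else 0.01,
                           seed = sim_seed)
  merged <- merge_observations(obs)
  truth <- as.numeric(model$atoms[model$anomalous_site, c("x", "y", "z")])
  b_cd <- model$atoms$b_imag[model$anomalous_site]
  list(model = model, merged = merged, truth = truth,
       b = complex(real = -8, imaginary = b_cd))
}

test_that("SAD phases are well-formed with calibrated figures of merit", {
  fx <- phasing_fixture()
  hkl <- as.matrix(fx$merged[, c("h", "k", "l")])
  fh <- heavy_atom_sf(rbind(fx$truth), hkl, fx$b, fx$model$cell)
  ps <- sad_phases(fx$merged, fh)
  expect_true(all(ps$fom >= 0 & ps$fom <= 1))
  expect_true(all(ps$phi >= 0 & ps$phi < 2 * pi))
  # centric reflections carry no Bijvoet signal: FOM is damped to 0
  expect_true(all(ps$fom[ps$centric] == 0))
  tps <- true_phase_set(fx$model, hkl)
  mae <- phase_error(ps, tps)
  wmae <- phase_error(ps, tps, weighted = TRUE)
  expect_lt(mae, 70)          # far better than the 90 deg random baseline
  expect_lt(wmae, mae)        # FOM weighting concentrates on good phases
})

test_that("figure of merit decreases monotonically with noise", {
  levels <- c(0.05, 0.25, 0.60)
  mean_fom <- vapply(levels, function(nf) {
    foms <- vapply(c(31, 32, 33), function(s) {
      fx <- phasing_fixture(seed = 3, noise_frac = nf, multiplicity = 4,
                            sim_seed = s)
      hkl <- as.matrix(fx$merged[, c("h", "k", "l")])
      fh <- heavy_atom_sf(rbind(fx$truth), hkl, fx$b, fx$model$cell)
      mean(sad_phases(fx$merged, fh)$fom)
    }, 0)
    mean(foms)
  }, 0)
  expect_gt(mean_fom[1], mean_fom[2])
  expect_gt(mean_fom[2], mean_fom[3])
})

test_that("FFT Fourier synthesis equals the direct sum on an 8^3 grid", {
  model <- generate_toy_structure(10, seed = 13)
  g <- expand.grid(h = 1:2, k = 1:2, l = 1:3)
  ps <- true_phase_set(model, as.matrix(g))
  map <- fourier_map(ps, model$cell, d_min = 0.1, grid = c(8, 8, 8))
  arr <- fourier_coef_array(ps, c(8L, 8L, 8L))
  direct <- Re(dft3_direct(arr, sgn = -1))
  expect_lt(max(abs(map_raw(map) - direct)) / max(abs(direct)), 1e-9)
})

test_that("map correlation behaves on trivial cases", {
  set.seed(8)
  v <- array(stats::rnorm(8^3), c(8, 8, 8))
  m <- fake_map(v)
  expect_equal(map_cc(m, m), 1)
  expect_equal(map_cc(m, fake_map(-v)), -1)
  expect_error(map_cc(m, fake_map(array(0, c(4, 4, 4)))), "grid")
  expect_gte(map_cc_best_origin(m, m), map_cc(m, m) - 1e-12)
})

test_that("map skewness and hand selection are antisymmetric", {
  set.seed(9)
  v <- array(stats::rexp(8^3), c(8, 8, 8))   # positively skewed
  m_pos <- fake_map(v)
  m_neg <- fake_map(-v)
  expect_gt(map_skewness(m_pos), 0)
  expect_equal(map_skewness(m_neg), -map_skewness(m_pos))
  expect_identical(choose_hand(m_pos, m_neg)$hand, "original")
  expect_identical(choose_hand(m_neg, m_pos)$hand, "inverted")
  expect_identical(choose_hand(m_pos, m_pos)$hand, "undecided")
})

test_that("phase_error measures circular differences in degrees", {
  a <- data.frame(h = 1:3, k = 1, l = 1, F = 1,
                  phi = c(0.1, 1.0, 6.2), fom = c(1, 0.5, 0.1))
  b <- a
  b$phi <- (a$phi + 10 * pi / 180) %% (2 * pi)
  expect_equal(phase_error(a, b), 10)
  expect_equal(phase_error(a, b, weighted = TRUE), 10)
  expect_equal(phase_error(a, a), 0)
})

test_that("phase_both_hands separates the hands on noiseless data", {
  fx <- phasing_fixture(seed = 3)
  ph <- phase_both_hands(fx$merged, fx$truth, fx$model$cell, fx$b,
                         model = fx$model)
  expect_identical(ph$hand$hand, "original")
  expect_gt(ph$cc_truth["original"], 0.4)
  expect_lt(ph$cc_truth["inverted"], 0.2)
  expect_gt(ph$hand$skew_orig, ph$hand$skew_inv)
  # phasing with the inverted site flips the decision
  ph_inv <- phase_both_hands(fx$merged, -fx$truth, fx$model$cell, fx$b,
                             model = fx$model)
  expect_identical(ph_inv$hand$hand, "inverted")
  expect_gt(ph_inv$cc_truth["inverted"], 0.4)
})
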