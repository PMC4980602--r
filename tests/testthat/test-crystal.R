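test_that("unit cell and d-spacings", {
  cell <- unit_cell(34.44, 35.14, 43.78)
  expect_equal(cell$volume, 34.44 * 35.14 * 43.78)
  expect_error(unit_cell(-1, 2, 3), "positive")
  expect_equal(d_spacing(c(1, 0, 0), cell), 34.44)
  expect_equal(d_spacing(c(0, 2, 0), cell), 35.14 / 2)
  expect_equal(d_spacing(c(1, 1, 1), cell),
               1 / sqrt(1 / 34.44^2 + 1 / 35.14^2 + 1 / 43.78^2))
})

test_that("P212121 systematic absences are exact", {
  expect_true(all(is_absent_p212121(rbind(c(1, 0, 0), c(3, 0, 0),
                                          c(0, 5, 0), c(0, 0, 7)))))
  expect_false(any(is_absent_p212121(rbind(c(2, 0, 0), c(0, 4, 0),
                                           c(0, 0, 6), c(1, 1, 0),
                                           c(1, 2, 3), c(0, 1, 1)))))
})

test_that("canonical indices and Friedel sign convention", {
  can <- canonical_hkl(rbind(c(1, 2, 3), c(-1, 2, 3), c(-1, -2, 3),
                             c(-1, -2, -3), c(0, 2, 3), c(0, -2, -3)))
  expect_equal(can$h, c(1, 1, 1, 1, 0, 0))
  expect_equal(can$k, c(2, 2, 2, 2, 2, 2))
  expect_equal(can$l, c(3, 3, 3, 3, 3, 3))
  expect_equal(can$sign, c(1L, -1L, 1L, -1L, 1L, 1L))
  expect_equal(can$centric, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("reflection list matches the frozen geometric count", {
  cell <- rubredoxin_cell()
  refl <- reflection_list(cell, 1.75)
  # frozen against an independent crystallographic library enumeration
  expect_identical(nrow(refl), 5701L)
  # within 3% of the conventional processing-table count for this cell
  expect_lt(abs(nrow(refl) - 5560) / 5560, 0.03)
  expect_true(all(refl$d >= 1.75))
  expect_false(any(is_absent_p212121(as.matrix(refl[, c("h", "k", "l")]))))
  expect_false(any(refl$h == 0 & refl$k == 0 & refl$l == 0))
  expect_equal(refl$centric, refl$h == 0 | refl$k == 0 | refl$l == 0)
  expect_warning(empty <- reflection_list(cell, 100), "no reflections")
  expect_identical(nrow(empty), 0L)
})

test_that("toy structure generation is seed-deterministic", {
  m1 <- generate_toy_structure(40, seed = 7)
  m2 <- generate_toy_structure(40, seed = 7)
  m3 <- generate_toy_structure(40, seed = 8)
  expect_identical(m1$atoms, m2$atoms)
  expect_false(identical(m1$atoms, m3$atoms))
  expect_equal(m1$atoms$b_real[m1$anomalous_site], -8.0)
  expect_gt(m1$atoms$b_imag[m1$anomalous_site], 0)
  expect_true(all(m1$atoms$b_imag[-m1$anomalous_site] == 0))
  expect_error(generate_toy_structure(1), "at least 2")
})

test_that("structure factors match naive direct summation", {
  model <- generate_toy_structure(5, seed = 11)
  hkl <- rbind(c(1, 2, 3), c(2, 0, 1), c(-3, 1, -2), c(0, 1, 1),
               c(4, 4, 4), c(-1, -1, -1))
  F_pkg <- structure_factor(model, hkl)
  F_ref <- sf_direct(model, hkl)
  expect_lt(max(Mod(F_pkg - F_ref)) / max(Mod(F_ref)), 1e-10)
})

test_that("structure-factor amplitudes are invariant under 222", {
  model <- generate_toy_structure(20, seed = 3)
  hkl <- rbind(c(2, 3, 4), c(1, 5, 2), c(3, 1, 6))
  ops <- p212121_ops()
  F0 <- Mod(structure_factor(model, hkl))
  for (j in 2:4) {
    Fj <- Mod(structure_factor(model, hkl %*% ops$R[[j]]))
    expect_equal(Fj, F0, tolerance = 1e-10)
  }
})

test_that("Friedel's law holds exactly when b'' = 0", {
  model <- generate_toy_structure(20, seed = 5, b_imag_scale = 0)
  refl <- reflection_list(model$cell, 3.0)
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  Fp <- Mod(structure_factor(model, hkl))
  Fm <- Mod(structure_factor(model, -hkl))
  expect_lt(max(abs(Fp - Fm)) / max(Fp), 1e-10)
})

test_that("absent reflections have exactly vanishing structure factors", {
  model <- generate_toy_structure(15, seed = 9)
  absent <- rbind(c(1, 0, 0), c(3, 0, 0), c(0, 5, 0), c(0, 0, 3))
  F_abs <- Mod(structure_factor(model, absent))
  F_ref <- max(Mod(structure_factor(model, rbind(c(1, 1, 1), c(2, 1, 3)))))
  expect_lt(max(F_abs) / F_ref, 1e-10)
})

test_that("Bijvoet differences grow with the anomalous b''", {
  cell <- rubredoxin_cell()
  refl <- reflection_list(cell, 3.0)
  refl <- refl[!refl$centric, , drop = FALSE]
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  rel_anom <- vapply(c(0, 0.5, 1), function(sc) {
    m <- generate_toy_structure(60, seed = 21, b_imag_scale = sc)
    Ip <- Mod(structure_factor(m, hkl))^2
    Im <- Mod(structure_factor(m, -hkl))^2
    mean(abs(Ip - Im)) / mean((Ip + Im) / 2)
  }, 0)
  expect_lt(rel_anom[1], 1e-10)
  expect_gt(rel_anom[2], rel_anom[1])
  expect_gt(rel_anom[3], rel_anom[2])
})

test_that("simulated observations reproduce truth in the noiseless limit", {
  model <- generate_toy_structure(25, seed = 2)
  obs <- simulate_unmerged(model, d_min = 3.0, multiplicity = 1,
                           noise_frac = 0, floor_frac = 0, seed = 4)
  refl <- reflection_list(model$cell, 3.0)
  n_cent <- sum(refl$centric)
  expect_equal(nrow(obs), n_cent + 2 * (nrow(refl) - n_cent))
  i <- which(obs$h == refl$h[1] & obs$k == refl$k[1] & obs$l == refl$l[1])[1]
  F1 <- structure_factor(model, as.matrix(refl[1, c("h", "k", "l")]))
  # a vanishing (1e-8 relative) sigma is kept so weights stay valid, so
  # "noiseless" intensities match truth to that level, not exactly
  expect_equal(obs$I[i], Mod(F1)^2, tolerance = 1e-6)
  expect_true(all(obs$sigma > 0))
})

test_that("simulation is seed-deterministic and validates arguments", {
  model <- generate_toy_structure(25, seed = 2)
  o1 <- simulate_unmerged(model, d_min = 3.0, multiplicity = 3, seed = 5)
  o2 <- simulate_unmerged(model, d_min = 3.0, multiplicity = 3, seed = 5)
  o3 <- simulate_unmerged(model, d_min = 3.0, multiplicity = 3, seed = 6)
  expect_identical(o1, o2)
  expect_false(identical(o1$I, o3$I))
  expect_error(simulate_unmerged(model, multiplicity = 0), "multiplicity")
  expect_error(simulate_unmerged(model, noise_frac = -0.1), "non-negative")
})

test_that("attenuation enters as a transmission factor on intensities", {
  model <- generate_toy_structure(25, seed = 2)
  o_free <- simulate_unmerged(model, d_min = 3.0, multiplicity = 1,
                              noise_frac = 0, floor_frac = 0, seed = 1)
  o_att <- simulate_unmerged(model, d_min = 3.0, multiplicity = 1,
                             noise_frac = 0, floor_frac = 0, seed = 1,
                             mu = 1.54, path = 0.165)
  expect_equal(o_att$I / o_free$I,
               rep(exp(-1.54 * 0.165), nrow(o_free)), tolerance = 1e-9)
})
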