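# small deterministic coefficient set with |h| <= 3 (fits an 8^3 grid)
small_coef <- function() {
  set.seed(17)
  g <- expand.grid(h = 1:3, k = 1:2, l = 1:2)
  data.frame(h = g$h, k = g$k, l = g$l,
             dF = stats::rnorm(nrow(g)), sig_dF = stats::runif(nrow(g), 0.5, 1))
}

test_that("FFT Patterson equals the direct sum on an 8^3 grid", {
  coef <- small_coef()
  cell <- rubredoxin_cell()
  map <- patterson_map(coef, cell, grid = c(8, 8, 8))
  arr <- patterson_coef_array(coef, c(8L, 8L, 8L))
  direct <- Re(dft3_direct(arr, sgn = +1))
  expect_lt(max(abs(map_raw(map) - direct)) / max(abs(direct)), 1e-9)
})

test_that("the Patterson map is centrosymmetric", {
  map <- patterson_map(small_coef(), rubredoxin_cell(), grid = c(8, 8, 8))
  v <- map$values
  d <- dim(v)
  inv <- v[c(1, d[1]:2), c(1, d[2]:2), c(1, d[3]:2)]
  expect_lt(max(abs(v - inv)), 1e-9)
})

test_that("sigma-scaled map is invariant under coefficient scaling", {
  coef <- small_coef()
  sc <- coef; sc$dF <- sc$dF * 10
  m1 <- patterson_map(coef, rubredoxin_cell(), grid = c(8, 8, 8))
  m2 <- patterson_map(sc, rubredoxin_cell(), grid = c(8, 8, 8))
  expect_lt(max(abs(m1$values - m2$values)), 1e-9)
})

test_that("patterson_map validates its inputs", {
  cell <- rubredoxin_cell()
  expect_error(patterson_map(small_coef()[1:5, ], cell), "at least 10")
  expect_error(patterson_map(small_coef(), cell, grid = c(7, 8, 8)), "even")
})

test_that("Harker sections carry the single-site peaks of P212121", {
  cell <- rubredoxin_cell()
  site <- c(0.1, 0.2, 0.3)
  coef <- planted_site_coef(site, cell, d_min = 2.3)
  map <- patterson_map(coef, cell, d_min = 2.3)
  secs <- harker_sections(map)
  step <- max(c(cell$a, cell$b, cell$c) / map$dims)
  # each section holds two coupled self-vector pairs (one per operator
  # pair), and the section symmetry is pmm, so the peak images sit at
  # all four per-axis sign combinations of the primary vector
  near <- function(peak, target, dims) {
    best <- Inf
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      dd <- (c(peak$u1, peak$u2) - c(s1, s2) * target + 0.5) %% 1 - 0.5
      best <- min(best, sqrt(sum((dd * dims)^2)))
    }
    best
  }
  # w = 1/2: (2x - 1/2, 2y); v = 1/2: (2x, 2z - 1/2); u = 1/2: (2y - 1/2, 2z)
  pw <- peak_search(secs$w)[1, ]
  pv <- peak_search(secs$v)[1, ]
  pu <- peak_search(secs$u)[1, ]
  expect_gt(pw$height_sigma, 5)
  dist_w <- near(pw, c(0.7, 0.4), c(cell$a, cell$b))
  dist_v <- near(pv, c(0.2, 0.1), c(cell$a, cell$c))
  dist_u <- near(pu, c(0.9, 0.6), c(cell$b, cell$c))
  expect_lt(dist_w, step)
  expect_lt(dist_v, step)
  expect_lt(dist_u, step)
})

test_that("2-D peak search refines to sub-grid accuracy", {
  n <- 32
  u0 <- c(0.312, 0.618)
  x <- (seq_len(n) - 1) / n
  dx <- outer((x - u0[1] + 0.5) %% 1 - 0.5, rep(1, n))
  dy <- outer(rep(1, n), (x - u0[2] + 0.5) %% 1 - 0.5)
  m <- 10 * exp(-(dx^2 + dy^2) / (2 * 0.03^2))
  m <- (m - mean(m)) / stats::sd(m)
  pk <- peak_search(m, top_n = 1)
  expect_equal(c(pk$u1, pk$u2), u0, tolerance = 0.01)
  flat <- matrix(0, 8, 8)
  expect_identical(nrow(peak_search(flat)), 0L)
})

test_that("canonical_site folds the full equivalence group", {
  s <- c(0.12, 0.23, 0.34)
  ref <- canonical_site(s)
  expect_true(all(ref >= 0 & ref < 0.5))
  # invariant under per-axis sign flips and half-cell shifts
  expect_equal(canonical_site(-s), ref)
  expect_equal(canonical_site(c(-s[1], s[2], s[3])), ref)
  expect_equal(canonical_site(s + c(0.5, 0.5, 0)), ref)
  expect_equal(canonical_site(c(s[1] - 0.5, -s[2], s[3] + 0.5)), ref)
})

test_that("site_distance vanishes on equivalents and measures offsets", {
  cell <- rubredoxin_cell()
  s <- c(0.12, 0.23, 0.34)
  expect_equal(site_distance(s, s, cell), 0)
  expect_equal(site_distance(-s + c(0.5, 0, 0.5), s, cell), 0)
  expect_equal(site_distance(c(-s[1], s[2] + 0.5, s[3]), s, cell), 0)
  off <- s + c(0.01, 0, 0)
  expect_equal(site_distance(off, s, cell), 0.01 * cell$a, tolerance = 1e-9)
})

test_that("single-site plant-and-recover from Harker sections", {
  cell <- rubredoxin_cell()
  site <- c(0.317, 0.128, 0.404)
  coef <- planted_site_coef(site, cell, d_min = 2.3)
  map <- patterson_map(coef, cell, d_min = 2.3)
  secs <- harker_sections(map)
  peaks <- list(u = peak_search(secs$u, sigma_cut = 2.5),
                v = peak_search(secs$v, sigma_cut = 2.5),
                w = peak_search(secs$w, sigma_cut = 2.5))
  sol <- solve_site_from_harker(peaks, cell)
  expect_gt(nrow(sol), 0)
  step <- max(c(cell$a, cell$b, cell$c) / map$dims)
  expect_lt(site_distance(as.numeric(sol[1, c("x", "y", "z")]), site, cell),
            step)
})

test_that("solver reports diagnostics when sections are empty", {
  empty <- data.frame(u1 = numeric(0), u2 = numeric(0),
                      height_sigma = numeric(0))
  sol <- solve_site_from_harker(list(u = empty, v = empty, w = empty),
                                rubredoxin_cell())
  expect_identical(nrow(sol), 0L)
  expect_match(attr(sol, "diagnostics"), "Harker")
})

test_that("locate_site runs end-to-end on simulated data", {
  model <- generate_toy_structure(120, seed = 6)
  obs <- simulate_unmerged(model, d_min = 2.3, multiplicity = 1,
                           noise_frac = 0, floor_frac = 0, seed = 16)
  merged <- merge_observations(obs)
  loc <- locate_site(merged, model$cell)
  expect_gt(nrow(loc$sites), 0)
  truth <- as.numeric(model$atoms[model$anomalous_site, c("x", "y", "z")])
  expect_lt(site_distance(as.numeric(loc$sites[1, c("x", "y", "z")]),
                          truth, model$cell), 0.8)
})
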