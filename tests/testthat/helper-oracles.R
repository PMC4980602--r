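# Independent brute-force oracles used by the equivalence tests. These
# deliberately use plain scalar loops, not the package's vectorized or
# FFT code paths.

# direct symmetry-sum structure factor, one reflection at a time
sf_direct <- function(model, hkl) {
  hkl <- rbind(hkl)
  ops <- model$ops
  at <- model$atoms
  edges <- c(model$cell$a, model$cell$b, model$cell$c)
  out <- complex(nrow(hkl))
  for (r in seq_len(nrow(hkl))) {
    h <- as.numeric(hkl[r, ])
    s2 <- sum((h / edges)^2)
    acc <- 0 + 0i
    for (a in seq_len(nrow(at))) {
      b <- complex(real = at$b_real[a], imaginary = at$b_imag[a])
      for (j in seq_along(ops$R)) {
        x <- as.numeric(ops$R[[j]] %*% c(at$x[a], at$y[a], at$z[a])) +
          ops$t[[j]]
        acc <- acc + at$occ[a] * b * exp(2i * pi * sum(h * x)) *
          exp(-at$B[a] * s2 / 4)
      }
    }
    out[r] <- acc
  }
  out
}

# direct 3-D DFT over the non-zero entries of a coefficient array;
# sgn = +1 matches fft(arr, inverse = TRUE), sgn = -1 matches fft(arr)
dft3_direct <- function(arr, sgn) {
  d <- dim(arr)
  out <- array(0 + 0i, d)
  nz <- which(arr != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    e1 <- exp(sgn * 2i * pi * (nz[r, 1] - 1) * (seq_len(d[1]) - 1) / d[1])
    e2 <- exp(sgn * 2i * pi * (nz[r, 2] - 1) * (seq_len(d[2]) - 1) / d[2])
    e3 <- exp(sgn * 2i * pi * (nz[r, 3] - 1) * (seq_len(d[3]) - 1) / d[3])
    val <- arr[nz[r, 1], nz[r, 2], nz[r, 3]]
    out <- out + val * outer(outer(e1, e2), e3)
  }
  out
}

# rebuild the Patterson coefficient array exactly as patterson_map does
patterson_coef_array <- function(coef, grid) {
  hkl <- as.matrix(coef[, c("h", "k", "l")])
  w <- coef$dF^2
  arr <- array(0, dim = grid)
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  for (s in seq_len(nrow(signs))) {
    hs <- sweep(hkl, 2, signs[s, ], `*`)
    arr[cbind((hs[, 1] %% grid[1]) + 1L, (hs[, 2] %% grid[2]) + 1L,
              (hs[, 3] %% grid[3]) + 1L)] <- w
  }
  arr
}

# rebuild the Fourier coefficient array exactly as fourier_map does
fourier_coef_array <- function(phase_set, grid) {
  ops <- p212121_ops()
  hkl <- as.matrix(phase_set[, c("h", "k", "l")])
  Fc <- phase_set$fom * phase_set$F * exp(1i * phase_set$phi)
  arr <- array(complex(real = 0, imaginary = 0), dim = grid)
  put <- function(h, val) {
    idx <- cbind((h[, 1] %% grid[1]) + 1L, (h[, 2] %% grid[2]) + 1L,
                 (h[, 3] %% grid[3]) + 1L)
    arr[idx] <<- val
  }
  for (j in seq_along(ops$R)) {
    hj <- hkl %*% ops$R[[j]]
    shift <- exp(-2i * pi * (hkl %*% ops$t[[j]]))[, 1]
    put(hj, Fc * shift)
    put(-hj, Conj(Fc * shift))
  }
  arr
}

# raw (un-sigma-scaled) values of an nsad_map
map_raw <- function(map) map$values * map$sigma_raw + map$mean_raw

# fabricate an nsad_map from a value array (for map-metric unit tests)
fake_map <- function(values, cell = rubredoxin_cell()) {
  structure(list(values = values, cell = cell, dims = dim(values),
                 mean_raw = 0, sigma_raw = 1,
                 origin_mask = array(FALSE, dim(values)),
                 kind = "density"),
            class = "nsad_map")
}

# noiseless single-site anomalous differences over a reflection list:
# the plant half of plant-and-recover
planted_site_coef <- function(site, cell, d_min,
                              b = complex(real = -8, imaginary = 8.4615)) {
  refl <- reflection_list(cell, d_min)
  refl <- refl[!refl$centric, , drop = FALSE]
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  fh <- heavy_atom_sf(rbind(site), hkl, b, cell)
  data.frame(h = refl$h, k = refl$k, l = refl$l,
             dF = Mod(fh$plus) - Mod(fh$minus),
             sig_dF = 1)
}

# hand-agreement bookkeeping for hand-selection validation: an undecided
# call counts as agreement only when the two hands' CC-to-truth are
# themselves indistinguishable (self-degenerate substructures give exact
# ties)
hand_agrees <- function(hand, cc_truth, cc_tie = 0.05) {
  if (hand == "undecided") return(abs(diff(cc_truth)) < cc_tie)
  hand == c("original", "inverted")[which.max(cc_truth)]
}
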