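# Synthetic P212121 crystal and Friedel-pair diffraction simulator.
#
# Conventions: fractional coordinates, right-handed axes, reflections on
# the standard reciprocal lattice. The four P212121 operators are
# hard-coded; no general space-group engine.

#' Orthorhombic unit cell
#' @param a,b,c Cell edges in Angstrom.
#' @return Object of class `nsad_cell` with fields `a`, `b`, `c`, `volume`.
#' @export
unit_cell <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("cell edges must be positive")
  structure(list(a = a, b = b, c = c, volume = a * b * c),
            class = "nsad_cell")
}

#' Reference cell of the simulated rubredoxin crystal
#' @return `nsad_cell` with a = 34.44, b = 35.14, c = 43.78 A.
#' @export
rubredoxin_cell <- function() unit_cell(34.44, 35.14, 43.78)

#' Symmetry operators of space group P212121
#'
#' The four operators as rotation matrices and fractional translations:
#' (x,y,z); (-x+1/2,-y,z+1/2); (-x,y+1/2,-z+1/2); (x+1/2,-y+1/2,-z).
#'
#' @return list with `R` (list of 3x3 matrices) and `t` (list of length-3
#'   translation vectors).
#' @export
p212121_ops <- function() {
  list(
    R = list(diag(3),
             diag(c(-1, -1, 1)),
             diag(c(-1, 1, -1)),
             diag(c(1, -1, -1))),
    t = list(c(0, 0, 0),
             c(0.5, 0, 0.5),
             c(0, 0.5, 0.5),
             c(0.5, 0.5, 0)))
}

#' Reciprocal resolution of reflections
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @param cell `nsad_cell`.
#' @return Vector of d-spacings (A).
#' @export
d_spacing <- function(hkl, cell) {
  hkl <- rbind(hkl)
  unname(1 / sqrt(hkl[, 1]^2 / cell$a^2 + hkl[, 2]^2 / cell$b^2 +
                    hkl[, 3]^2 / cell$c^2))
}

#' Systematic absence test for P212121
#'
#' Axial reflections h00, 0k0, 00l with odd index are extinguished by the
#' three 2_1 screw axes.
#' @param hkl Integer matrix (n x 3).
#' @return Logical vector, TRUE where systematically absent.
#' @export
is_absent_p212121 <- function(hkl) {
  hkl <- rbind(hkl)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  (k == 0 & l == 0 & h %% 2 == 1) |
    (h == 0 & l == 0 & k %% 2 == 1) |
    (h == 0 & k == 0 & l %% 2 == 1)
}

#' Canonical index under point group 222 with Friedel sign
#'
#' Maps observed indices to the asymmetric-unit representative
#' (|h|,|k|,|l|) and records which Friedel branch the observation belongs
#' to. Zone reflections (any index zero) are centric: both branches are
#' symmetry-equivalent and the sign is fixed to +1.
#'
#' @param hkl Integer matrix (n x 3) of observed indices.
#' @return data.frame `h`, `k`, `l` (canonical), `sign` (+1/-1),
#'   `centric` (logical).
#' @export
canonical_hkl <- function(hkl) {
  hkl <- rbind(hkl)
  centric <- rowSums(hkl == 0) > 0
  n_neg <- rowSums(hkl < 0)
  sign <- ifelse(centric, 1L, ifelse(n_neg %% 2 == 1, -1L, 1L))
  data.frame(h = abs(hkl[, 1]), k = abs(hkl[, 2]), l = abs(hkl[, 3]),
             sign = sign, centric = centric)
}

#' Unique reflections of P212121 to a resolution limit
#'
#' All Miller indices with d >= d_min in the 222 asymmetric unit
#' (h, k, l >= 0), excluding (0,0,0) and the screw-axis systematic
#' absences. Friedel mates are the negated triples, tracked downstream by
#' the `sign` convention of [canonical_hkl()].
#'
#' @param cell `nsad_cell`.
#' @param d_min Resolution limit in A.
#' @return data.frame `h`, `k`, `l`, `d`, `centric`.
#' @export
reflection_list <- function(cell, d_min) {
  if (d_min <= 0) stop("d_min must be positive")
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  if (hmax < 1 && kmax < 1 && lmax < 1) {
    warning("d_min coarser than the cell; no reflections")
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      d = numeric(0), centric = logical(0)))
  }
  g <- expand.grid(h = 0:hmax, k = 0:kmax, l = 0:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  d <- d_spacing(as.matrix(g), cell)
  keep <- d >= d_min & !is_absent_p212121(as.matrix(g))
  g <- g[keep, ]
  d <- d[keep]
  ord <- order(g$h, g$k, g$l)
  data.frame(h = g$h[ord], k = g$k[ord], l = g$l[ord], d = d[ord],
             centric = (g$h[ord] == 0) | (g$k[ord] == 0) | (g$l[ord] == 0),
             row.names = NULL)
}

# run expr with a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate a toy perdeuterated-protein crystal with one anomalous site
#'
#' Builds an asymmetric unit of `n_atoms - 1` protein-like atoms drawn
#' from the perdeuterated palette (C, D, N, O, S with standard coherent
#' scattering lengths) with a compact globular bias, plus one anomalous
#' atom with b' = -8.0 fm and b'' from the Breit-Wigner resonance at the
#' working wavelength. Reproducible: the same seed gives an identical
#' model.
#'
#' @param n_atoms Total atoms per asymmetric unit (>= 2).
#' @param cell `nsad_cell` (default the rubredoxin cell).
#' @param seed Integer seed.
#' @param wavelength Working wavelength in A (default 1.17).
#' @param anomalous Anomalous isotope label (default `"Cd113"`).
#' @param b_imag_scale Multiplier on the anomalous b'' (for signal scans;
#'   default 1; 0 switches the anomalous signal off).
#' @return Object of class `nsad_model`: list with `cell`, `ops`, `atoms`
#'   (data.frame `isotope`, `x`, `y`, `z`, `occ`, `B`, `b_real`,
#'   `b_imag`), `anomalous_site`, `seed`, `wavelength`.
#' @export
generate_toy_structure <- function(n_atoms, cell = rubredoxin_cell(), seed = 1L,
                                   wavelength = 1.17, anomalous = "Cd113",
                                   b_imag_scale = 1) {
  if (n_atoms < 2) stop("need at least 2 atoms (protein + anomalous site)")
  beam <- neutron_beam(wavelength)
  pal_counts <- perdeuterated_protein_composition()
  tab <- isotope_table()
  pal_b <- tab$b_coh_far_fm[match(names(pal_counts), tab$isotope)]
  b_cd <- breit_wigner(anomalous, beam)
  atoms <- with_seed(seed, {
    np <- n_atoms - 1L
    iso <- sample(names(pal_counts), np, replace = TRUE,
                  prob = pal_counts / sum(pal_counts))
    # compact globular cluster around the cell centre (Cartesian normal,
    # sd ~ protein radius), wrapped into the cell
    xyz_cart <- cbind(stats::rnorm(np, cell$a / 2, 8),
                      stats::rnorm(np, cell$b / 2, 8),
                      stats::rnorm(np, cell$c / 2, 8))
    frac <- cbind(xyz_cart[, 1] / cell$a, xyz_cart[, 2] / cell$b,
                  xyz_cart[, 3] / cell$c) %% 1
    cd_xyz <- (c(stats::runif(1, 0.3, 0.7), stats::runif(1, 0.3, 0.7),
                 stats::runif(1, 0.3, 0.7)))
    B <- stats::runif(n_atoms, 5, 20)
    data.frame(
      isotope = c(iso, anomalous),
      x = c(frac[, 1], cd_xyz[1]),
      y = c(frac[, 2], cd_xyz[2]),
      z = c(frac[, 3], cd_xyz[3]),
      occ = rep(1, n_atoms),
      B = B,
      b_real = c(pal_b[match(iso, names(pal_counts))], -8.0),
      b_imag = c(rep(0, np), b_cd$b_imag * b_imag_scale),
      stringsAsFactors = FALSE)
  })
  structure(list(cell = cell, ops = p212121_ops(), atoms = atoms,
                 anomalous_site = n_atoms, seed = seed,
                 wavelength = wavelength),
            class = "nsad_model")
}

# symmetry-expanded cell contents: positions (n_at*4 x 3), complex b with
# occupancy folded in, and B factors
expand_cell_atoms <- function(model) {
  at <- model$atoms
  ops <- model$ops
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pos <- do.call(rbind, lapply(seq_along(ops$R), function(j) {
    sweep(xyz %*% t(ops$R[[j]]), 2, ops$t[[j]], `+`)
  }))
  list(pos = pos,
       b = rep(complex(real = at$b_real, imaginary = at$b_imag) * at$occ,
               times = length(ops$R)),
       B = rep(at$B, times = length(ops$R)))
}

#' Neutron structure factors of the model
#'
#' F(h) = sum over symmetry-expanded atoms of
#' occ * b * exp(2 pi i h.x) * exp(-B s^2 / 4), with s = 1/d. Because the
#' anomalous site has b'' > 0, F(-h) != conj(F(h)) in general; Friedel
#' mates must be computed by passing the negated indices.
#'
#' @param model `nsad_model`.
#' @param hkl Integer matrix (n x 3), any signs.
#' @return Complex vector of structure factors (fm).
#' @export
structure_factor <- function(model, hkl) {
  hkl <- rbind(hkl)
  ex <- expand_cell_atoms(model)
  s2 <- 1 / d_spacing(hkl, model$cell)^2
  n <- nrow(hkl)
  F <- complex(n)
  block <- 2000L
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    idx <- i0:i1
    phase <- hkl[idx, , drop = FALSE] %*% t(ex$pos)       # n_blk x n_atoms
    dw <- exp(outer(-s2[idx] / 4, ex$B))
    F[idx] <- (exp(2i * pi * phase) * dw) %*% ex$b
  }
  F
}

#' Simulate unmerged Friedel-pair intensity observations
#'
#' For every unique reflection and both Friedel branches, draws
#' `multiplicity` observations of I = T * |F|^2 with Gaussian noise of
#' standard deviation `noise_frac * I + floor`, where the floor is
#' `floor_frac` times the mean true intensity. Negative draws are clamped
#' to a small positive epsilon with sigma kept truthful. Attenuation is
#' applied as a single mean-path transmission factor.
#'
#' @param model `nsad_model`.
#' @param d_min Resolution limit in A (default 1.75).
#' @param multiplicity Observations per reflection per branch (>= 1).
#' @param noise_frac Fractional Gaussian noise level (>= 0).
#' @param mu Attenuation coefficient (cm^-1, default 0).
#' @param path Mean path length (cm, default 0).
#' @param seed Integer seed.
#' @param floor_frac Noise floor as a fraction of the mean intensity
#'   (default 0.01; set to 0 with `noise_frac = 0` for noiseless data,
#'   where a tiny positive sigma is still recorded to keep weights valid).
#' @return data.frame of observations: `h`, `k`, `l` (signed as
#'   observed), `I`, `sigma`, `batch`.
#' @export
simulate_unmerged <- function(model, d_min = 1.75, multiplicity = 13L,
                              noise_frac = 0.25, mu = 0, path = 0,
                              seed = 1L, floor_frac = 0.01) {
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  if (noise_frac < 0) stop("noise_frac must be non-negative")
  refl <- reflection_list(model$cell, d_min)
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  Tfac <- transmission(mu, path)
  F_plus <- structure_factor(model, hkl)
  F_minus <- structure_factor(model, -hkl)
  # centric zones: the Friedel mate is symmetry-equivalent; observe the
  # plus branch only (twice the multiplicity would double-count)
  acent <- !refl$centric
  obs_hkl <- rbind(hkl, -hkl[acent, , drop = FALSE])
  I_true <- Tfac * c(Mod(F_plus)^2, Mod(F_minus[acent])^2)
  n_ref <- length(I_true)
  m <- as.integer(multiplicity)
  I_rep <- rep(I_true, each = m)
  floor_sig <- floor_frac * mean(I_true)
  sig <- noise_frac * I_rep + floor_sig
  sig[sig <= 0] <- 1e-8 * max(mean(I_true), 1e-12)
  I_obs <- with_seed(seed, I_rep + stats::rnorm(n_ref * m, 0, sig))
  eps <- 1e-6 * mean(I_true)
  I_obs[I_obs < eps] <- eps
  data.frame(h = rep(obs_hkl[, 1], each = m),
             k = rep(obs_hkl[, 2], each = m),
             l = rep(obs_hkl[, 3], each = m),
             I = I_obs, sigma = sig,
             batch = rep(seq_len(m), times = n_ref))
}
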