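# Resonance neutron scattering physics: wavelength/energy conversions,
# Breit-Wigner complex scattering lengths, absorption cross sections,
# linear attenuation, and the anomalous-signal feasibility estimator.
#
# Unit conventions (fixed package-wide):
#   energy meV, wavelength Angstrom, scattering lengths fm,
#   cross sections barn, attenuation cm^-1.
#   1 fm = 1e-5 A; 1 barn = 1e-8 A^2; 1 barn/A^3 = 1 cm^-1 exactly.

#' De Broglie constant linking neutron energy and wavelength
#'
#' E\[meV\] = 81.804 / lambda\[A\]^2.
#' @keywords internal
DEBROGLIE_MEV_A2 <- 81.804

# 2200 m/s thermal reference energy (meV); tabulated absorption cross
# sections are quoted at this point and scale as 1/v, i.e. proportional
# to the wavelength.
E_THERMAL_MEV <- 25.30

FM_PER_A <- 1e5
BARN_PER_A2 <- 1e8

#' Construct a neutron beam from its wavelength
#'
#' Returns the mutually consistent (wavelength, energy, wavenumber) triple
#' for a monochromatic neutron beam, with E = 81.804/lambda^2 meV and
#' k = 2*pi/lambda.
#'
#' @param wavelength Wavelength in Angstrom (> 0).
#' @return An object of class `nsad_beam`: list with `wavelength` (A),
#'   `energy` (meV) and `k` (A^-1).
#' @examples
#' neutron_beam(1.17)$energy  # ~59.8 meV
#' @export
neutron_beam <- function(wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0) {
    stop("wavelength must be a single positive number (Angstrom)")
  }
  structure(
    list(wavelength = wavelength,
         energy = DEBROGLIE_MEV_A2 / wavelength^2,
         k = 2 * pi / wavelength),
    class = "nsad_beam")
}

#' @rdname neutron_beam
#' @export
energy_from_wavelength <- neutron_beam

#' Wavelength corresponding to a neutron energy
#' @param energy Energy in meV (> 0).
#' @return Wavelength in Angstrom.
#' @export
wavelength_from_energy <- function(energy) {
  if (!is.numeric(energy) || any(energy <= 0)) stop("energy must be positive (meV)")
  sqrt(DEBROGLIE_MEV_A2 / energy)
}

.isotope_cache <- new.env(parent = emptyenv())

#' Shipped isotope and resonance-parameter table
#'
#' Coherent scattering lengths, incoherent cross sections, 2200 m/s
#' absorption cross sections, and single-level resonance parameters
#' (E_r, Gamma, Gamma_n at E_r, potential radius R) for the perdeuterated
#' protein palette (C, D, N, O, S) and the strong resonant absorbers
#' 113Cd, 149Sm, 151Eu, 157Gd. The 113Cd entry is calibrated so that the
#' absorption cross section at 1.17 A equals 19800 barn and b' at the
#' thermal reference equals -8.0 fm.
#'
#' @return data.frame, one row per isotope.
#' @export
isotope_table <- function() {
  if (is.null(.isotope_cache$tab)) {
    path <- system.file("extdata", "isotope_resonances.csv", package = "nsad")
    if (path == "") path <- file.path("inst", "extdata", "isotope_resonances.csv")
    .isotope_cache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .isotope_cache$tab
}

#' Look up one isotope entry
#' @param label Isotope label, e.g. `"Cd113"` or `"D"`.
#' @return list with fields `label`, `b_coh_far` (fm), `sigma_inc` (barn),
#'   `sigma_abs_2200` (barn or NA), and `resonances` (data.frame, possibly
#'   0 rows, with `E_r`, `Gamma`, `Gamma_n`, `R`).
#' @export
isotope <- function(label) {
  tab <- isotope_table()
  row <- tab[tab$isotope == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown isotope: ", label)
  res <- if (is.na(row$E_r_meV)) {
    data.frame(E_r = numeric(0), Gamma = numeric(0),
               Gamma_n = numeric(0), R = numeric(0))
  } else {
    data.frame(E_r = row$E_r_meV, Gamma = row$Gamma_meV,
               Gamma_n = row$Gamma_n_meV, R = row$R_fm)
  }
  list(label = label,
       b_coh_far = row$b_coh_far_fm,
       sigma_inc = row$sigma_inc_barn,
       sigma_abs_2200 = row$sigma_abs_2200_barn,
       resonances = res)
}

#' Breit-Wigner complex neutron scattering length
#'
#' Single-level Breit-Wigner scattering length under the convention
#' b = b' + i b'' with b'' >= 0 for absorbers:
#'
#'   b(E) = R + sum_res (Gamma_n(E) / 2k) *
#'              \[(E - E_r) + i Gamma/2\] / \[(E - E_r)^2 + (Gamma/2)^2\]
#'
#' with Gamma_n(E) = Gamma_n(E_r) * sqrt(E / E_r) (s-wave energy
#' dependence). The dispersive real part is negative below the resonance,
#' which is what drives b'(113Cd) to -8.0 fm at thermal wavelengths, and
#' the imaginary part satisfies sigma_abs = 4 pi b'' / k.
#'
#' @param iso Isotope entry from [isotope()], or a label.
#' @param beam `nsad_beam` from [neutron_beam()].
#' @return list of class `nsad_bcomplex`: `b_real` (fm), `b_imag` (fm),
#'   `at_wavelength` (A), `no_resonance` flag.
#' @export
breit_wigner <- function(iso, beam) {
  if (is.character(iso)) iso <- isotope(iso)
  stopifnot(inherits(beam, "nsad_beam"))
  res <- iso$resonances
  if (nrow(res) == 0L) {
    warning("isotope ", iso$label, " has no tabulated resonance; b'' = 0")
    return(structure(list(b_real = iso$b_coh_far, b_imag = 0,
                          at_wavelength = beam$wavelength,
                          no_resonance = TRUE),
                     class = "nsad_bcomplex"))
  }
  E <- beam$energy
  k <- beam$k
  b_re <- res$R[1L] / FM_PER_A   # potential term, in A
  b_im <- 0
  for (j in seq_len(nrow(res))) {
    GnE <- res$Gamma_n[j] * sqrt(E / res$E_r[j])
    denom <- (E - res$E_r[j])^2 + (res$Gamma[j] / 2)^2
    amp <- GnE / (2 * k) / denom            # A / meV
    b_re <- b_re + amp * (E - res$E_r[j])
    b_im <- b_im + amp * (res$Gamma[j] / 2)
  }
  structure(list(b_real = b_re * FM_PER_A, b_imag = b_im * FM_PER_A,
                 at_wavelength = beam$wavelength, no_resonance = FALSE),
            class = "nsad_bcomplex")
}

#' Scan b' and b'' over a wavelength range
#'
#' Numerical counterpart of the resonance dispersion curves: evaluates the
#' Breit-Wigner complex scattering length of one isotope on a wavelength
#' grid.
#'
#' @param iso Isotope label or entry.
#' @param wavelengths Numeric vector of wavelengths (A).
#' @return data.frame with `wavelength`, `energy`, `b_real`, `b_imag`.
#' @export
scattering_length_scan <- function(iso, wavelengths) {
  if (is.character(iso)) iso <- isotope(iso)
  out <- lapply(wavelengths, function(l) {
    b <- suppressWarnings(breit_wigner(iso, neutron_beam(l)))
    data.frame(wavelength = l, energy = DEBROGLIE_MEV_A2 / l^2,
               b_real = b$b_real, b_imag = b$b_imag)
  })
  do.call(rbind, out)
}

#' Absorption cross section from the imaginary scattering length
#'
#' Optical-theorem relation sigma_abs = 4 pi b'' / k, with exact unit
#' handling fm, A^-1 -> barn.
#'
#' @param b_imag b'' in fm (>= 0).
#' @param beam `nsad_beam`.
#' @return Cross section in barn.
#' @export
cross_section_from_b_imag <- function(b_imag, beam) {
  stopifnot(inherits(beam, "nsad_beam"))
  if (any(b_imag < 0)) stop("b_imag must be non-negative under the b = b' + i b'' convention")
  4 * pi * (b_imag / FM_PER_A) / beam$k * BARN_PER_A2
}

#' @rdname cross_section_from_b_imag
#' @param sigma_barn Absorption cross section in barn.
#' @export
b_imag_from_cross_section <- function(sigma_barn, beam) {
  stopifnot(inherits(beam, "nsad_beam"))
  if (any(sigma_barn < 0)) stop("cross section must be non-negative")
  (sigma_barn / BARN_PER_A2) * beam$k / (4 * pi) * FM_PER_A
}

#' Removal cross section of one isotope at a given beam
#'
#' sigma_inc + sigma_abs(lambda). For resonant isotopes the absorption is
#' evaluated from the Breit-Wigner b''; otherwise the tabulated 2200 m/s
#' value is scaled by 1/v (proportional to wavelength).
#'
#' @param iso Isotope label or entry.
#' @param beam `nsad_beam`.
#' @return Cross section in barn.
#' @export
removal_cross_section <- function(iso, beam) {
  if (is.character(iso)) iso <- isotope(iso)
  if (nrow(iso$resonances) > 0L) {
    s_abs <- cross_section_from_b_imag(breit_wigner(iso, beam)$b_imag, beam)
  } else {
    s_abs <- iso$sigma_abs_2200 * sqrt(E_THERMAL_MEV / beam$energy)
  }
  iso$sigma_inc + s_abs
}

#' Linear neutron attenuation coefficient of a unit cell
#'
#' mu = sum over cell contents of (incoherent + absorption cross section)
#' divided by the cell volume. Because 1 barn/A^3 equals exactly 1 cm^-1,
#' no numeric conversion factor appears.
#'
#' @param composition data.frame with columns `isotope` (label),
#'   `count_per_cell` and `sigma_barn` (removal cross section at the
#'   working wavelength), e.g. from [cell_composition()].
#' @param cell_volume Unit-cell volume in A^3.
#' @return mu in cm^-1.
#' @export
attenuation_coefficient <- function(composition, cell_volume) {
  if (!is.numeric(cell_volume) || cell_volume <= 0) stop("cell_volume must be positive")
  if (nrow(composition) == 0L) {
    warning("empty composition; mu = 0")
    return(0)
  }
  if (any(composition$count_per_cell < 0) || any(composition$sigma_barn < 0)) {
    stop("counts and cross sections must be non-negative")
  }
  sum(composition$count_per_cell * composition$sigma_barn) / cell_volume
}

#' Beam transmission through a path
#' @param mu Attenuation coefficient (cm^-1, >= 0).
#' @param path Path length (cm, >= 0).
#' @return Transmitted fraction exp(-mu * path) in (0, 1].
#' @export
transmission <- function(mu, path) {
  if (any(mu < 0) || any(path < 0)) stop("mu and path must be non-negative")
  exp(-mu * path)
}

#' Atom counts of a perdeuterated protein asymmetric unit
#'
#' Element counts for an n-residue perdeuterated protein (all hydrogens
#' replaced by deuterium), using average per-residue composition rounded
#' to whole atoms. For the 54-residue rubredoxin-sized default this gives
#' 710 atoms, inside the 700-760 range expected for this protein.
#'
#' @param n_residues Number of residues (default 54).
#' @return Named integer vector with counts for C, D, N, O, S.
#' @export
perdeuterated_protein_composition <- function(n_residues = 54L) {
  per_res <- c(C = 230, D = 340, N = 66, O = 72, S = 2) / 54
  round(per_res * n_residues)
}

#' Composition-weighted mean coherent scattering length
#' @param counts Named numeric vector of atom counts (names are isotope labels).
#' @return Mean b_coh in fm.
#' @export
mean_coherent_b <- function(counts) {
  tab <- isotope_table()
  b <- tab$b_coh_far_fm[match(names(counts), tab$isotope)]
  if (anyNA(b)) stop("unknown isotope label in counts")
  # for the resonant absorbers the tabulated b_coh_far is the potential
  # radius; protein-palette entries are plain coherent lengths
  sum(counts * b) / sum(counts)
}

#' Full unit-cell composition with removal cross sections
#'
#' Builds the attenuation composition table for the simulated crystal:
#' `n_asu` copies of the perdeuterated protein plus one anomalous isotope
#' each, plus ordered D2O waters.
#'
#' @param beam `nsad_beam` at the working wavelength.
#' @param n_residues Residues per asymmetric unit (default 54).
#' @param anomalous Label of the anomalous isotope (default `"Cd113"`).
#' @param n_asu Asymmetric units per cell (4 in P212121).
#' @param n_waters Ordered waters per asymmetric unit (default 49).
#' @return data.frame with `isotope`, `count_per_cell`, `sigma_barn`.
#' @export
cell_composition <- function(beam, n_residues = 54L, anomalous = "Cd113",
                             n_asu = 4L, n_waters = 49L) {
  prot <- perdeuterated_protein_composition(n_residues) * n_asu
  water <- c(D = 2L, O = 1L) * n_waters * n_asu
  counts <- prot
  counts[names(water)] <- counts[names(water)] + water
  counts[anomalous] <- n_asu
  data.frame(
    isotope = names(counts),
    count_per_cell = as.numeric(counts),
    sigma_barn = vapply(names(counts), function(l) removal_cross_section(l, beam), 0),
    row.names = NULL)
}

#' Expected anomalous signal as a fraction of |F|
#'
#' Feasibility estimator for SAD phasing:
#' dF/F ~ sqrt(2) * (sqrt(N_a) * delta_b'') / (sqrt(N_p) * b_av),
#' independent of scattering angle because nuclei scatter as points.
#'
#' @param N_a Number of anomalous scatterers per asymmetric unit.
#' @param N_p Number of protein atoms per asymmetric unit.
#' @param b_av Mean coherent scattering length of the protein atoms (fm).
#' @param delta_b_imag Imaginary scattering-length contrast b'' (fm).
#' @return Expected |dF|/|F| as a dimensionless fraction.
#' @export
anomalous_signal_estimate <- function(N_a, N_p, b_av, delta_b_imag) {
  if (any(c(N_a, N_p, b_av) <= 0)) stop("N_a, N_p and b_av must be positive")
  if (delta_b_imag < 0) stop("delta_b_imag must be non-negative")
  if (N_a > N_p) stop("N_a cannot exceed N_p")
  sqrt(2) * (sqrt(N_a) * delta_b_imag) / (sqrt(N_p) * b_av)
}
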