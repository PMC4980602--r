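# Orchestration: configuration, SHELX-format reflection I/O, and the
# end-to-end simulate -> merge -> stats -> Patterson -> phase pipeline.

#' Write reflections in SHELX HKL fixed-width format
#'
#' Format (3I4, 2F8.2): h, k, l, I, sigma(I), terminated by an all-zero
#' record. Values must fit the 8.2 field (|I| < 1e6); use `scale` to
#' bring simulated intensities onto a printable scale.
#'
#' @param obs data.frame with `h`, `k`, `l`, `I`, `sigma`.
#' @param path Output file path.
#' @param scale Multiplier applied to I and sigma before writing
#'   (default 1).
#' @export
write_hkl <- function(obs, path, scale = 1) {
  I <- obs$I * scale
  s <- obs$sigma * scale
  if (any(abs(I) >= 1e6) || any(abs(s) >= 1e6)) {
    stop("intensities too large for the 8.2 field; use a smaller scale")
  }
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", obs$h, obs$k, obs$l, I, s)
  lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  writeLines(lines, path)
}

#' Read reflections from SHELX HKL fixed-width format
#'
#' Accepts the (3I4, 2F8.2) dialect written by [write_hkl()]; reading
#' stops at the all-zero terminator record. Malformed lines raise an
#' error naming the line number.
#'
#' @param path Input file path.
#' @return data.frame `h`, `k`, `l`, `I`, `sigma`.
#' @export
read_hkl <- function(path) {
  lines <- readLines(path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (nchar(ln) < 28L) stop("line ", i, ": expected 3I4,2F8.2 record (>= 28 chars)")
    f <- c(substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
           substr(ln, 13, 20), substr(ln, 21, 28))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("line ", i, ": unparseable fixed-width record")
    if (all(v[1:3] == 0)) {
      out <- out[seq_len(i - 1L)]
      break
    }
    out[[i]] <- v
  }
  m <- do.call(rbind, out)
  data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
             l = as.integer(m[, 3]), I = m[, 4], sigma = m[, 5])
}

#' Pipeline configuration with the reference preset
#'
#' Defaults mirror the neutron experiment the simulator emulates: the
#' orthorhombic rubredoxin cell, lambda = 1.17 A, data to 1.75 A with
#' multiplicity 13, substructure search truncated at 2.3 A, experimental
#' map at 2.30 A, attenuation from the full perdeuterated cell contents
#' and a mean-path transmission factor.
#'
#' @param cell `nsad_cell` (default [rubredoxin_cell()]).
#' @param n_atoms Atoms per asymmetric unit including the anomalous site
#'   (default 711: a perdeuterated 54-residue protein plus one 113Cd).
#' @param d_min Data resolution limit (A, default 1.75).
#' @param multiplicity Observations per reflection per Friedel branch
#'   (default 13).
#' @param noise_frac Fractional intensity noise (default 0.25, giving a
#'   merged mean I/sigma near 13 at multiplicity 13).
#' @param wavelength Beam wavelength (A, default 1.17).
#' @param isotope Anomalous isotope (default `"Cd113"`).
#' @param seed Master seed; all stage seeds derive from it.
#' @param d_min_sub Substructure-search cutoff (A, default 2.3).
#' @param d_min_map Experimental-map cutoff (A, default 2.30).
#' @param b_imag_scale Multiplier on the anomalous b'' (default 1;
#'   0 = negative control without anomalous signal).
#' @param path_cm Mean attenuation path (cm, default 0.165, the mean
#'   chord of a 4.5 mm^3 crystal).
#' @param n_waters Ordered waters per asymmetric unit entering the
#'   attenuation composition (default 49).
#' @param n_shells Resolution shells in the statistics report.
#' @param out_dir Optional output directory for reflection files and
#'   reports.
#' @return list of class `nsad_config`.
#' @export
pipeline_config <- function(cell = rubredoxin_cell(), n_atoms = 711L,
                            d_min = 1.75, multiplicity = 13L,
                            noise_frac = 0.25, wavelength = 1.17,
                            isotope = "Cd113", seed = 1L,
                            d_min_sub = 2.3, d_min_map = 2.30,
                            b_imag_scale = 1, path_cm = 0.165,
                            n_waters = 49L, n_shells = 10L,
                            out_dir = NULL) {
  cfg <- list(cell = cell, n_atoms = as.integer(n_atoms), d_min = d_min,
              multiplicity = as.integer(multiplicity),
              noise_frac = noise_frac, wavelength = wavelength,
              isotope = isotope, seed = as.integer(seed),
              d_min_sub = d_min_sub, d_min_map = d_min_map,
              b_imag_scale = b_imag_scale, path_cm = path_cm,
              n_waters = as.integer(n_waters),
              n_shells = as.integer(n_shells), out_dir = out_dir)
  stopifnot(cfg$n_atoms >= 2, cfg$d_min > 0, cfg$multiplicity >= 1,
            cfg$noise_frac >= 0, cfg$wavelength > 0, cfg$path_cm >= 0)
  class(cfg) <- "nsad_config"
  cfg
}

#' Run the full simulated SAD pipeline
#'
#' Stages: feasibility physics, toy-crystal generation, Friedel-pair
#' simulation, merging and statistics, anomalous-difference Patterson
#' site location, SAD phasing of both hands with hand selection (no
#' density modification). All stage seeds derive from the config seed, so
#' a fixed config yields an identical report. When the substructure
#' search finds no site (e.g. the no-signal negative control) the
#' phasing block reports this gracefully instead of failing.
#'
#' @param config `nsad_config` from [pipeline_config()].
#' @param verbose Print a stage log (default FALSE).
#' @return list of class `nsad_report` with blocks `feasibility`,
#'   `statistics`, `substructure`, `phasing`, `provenance`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  beam <- neutron_beam(cfg$wavelength)
  b_cd <- breit_wigner(cfg$isotope, beam)
  sigma_abs <- cross_section_from_b_imag(b_cd$b_imag, beam)
  comp <- cell_composition(beam, anomalous = cfg$isotope,
                           n_waters = cfg$n_waters)
  mu <- attenuation_coefficient(comp, cfg$cell$volume)
  Tfac <- transmission(mu, cfg$path_cm)
  prot <- perdeuterated_protein_composition()
  feas <- anomalous_signal_estimate(
    N_a = 1, N_p = cfg$n_atoms - 1L,
    b_av = mean_coherent_b(prot),
    delta_b_imag = b_cd$b_imag * cfg$b_imag_scale)
  say("feasibility: sigma_abs=%.0f barn, mu=%.3f /cm, T=%.3f, dF/F=%.3f%%",
      sigma_abs, mu, Tfac, 100 * feas)

  model <- generate_toy_structure(cfg$n_atoms, cfg$cell, seed = cfg$seed,
                                  wavelength = cfg$wavelength,
                                  anomalous = cfg$isotope,
                                  b_imag_scale = cfg$b_imag_scale)
  obs <- simulate_unmerged(model, d_min = cfg$d_min,
                           multiplicity = cfg$multiplicity,
                           noise_frac = cfg$noise_frac,
                           mu = mu, path = cfg$path_cm,
                           seed = cfg$seed + 1L)
  say("simulated %d observations of %d unique reflections",
      nrow(obs), nrow(reflection_list(cfg$cell, cfg$d_min)))
  merged <- merge_observations(obs)
  stats_rep <- table1_report(obs, cfg$cell, cfg$d_min,
                             n_shells = cfg$n_shells, seed = cfg$seed + 2L)
  say("overall: Rmerge=%.3f Rpim=%.3f Ranom=%.3f CC1/2=%.3f",
      stats_rep$overall$r_merge, stats_rep$overall$r_pim,
      stats_rep$overall$r_anom, stats_rep$overall$cc_half)

  loc <- locate_site(merged, cfg$cell, d_min_sub = cfg$d_min_sub)
  phasing <- NULL
  if (nrow(loc$sites) == 0L) {
    say("substructure: no site found (%s)",
        attr(loc$sites, "diagnostics") %||% "no peaks")
    substruct <- list(found = FALSE, sites = loc$sites,
                      top_peaks = lapply(loc$peaks, utils::head, 1L))
  } else {
    site <- as.numeric(loc$sites[1L, c("x", "y", "z")])
    substruct <- list(found = TRUE, sites = loc$sites, site = site,
                      top_peaks = lapply(loc$peaks, utils::head, 1L))
    say("substructure: site (%.3f, %.3f, %.3f), score %.2f A",
        site[1], site[2], site[3], loc$sites$score[1])
    phasing <- phase_both_hands(
      merged, site, cfg$cell,
      b = complex(real = -8.0, imaginary = b_cd$b_imag * cfg$b_imag_scale),
      d_min_map = cfg$d_min_map, scale = sqrt(Tfac), model = model)
    say("hand: %s (skew %.3f vs %.3f)", phasing$hand$hand,
        phasing$hand$skew_orig, phasing$hand$skew_inv)
  }
  report <- list(
    feasibility = list(wavelength = cfg$wavelength,
                       energy_meV = beam$energy,
                       b_real_fm = -8.0, b_imag_fm = b_cd$b_imag,
                       sigma_abs_barn = sigma_abs, mu_cm = mu,
                       transmission = Tfac, dF_over_F = feas),
    statistics = stats_rep,
    substructure = substruct,
    phasing = if (is.null(phasing)) list(performed = FALSE)
    else list(performed = TRUE, hand = phasing$hand,
              mean_fom = phasing$mean_fom, cc_truth = phasing$cc_truth),
    provenance = list(config = cfg,
                      package_version = as.character(utils::packageVersion("nsad"))))
  class(report) <- "nsad_report"
  if (!is.null(cfg$out_dir)) .write_outputs(report, obs, merged, loc, cfg)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write reflection files, peak/site tables and a plain-text log that
# records every default actually used
.write_outputs <- function(report, obs, merged, loc, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- 1
  if (max(obs$I) >= 1e6) sc <- 1e5 / max(obs$I)
  write_hkl(obs, file.path(cfg$out_dir, "unmerged.hkl"), scale = sc)
  mm <- merged[!is.na(merged$I_plus), c("h", "k", "l", "I_plus", "sig_plus")]
  names(mm) <- c("h", "k", "l", "I", "sigma")
  mneg <- merged[!is.na(merged$I_minus), c("h", "k", "l", "I_minus", "sig_minus")]
  mneg[, 1:3] <- -mneg[, 1:3]
  names(mneg) <- names(mm)
  write_hkl(rbind(mm, mneg), file.path(cfg$out_dir, "merged.hkl"), scale = sc)
  utils::write.csv(report$statistics$shells,
                   file.path(cfg$out_dir, "shell_statistics.csv"),
                   row.names = FALSE)
  if (nrow(loc$sites) > 0L) {
    utils::write.csv(loc$sites, file.path(cfg$out_dir, "sites.csv"),
                     row.names = FALSE)
  }
  log <- c(
    "nsad pipeline run",
    sprintf("package version: %s", report$provenance$package_version),
    sprintf("cell: %.2f %.2f %.2f A", cfg$cell$a, cfg$cell$b, cfg$cell$c),
    sprintf("wavelength: %.3f A  isotope: %s", cfg$wavelength, cfg$isotope),
    sprintf("n_atoms: %d  d_min: %.2f A  multiplicity: %d  noise_frac: %.3f",
            cfg$n_atoms, cfg$d_min, cfg$multiplicity, cfg$noise_frac),
    sprintf("d_min_sub: %.2f A  d_min_map: %.2f A", cfg$d_min_sub, cfg$d_min_map),
    sprintf("path: %.3f cm  n_waters: %d  n_shells: %d  hkl scale: %.3g",
            cfg$path_cm, cfg$n_waters, cfg$n_shells, sc),
    sprintf("seed: %d (stages use seed, seed+1, seed+2)", cfg$seed),
    sprintf("mu: %.4f /cm  transmission: %.4f  dF/F: %.4f",
            report$feasibility$mu_cm, report$feasibility$transmission,
            report$feasibility$dF_over_F))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
}
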