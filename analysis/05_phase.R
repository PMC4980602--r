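#!/usr/bin/env Rscript
# SAD phasing of both substructure hands, hand selection, and validation
# against the known ground truth. Writes results/phasing_summary.txt.
# Usage: Rscript analysis/05_phase.R [--seed <int>]

suppressPackageStartupMessages(library(nsad))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- pipeline_config(seed = seed)
beam <- neutron_beam(cfg$wavelength)
b_cd <- breit_wigner(cfg$isotope, beam)
model <- generate_toy_structure(cfg$n_atoms, cfg$cell, seed = cfg$seed,
                                wavelength = cfg$wavelength)
obs <- simulate_unmerged(model, d_min = cfg$d_min,
                         multiplicity = cfg$multiplicity,
                         noise_frac = cfg$noise_frac, seed = cfg$seed + 1L)
merged <- merge_observations(obs)
loc <- locate_site(merged, cfg$cell, d_min_sub = cfg$d_min_sub)
stopifnot(nrow(loc$sites) > 0)
site <- as.numeric(loc$sites[1, c("x", "y", "z")])

ph <- phase_both_hands(merged, site, cfg$cell,
                       b = complex(real = -8, imaginary = b_cd$b_imag),
                       d_min_map = cfg$d_min_map, model = model)
hkl <- as.matrix(merged[, c("h", "k", "l")])
tps <- true_phase_set(model, hkl)
sel <- if (ph$hand$hand == "inverted") "inverted" else "original"
mae <- phase_error(ph$phases[[sel]], tps)
wmae <- phase_error(ph$phases[[sel]], tps, weighted = TRUE)

lines <- c(
  sprintf("seed                         : %d", seed),
  sprintf("site used                    : (%.4f, %.4f, %.4f)",
          site[1], site[2], site[3]),
  sprintf("hand selected                : %s (skew %.4f vs %.4f)",
          ph$hand$hand, ph$hand$skew_orig, ph$hand$skew_inv),
  sprintf("mean FOM (orig / inv)        : %.3f / %.3f",
          ph$mean_fom[["original"]], ph$mean_fom[["inverted"]]),
  sprintf("map CC to truth (orig / inv) : %.3f / %.3f",
          ph$cc_truth[["original"]], ph$cc_truth[["inverted"]]),
  sprintf("selected-hand phase error    : %.1f deg (FOM-weighted %.1f deg)",
          mae, wmae),
  "note: the selected-hand map may sit on a shifted permissible origin,",
  "so the plain phase error is only meaningful when CC-to-truth is high",
  "at the identity origin; cc values above are origin-maximized.")
writeLines(lines, "results/phasing_summary.txt")
cat(paste(lines, collapse = "\n"), "\n")
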