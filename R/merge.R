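# Merging and data-quality statistics with anomalous (Friedel) pairs kept
# separate, reporting the conventional R_merge / R_p.i.m. / R_anom /
# CC(1/2) block per resolution shell.
#
# Grouping convention: a "group" is one canonical index plus Friedel
# branch; groups with a single observation are excluded from the
# R_merge / R_p.i.m. sums.

# integer group key for canonical (hkl, sign); indices must be < 512
.group_key <- function(can) {
  (((can$h * 512L + can$k) * 512L + can$l) * 2L) + as.integer(can$sign > 0)
}

#' Merge observations into Friedel-separated unique reflections
#'
#' Observations are mapped to their canonical 222 index and Friedel
#' branch, then combined per branch by inverse-variance weighting,
#' sigma_merged = (sum of weights)^(-1/2).
#'
#' @param obs data.frame of observations with columns `h`, `k`, `l`
#'   (signed as observed), `I`, `sigma`.
#' @return data.frame of merged reflections: `h`, `k`, `l` (canonical),
#'   `centric`, `I_plus`, `sig_plus`, `n_plus`, `I_minus`, `sig_minus`,
#'   `n_minus` (NA where a branch is unobserved; centric reflections
#'   carry the plus branch only).
#' @export
merge_observations <- function(obs) {
  if (nrow(obs) < 1L) stop("need at least one observation")
  if (any(obs$sigma <= 0)) stop("all sigmas must be positive")
  can <- canonical_hkl(as.matrix(obs[, c("h", "k", "l")]))
  ukey <- paste(can$h, can$k, can$l)
  w <- 1 / obs$sigma^2
  side <- ifelse(can$sign > 0, "p", "m")
  skey <- paste(ukey, side)
  sw <- rowsum(w, skey)
  swI <- rowsum(w * obs$I, skey)
  n <- rowsum(rep(1L, nrow(obs)), skey)
  I_m <- swI / sw
  sig_m <- 1 / sqrt(sw)
  parts <- do.call(rbind, strsplit(rownames(sw), " "))
  uhkl <- paste(parts[, 1], parts[, 2], parts[, 3])
  uu <- unique(uhkl)
  idx <- match(uhkl, uu)
  res <- data.frame(h = as.integer(parts[match(uu, uhkl), 1]),
                    k = as.integer(parts[match(uu, uhkl), 2]),
                    l = as.integer(parts[match(uu, uhkl), 3]))
  res$centric <- (res$h == 0) | (res$k == 0) | (res$l == 0)
  for (col in c("I_plus", "sig_plus", "I_minus", "sig_minus")) res[[col]] <- NA_real_
  res$n_plus <- 0L; res$n_minus <- 0L
  is_p <- parts[, 4] == "p"
  res$I_plus[idx[is_p]] <- I_m[is_p]
  res$sig_plus[idx[is_p]] <- sig_m[is_p]
  res$n_plus[idx[is_p]] <- n[is_p]
  res$I_minus[idx[!is_p]] <- I_m[!is_p]
  res$sig_minus[idx[!is_p]] <- sig_m[!is_p]
  res$n_minus[idx[!is_p]] <- n[!is_p]
  res[order(res$h, res$k, res$l), , drop = FALSE]
}

# per-observation group assignment used by the unmerged R statistics
.grouped <- function(obs) {
  can <- canonical_hkl(as.matrix(obs[, c("h", "k", "l")]))
  key <- .group_key(can)
  g <- match(key, unique(key))
  n_g <- tabulate(g)
  mean_g <- rowsum(obs$I, g)[, 1] / n_g
  list(g = g, n = n_g, mean = mean_g)
}

#' Merging R factor
#'
#' R_merge = sum_hkl sum_i |I_i - <I>| / sum_hkl sum_i I_i over groups
#' with at least two observations (Friedel branches kept separate).
#'
#' @param obs data.frame with `h`, `k`, `l`, `I` (and `sigma`, unused).
#' @return R_merge as a fraction.
#' @export
r_merge <- function(obs) {
  gr <- .grouped(obs)
  keep <- gr$n[gr$g] >= 2L
  if (!any(keep)) stop("no multiply-observed groups")
  denom <- sum(obs$I[keep])
  if (denom <= 0) stop("non-positive intensity sum")
  sum(abs(obs$I - gr$mean[gr$g])[keep]) / denom
}

#' Precision-indicating merging R factor
#'
#' R_p.i.m. = sum_hkl sqrt(1/(N-1)) sum_i |I_i - <I>| / sum_hkl sum_i I_i,
#' the multiplicity-weighted analogue of R_merge.
#'
#' @inheritParams r_merge
#' @return R_p.i.m. as a fraction.
#' @export
r_pim <- function(obs) {
  gr <- .grouped(obs)
  keep <- gr$n[gr$g] >= 2L
  if (!any(keep)) stop("no multiply-observed groups")
  denom <- sum(obs$I[keep])
  if (denom <= 0) stop("non-positive intensity sum")
  fac <- 1 / sqrt(pmax(gr$n - 1L, 1L))
  sum((fac[gr$g] * abs(obs$I - gr$mean[gr$g]))[keep]) / denom
}

#' Anomalous R factor
#'
#' R_anom = sum |I+ - I-| / sum (I+ + I-)/2 over acentric reflections
#' with both Friedel branches observed. A ratio R_anom / R_p.i.m. > 1 is
#' the usual first indication of a measurable anomalous signal.
#'
#' @param merged Output of [merge_observations()].
#' @return R_anom as a fraction.
#' @export
r_anom <- function(merged) {
  ok <- !merged$centric & !is.na(merged$I_plus) & !is.na(merged$I_minus)
  if (!any(ok)) stop("no complete Bijvoet pairs")
  num <- sum(abs(merged$I_plus[ok] - merged$I_minus[ok]))
  den <- sum((merged$I_plus[ok] + merged$I_minus[ok]) / 2)
  if (den <= 0) stop("non-positive intensity sum")
  num / den
}

#' Half-dataset intensity correlation CC(1/2)
#'
#' Observations of each multiply-observed group are split at random
#' (seeded, one split) into two halves; CC(1/2) is the Pearson
#' correlation of the half-set mean intensities across groups.
#'
#' @inheritParams r_merge
#' @param seed Integer seed for the random split.
#' @return Correlation in \[-1, 1\].
#' @export
cc_half <- function(obs, seed = 1L) {
  gr <- .grouped(obs)
  usable <- which(gr$n >= 2L)
  if (length(usable) < 3L) stop("need >= 3 multiply-observed groups")
  u <- with_seed(seed, stats::runif(nrow(obs)))
  ord_rank <- stats::ave(u, gr$g, FUN = rank)
  half1 <- ord_rank <= gr$n[gr$g] / 2
  m1 <- rowsum(ifelse(half1, obs$I, 0), gr$g)[, 1] /
    pmax(rowsum(as.numeric(half1), gr$g)[, 1], 1)
  m2 <- rowsum(ifelse(!half1, obs$I, 0), gr$g)[, 1] /
    pmax(rowsum(as.numeric(!half1), gr$g)[, 1], 1)
  stats::cor(m1[usable], m2[usable])
}

#' Bijvoet differences on the amplitude scale
#'
#' dF = sqrt(I+) - sqrt(I-) with delta-method error propagation
#' sigma(sqrt(I)) = sigma_I / (2 sqrt(I)). Acentric complete pairs only;
#' non-positive intensities are skipped and counted.
#'
#' @param merged Output of [merge_observations()].
#' @return data.frame `h`, `k`, `l`, `dF`, `sig_dF`, `F_mean`, plus an
#'   attribute `n_skipped`.
#' @export
anomalous_differences <- function(merged) {
  ok <- !merged$centric & !is.na(merged$I_plus) & !is.na(merged$I_minus)
  if (!any(ok)) stop("no complete Bijvoet pairs")
  m <- merged[ok, , drop = FALSE]
  pos <- m$I_plus > 0 & m$I_minus > 0
  n_skip <- sum(!pos)
  m <- m[pos, , drop = FALSE]
  Fp <- sqrt(m$I_plus); Fm <- sqrt(m$I_minus)
  sFp <- m$sig_plus / (2 * Fp); sFm <- m$sig_minus / (2 * Fm)
  out <- data.frame(h = m$h, k = m$k, l = m$l,
                    dF = Fp - Fm,
                    sig_dF = sqrt(sFp^2 + sFm^2),
                    F_mean = (Fp + Fm) / 2)
  attr(out, "n_skipped") <- n_skip
  out
}

# equal-reciprocal-volume shell assignment on 1/d^3
shell_assign <- function(d, n_shells) {
  s3 <- 1 / d^3
  brk <- seq(0, max(s3), length.out = n_shells + 1)
  pmin(pmax(findInterval(s3, brk, rightmost.closed = TRUE), 1L), n_shells)
}

#' Per-shell anomalous signal-to-noise
#'
#' Shell means of |dF| / sigma(dF), the quantity SHELX-style programs plot
#' as <d''/sig>. A pure-noise dataset gives ~ sqrt(2/pi) x E|z| ~ 0.8;
#' values well above 0.8 indicate usable anomalous signal. Infinite
#' ratios from vanishing sigmas are capped at `cap`.
#'
#' @param merged Output of [merge_observations()].
#' @param cell `nsad_cell` (for resolution binning).
#' @param n_shells Number of equal-reciprocal-volume shells.
#' @param cap Cap applied to |dF|/sigma before averaging (default 1e3).
#' @return data.frame `shell`, `d_max`, `d_min`, `n_pairs`, `anom_snr`.
#' @export
anom_snr_by_shell <- function(merged, cell, n_shells = 10L, cap = 1e3) {
  ad <- anomalous_differences(merged)
  d <- d_spacing(as.matrix(ad[, c("h", "k", "l")]), cell)
  sh <- shell_assign(d, n_shells)
  snr <- pmin(abs(ad$dF) / ad$sig_dF, cap)
  out <- do.call(rbind, lapply(sort(unique(sh)), function(s) {
    data.frame(shell = s, d_max = max(d[sh == s]), d_min = min(d[sh == s]),
               n_pairs = sum(sh == s), anom_snr = mean(snr[sh == s]))
  }))
  out
}

#' Table-style merging report by resolution shell
#'
#' Computes completeness, multiplicity, mean I/sigma (merged), R_merge,
#' R_p.i.m., R_anom, CC(1/2) and the anomalous signal-to-noise per
#' equal-reciprocal-volume shell plus an overall row, in the layout of a
#' standard data-collection statistics table.
#'
#' @param obs Unmerged observations (`h`, `k`, `l`, `I`, `sigma`).
#' @param cell `nsad_cell`.
#' @param d_min Resolution limit used for theoretical completeness.
#' @param n_shells Number of shells (default 10).
#' @param seed Seed for the CC(1/2) split.
#' @return list with `shells` (data.frame, one row per shell) and
#'   `overall` (one-row data.frame).
#' @export
table1_report <- function(obs, cell, d_min, n_shells = 10L, seed = 1L) {
  theo <- reflection_list(cell, d_min)
  d_theo <- theo$d
  sh_theo <- shell_assign(d_theo, n_shells)
  can <- canonical_hkl(as.matrix(obs[, c("h", "k", "l")]))
  d_obs <- d_spacing(as.matrix(can[, c("h", "k", "l")]), cell)
  sh_obs <- shell_assign(d_obs, n_shells)
  merged <- merge_observations(obs)
  d_mrg <- d_spacing(as.matrix(merged[, c("h", "k", "l")]), cell)
  sh_mrg <- shell_assign(d_mrg, n_shells)

  one_block <- function(sel_obs, sel_mrg, sel_theo) {
    o <- obs[sel_obs, , drop = FALSE]
    m <- merged[sel_mrg, , drop = FALSE]
    uniq_obs <- unique(paste(can$h, can$k, can$l)[sel_obs])
    Im <- c(m$I_plus, m$I_minus); Sm <- c(m$sig_plus, m$sig_minus)
    okm <- !is.na(Im)
    data.frame(
      n_obs = nrow(o),
      n_unique = length(uniq_obs),
      completeness = length(uniq_obs) / sum(sel_theo),
      multiplicity = nrow(o) / max(length(uniq_obs), 1L),
      mean_i_over_sigma = mean(Im[okm] / Sm[okm]),
      r_merge = r_merge(o),
      r_pim = r_pim(o),
      r_anom = r_anom(m),
      cc_half = cc_half(o, seed = seed),
      anom_flag = r_anom(m) / r_pim(o) > 1)
  }
  shells <- do.call(rbind, lapply(seq_len(n_shells), function(s) {
    blk <- one_block(sh_obs == s, sh_mrg == s, sh_theo == s)
    cbind(data.frame(shell = s,
                     d_max = max(d_theo[sh_theo == s]),
                     d_min = min(d_theo[sh_theo == s])), blk)
  }))
  snr <- anom_snr_by_shell(merged, cell, n_shells = n_shells)
  shells$anom_snr <- snr$anom_snr[match(shells$shell, snr$shell)]
  overall <- one_block(rep(TRUE, nrow(obs)), rep(TRUE, nrow(merged)),
                       rep(TRUE, nrow(theo)))
  overall$anom_snr <- mean(pmin(abs(anomalous_differences(merged)$dF) /
                                  anomalous_differences(merged)$sig_dF, 1e3))
  list(shells = shells, overall = overall)
}
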