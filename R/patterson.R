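# Anomalous-difference Patterson synthesis, Harker sections, peak search
# and single-site back-solving for P212121.
#
# Harker geometry of P212121 for a site (x, y, z):
#   w = 1/2 section : peak at (2x - 1/2, 2y)
#   v = 1/2 section : peak at (2x, 2z - 1/2)
#   u = 1/2 section : peak at (2y - 1/2, 2z)

#' Anomalous-difference Patterson map
#'
#' P(u) = sum_h |dF(h)|^2 cos(2 pi h.u), real and centrosymmetric,
#' computed by FFT on a fractional grid. Grid dimensions default to a
#' spacing of d_min/3 and are rounded up to even numbers so the
#' half-integral Harker planes are exact grid planes. The map is
#' sigma-scaled: mean 0, sigma 1 computed outside a masked origin region.
#'
#' @param coef data.frame with `h`, `k`, `l`, `dF` (and optionally
#'   `sig_dF` when `weighted = TRUE`), e.g. from
#'   [anomalous_differences()].
#' @param cell `nsad_cell`.
#' @param grid Optional integer vector of grid dimensions (even); default
#'   derived from `d_min`.
#' @param d_min Resolution used for the default grid spacing (default the
#'   finest d present in `coef`).
#' @param weighted If TRUE, coefficients are weighted by 1/sigma(dF)^2;
#'   default FALSE (classic unweighted |dF|^2 Patterson).
#' @param origin_mask_steps Radius of the origin mask in grid steps
#'   (default 1.5) used for the sigma scaling and honoured by
#'   [peak_search()].
#' @return Object of class `nsad_map`: list with `values` (3-D array, in
#'   sigma units), `cell`, `dims`, `mean_raw`, `sigma_raw`,
#'   `origin_mask` (logical array), `kind = "patterson"`.
#' @export
patterson_map <- function(coef, cell, grid = NULL, d_min = NULL,
                          weighted = FALSE, origin_mask_steps = 1.5) {
  if (nrow(coef) < 10L) stop("need at least 10 coefficients")
  hkl <- as.matrix(coef[, c("h", "k", "l")])
  if (is.null(d_min)) d_min <- min(d_spacing(hkl, cell))
  if (is.null(grid)) {
    step <- d_min / 3
    grid <- vapply(c(cell$a, cell$b, cell$c),
                   function(e) 2L * as.integer(ceiling(e / step / 2)), 0L)
  }
  grid <- as.integer(grid)
  if (any(grid < 2L)) stop("degenerate grid")
  if (any(grid %% 2L != 0L)) stop("grid dimensions must be even for exact Harker planes")
  w <- coef$dF^2
  if (weighted) w <- w / coef$sig_dF^2
  arr <- array(0, dim = grid)
  # expand |dF|^2 over the full mmm-symmetric sphere: all eight sign
  # combinations carry the same coefficient (assignment, so duplicated
  # zone images are not double counted)
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  for (s in seq_len(nrow(signs))) {
    hs <- sweep(hkl, 2, signs[s, ], `*`)
    i1 <- (hs[, 1] %% grid[1]) + 1L
    i2 <- (hs[, 2] %% grid[2]) + 1L
    i3 <- (hs[, 3] %% grid[3]) + 1L
    arr[cbind(i1, i2, i3)] <- w
  }
  vals <- Re(stats::fft(arr, inverse = TRUE))
  .finish_map(vals, cell, grid, origin_mask_steps, kind = "patterson")
}

# sigma-scale a raw map with an origin mask (wraparound distance in grid
# steps <= origin_mask_steps)
.finish_map <- function(vals, cell, grid, origin_mask_steps, kind) {
  ix <- seq_len(grid[1]) - 1L; iy <- seq_len(grid[2]) - 1L; iz <- seq_len(grid[3]) - 1L
  dx <- pmin(ix, grid[1] - ix); dy <- pmin(iy, grid[2] - iy); dz <- pmin(iz, grid[3] - iz)
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  mask <- d2 <= origin_mask_steps^2
  mu <- mean(vals[!mask])
  sg <- stats::sd(vals[!mask])
  if (sg <= 0) stop("map sigma is zero")
  structure(list(values = (vals - mu) / sg, cell = cell, dims = grid,
                 mean_raw = mu, sigma_raw = sg, origin_mask = mask,
                 kind = kind),
            class = "nsad_map")
}

#' Extract the three Harker sections of a P212121 Patterson map
#'
#' Sections u = 1/2, v = 1/2 and w = 1/2 taken on the exact half-way grid
#' planes (grid dimensions are even by construction). Values are the
#' map's own sigma-scaled values; no interpolation.
#'
#' @param map `nsad_map` from [patterson_map()].
#' @return list of three matrices `u`, `v`, `w`; each has an `axes`
#'   attribute naming its in-plane fractional coordinates.
#' @export
harker_sections <- function(map) {
  d <- map$dims
  if (any(d %% 2L != 0L)) stop("grid dimensions must be even")
  sec_u <- map$values[d[1] / 2 + 1L, , ]
  sec_v <- map$values[, d[2] / 2 + 1L, ]
  sec_w <- map$values[, , d[3] / 2 + 1L]
  attr(sec_u, "axes") <- c("v", "w")
  attr(sec_v, "axes") <- c("u", "w")
  attr(sec_w, "axes") <- c("u", "v")
  list(u = sec_u, v = sec_v, w = sec_w)
}

# one-dimensional quadratic sub-grid peak offset
.quad_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (den >= 0) return(0)
  off <- 0.5 * (fm - fp) / den
  max(min(off, 0.5), -0.5)
}

#' Peak search on a Harker section or a full map
#'
#' Finds local maxima (with wraparound) above a sigma threshold, refines
#' each position by per-axis quadratic interpolation, and returns peaks
#' sorted by height in map-sigma units. For a full `nsad_map` the origin
#' region recorded in the map is excluded.
#'
#' @param x Matrix (a Harker section, in sigma units) or `nsad_map`.
#' @param top_n Maximum number of peaks returned (default 10).
#' @param sigma_cut Height threshold in sigma units (default 2).
#' @return data.frame of peaks: fractional coordinates (`u1`, `u2` for a
#'   section; `u`, `v`, `w` for a map) and `height_sigma`. Empty when no
#'   peak clears the threshold.
#' @export
peak_search <- function(x, top_n = 10L, sigma_cut = 2) {
  if (inherits(x, "nsad_map")) return(.peak_search_3d(x, top_n, sigma_cut))
  m <- x
  n1 <- nrow(m); n2 <- ncol(m)
  sh <- function(a, i, j) a[((seq_len(n1) - 1 + i) %% n1) + 1,
                            ((seq_len(n2) - 1 + j) %% n2) + 1, drop = FALSE]
  is_max <- m > sigma_cut
  for (i in -1:1) for (j in -1:1) {
    if (i == 0 && j == 0) next
    is_max <- is_max & (m >= sh(m, i, j))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(u1 = numeric(0), u2 = numeric(0), height_sigma = numeric(0)))
  }
  peaks <- do.call(rbind, lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    gv <- function(di, dj) m[((i - 1 + di) %% n1) + 1, ((j - 1 + dj) %% n2) + 1]
    o1 <- .quad_offset(gv(-1, 0), gv(0, 0), gv(1, 0))
    o2 <- .quad_offset(gv(0, -1), gv(0, 0), gv(0, 1))
    data.frame(u1 = ((i - 1 + o1) / n1) %% 1, u2 = ((j - 1 + o2) / n2) %% 1,
               height_sigma = gv(0, 0))
  }))
  peaks <- peaks[order(-peaks$height_sigma), , drop = FALSE]
  utils::head(peaks, top_n)
}

.peak_search_3d <- function(map, top_n, sigma_cut) {
  m <- map$values
  d <- dim(m)
  is_max <- m > sigma_cut & !map$origin_mask
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    if (i == 0 && j == 0 && k == 0) next
    shifted <- m[((seq_len(d[1]) - 1 + i) %% d[1]) + 1,
                 ((seq_len(d[2]) - 1 + j) %% d[2]) + 1,
                 ((seq_len(d[3]) - 1 + k) %% d[3]) + 1]
    is_max <- is_max & (m >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(u = numeric(0), v = numeric(0), w = numeric(0),
                      height_sigma = numeric(0)))
  }
  gv <- function(i, j, k) m[((i - 1) %% d[1]) + 1, ((j - 1) %% d[2]) + 1,
                            ((k - 1) %% d[3]) + 1]
  peaks <- do.call(rbind, lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    o1 <- .quad_offset(gv(i - 1, j, k), gv(i, j, k), gv(i + 1, j, k))
    o2 <- .quad_offset(gv(i, j - 1, k), gv(i, j, k), gv(i, j + 1, k))
    o3 <- .quad_offset(gv(i, j, k - 1), gv(i, j, k), gv(i, j, k + 1))
    data.frame(u = ((i - 1 + o1) / d[1]) %% 1, v = ((j - 1 + o2) / d[2]) %% 1,
               w = ((k - 1 + o3) / d[3]) %% 1, height_sigma = gv(i, j, k))
  }))
  peaks <- peaks[order(-peaks$height_sigma), , drop = FALSE]
  utils::head(peaks, top_n)
}

# wrapped fractional difference in [-1/2, 1/2)
.wrap <- function(x) ((x + 0.5) %% 1) - 0.5

#' Canonical representative of a single-site solution
#'
#' A single anomalous site in P212121 is determined by its Patterson only
#' up to the permissible origin shifts (1/2 along each axis), the
#' space-group rotations, and inversion (hand). Because the rotations are
#' diagonal sign changes whose translations are half-cell vectors, the
#' full equivalence group acts as all eight per-axis sign patterns
#' combined with the half-cell shifts (even sign patterns are the same
#' hand, odd patterns the inverted hand). The canonical representative
#' folds every image into \[0, 1/2)^3 and takes the lexicographic
#' minimum.
#'
#' @param xyz Numeric length-3 fractional coordinates.
#' @return Numeric length-3 canonical coordinates.
#' @export
canonical_site <- function(xyz) {
  fold <- function(t) {
    u <- t %% 1
    ifelse(u < 0.5, u, u - 0.5)
  }
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  best <- NULL
  for (s in seq_len(nrow(signs))) {
    cand <- fold(signs[s, ] * xyz)
    if (is.null(best)) best <- cand
    else {
      cmp <- cand - best
      nz <- which(abs(cmp) > 1e-12)
      if (length(nz) > 0L && cmp[nz[1]] < 0) best <- cand
    }
  }
  best
}

#' Distance between two sites modulo origin shifts and hand
#'
#' Minimum Cartesian distance (A) between the images of `a` under the
#' single-site equivalence group of P212121 (all per-axis sign patterns
#' times half-cell origin shifts; see [canonical_site()]) and the site
#' `b`.
#'
#' @param a,b Fractional coordinates (length 3).
#' @param cell `nsad_cell`.
#' @return Distance in Angstrom.
#' @export
site_distance <- function(a, b, cell) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  edges <- c(cell$a, cell$b, cell$c)
  # per-axis: min over sign and half-cell shift of the wrapped difference
  d_axis <- function(t, u, e) {
    cand <- c(t - u, -t - u)
    frac <- abs(((cand + 0.25) %% 0.5) - 0.25)
    min(frac) * e
  }
  # sign patterns act jointly but shifts are per-axis, so the per-axis
  # minimum over both sign choices is attainable: every sign pattern is
  # in the group
  sqrt(sum(vapply(1:3, function(i) d_axis(a[i], b[i], edges[i]), 0)^2))
}

#' Solve the anomalous site from Harker-section peaks
#'
#' Inverts the three P212121 Harker relations for a single site: each
#' section peak determines two coordinates up to sign and half-cell
#' ambiguity; all candidate (x, y, z) from the w = 1/2 section peaks and
#' z candidates from the v = 1/2 peaks are enumerated and scored by the
#' agreement (wrapped Cartesian distance, A) between their predicted and
#' observed peak positions on all three sections. Candidates are
#' canonicalized, deduplicated, and returned best (lowest score) first;
#' ties break lexicographically.
#'
#' @param peaks list with components `w`, `v`, `u`: peak tables from
#'   [peak_search()] on the corresponding sections (at least `w` and `v`
#'   must be non-empty).
#' @param cell `nsad_cell`.
#' @param max_score Mean per-section disagreement (A) above which
#'   candidates are dropped (default 1.5 A).
#' @param n_peaks How many peaks per section to consider (default 3).
#' @return data.frame of candidate sites `x`, `y`, `z` (canonical),
#'   `score` (A); zero rows with a `diagnostics` attribute when nothing
#'   scores below `max_score`.
#' @export
solve_site_from_harker <- function(peaks, cell, max_score = 1.5, n_peaks = 3L) {
  pw <- utils::head(peaks$w, n_peaks)
  pv <- utils::head(peaks$v, n_peaks)
  pu <- utils::head(peaks$u, n_peaks)
  if (nrow(pw) == 0L || nrow(pv) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0))
    attr(out, "diagnostics") <- "need peaks on at least the w and v Harker sections"
    return(out)
  }
  edges <- c(cell$a, cell$b, cell$c)
  # candidate generation: (x, y) from w-section peaks (p, q) via
  # x = (s p + 1/2)/2 + {0, 1/2}, y = s q / 2 + {0, 1/2} (s the joint
  # centrosymmetric sign); z from v-section second coordinate
  cand <- list()
  for (iw in seq_len(nrow(pw))) {
    p <- pw$u1[iw]; q <- pw$u2[iw]
    for (s in c(1, -1)) for (ax in c(0, 0.5)) for (ay in c(0, 0.5)) {
      x <- ((s * p + 0.5) / 2 + ax) %% 1
      y <- ((s * q) / 2 + ay) %% 1
      for (iv in seq_len(nrow(pv))) {
        r2 <- pv$u2[iv]
        for (sz in c(1, -1)) for (az in c(0, 0.5)) {
          z <- ((sz * r2 + 0.5) / 2 + az) %% 1
          cand[[length(cand) + 1L]] <- c(x, y, z)
        }
      }
    }
  }
  cand <- unique(do.call(rbind, cand))
  score_one <- function(site, pred, obs, dims) {
    if (nrow(obs) == 0L) return(NA_real_)
    dmin <- Inf
    for (i in seq_len(nrow(obs))) {
      for (s in c(1, -1)) {
        dd <- .wrap(pred - s * c(obs$u1[i], obs$u2[i])) * dims
        dmin <- min(dmin, sqrt(sum(dd^2)))
      }
    }
    dmin
  }
  scores <- apply(cand, 1, function(site) {
    x <- site[1]; y <- site[2]; z <- site[3]
    sw <- score_one(site, c(2 * x - 0.5, 2 * y), pw, edges[c(1, 2)])
    sv <- score_one(site, c(2 * x, 2 * z - 0.5), pv, edges[c(1, 3)])
    su <- score_one(site, c(2 * y - 0.5, 2 * z), pu, edges[c(2, 3)])
    mean(c(sw, sv, su), na.rm = TRUE)
  })
  keep <- which(scores <= max_score)
  if (length(keep) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0))
    attr(out, "diagnostics") <- sprintf(
      "best candidate score %.2f A exceeds max_score %.2f A", min(scores), max_score)
    return(out)
  }
  sites <- t(apply(cand[keep, , drop = FALSE], 1, canonical_site))
  out <- data.frame(x = sites[, 1], y = sites[, 2], z = sites[, 3],
                    score = scores[keep])
  out <- out[order(out$score, out$x, out$y, out$z), , drop = FALSE]
  # deduplicate canonically equivalent candidates (keep best-scoring)
  dup <- duplicated(round(out[, c("x", "y", "z")], 4))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the anomalous site from merged data
#'
#' Convenience wrapper: Bijvoet differences (truncated at `d_min_sub`,
#' the substructure-search cutoff), anomalous-difference Patterson,
#' Harker sections, peak search, Harker inversion.
#'
#' @param merged Output of [merge_observations()].
#' @param cell `nsad_cell`.
#' @param d_min_sub Resolution cutoff for the substructure search
#'   (default 2.3 A, excluding the noisier high-resolution differences).
#' @param sigma_cut Peak threshold in sigma units (default 2.5).
#' @param ... Passed to [solve_site_from_harker()].
#' @return list with `sites` (candidate table), `peaks`, `sections`,
#'   `map`.
#' @export
locate_site <- function(merged, cell, d_min_sub = 2.3, sigma_cut = 2.5, ...) {
  ad <- anomalous_differences(merged)
  d <- d_spacing(as.matrix(ad[, c("h", "k", "l")]), cell)
  ad <- ad[d >= d_min_sub, , drop = FALSE]
  map <- patterson_map(ad, cell, d_min = d_min_sub)
  secs <- harker_sections(map)
  peaks <- list(u = peak_search(secs$u, sigma_cut = sigma_cut),
                v = peak_search(secs$v, sigma_cut = sigma_cut),
                w = peak_search(secs$w, sigma_cut = sigma_cut))
  sites <- solve_site_from_harker(peaks, cell, ...)
  list(sites = sites, peaks = peaks, sections = secs, map = map)
}
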