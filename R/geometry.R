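# Superposition-based deviation/fluctuation metrics, compactness,
# exposure and distance series.
#
# Coordinates are assumed whole/unwrapped; there is no periodic-boundary
# minimum-image handling anywhere in the package.

# Bondi van der Waals radii (nm), keyed by element.
.bondi_radii <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                  F = 0.147, P = 0.180, S = 0.180, CL = 0.175,
                  BR = 0.185, I = 0.198)

.series <- function(times_ps, values, label, units) {
  stopifnot(length(times_ps) == length(values))
  structure(data.frame(time_ps = times_ps, value = values),
            label = label, units = units,
            class = c("md_series", "data.frame"))
}

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD of `mobile` onto `reference`; the reflection branch of
#' the SVD solution is corrected so the rotation always has determinant +1.
#'
#' @param mobile `n x 3` coordinate matrix (nm).
#' @param reference `n x 3` coordinate matrix (nm).
#' @param weights optional per-atom weights (e.g. masses).
#' @return list with `rotation` (3x3), `translation` (length 3, so that
#'   `reference ~ mobile %*% t(rotation) + translation`) and `rmsd` (nm,
#'   after the fit).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("coordinate counts differ")
  if (n < 3L) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  mu_x <- colSums(mobile * w)
  mu_y <- colSums(reference * w)
  X <- sweep(mobile, 2L, mu_x)
  Y <- sweep(reference, 2L, mu_y)
  sv_chk <- svd(X * sqrt(w))$d
  if (sv_chk[2L] <= 1e-10 * max(sv_chk[1L], 1e-300)) {
    stop("degenerate (collinear) configuration: superposition rank < 2")
  }
  C <- t(X * w) %*% Y
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.numeric(mu_y - R %*% mu_x), rmsd = rmsd)
}

# Apply a fit computed on fit_idx of each frame to all atoms of the frame.
# Returns an n_atoms x 3 x n_frames array of fitted coordinates.
.fit_frames <- function(coords, ref, fit_idx, weights = NULL) {
  nf <- dim(coords)[3L]
  out <- coords
  for (k in seq_len(nf)) {
    fr <- coords[, , k]
    fit <- kabsch_superpose(fr[fit_idx, , drop = FALSE], ref, weights)
    out[, , k] <- fr %*% t(fit$rotation) +
      matrix(fit$translation, nrow(fr), 3L, byrow = TRUE)
  }
  out
}

# Iterated mean structure on fit_idx: fit to first frame, average, refit to
# the mean, re-average.  Returns list(mean_all = n x 3 mean over all atoms,
# fitted = fitted coordinate array).
.mean_structure <- function(coords, fit_idx) {
  ref <- coords[fit_idx, , 1L, drop = TRUE]
  fitted <- .fit_frames(coords, ref, fit_idx)
  m <- apply(fitted, c(1L, 2L), mean)
  fitted <- .fit_frames(coords, m[fit_idx, , drop = FALSE], fit_idx)
  m <- apply(fitted, c(1L, 2L), mean)
  list(mean_all = m, fitted = fitted)
}

#' RMSD time series after least-squares fitting
#'
#' Each frame is superposed onto the reference frame on the selection and
#' the RMSD over that selection is recorded.
#'
#' @param traj an `md_trajectory`.
#' @param selection selection expression or integer atom indices.
#' @param reference_frame index of the reference frame (default 1).
#' @return an `md_series` data frame with columns `time_ps`, `value` (nm).
#' @export
rmsd_series <- function(traj, selection = "backbone", reference_frame = 1L) {
  idx <- .resolve(traj, selection)
  if (length(idx) == 0L) stop("empty selection")
  ref <- traj$coords[idx, , reference_frame, drop = TRUE]
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    vals[k] <- kabsch_superpose(traj$coords[idx, , k, drop = TRUE], ref)$rmsd
  }
  .series(frame_times(traj), vals, "RMSD", "nm")
}

.resolve <- function(traj, selection) {
  if (is.character(selection)) select_atoms(traj, selection)
  else as.integer(selection)
}

#' Root mean square fluctuation profile
#'
#' Frames in the window are superposed on `fit_selection` onto the
#' window-mean structure (computed by one fit-average iteration, or onto
#' the first window frame with `fit_reference = "first_frame"`); the RMSF
#' of each selected atom about its mean position is then taken, optionally
#' aggregated per residue as the root mean square over the residue's
#' selected atoms.
#'
#' @param traj an `md_trajectory`.
#' @param selection atoms to profile.
#' @param fit_selection atoms used for the superposition (defaults to
#'   `selection`).
#' @param window_ns trailing window in ns (`NULL` = all frames).
#' @param by_residue aggregate per residue (default) or per atom.
#' @param fit_reference `"window_mean"` (default) or `"first_frame"`.
#' @return data frame with columns `chain`, `resid`, `value` (nm) and, for
#'   per-atom profiles, `name`.
#' @export
rmsf <- function(traj, selection = "backbone", fit_selection = selection,
                 window_ns = NULL, by_residue = TRUE,
                 fit_reference = c("window_mean", "first_frame")) {
  fit_reference <- match.arg(fit_reference)
  idx <- .resolve(traj, selection)
  fit_idx <- .resolve(traj, fit_selection)
  if (length(idx) == 0L || length(fit_idx) == 0L) stop("empty selection")
  frames <- frames_in_window(traj, window_ns)
  if (length(frames) < 2L) stop("RMSF window must span at least 2 frames")
  coords <- traj$coords[, , frames, drop = FALSE]
  if (fit_reference == "window_mean") {
    ms <- .mean_structure(coords, fit_idx)
    fitted <- ms$fitted
  } else {
    fitted <- .fit_frames(coords, coords[fit_idx, , 1L, drop = TRUE], fit_idx)
  }
  sub <- fitted[idx, , , drop = FALSE]
  mean_pos <- apply(sub, c(1L, 2L), mean)
  dev2 <- sweep(sub, c(1L, 2L), mean_pos)^2
  # mean over frames of the squared displacement summed over x,y,z
  msf <- rowMeans(matrix(apply(dev2, 3L, rowSums), nrow = length(idx)))
  at <- traj$atoms[idx, ]
  if (!by_residue) {
    return(data.frame(chain = at$chain, resid = at$resid, name = at$name,
                      value = sqrt(msf)))
  }
  key <- paste(at$chain, at$resid, sep = "\r")
  agg <- tapply(msf, key, mean)
  first <- !duplicated(key)
  ord <- match(unique(key), names(agg))
  data.frame(chain = at$chain[first], resid = at$resid[first],
             value = sqrt(as.numeric(agg[ord])))
}

#' Pearson correlation between two chains' RMSF profiles
#'
#' @param profile_a,profile_b equal-length numeric vectors or RMSF data
#'   frames (their `value` columns are used) for the two chains' identical
#'   residues.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
rmsf_chain_correlation <- function(profile_a, profile_b) {
  a <- if (is.data.frame(profile_a)) profile_a$value else profile_a
  b <- if (is.data.frame(profile_b)) profile_b$value else profile_b
  if (length(a) != length(b)) stop("profiles have different lengths")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero variance in a profile")
  }
  stats::cor(a, b)
}

#' Radius of gyration time series
#'
#' Mass-weighted by default:
#' `Rg = sqrt(sum(m_i |x_i - x_com|^2) / sum(m_i))`.
#'
#' @param traj an `md_trajectory`.
#' @param selection atoms to include.
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @return an `md_series` (nm).
#' @export
radius_of_gyration <- function(traj, selection = "all",
                               mass_weighted = TRUE) {
  idx <- .resolve(traj, selection)
  if (length(idx) == 0L) stop("empty selection")
  m <- if (mass_weighted) traj$atoms$mass[idx] else rep(1, length(idx))
  if (sum(m) <= 0) stop("total mass is zero")
  w <- m / sum(m)
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    x <- traj$coords[idx, , k, drop = FALSE]
    dim(x) <- c(length(idx), 3L)
    com <- colSums(x * w)
    vals[k] <- sqrt(sum(w * rowSums(sweep(x, 2L, com)^2)))
  }
  .series(frame_times(traj), vals, "Rg", "nm")
}

.com <- function(x, w) colSums(x * (w / sum(w)))

#' Centre-of-mass distance time series between two groups
#'
#' @param traj an `md_trajectory`.
#' @param selection_a,selection_b the two atom groups.
#' @param mass_weighted mass-weighted centres (default) or geometric.
#' @return an `md_series` (nm).
#' @export
com_distance <- function(traj, selection_a, selection_b,
                         mass_weighted = TRUE) {
  ia <- .resolve(traj, selection_a)
  ib <- .resolve(traj, selection_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  wa <- if (mass_weighted) traj$atoms$mass[ia] else rep(1, length(ia))
  wb <- if (mass_weighted) traj$atoms$mass[ib] else rep(1, length(ib))
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    xa <- matrix(traj$coords[ia, , k], length(ia), 3L)
    xb <- matrix(traj$coords[ib, , k], length(ib), 3L)
    vals[k] <- sqrt(sum((.com(xa, wa) - .com(xb, wb))^2))
  }
  .series(frame_times(traj), vals, "COM distance", "nm")
}

# Pairwise cross distances between two coordinate sets (na x nb matrix).
.cross_dist <- function(xa, xb) {
  a2 <- rowSums(xa^2); b2 <- rowSums(xb^2)
  d2 <- outer(a2, b2, "+") - 2 * xa %*% t(xb)
  sqrt(pmax(d2, 0))
}

#' Minimum cross-pair distance time series between two groups
#'
#' @param traj an `md_trajectory`.
#' @param selection_a,selection_b two disjoint atom groups.
#' @return an `md_series` (nm).
#' @export
min_distance <- function(traj, selection_a, selection_b) {
  ia <- .resolve(traj, selection_a)
  ib <- .resolve(traj, selection_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  if (length(intersect(ia, ib)) > 0L) {
    stop("selections overlap; minimum cross distance is undefined")
  }
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    xa <- matrix(traj$coords[ia, , k], length(ia), 3L)
    xb <- matrix(traj$coords[ib, , k], length(ib), 3L)
    vals[k] <- min(.cross_dist(xa, xb))
  }
  .series(frame_times(traj), vals, "minimum distance", "nm")
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quasi-uniform test points are placed on each selected atom's expanded
#' sphere (van der Waals radius + probe); a point is exposed iff it lies
#' outside every other selected atom's expanded sphere, and the atom's
#' area is the exposed fraction of `4 pi (r_vdw + probe)^2`.
#'
#' @param x an `md_trajectory` (frame `frame`) or an `n x 3` coordinate
#'   matrix with `elements` supplied.
#' @param selection atoms to include (ignored for a bare matrix).
#' @param probe_radius probe radius in nm (water: 0.14).
#' @param n_points test points per atom.
#' @param frame frame index when `x` is a trajectory.
#' @param elements element symbols when `x` is a bare matrix.
#' @param radii named vdW radius table in nm (defaults to the Bondi set).
#' @return list with `per_atom` (nm^2) and `total` (nm^2).
#' @export
sasa <- function(x, selection = "heavy", probe_radius = 0.14,
                 n_points = 960L, frame = 1L, elements = NULL,
                 radii = .bondi_radii) {
  if (inherits(x, "md_trajectory")) {
    idx <- .resolve(x, selection)
    if (length(idx) == 0L) stop("empty selection")
    coords <- matrix(x$coords[idx, , frame], length(idx), 3L)
    elements <- x$atoms$element[idx]
  } else {
    coords <- as.matrix(x)
    if (is.null(elements)) stop("elements must be given for bare coordinates")
  }
  rv <- radii[toupper(elements)]
  if (anyNA(rv)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(rv)]), collapse = ", "))
  }
  R <- unname(rv) + probe_radius
  n <- nrow(coords)
  pts <- .sphere_points(n_points)
  per_atom <- numeric(n)
  dmat <- .cross_dist(coords, coords)
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < R[i] + R & seq_len(n) != i)
    if (length(nb) == 0L) {
      per_atom[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2L, coords[i, ], "+")
    d <- .cross_dist(p, coords[nb, , drop = FALSE])
    exposed <- rowSums(d <= matrix(R[nb], n_points, length(nb),
                                   byrow = TRUE)) == 0L
    per_atom[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' SASA time series
#'
#' @param traj an `md_trajectory`.
#' @param selection atoms to include.
#' @param stride evaluate every `stride`-th frame (SASA is the most
#'   expensive per-frame metric).
#' @param ... passed to [sasa()].
#' @return an `md_series` (nm^2) over the strided frames.
#' @export
sasa_series <- function(traj, selection = "heavy", stride = 1L, ...) {
  frames <- seq(1L, n_frames(traj), by = stride)
  vals <- vapply(frames, function(k) {
    sasa(traj, selection = selection, frame = k, ...)$total
  }, numeric(1L))
  .series(frame_times(traj)[frames], vals, "SASA", "nm^2")
}
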