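# Essential dynamics: coordinate covariance analysis, principal-component
# projections, free-energy landscapes, covariance overlap, RMSIP and
# porcupine vectors.

#' Boltzmann constant, kJ mol^-1 K^-1
#' @export
BOLTZMANN_KJ_MOL_K <- 0.0083144621

# Pool windowed frames from one trajectory or a list of runs, as selection
# coordinates (n_sel x 3 x total_frames) plus full frame bookkeeping.
.pool_frames <- function(trajs, idx, window_ns) {
  if (inherits(trajs, "md_trajectory")) trajs <- list(trajs)
  blocks <- lapply(trajs, function(tr) {
    frames <- frames_in_window(tr, window_ns)
    list(coords = tr$coords[idx, , frames, drop = FALSE],
         times = frame_times(tr)[frames])
  })
  n_each <- vapply(blocks, function(b) dim(b$coords)[3L], integer(1L))
  coords <- array(unlist(lapply(blocks, `[[`, "coords")),
                  dim = c(length(idx), 3L, sum(n_each)))
  list(coords = coords, times = unlist(lapply(blocks, `[[`, "times")),
       run = rep(seq_along(blocks), n_each))
}

# Fit selection coordinate blocks to a reference selection structure.
.fit_sel_frames <- function(coords, ref, weights = NULL) {
  nf <- dim(coords)[3L]
  out <- coords
  for (k in seq_len(nf)) {
    fr <- matrix(coords[, , k], dim(coords)[1L], 3L)
    fit <- kabsch_superpose(fr, ref, weights)
    out[, , k] <- fr %*% t(fit$rotation) +
      matrix(fit$translation, nrow(fr), 3L, byrow = TRUE)
  }
  out
}

#' Build a coordinate covariance model
#'
#' Frames from the trailing window (pooled across runs when a list of
#' trajectories is given, emulating concatenated independent simulations)
#' are least-squares fitted on the selection, by one fit-average
#' iteration: fit to the first frame, average, refit to that mean.  The
#' 3N x 3N covariance `C = <(x - <x>)(x - <x>)^T>` (ensemble average,
#' divisor n) is then diagonalised.  Covariance is unweighted by default;
#' `mass_weighted = TRUE` scales coordinates by `sqrt(m_i)` first.
#'
#' @param trajs an `md_trajectory` or a list of them (independent runs
#'   sharing one topology).
#' @param selection atoms entering the covariance (expression or indices,
#'   resolved on the first trajectory).
#' @param window_ns trailing window in ns (`NULL` = all frames).
#' @param mass_weighted mass-weight coordinates before accumulation.
#' @return a `covariance_model`: list with `atoms`, `selection`,
#'   `fit_reference` (N x 3 Kabsch target), `mean` (3N), `cov`,
#'   `eigenvalues` (descending, nm^2), `eigenvectors` (orthonormal
#'   columns), `trace` (nm^2), `n_frames`.
#' @export
build_covariance <- function(trajs, selection = "backbone",
                             window_ns = NULL, mass_weighted = FALSE) {
  first <- if (inherits(trajs, "md_trajectory")) trajs else trajs[[1L]]
  idx <- .resolve(first, selection)
  if (length(idx) == 0L) stop("empty selection")
  pool <- .pool_frames(trajs, idx, window_ns)
  nf <- dim(pool$coords)[3L]
  if (nf < 2L) stop("covariance needs at least 2 frames")
  fitted <- .fit_sel_frames(pool$coords, matrix(pool$coords[, , 1L],
                                                length(idx), 3L))
  m1 <- apply(fitted, c(1L, 2L), mean)
  fitted <- .fit_sel_frames(pool$coords, m1)
  w <- if (mass_weighted) sqrt(first$atoms$mass[idx]) else rep(1, length(idx))
  X <- t(apply(fitted, 3L, function(m) as.numeric(t(m * w))))
  # rows = frames, columns = (x1,y1,z1,x2,...) in nm
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nf
  eig <- eigen(C, symmetric = TRUE)
  structure(
    list(atoms = first$atoms[idx, ], selection = idx,
         fit_reference = m1, mean = mu, cov = C,
         eigenvalues = eig$values, eigenvectors = eig$vectors,
         trace = sum(diag(C)), n_frames = nf,
         mass_weights = w),
    class = "covariance_model"
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("covariance_model:", nrow(x$atoms), "atoms,", x$n_frames, "frames\n")
  cat("  trace:", format(x$trace), "nm^2; top eigenvalues:",
      paste(format(utils::head(x$eigenvalues, 3L), digits = 4L),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative variance fraction of the leading modes
#'
#' @param model a `covariance_model`.
#' @param k number of leading eigenvalues.
#' @return `sum(eigenvalues[1:k]) / trace`.
#' @export
cumulative_variance <- function(model, k) {
  if (k > length(model$eigenvalues)) stop("k exceeds 3N")
  if (model$trace <= 0) stop("cumulative variance undefined: zero trace")
  sum(model$eigenvalues[seq_len(k)]) / model$trace
}

#' Project a trajectory onto the leading principal components
#'
#' Each frame's selection coordinates are fitted to the model's fit
#' reference (exactly as during [build_covariance()]) and the centred 3N
#' vector is projected onto the first `k` eigenvectors.  Projecting the
#' training frames reproduces the eigenvalues as score variances
#' (divisor n).
#'
#' @param trajs an `md_trajectory` or list of runs.
#' @param model a `covariance_model`.
#' @param k number of components (default 10, capped at 3N).
#' @param window_ns trailing window in ns (`NULL` = all frames).
#' @return data frame with columns `time_ps`, `run`, `pc1` ... `pck`
#'   (scores in nm).
#' @export
project_trajectory <- function(trajs, model, k = 10L, window_ns = NULL) {
  k <- min(k, length(model$eigenvalues))
  pool <- .pool_frames(trajs, model$selection, window_ns)
  fitted <- .fit_sel_frames(pool$coords, model$fit_reference)
  w <- model$mass_weights
  X <- t(apply(fitted, 3L, function(m) as.numeric(t(m * w))))
  scores <- sweep(X, 2L, model$mean) %*% model$eigenvectors[, seq_len(k),
                                                            drop = FALSE]
  out <- data.frame(time_ps = pool$times, run = pool$run, scores)
  names(out)[-(1:2)] <- paste0("pc", seq_len(k))
  out
}

.score_matrix <- function(projections) {
  if (is.matrix(projections)) return(projections)
  as.matrix(projections[, grep("^pc[0-9]+$", names(projections)),
                        drop = FALSE])
}

#' Free-energy landscape over two principal components
#'
#' 2D histogram of the scores over `n_bins x n_bins` bins (data range
#' padded by 5 percent), converted to
#' `dG = -kB T log(P / P_max)`; unoccupied bins are `Inf` and the global
#' minimum over occupied bins is 0 by construction.
#'
#' @param projections projection data frame (from [project_trajectory()])
#'   or score matrix.
#' @param i,j principal-component indices for the two axes.
#' @param n_bins bins per axis (>= 2).
#' @param temperature_K temperature for `kB T` (default 300).
#' @return a `fel_grid`: list with `centers_i`, `centers_j`, `edges_i`,
#'   `edges_j`, `counts`, `dG` (kJ/mol), `temperature_K`, `pc` (the pair
#'   `c(i, j)`).
#' @export
fel <- function(projections, i = 1L, j = 2L, n_bins = 32L,
                temperature_K = 300) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  S <- .score_matrix(projections)
  si <- S[, i]; sj <- S[, j]
  edges <- function(v) {
    r <- range(v)
    pad <- 0.05 * diff(r)
    if (pad == 0) pad <- max(1e-9, abs(r[1L]) * 1e-9 + 1e-9)
    seq(r[1L] - pad, r[2L] + pad, length.out = n_bins + 1L)
  }
  ei <- edges(si); ej <- edges(sj)
  bi <- pmin(pmax(findInterval(si, ei, rightmost.closed = TRUE), 1L), n_bins)
  bj <- pmin(pmax(findInterval(sj, ej, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (t in seq_along(bi)) counts[bi[t], bj[t]] <- counts[bi[t], bj[t]] + 1L
  p <- counts / length(bi)
  dG <- matrix(Inf, n_bins, n_bins)
  occ <- counts > 0L
  dG[occ] <- -BOLTZMANN_KJ_MOL_K * temperature_K * log(p[occ] / max(p))
  structure(list(centers_i = (ei[-1L] + ei[-length(ei)]) / 2,
                 centers_j = (ej[-1L] + ej[-length(ej)]) / 2,
                 edges_i = ei, edges_j = ej, counts = counts, dG = dG,
                 temperature_K = temperature_K, pc = c(i, j)),
            class = "fel_grid")
}

#' Frame closest to the free-energy minimum
#'
#' Returns the frame whose score pair lies nearest (Euclidean distance in
#' PC space) to the centre of the global-minimum bin of the landscape;
#' ties resolve to the lowest frame index.
#'
#' @param felgrid a `fel_grid`.
#' @param projections the projections the grid was built from.
#' @return integer frame index into the projection rows.
#' @export
representative_frame <- function(felgrid, projections) {
  S <- .score_matrix(projections)
  si <- S[, felgrid$pc[1L]]; sj <- S[, felgrid$pc[2L]]
  occ <- which(felgrid$counts > 0L, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("no occupied bins")
  g <- felgrid$dG[occ]
  best <- occ[which.min(g), ]
  cx <- felgrid$centers_i[best[1L]]
  cy <- felgrid$centers_j[best[2L]]
  d2 <- (si - cx)^2 + (sj - cy)^2
  which.min(d2)  # which.min takes the first (lowest index) on ties
}

# Symmetric PSD matrix square root via eigendecomposition.  Eigenvalues
# below 1e-12 of the largest are zeroed outright: round-off values of
# order 1e-16 would otherwise contribute 1e-8-sized square roots along
# arbitrary directions.
.sqrtm_psd <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  v[v < max(v) * 1e-12] <- 0
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

.rank_k_reconstruction <- function(model, k) {
  k <- min(k, length(model$eigenvalues))
  V <- model$eigenvectors[, seq_len(k), drop = FALSE]
  lam <- pmax(model$eigenvalues[seq_len(k)], 0)
  V %*% (lam * t(V))
}

#' Normalized covariance overlap between two models
#'
#' Hess covariance overlap on the rank-k reconstructions `A_k`, `B_k`:
#' `1 - sqrt( tr(A_k + B_k - 2 (A_k^{1/2} B_k A_k^{1/2})^{1/2})
#'            / (tr A_k + tr B_k) )`,
#' clipped to \[0, 1\] against negative round-off.  1 means identical
#' fluctuation spaces, 0 means no shared variance.
#'
#' @param model_a,model_b `covariance_model`s over the same selection
#'   dimension.
#' @param k number of leading modes kept (default 10).
#' @return scalar overlap in \[0, 1\].
#' @export
covariance_overlap <- function(model_a, model_b, k = 10L) {
  if (length(model_a$mean) != length(model_b$mean)) {
    stop("models have different selection dimensions")
  }
  A <- .rank_k_reconstruction(model_a, k)
  B <- .rank_k_reconstruction(model_b, k)
  tra <- sum(diag(A)); trb <- sum(diag(B))
  if (tra + trb <= 0) stop("overlap undefined: both traces are zero")
  sa <- .sqrtm_psd(A)
  sb <- .sqrtm_psd(B)
  # tr((A^{1/2} B A^{1/2})^{1/2}) equals the nuclear norm of B^{1/2}A^{1/2},
  # so the distance term is the orthogonal-Procrustes residual
  # min_W ||A^{1/2} - B^{1/2} W||_F^2, evaluated here as an explicit
  # difference: this is algebraically the Hess formula but avoids the
  # catastrophic trace cancellation when A and B are close.
  s <- svd(sb %*% sa)
  W <- s$u %*% t(s$v)
  d <- sum((sa - sb %*% W)^2)
  ov <- 1 - sqrt(max(d, 0) / (tra + trb))
  min(max(ov, 0), 1)
}

#' Root mean square inner product of two eigenvector sets
#'
#' `rmsip = sqrt( (1/k) sum_{i<=k} sum_{j<=k} (v_i . w_j)^2 )`; 1 for
#' identical k-dimensional subspaces, 0 for orthogonal ones.
#'
#' @param model_a,model_b `covariance_model`s over the same selection
#'   dimension.
#' @param k number of leading eigenvectors from each model.
#' @return list with `rmsip` and the `k x k` `inner_products` matrix.
#' @export
rmsip <- function(model_a, model_b, k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  if (length(model_a$mean) != length(model_b$mean)) {
    stop("models have different selection dimensions")
  }
  k <- min(k, length(model_a$eigenvalues), length(model_b$eigenvalues))
  Va <- model_a$eigenvectors[, seq_len(k), drop = FALSE]
  Vb <- model_b$eigenvectors[, seq_len(k), drop = FALSE]
  M <- t(Va) %*% Vb
  list(rmsip = sqrt(sum(M^2) / k), inner_products = M)
}

#' Porcupine displacement vectors and extreme structures along one mode
#'
#' The per-atom displacement of mode `m` is
#' `scale * sqrt(eigenvalue_m) * eigenvector_m` reshaped to atoms; the two
#' extreme structures are the model mean plus/minus that displacement.
#'
#' @param model a `covariance_model`.
#' @param mode_index mode number (1 = largest eigenvalue).
#' @param scale displacement scale in standard deviations (default 1).
#' @return list with `vectors` (N x 3, nm), `norms` (per atom), `plus`,
#'   `minus` (N x 3 structures) and `atoms`.
#' @export
porcupine <- function(model, mode_index = 1L, scale = 1) {
  if (mode_index > length(model$eigenvalues)) stop("mode does not exist")
  lam <- model$eigenvalues[mode_index]
  if (lam <= 0 && scale != 0) {
    warning("mode ", mode_index, " has zero eigenvalue: zero vectors")
    lam <- 0
  }
  v <- model$eigenvectors[, mode_index]
  disp <- matrix(scale * sqrt(max(lam, 0)) * v, ncol = 3L, byrow = TRUE)
  disp <- disp / model$mass_weights  # undo mass weighting if any
  mean_struct <- matrix(model$mean, ncol = 3L, byrow = TRUE) /
    model$mass_weights
  list(vectors = disp, norms = sqrt(rowSums(disp^2)),
       plus = mean_struct + disp, minus = mean_struct - disp,
       atoms = model$atoms)
}
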