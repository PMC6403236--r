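# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use naive scalar loops (or an unrelated library)
# so they cannot share a code path with the implementation they check.

# Minimal topology: one residue per atom unless resid given.
tiny_topology <- function(names, chains = "A", resids = NULL,
                          resnames = "ALA") {
  n <- length(names)
  if (is.null(resids)) resids <- seq_len(n)
  atom_table(seq_len(n), names, rep_len(resnames, n),
             rep_len(resids, n), rep_len(chains, n))
}

one_frame <- function(atoms, coords, ...) {
  trajectory(atoms, as.matrix(coords), ...)
}

# --- hydrogen bonds: brute-force triple scan -------------------------------
brute_force_hbonds <- function(coords, donors, acceptors,
                               da_cutoff = 0.35, angle_cutoff = 30) {
  hits <- NULL
  for (i in seq_len(nrow(donors))) {
    d <- donors$donor[i]; h <- donors$hydrogen[i]
    for (a in acceptors) {
      if (a == d || a == h) next
      rda <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (rda > da_cutoff) next
      vh <- coords[h, ] - coords[d, ]
      va <- coords[a, ] - coords[d, ]
      ang <- acos(min(max(sum(vh * va) /
                            sqrt(sum(vh^2) * sum(va^2)), -1), 1)) * 180 / pi
      if (ang <= angle_cutoff) {
        hits <- rbind(hits, c(d, h, a))
      }
    }
  }
  if (is.null(hits)) return(character(0))
  sort(paste(hits[, 1], hits[, 2], hits[, 3]))
}

# --- betweenness: exhaustive simple-path enumeration -----------------------
# Enumerates every simple path per node pair, keeps the shortest-length
# ones (hop count or edge-length sum) and accumulates pair fractions.
brute_force_betweenness <- function(graph,
                                    mode = c("unweighted",
                                             "hbond_weighted")) {
  mode <- match.arg(mode)
  n <- nrow(graph$nodes)
  len <- if (mode == "unweighted") rep(1, nrow(graph$edges)) else
    1 / (1 + graph$edges$hbond_weight)
  nb <- lapply(seq_len(n), function(v) {
    rows <- which(graph$edges$i == v | graph$edges$j == v)
    data.frame(to = ifelse(graph$edges$i[rows] == v,
                           graph$edges$j[rows], graph$edges$i[rows]),
               w = len[rows])
  })
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path, total) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1L]] <<- list(path = path, total = total)
        return()
      }
      e <- nb[[v]]
      for (r in seq_len(nrow(e))) {
        if (e$to[r] %in% path) next
        walk(c(path, e$to[r]), total + e$w[r])
      }
    }
    walk(s, 0)
    out
  }
  cb <- numeric(n)
  tol <- 1e-9
  for (s in seq_len(n - 1L)) {
    for (t in seq((s + 1L), n)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0L) next
      totals <- vapply(paths, `[[`, numeric(1L), "total")
      best <- min(totals)
      shortest <- paths[totals <= best + tol]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p$path,
                              logical(1L)))
        cb[v] <- cb[v] + through / sigma
      }
    }
  }
  cb * 2 / ((n - 2) * (n - 1))
}

# --- geometry: rotation-grid RMSD oracle -----------------------------------
# Exhaustive minimum of the superposition RMSD over a ZYZ Euler grid with
# the given step (degrees), after optimal centering.  Uses the identity
# rmsd^2 = c0 - 2 tr(R C) / n with C the cross-covariance.
grid_min_rmsd <- function(mobile, reference, step_deg = 2) {
  n <- nrow(mobile)
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  C <- t(X) %*% Y
  c0 <- sum(X^2) + sum(Y^2)
  ang <- seq(0, 358, by = step_deg) * pi / 180
  ang_b <- seq(0, 178, by = step_deg) * pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0,
                             sin(b), 0, cos(b)), 3, 3)
  best <- -Inf
  for (a in ang) {
    Ra <- rz(a)
    for (b in ang_b) {
      # tr(Rz(g) B) with B = C %*% Rz(a) %*% Ry(b), vectorized over g
      B <- C %*% Ra %*% ry(b)
      tr_g <- cos(ang) * (B[1, 1] + B[2, 2]) +
        sin(ang) * (B[1, 2] - B[2, 1]) + B[3, 3]
      best <- max(best, max(tr_g))
    }
  }
  sqrt(max(c0 - 2 * best, 0) / n)
}

# --- essential dynamics helpers --------------------------------------------
# A unit mode vector orthogonal to the 6 rigid-body directions of a
# structure, so that least-squares fitting leaves it (almost) untouched.
make_nonrigid_mode <- function(ref_coords, seed = 1L) {
  n <- nrow(ref_coords)
  centred <- sweep(ref_coords, 2, colMeans(ref_coords))
  rigid <- matrix(0, 3 * n, 6)
  for (k in 1:3) rigid[seq(k, 3 * n, by = 3), k] <- 1  # translations
  # infinitesimal rotations r x e_k
  for (i in seq_len(n)) {
    r <- centred[i, ]
    rows <- (3 * (i - 1) + 1):(3 * i)
    rigid[rows, 4] <- c(0, -r[3], r[2])
    rigid[rows, 5] <- c(r[3], 0, -r[1])
    rigid[rows, 6] <- c(-r[2], r[1], 0)
  }
  set.seed(seed)
  v <- stats::rnorm(3 * n)
  q <- qr.Q(qr(rigid))
  v <- v - q %*% (t(q) %*% v)
  as.numeric(v / sqrt(sum(v^2)))
}

random_spd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.1
}

# Wrap a covariance matrix as a minimal model for overlap/rmsip tests.
as_model <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  list(mean = rep(0, nrow(C)), cov = C, eigenvalues = e$values,
       eigenvectors = e$vectors, trace = sum(diag(C)),
       mass_weights = rep(1, nrow(C) / 3))
}

# Standard toy complex shared by several test files (cached per session).
toy_cache <- local({
  cx <- NULL
  function() {
    if (is.null(cx)) cx <<- make_toy_complex()
    cx
  }
})
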