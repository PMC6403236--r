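# Pairwise nonbonded interaction-energy decomposition between groups.
#
# Plain truncated Coulomb plus Lennard-Jones over explicit cross pairs;
# no reaction field or Ewald long-range correction is applied, so group
# energies are directly decomposable (per-residue terms sum exactly to
# the group total) but absolute magnitudes are not comparable with
# simulations that used mesh Ewald electrostatics.

#' Coulomb conversion factor, kJ mol^-1 nm e^-2
#'
#' `f = 1/(4 pi eps0) * e^2 * N_A`, expressed in kJ/mol for charges in e
#' and distances in nm.
#' @export
COULOMB_CONSTANT <- 138.935458

.pair_distances <- function(coords, pairs) {
  d <- coords[pairs[, 1L], , drop = FALSE] - coords[pairs[, 2L], , drop = FALSE]
  sqrt(rowSums(d^2))
}

.cross_pairs <- function(idx_a, idx_b) {
  cbind(rep(idx_a, times = length(idx_b)),
        rep(idx_b, each = length(idx_a)))
}

#' Coulomb energy over a pair list
#'
#' `sum f q_i q_j / r_ij` over the given pairs with `r <= cutoff`
#' (`cutoff = NULL` keeps all pairs); `f` is [COULOMB_CONSTANT].
#'
#' @param coords `n x 3` coordinate matrix (nm).
#' @param charges per-atom charges (e), indexed by the pair columns.
#' @param pairs two-column integer matrix of atom index pairs.
#' @param cutoff distance cutoff in nm, or `NULL` for none.
#' @return energy in kJ/mol.
#' @export
coulomb_energy <- function(coords, charges, pairs, cutoff = NULL) {
  if (nrow(pairs) == 0L) return(0)
  r <- .pair_distances(as.matrix(coords), pairs)
  if (any(r == 0)) {
    bad <- which(r == 0)[1L]
    stop("zero interatomic distance between atoms ", pairs[bad, 1L],
         " and ", pairs[bad, 2L])
  }
  keep <- if (is.null(cutoff)) rep(TRUE, length(r)) else r <= cutoff
  sum(COULOMB_CONSTANT * charges[pairs[keep, 1L]] * charges[pairs[keep, 2L]] /
        r[keep])
}

# sigma_ij, epsilon_ij under the active combination rule
.combine_lj <- function(params, i, j) {
  rule <- attr(params, "combination_rule")
  if (identical(rule, "geometric")) {
    sig <- sqrt(params$sigma[i] * params$sigma[j])
  } else {
    sig <- (params$sigma[i] + params$sigma[j]) / 2
  }
  list(sigma = sig, epsilon = sqrt(params$epsilon[i] * params$epsilon[j]))
}

#' Lennard-Jones energy over a pair list
#'
#' `sum 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)` with `sig_ij`, `eps_ij`
#' from the parameter object's combination rule.
#'
#' @param coords `n x 3` coordinate matrix (nm).
#' @param params a [nonbonded_params()] object.
#' @param pairs two-column integer matrix of atom index pairs.
#' @param cutoff distance cutoff in nm, or `NULL` for none.
#' @return energy in kJ/mol.
#' @export
lj_energy <- function(coords, params, pairs, cutoff = NULL) {
  if (nrow(pairs) == 0L) return(0)
  r <- .pair_distances(as.matrix(coords), pairs)
  if (any(r == 0)) {
    bad <- which(r == 0)[1L]
    stop("zero interatomic distance between atoms ", pairs[bad, 1L],
         " and ", pairs[bad, 2L])
  }
  keep <- if (is.null(cutoff)) rep(TRUE, length(r)) else r <= cutoff
  lj <- .combine_lj(params, pairs[keep, 1L], pairs[keep, 2L])
  sr6 <- (lj$sigma / r[keep])^6
  sum(4 * lj$epsilon * (sr6^2 - sr6))
}

.energy_breakdown_frame <- function(coords, params, pairs, cutoff) {
  cou <- coulomb_energy(coords, params$charge, pairs, cutoff)
  lj <- lj_energy(coords, params, pairs, cutoff)
  c(coulomb = cou, lj = lj, total = cou + lj)
}

# Block-averaged error: sd of the means of n_blocks nearly equal
# contiguous blocks, divided by sqrt(n_blocks).
.block_error <- function(x, n_blocks = 5L) {
  if (length(x) < 2L) return(0)
  if (length(x) < n_blocks) n_blocks <- length(x)
  blocks <- split(x, cut(seq_along(x), n_blocks, labels = FALSE))
  means <- vapply(blocks, mean, numeric(1L))
  if (length(means) < 2L) return(0)
  stats::sd(means) / sqrt(length(means))
}

#' Interaction-energy time series between two groups
#'
#' Per-frame Coulomb + Lennard-Jones decomposition over cross pairs only
#' (intra-group pairs are excluded), with window mean and a block-averaged
#' error estimate (5 equal blocks; error = sd of block means / sqrt(5)).
#'
#' @param traj an `md_trajectory`.
#' @param group_a,group_b disjoint selections.
#' @param params a [nonbonded_params()] object covering the topology.
#' @param cutoff pair distance cutoff in nm (`NULL` = all cross pairs).
#' @param window_ns trailing window (ns) for the summary statistics.
#' @return list with `series` (data frame `time_ps`, `coulomb`, `lj`,
#'   `total`, all kJ/mol), `mean` (window mean total), `error`
#'   (block-averaged), and the window means `mean_coulomb`, `mean_lj`.
#' @export
interaction_energy_series <- function(traj, group_a, group_b, params,
                                      cutoff = NULL, window_ns = NULL) {
  ia <- .resolve(traj, group_a)
  ib <- .resolve(traj, group_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty group")
  if (length(intersect(ia, ib)) > 0L) stop("groups overlap")
  pairs <- .cross_pairs(ia, ib)
  nf <- n_frames(traj)
  vals <- matrix(NA_real_, nf, 3L,
                 dimnames = list(NULL, c("coulomb", "lj", "total")))
  for (k in seq_len(nf)) {
    fr <- matrix(traj$coords[, , k], nrow(traj$atoms), 3L)
    vals[k, ] <- .energy_breakdown_frame(fr, params, pairs, cutoff)
  }
  win <- frames_in_window(traj, window_ns)
  if (length(win) == 0L) stop("empty window")
  list(series = data.frame(time_ps = frame_times(traj), vals),
       mean = mean(vals[win, "total"]),
       error = .block_error(vals[win, "total"]),
       mean_coulomb = mean(vals[win, "coulomb"]),
       mean_lj = mean(vals[win, "lj"]))
}

#' Interaction energy of one residue against a group
#'
#' The same computation as [interaction_energy_series()] restricted to the
#' atoms of one residue versus the group; summing this over all residues
#' of a chain reproduces the chain-versus-group total exactly.
#'
#' @param traj an `md_trajectory`.
#' @param residue selection resolving to the residue's atoms (e.g.
#'   `"chain A and resid 60"`).
#' @param group_b opposing group selection.
#' @param params,cutoff,window_ns as in [interaction_energy_series()].
#' @return list as from [interaction_energy_series()].
#' @export
residue_pair_energy <- function(traj, residue, group_b, params,
                                cutoff = NULL, window_ns = NULL) {
  ir <- .resolve(traj, residue)
  if (length(ir) == 0L) stop("residue selection resolves to no atoms")
  interaction_energy_series(traj, ir, group_b, params, cutoff = cutoff,
                            window_ns = window_ns)
}
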