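# Geometric hydrogen-bond detection and per-frame counting.
#
# Conventions (matching gmx hbond): the distance criterion is
# donor-to-acceptor (not hydrogen-to-acceptor) and the angle criterion is
# hydrogen-donor-acceptor <= angle_cutoff.  The common alternative
# (donor-hydrogen-acceptor >= 150 degrees) is NOT used.

#' Hydrogen-bond criteria
#'
#' @param da_cutoff donor-acceptor distance cutoff in nm (default 0.35).
#' @param angle_cutoff hydrogen-donor-acceptor angle cutoff in degrees
#'   (default 30).
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(da_cutoff = 0.35, angle_cutoff = 30) {
  if (da_cutoff <= 0 || angle_cutoff <= 0) stop("cutoffs must be > 0")
  structure(list(da_cutoff = da_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

#' Infer hydrogen-bond donors and acceptors from the topology
#'
#' Donors are N or O atoms covalently bonded to a hydrogen, with the bond
#' inferred from a distance < 0.12 nm in the given frame (frame 1 by
#' default, and only there: the assignment is static).  Hydrogens bonded
#' to carbon are never donors.  Acceptors are all N and O atoms.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame used for covalent-bond inference.
#' @return list with `donors` (data frame: columns `donor`, `hydrogen`,
#'   atom indices; one row per D-H pair) and `acceptors` (integer atom
#'   indices).  A topology without hydrogens yields an empty donor set
#'   with a warning.
#' @export
infer_donors_acceptors <- function(traj, frame = 1L) {
  at <- traj$atoms
  h_idx <- which(at$element == "H")
  no_idx <- which(at$element %in% c("N", "O"))
  donors <- data.frame(donor = integer(0), hydrogen = integer(0))
  if (length(h_idx) == 0L) {
    warning("topology has no hydrogens: empty donor set")
  } else if (length(no_idx) > 0L) {
    xh <- matrix(traj$coords[h_idx, , frame], length(h_idx), 3L)
    xno <- matrix(traj$coords[no_idx, , frame], length(no_idx), 3L)
    d <- .cross_dist(xno, xh)
    hit <- which(d < 0.12, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      donors <- data.frame(donor = no_idx[hit[, 1L]],
                           hydrogen = h_idx[hit[, 2L]])
      donors <- donors[order(donors$donor, donors$hydrogen), ,
                       drop = FALSE]
      rownames(donors) <- NULL
    }
  }
  list(donors = donors, acceptors = no_idx)
}

#' Detect hydrogen bonds in one frame
#'
#' A bond D-H...A exists iff the donor-acceptor distance is <=
#' `criteria$da_cutoff` and the H-D-A angle is <= `criteria$angle_cutoff`;
#' the donor and its own hydrogens are excluded as acceptors for that
#' bond.
#'
#' @param coords `n x 3` coordinate matrix (nm) for the frame.
#' @param donors donor table as from [infer_donors_acceptors()].
#' @param acceptors integer acceptor atom indices.
#' @param criteria an [hbond_criteria()] object.
#' @return data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `da_distance` (nm), `hda_angle` (degrees); zero rows if none.
#' @export
detect_hbonds <- function(coords, donors, acceptors,
                          criteria = hbond_criteria()) {
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), da_distance = numeric(0),
                      hda_angle = numeric(0))
  if (nrow(donors) == 0L || length(acceptors) == 0L) return(empty)
  coords <- as.matrix(coords)
  xd <- coords[donors$donor, , drop = FALSE]
  xa <- coords[acceptors, , drop = FALSE]
  dda <- .cross_dist(xd, xa)  # n_donor_pairs x n_acceptors
  cand <- which(dda <= criteria$da_cutoff, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    # drop self pairs (acceptor is the donor atom itself or its hydrogen)
    keep <- acceptors[cand[, 2L]] != donors$donor[cand[, 1L]] &
      acceptors[cand[, 2L]] != donors$hydrogen[cand[, 1L]]
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(empty)
  di <- cand[, 1L]; ai <- cand[, 2L]
  vh <- coords[donors$hydrogen[di], , drop = FALSE] - xd[di, , drop = FALSE]
  va <- xa[ai, , drop = FALSE] - xd[di, , drop = FALSE]
  cosang <- rowSums(vh * va) /
    (sqrt(rowSums(vh^2)) * sqrt(rowSums(va^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang <= criteria$angle_cutoff
  out <- data.frame(donor = donors$donor[di][ok],
                    hydrogen = donors$hydrogen[di][ok],
                    acceptor = acceptors[ai][ok],
                    da_distance = dda[cand][ok],
                    hda_angle = ang[ok])
  out <- out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-frame hydrogen-bond count between two groups
#'
#' Counts bonds with the donor in group A and the acceptor in group B plus
#' bonds with the donor in B and the acceptor in A; the count is therefore
#' symmetric in the two groups.
#'
#' @param traj an `md_trajectory`.
#' @param group_a,group_b disjoint selections (expressions or indices).
#' @param criteria an [hbond_criteria()] object.
#' @param window_ns trailing window (ns) over which `mean` and `sd` are
#'   taken; the series always covers all frames.
#' @param donors_acceptors optional precomputed result of
#'   [infer_donors_acceptors()].
#' @return list with `series` (an `md_series` of counts), `mean` and `sd`
#'   over the window.
#' @export
hbond_count_series <- function(traj, group_a, group_b,
                               criteria = hbond_criteria(),
                               window_ns = NULL,
                               donors_acceptors = NULL) {
  ia <- .resolve(traj, group_a)
  ib <- .resolve(traj, group_b)
  if (length(intersect(ia, ib)) > 0L) stop("groups overlap")
  da <- donors_acceptors
  if (is.null(da)) {
    da <- suppressWarnings(infer_donors_acceptors(traj))
  }
  in_a <- da$donors$donor %in% ia
  in_b <- da$donors$donor %in% ib
  don_ab <- da$donors[in_a, , drop = FALSE]
  don_ba <- da$donors[in_b, , drop = FALSE]
  acc_a <- intersect(da$acceptors, ia)
  acc_b <- intersect(da$acceptors, ib)
  nf <- n_frames(traj)
  counts <- integer(nf)
  for (k in seq_len(nf)) {
    fr <- matrix(traj$coords[, , k], nrow(traj$atoms), 3L)
    n1 <- nrow(detect_hbonds(fr, don_ab, acc_b, criteria))
    n2 <- nrow(detect_hbonds(fr, don_ba, acc_a, criteria))
    counts[k] <- n1 + n2
  }
  win <- frames_in_window(traj, window_ns)
  list(series = .series(frame_times(traj), counts, "H-bond count", "count"),
       mean = mean(counts[win]),
       sd = if (length(win) > 1L) stats::sd(counts[win]) else 0)
}
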