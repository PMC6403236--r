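# Deterministic synthetic inputs: toy receptor-ligand complexes with
# planted hydrogen bonds, low-rank Gaussian fluctuation trajectories,
# graph fixtures with known centralities, and parameter fixtures.
#
# Every generator takes an explicit seed and restores the caller's RNG
# state, so fixtures are bit-reproducible and leave no global trace.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic receptor-ligand complex
#'
#' Describes a two-chain horseshoe-like protein dimer (arc-shaped chains
#' A and B stacked along z) with an optional central two-strand duplex
#' ligand (chains C and D), plus a list of planted hydrogen bonds at
#' named interaction sites.  Planted bond geometries satisfy the
#' 0.35 nm / 30 degree criteria by construction; all other cross-group
#' donor-acceptor distances exceed 0.4 nm.
#'
#' @param n_res_per_chain protein residues per chain (>= 6).
#' @param n_lig_res_per_strand ligand residues per strand (0 disables the
#'   ligand).
#' @param planted_hbonds data frame with columns `site` (one of
#'   `"N-terminal"`, `"C-terminal"`, `"dimer"`), `donor_chain`,
#'   `donor_resid`, `acceptor_chain`, `acceptor_resid`.  `NULL` gives the
#'   default architecture: per protein chain, 3 ligand bonds at the
#'   N-terminal site and 2 at the C-terminal site, plus 1 bond across the
#'   dimer interface.
#' @param jitter_nm uniform coordinate jitter amplitude (small enough to
#'   never break a planted criterion).
#' @param seed geometry seed.
#' @return a `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_res_per_chain = 12L,
                             n_lig_res_per_strand = 8L,
                             planted_hbonds = NULL,
                             jitter_nm = 0.008, seed = 1L) {
  if (n_res_per_chain < 6L) stop("need at least 6 residues per chain")
  if (is.null(planted_hbonds)) {
    if (n_lig_res_per_strand > 0L) {
      if (n_lig_res_per_strand < 6L) {
        stop("default planting needs at least 6 ligand residues per strand")
      }
      nl <- n_lig_res_per_strand
      planted_hbonds <- rbind(
        data.frame(site = "N-terminal", donor_chain = "A",
                   donor_resid = 2:4, acceptor_chain = "C",
                   acceptor_resid = 1:3),
        data.frame(site = "C-terminal", donor_chain = "A",
                   donor_resid = n_res_per_chain - c(2L, 1L),
                   acceptor_chain = "C", acceptor_resid = nl - c(1L, 0L)),
        data.frame(site = "N-terminal", donor_chain = "B",
                   donor_resid = 2:4, acceptor_chain = "D",
                   acceptor_resid = 1:3),
        data.frame(site = "C-terminal", donor_chain = "B",
                   donor_resid = n_res_per_chain - c(2L, 1L),
                   acceptor_chain = "D", acceptor_resid = nl - c(1L, 0L)),
        data.frame(site = "dimer", donor_chain = "A",
                   donor_resid = n_res_per_chain %/% 2L,
                   acceptor_chain = "B",
                   acceptor_resid = n_res_per_chain %/% 2L)
      )
    } else {
      planted_hbonds <- data.frame(
        site = "dimer", donor_chain = "A",
        donor_resid = n_res_per_chain %/% 2L,
        acceptor_chain = "B", acceptor_resid = n_res_per_chain %/% 2L)
    }
  }
  structure(list(n_res_per_chain = as.integer(n_res_per_chain),
                 n_lig_res_per_strand = as.integer(n_lig_res_per_strand),
                 planted_hbonds = planted_hbonds,
                 jitter_nm = jitter_nm, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# One idealised protein residue: N (donor), H on N, CA, C, O.
# p = base point, tang = unit tangent along the chain, inward = unit
# direction the N-H donor points (toward the ligand axis by default).
.protein_residue_atoms <- function(p, tang, inward) {
  up <- c(0, 0, 1)
  rbind(N = p,
        H = p + 0.10 * inward,
        CA = p + 0.14 * tang,
        C = p + 0.28 * tang,
        O = p + 0.28 * tang + 0.12 * up)
}

# One idealised nucleic residue (rigid-ladder backbone).
.nucleic_residue_atoms <- function(q, axis_dir) {
  rbind(`P` = q,
        `O5'` = q + c(0.05, 0.05, 0) + 0.10 * axis_dir,
        `C5'` = q + c(0.10, 0.00, 0) + 0.20 * axis_dir,
        `C4'` = q + c(0.12, 0.00, 0) + 0.30 * axis_dir,
        `C3'` = q + c(0.10, -0.05, 0) + 0.40 * axis_dir,
        `O3'` = q + c(0.05, -0.05, 0) + 0.50 * axis_dir)
}

# Planted-acceptor nucleic residue: O3' exactly at `a`, the rest of the
# backbone marching away from the donor along `away`.
.planted_nucleic_atoms <- function(a, away) {
  side <- if (abs(away[3L]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  rbind(`O3'` = a,
        `C3'` = a + 0.15 * away,
        `C4'` = a + 0.30 * away,
        `C5'` = a + 0.42 * away + 0.10 * side,
        `O5'` = a + 0.55 * away + 0.10 * side,
        `P` = a + 0.70 * away)
}

# Planted-acceptor protein residue (dimer interface): carbonyl O exactly
# at `a`, remaining atoms marching along `away`, H pointing along `away`
# so it cannot donate back toward the partner chain.
.planted_protein_atoms <- function(a, away) {
  side <- if (abs(away[3L]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  rbind(O = a,
        C = a + 0.12 * away,
        CA = a + 0.26 * away,
        N = a + 0.26 * away + 0.14 * side,
        H = a + 0.26 * away + 0.14 * side + 0.10 * away)
}

#' Generate a toy receptor-ligand complex with planted hydrogen bonds
#'
#' Builds a single-frame trajectory realising the spec: two arc-shaped
#' protein chains stacked along z around a central rigid-ladder duplex,
#' with exactly the planted inter-group hydrogen bonds satisfying the
#' 0.35 nm / 30 degree criteria (each planted donor-acceptor pair is
#' collinear at 0.30 nm).  Generation is deterministic given the spec;
#' changing the seed changes only the coordinate jitter, never the bond
#' counts.  The construction is verified by running the hydrogen-bond
#' detector; any violation raises a construction error.
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `traj` (1-frame `md_trajectory`), `planted` (the
#'   spec's bond table with donor/acceptor atom indices attached),
#'   `groups` (named selection expressions for chains A, B, protein and
#'   ligand) and `spec`.
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  nres <- spec$n_res_per_chain
  nlig <- spec$n_lig_res_per_strand
  planted <- spec$planted_hbonds
  radius <- 2.5
  arc_step <- 0.60 / radius
  z_chain <- c(A = 0.8, B = -0.8)

  res_atoms <- list()  # per residue: list(chain, resid, resname, atoms)
  donor_override <- split(planted, paste(planted$donor_chain,
                                         planted$donor_resid))
  acceptor_override <- split(planted, paste(planted$acceptor_chain,
                                            planted$acceptor_resid))
  # donor positions are fixed by the regular arc; compute them first
  donor_pos <- list()
  base_point <- function(chain, i) {
    th <- pi / 3 + (i - 1L) * arc_step
    c(radius * cos(th), radius * sin(th), z_chain[[chain]])
  }
  for (chain in c("A", "B")) {
    for (i in seq_len(nres)) {
      key <- paste(chain, i)
      p <- base_point(chain, i)
      th <- pi / 3 + (i - 1L) * arc_step
      tang <- c(-sin(th), cos(th), 0)
      inward <- -c(cos(th), sin(th), 0)
      ov <- donor_override[[key]]
      if (!is.null(ov) && nrow(ov) > 0L && ov$site[1L] == "dimer") {
        # dimer-site donors point across the interface (along -/+ z)
        inward <- c(0, 0, -sign(z_chain[[chain]]))
      }
      if (!is.null(acceptor_override[[paste(chain, i)]])) next
      res_atoms[[key]] <- list(chain = chain, resid = i, resname = "ALA",
                               atoms = .protein_residue_atoms(p, tang, inward))
      donor_pos[[key]] <- list(N = p, H = p + 0.10 * inward)
    }
  }
  # planted acceptor residues (protein, dimer interface)
  for (key in names(acceptor_override)) {
    ov <- acceptor_override[[key]][1L, ]
    if (!(ov$acceptor_chain %in% c("A", "B"))) next
    dkey <- paste(ov$donor_chain, ov$donor_resid)
    dp <- donor_pos[[dkey]]
    if (is.null(dp)) stop("planted donor residue ", dkey, " not available")
    u <- dp$H - dp$N; u <- u / sqrt(sum(u^2))
    a <- dp$N + 0.30 * u
    res_atoms[[key]] <- list(chain = ov$acceptor_chain,
                             resid = ov$acceptor_resid, resname = "ALA",
                             atoms = .planted_protein_atoms(a, u))
  }
  # regular ligand residues
  if (nlig > 0L) {
    x_strand <- c(C = 0.15, D = -0.15)
    for (chain in c("C", "D")) {
      for (i in seq_len(nlig)) {
        key <- paste(chain, i)
        if (!is.null(acceptor_override[[key]])) next
        q <- c(x_strand[[chain]], 0,
               -0.3 * nlig + (i - 1L) * 0.60 +
                 if (chain == "D") 0.30 else 0)
        res_atoms[[key]] <- list(chain = chain, resid = i, resname = "U",
                                 atoms = .nucleic_residue_atoms(q, c(0, 0, 1)))
      }
    }
    # planted acceptor residues (nucleic)
    for (key in names(acceptor_override)) {
      ov <- acceptor_override[[key]][1L, ]
      if (!(ov$acceptor_chain %in% c("C", "D"))) next
      dkey <- paste(ov$donor_chain, ov$donor_resid)
      dp <- donor_pos[[dkey]]
      if (is.null(dp)) stop("planted donor residue ", dkey, " not available")
      u <- dp$H - dp$N; u <- u / sqrt(sum(u^2))
      a <- dp$N + 0.30 * u
      res_atoms[[key]] <- list(chain = ov$acceptor_chain,
                               resid = ov$acceptor_resid, resname = "U",
                               atoms = .planted_nucleic_atoms(a, u))
    }
  }
  # assemble in chain/resid order
  ord <- order(vapply(res_atoms, `[[`, character(1L), "chain"),
               vapply(res_atoms, `[[`, integer(1L), "resid"))
  res_atoms <- res_atoms[ord]
  coords <- do.call(rbind, lapply(res_atoms, `[[`, "atoms"))
  names_v <- unlist(lapply(res_atoms, function(r) rownames(r$atoms)))
  chain_v <- unlist(lapply(res_atoms, function(r)
    rep(r$chain, nrow(r$atoms))))
  resid_v <- unlist(lapply(res_atoms, function(r)
    rep(r$resid, nrow(r$atoms))))
  resname_v <- unlist(lapply(res_atoms, function(r)
    rep(r$resname, nrow(r$atoms))))
  jit <- .with_seed(spec$seed, {
    matrix(stats::runif(length(coords), -spec$jitter_nm, spec$jitter_nm),
           nrow(coords), 3L)
  })
  atoms <- atom_table(seq_len(nrow(coords)), names_v, resname_v,
                      resid_v, chain_v)
  traj <- trajectory(atoms, coords + jit, timestep_ps = 2)

  # attach atom indices of the planted pairs and verify the construction
  akey <- paste(atoms$chain, atoms$resid, atoms$name)
  planted$donor_atom <- match(paste(planted$donor_chain,
                                    planted$donor_resid, "N"), akey)
  acc_name <- ifelse(planted$acceptor_chain %in% c("A", "B"), "O", "O3'")
  planted$acceptor_atom <- match(paste(planted$acceptor_chain,
                                       planted$acceptor_resid, acc_name),
                                 akey)
  .verify_planted(traj, planted)
  groups <- c(A = "chain A", B = "chain B",
              protein = "chain A or chain B",
              ligand = if (nlig > 0L) "chain C or chain D" else NA,
              strand1 = if (nlig > 0L) "chain C" else NA,
              strand2 = if (nlig > 0L) "chain D" else NA)
  list(traj = traj, planted = planted,
       groups = groups[!is.na(groups)], spec = spec)
}

# Construction check: detected inter-group bonds must be exactly the
# planted ones, pair by pair.
.verify_planted <- function(traj, planted) {
  da <- suppressWarnings(infer_donors_acceptors(traj))
  fr <- matrix(traj$coords[, , 1L], nrow(traj$atoms), 3L)
  hb <- detect_hbonds(fr, da$donors, da$acceptors)
  ch <- traj$atoms$chain
  cross <- hb[ch[hb$donor] != ch[hb$acceptor], , drop = FALSE]
  got <- sort(paste(cross$donor, cross$acceptor))
  want <- sort(paste(planted$donor_atom, planted$acceptor_atom))
  if (!identical(got, want)) {
    stop("infeasible planting: detected inter-chain bonds (",
         paste(got, collapse = "; "), ") differ from planted (",
         paste(want, collapse = "; "), ")")
  }
  invisible(TRUE)
}

#' Generate a low-rank Gaussian fluctuation trajectory
#'
#' Frames are `reference + sum_m a_tm v_m + noise`, with mode amplitudes
#' `a_tm ~ Normal(0, variance_m)` and isotropic Gaussian coordinate noise
#' of standard deviation `noise_sd` on every atom.  Modes live on the
#' selection and must be orthonormal 3N-vectors (coordinate layout
#' x1, y1, z1, x2, ...).
#'
#' @param reference an `md_trajectory` whose first frame is the mean
#'   structure.
#' @param n_frames number of frames.
#' @param modes `3N_sel x m` matrix of orthonormal mode vectors (or
#'   `NULL` for pure noise).
#' @param variances length-m mode variances (nm^2).
#' @param noise_sd isotropic per-coordinate noise sd (nm).
#' @param selection atoms the modes act on.
#' @param timestep_ps frame spacing of the result.
#' @param seed RNG seed (generation is bit-reproducible).
#' @return an `md_trajectory` with `n_frames` frames.
#' @export
make_gaussian_trajectory <- function(reference, n_frames, modes = NULL,
                                     variances = NULL, noise_sd = 0,
                                     selection = "all", timestep_ps = 20,
                                     seed = 1L) {
  idx <- .resolve(reference, selection)
  ref <- matrix(reference$coords[, , 1L], nrow(reference$atoms), 3L)
  nsel <- length(idx)
  if (!is.null(modes)) {
    modes <- as.matrix(modes)
    if (nrow(modes) != 3L * nsel) {
      stop("modes must have 3 * n_selected rows")
    }
    gram <- crossprod(modes)
    if (max(abs(gram - diag(ncol(modes)))) > 1e-8) {
      stop("mode directions are not orthonormal")
    }
    if (length(variances) != ncol(modes) || any(variances < 0)) {
      stop("variances must be non-negative, one per mode")
    }
  }
  coords <- .with_seed(seed, {
    out <- array(rep(ref, n_frames), dim = c(nrow(ref), 3L, n_frames))
    if (!is.null(modes) && ncol(modes) > 0L) {
      amp <- matrix(stats::rnorm(n_frames * ncol(modes)), n_frames) *
        rep(sqrt(variances), each = n_frames)
      disp <- amp %*% t(modes)  # n_frames x 3N_sel
      for (k in seq_len(n_frames)) {
        out[idx, , k] <- out[idx, , k] +
          matrix(disp[k, ], nsel, 3L, byrow = TRUE)
      }
    }
    if (noise_sd > 0) {
      out <- out + array(stats::rnorm(length(out), sd = noise_sd), dim(out))
    }
    out
  })
  trajectory(reference$atoms, coords, timestep_ps = timestep_ps)
}

#' Random orthonormal mode matrix
#'
#' @param n3 ambient dimension (3 times the number of selected atoms).
#' @param k number of modes.
#' @param seed RNG seed.
#' @return `n3 x k` matrix with orthonormal columns.
#' @export
make_planted_modes <- function(n3, k, seed = 1L) {
  .with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n3 * k), n3, k)))
  })
}

#' Graph fixtures with known centrality structure
#'
#' @param kind one of `"path"`, `"star"`, `"cycle"`, `"complete"`,
#'   `"two_cluster_bridge"`, `"random_connected"`.
#' @param n number of nodes (>= 3).
#' @param seed RNG seed (used by `random_connected` for the topology and
#'   by all kinds for random hydrogen-bond weights when
#'   `random_weights = TRUE`).
#' @param random_weights attach random integer hbond weights in 0..3.
#' @return a `residue_graph` with pseudo-residue labels.
#' @export
make_graph_fixture <- function(kind = c("path", "star", "cycle",
                                        "complete", "two_cluster_bridge",
                                        "random_connected"),
                               n = 6L, seed = 1L, random_weights = FALSE) {
  kind <- match.arg(kind)
  if (n < 3L) stop("graph fixtures need n >= 3")
  nodes <- data.frame(chain = "A", resid = seq_len(n), resname = "GLY",
                      stringsAsFactors = FALSE)
  e <- switch(kind,
    path = cbind(seq_len(n - 1L), seq(2L, n)),
    cycle = rbind(cbind(seq_len(n - 1L), seq(2L, n)), c(n, 1L)),
    star = cbind(1L, seq(2L, n)),
    complete = t(utils::combn(n, 2L)),
    two_cluster_bridge = {
      h <- n %/% 2L
      c1 <- t(utils::combn(seq_len(h), 2L))
      c2 <- t(utils::combn(seq(h + 1L, n), 2L))
      rbind(c1, c2, c(h, h + 1L))
    },
    random_connected = .with_seed(seed, {
      perm <- sample(n)
      tree <- cbind(perm[2:n],
                    vapply(2:n, function(i) perm[sample.int(i - 1L, 1L)],
                           integer(1L)))
      extra_n <- sample.int(n, 1L) - 1L
      all_pairs <- t(utils::combn(n, 2L))
      key <- paste(pmin(tree[, 1L], tree[, 2L]),
                   pmax(tree[, 1L], tree[, 2L]))
      remaining <- all_pairs[!(paste(all_pairs[, 1L], all_pairs[, 2L])
                               %in% key), , drop = FALSE]
      if (extra_n > 0L && nrow(remaining) > 0L) {
        take <- sample.int(nrow(remaining), min(extra_n, nrow(remaining)))
        rbind(tree, remaining[take, , drop = FALSE])
      } else tree
    })
  )
  e <- matrix(as.integer(e), ncol = 2L)
  edges <- data.frame(i = pmin(e[, 1L], e[, 2L]),
                      j = pmax(e[, 1L], e[, 2L]))
  w <- if (random_weights) {
    .with_seed(seed + 1L, sample(0:3, nrow(edges), replace = TRUE))
  } else 0L
  edges$hbond_weight <- w
  residue_graph(nodes, edges)
}

#' Nonbonded parameter fixtures
#'
#' @param topology atom table or `md_trajectory`.
#' @param scheme `"zeros"` (null energies), `"unit_charges"` (+1/-1 e on
#'   designated atom pairs, all epsilon 0) or `"random"` (bounded random
#'   charges and LJ parameters).
#' @param pairs for `unit_charges`: two-column matrix of atom indices;
#'   column 1 gets +1 e, column 2 gets -1 e.  Defaults to the first and
#'   last atom.
#' @param seed RNG seed for `"random"`.
#' @return a `nonbonded_params` object.
#' @export
make_params_fixture <- function(topology,
                                scheme = c("zeros", "unit_charges",
                                           "random"),
                                pairs = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  atoms <- if (inherits(topology, "md_trajectory")) topology$atoms
           else topology
  n <- nrow(atoms)
  switch(scheme,
    zeros = nonbonded_params(rep(0, n), rep(0.3, n), rep(0, n)),
    unit_charges = {
      if (is.null(pairs)) pairs <- cbind(1L, n)
      q <- rep(0, n)
      q[pairs[, 1L]] <- 1
      q[pairs[, 2L]] <- -1
      nonbonded_params(q, rep(0.3, n), rep(0, n))
    },
    random = .with_seed(seed, {
      nonbonded_params(stats::runif(n, -1, 1),
                       stats::runif(n, 0.25, 0.4),
                       stats::runif(n, 0.1, 1))
    })
  )
}

#' Write a toy complex as plain-text fixture files
#'
#' Writes `complex.pdb` (coordinates), `params.tsv` (a covering random
#' nonbonded table) and `truth.json` (the planted hydrogen-bond table and
#' group selections) into a directory.
#'
#' @param complex result of [make_toy_complex()].
#' @param dir output directory (created if needed).
#' @param params optional `nonbonded_params` to write instead of a
#'   seeded random table.
#' @return the directory, invisibly.
#' @export
write_complex_fixture <- function(complex, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(complex$traj, file.path(dir, "complex.pdb"))
  if (is.null(params)) {
    params <- make_params_fixture(complex$traj, "random",
                                  seed = complex$spec$seed)
  }
  write_params(params, complex$traj, file.path(dir, "params.tsv"))
  truth <- list(planted_hbonds = complex$planted,
                groups = as.list(complex$groups),
                seed = complex$spec$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
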