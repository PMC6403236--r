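# Config-driven orchestration: stability metrics -> hydrogen bonds ->
# distances -> energies -> essential dynamics -> residue network, for a
# set of labelled complexes with multiple independent runs, writing a
# CSV/PDB report tree.

#' Assemble a pipeline configuration
#'
#' @param complexes named list; each element is a list with `runs` (a
#'   list of `md_trajectory` objects or PDB paths, >= 1 independent run),
#'   optional `params` (a `nonbonded_params` object or parameter-table
#'   path) and optional `selections` overriding the defaults
#'   `list(chain_a = "chain A", chain_b = "chain B", ligand = "chain C or
#'   chain D", fit = "backbone")`; set `ligand = NULL` for apo systems.
#' @param reference label of the reference complex for differential
#'   centrality (`NULL` disables differentials).
#' @param window_ns trailing analysis window in ns.
#' @param hbond an [hbond_criteria()].
#' @param energy_cutoff nonbonded pair cutoff in nm (`NULL` = all cross
#'   pairs).
#' @param pca_k eigenvectors kept for projections/overlap (default 10).
#' @param fel_bins free-energy-landscape bins per axis.
#' @param temperature_K temperature for the landscape.
#' @param network_cutoff residue contact cutoff in nm.
#' @param central_threshold centrality selection threshold.
#' @param differential_threshold `|delta cb|` threshold.
#' @param sasa_stride frame stride for the SASA series.
#' @param sasa_n_points sphere points per atom for SASA.
#' @param seed recorded seed (the pipeline itself is deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(complexes, reference = NULL, window_ns = 60,
                            hbond = hbond_criteria(), energy_cutoff = NULL,
                            pca_k = 10L, fel_bins = 32L,
                            temperature_K = 300, network_cutoff = 0.7,
                            central_threshold = 0.1,
                            differential_threshold = 0.05,
                            sasa_stride = 10L, sasa_n_points = 960L,
                            seed = 1L) {
  if (is.null(names(complexes)) || anyDuplicated(names(complexes))) {
    stop("complexes must be a uniquely named list")
  }
  if (!is.null(reference) && !(reference %in% names(complexes))) {
    stop("reference label '", reference, "' not among complexes")
  }
  structure(list(complexes = complexes, reference = reference,
                 window_ns = window_ns, hbond = hbond,
                 energy_cutoff = energy_cutoff, pca_k = pca_k,
                 fel_bins = fel_bins, temperature_K = temperature_K,
                 network_cutoff = network_cutoff,
                 central_threshold = central_threshold,
                 differential_threshold = differential_threshold,
                 sasa_stride = sasa_stride,
                 sasa_n_points = sasa_n_points, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; each entry
#' of `complexes` lists `runs` (PDB paths), optionally `params` (table
#' path) and `selections`.  Relative paths resolve against the config
#' file's directory.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve_path <- function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  }
  complexes <- lapply(y$complexes, function(cx) {
    runs <- lapply(cx$runs, function(p) read_pdb(resolve_path(p)))
    params <- if (!is.null(cx$params)) {
      load_params(resolve_path(cx$params), runs[[1L]])
    }
    list(runs = runs, params = params, selections = cx$selections)
  })
  args <- y[setdiff(names(y), c("complexes", "hbond"))]
  args$complexes <- complexes
  if (!is.null(y$hbond)) args$hbond <- do.call(hbond_criteria, y$hbond)
  do.call(pipeline_config, args)
}

.default_selections <- list(chain_a = "chain A", chain_b = "chain B",
                            ligand = "chain C or chain D",
                            fit = "backbone")

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

.series_csv <- function(series, path) .write_csv(series, path)

.load_runs <- function(cx) {
  lapply(cx$runs, function(r) {
    if (inherits(r, "md_trajectory")) r else read_pdb(r)
  })
}

.stage <- function(stage, label, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed for complex '", label,
         "': ", conditionMessage(e), call. = FALSE)
  })
}

# Per-complex analysis; returns the covariance model, centrality table
# and pooled projection bookkeeping for the cross-complex stage.
.run_complex <- function(label, cx, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- .load_runs(cx)
  sel <- utils::modifyList(.default_selections,
                           cx$selections %||% list())
  topo <- runs[[1L]]
  has_ligand <- !is.null(sel$ligand) &&
    length(select_atoms(topo, sel$ligand)) > 0L
  wn <- config$window_ns
  da <- suppressWarnings(infer_donors_acceptors(topo))

  for (r in seq_along(runs)) {
    tr <- runs[[r]]
    tag <- function(name) file.path(dir, sprintf("run%d_%s.csv", r, name))
    .stage("rmsd", label,
           .series_csv(rmsd_series(tr, sel$fit), tag("rmsd")))
    .stage("rmsf", label, {
      prof_a <- rmsf(tr, paste0("(", sel$chain_a, ") and backbone"),
                     fit_selection = sel$fit, window_ns = wn)
      prof_b <- rmsf(tr, paste0("(", sel$chain_b, ") and backbone"),
                     fit_selection = sel$fit, window_ns = wn)
      .write_csv(prof_a, tag("rmsf_chain_a"))
      .write_csv(prof_b, tag("rmsf_chain_b"))
      if (nrow(prof_a) == nrow(prof_b)) {
        .write_csv(data.frame(
          pearson_r = rmsf_chain_correlation(prof_a, prof_b)),
          tag("rmsf_chain_correlation"))
      }
    })
    .stage("rg", label,
           .series_csv(radius_of_gyration(tr, sel$fit), tag("rg")))
    .stage("sasa", label,
           .series_csv(sasa_series(tr, "heavy",
                                   stride = config$sasa_stride,
                                   n_points = config$sasa_n_points),
                       tag("sasa")))
    .stage("hbonds", label, {
      if (has_ligand) {
        for (side in c("chain_a", "chain_b")) {
          hb <- hbond_count_series(tr, sel[[side]], sel$ligand,
                                   criteria = config$hbond,
                                   window_ns = wn,
                                   donors_acceptors = da)
          .series_csv(hb$series, tag(paste0("hbonds_", side, "_ligand")))
        }
      }
      hb_dimer <- hbond_count_series(tr, sel$chain_a, sel$chain_b,
                                     criteria = config$hbond,
                                     window_ns = wn,
                                     donors_acceptors = da)
      .series_csv(hb_dimer$series, tag("hbonds_dimer"))
    })
    .stage("distances", label, {
      .series_csv(com_distance(tr, sel$chain_a, sel$chain_b),
                  tag("comdist_dimer"))
      if (has_ligand) {
        .series_csv(min_distance(tr, sel$chain_a, sel$ligand),
                    tag("mindist_chain_a_ligand"))
        .series_csv(min_distance(tr, sel$chain_b, sel$ligand),
                    tag("mindist_chain_b_ligand"))
      }
    })
    if (!is.null(cx$params)) {
      .stage("energy", label, {
        comps <- list(dimer = c(sel$chain_a, sel$chain_b))
        if (has_ligand) {
          comps$chain_a_ligand <- c(sel$chain_a, sel$ligand)
          comps$chain_b_ligand <- c(sel$chain_b, sel$ligand)
        }
        rows <- lapply(names(comps), function(nm) {
          en <- interaction_energy_series(tr, comps[[nm]][1L],
                                          comps[[nm]][2L], cx$params,
                                          cutoff = config$energy_cutoff,
                                          window_ns = wn)
          .series_csv(en$series, tag(paste0("energy_", nm)))
          data.frame(component = nm, run = r, mean_coulomb = en$mean_coulomb,
                     mean_lj = en$mean_lj, mean_total = en$mean,
                     error = en$error)
        })
        .write_csv(do.call(rbind, rows), tag("energy_table"))
      })
    }
  }

  # essential dynamics on pooled windowed runs
  model <- .stage("pca", label,
                  build_covariance(runs, sel$fit, window_ns = wn))
  k <- min(config$pca_k, length(model$eigenvalues))
  eig <- data.frame(index = seq_along(model$eigenvalues),
                    eigenvalue_nm2 = model$eigenvalues)
  eig$cumulative <- cumsum(pmax(eig$eigenvalue_nm2, 0)) /
    max(model$trace, .Machine$double.eps)
  .write_csv(eig[seq_len(min(nrow(eig), 50L)), ],
             file.path(dir, "pca_eigenvalues.csv"))
  proj <- .stage("pca", label,
                 project_trajectory(runs, model, k = k, window_ns = wn))
  .write_csv(proj, file.path(dir, "pca_projections.csv"))
  grid <- .stage("fel", label,
                 fel(proj, 1L, 2L, n_bins = config$fel_bins,
                     temperature_K = config$temperature_K))
  occ <- grid$counts > 0L
  fel_df <- data.frame(
    i = rep(seq_along(grid$centers_i), times = length(grid$centers_j)),
    j = rep(seq_along(grid$centers_j), each = length(grid$centers_i)),
    center_i = rep(grid$centers_i, times = length(grid$centers_j)),
    center_j = rep(grid$centers_j, each = length(grid$centers_i)),
    count = as.integer(grid$counts),
    dG_kj_mol = ifelse(occ, grid$dG, max(grid$dG[occ]) + 1),
    occupied = as.integer(occ)
  )
  .write_csv(fel_df, file.path(dir, "fel.csv"))
  rep_idx <- representative_frame(grid, proj)
  rep_run <- proj$run[rep_idx]
  run_frames <- frames_in_window(runs[[rep_run]], wn)
  local_idx <- run_frames[sum(proj$run[seq_len(rep_idx)] == rep_run)]
  rep_traj <- subset_frames(runs[[rep_run]], local_idx)
  write_pdb(rep_traj, file.path(dir, "representative.pdb"))
  .write_csv(data.frame(pooled_index = rep_idx, run = rep_run,
                        frame = local_idx,
                        time_ps = proj$time_ps[rep_idx]),
             file.path(dir, "representative_frame.csv"))

  # residue interaction network on the representative frame
  table <- .stage("network", label, {
    fr <- matrix(rep_traj$coords[, , 1L], nrow(rep_traj$atoms), 3L)
    hb <- detect_hbonds(fr, da$donors, da$acceptors, config$hbond)
    rin <- build_rin(rep_traj, frame = 1L, hbonds = hb,
                     contact_cutoff = config$network_cutoff)
    edges_out <- data.frame(
      chain_i = rin$nodes$chain[rin$edges$i],
      resid_i = rin$nodes$resid[rin$edges$i],
      chain_j = rin$nodes$chain[rin$edges$j],
      resid_j = rin$nodes$resid[rin$edges$j],
      distance_nm = rin$edges$distance_nm,
      hbond_weight = rin$edges$hbond_weight)
    .write_csv(edges_out, file.path(dir, "rin_edges.csv"))
    tab <- betweenness_centrality(rin)
    tab$flagged <- as.integer(tab$cb >= config$central_threshold)
    .write_csv(tab, file.path(dir, "centrality.csv"))
    map_centrality_to_structure(rep_traj, tab[, c("chain", "resid",
                                                  "resname", "cb")],
                                file.path(dir, "centrality.pdb"),
                                threshold = config$central_threshold)
    tab
  })
  list(model = model, centrality = table, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, per complex and run: RMSD, RMSF (+ chain correlation), Rg,
#' SASA, hydrogen-bond counts, COM/minimum distances and interaction
#' energies; per complex on pooled windowed runs: covariance analysis,
#' projections, free-energy landscape, representative structure, residue
#' interaction network and betweenness centrality; across complexes:
#' covariance-overlap and RMSIP matrices and, when a reference is set,
#' differential-centrality tables with the common flagged-residue
#' intersection.  All outputs are plain CSV/PDB files; rerunning with the
#' same config reproduces them bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir report directory (created; existing files overwritten).
#' @return invisibly, a list with per-complex covariance models and
#'   centrality tables.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(config$complexes)
  results <- list()
  for (label in labels) {
    results[[label]] <- tryCatch(
      .run_complex(label, config$complexes[[label]], config,
                   file.path(out_dir, label)),
      error = function(e) {
        dir.create(file.path(out_dir, label), showWarnings = FALSE,
                   recursive = TRUE)
        writeLines(conditionMessage(e),
                   file.path(out_dir, label, "FAILED"))
        stop(conditionMessage(e), call. = FALSE)
      })
  }
  # cross-complex comparisons
  if (length(labels) > 1L) {
    k <- min(vapply(results, `[[`, integer(1L), "k"))
    ov <- matrix(NA_real_, length(labels), length(labels),
                 dimnames = list(labels, labels))
    rm_mat <- ov
    for (a in labels) {
      for (b in labels) {
        ov[a, b] <- covariance_overlap(results[[a]]$model,
                                       results[[b]]$model, k = k)
        rm_mat[a, b] <- rmsip(results[[a]]$model, results[[b]]$model,
                              k = k)$rmsip
      }
    }
    .write_csv(data.frame(label = labels, ov, check.names = FALSE),
               file.path(out_dir, "overlap_matrix.csv"))
    .write_csv(data.frame(label = labels, rm_mat, check.names = FALSE),
               file.path(out_dir, "rmsip_matrix.csv"))
  }
  if (!is.null(config$reference) && length(labels) > 1L) {
    ref <- results[[config$reference]]$centrality
    alts <- setdiff(labels, config$reference)
    diffs <- differential_centrality(
      ref[, c("chain", "resid", "resname", "cb")],
      lapply(stats::setNames(alts, alts), function(a) {
        results[[a]]$centrality[, c("chain", "resid", "resname", "cb")]
      }),
      threshold = config$differential_threshold)
    for (a in alts) {
      .write_csv(diffs$tables[[a]],
                 file.path(out_dir, sprintf("differential_%s.csv", a)))
    }
    .write_csv(diffs$common, file.path(out_dir, "differential_common.csv"))
  }
  writeLines(c(sprintf("complexes: %s", paste(labels, collapse = ", ")),
               sprintf("reference: %s", config$reference %||% "none"),
               sprintf("window_ns: %s", config$window_ns),
               sprintf("seed: %s", config$seed),
               sprintf("package: mdrin %s",
                       as.character(utils::packageVersion("mdrin")))),
             file.path(out_dir, "run_log.txt"))
  invisible(results)
}
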