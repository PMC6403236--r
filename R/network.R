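# Residue interaction networks and Brandes betweenness centrality,
# including the reference-vs-variant differential procedure.

#' Build a residue interaction network from one frame
#'
#' Nodes are residues; an edge connects two distinct residues whose
#' closest heavy-atom (non-hydrogen) cross-pair distance is at most
#' `contact_cutoff` (default 0.7 nm).  Sequence-adjacent residues are
#' treated like any other pair.  When a hydrogen-bond table is supplied,
#' each edge carries the number of hydrogen bonds between the two
#' residues as its `hbond_weight` (0 allowed).
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index the network is built from (typically a
#'   representative frame).
#' @param hbonds optional data frame from [detect_hbonds()] whose
#'   donor/acceptor atom indices refer to this topology.
#' @param contact_cutoff heavy-atom contact distance in nm.
#' @param selection atoms considered (default all; restrict to
#'   `"protein"` to drop nucleotide nodes).
#' @return a `residue_graph`: list with `nodes` (chain, resid, resname),
#'   `edges` (i, j node indices with i < j, `distance_nm`,
#'   `hbond_weight`) and `contact_cutoff`.
#' @export
build_rin <- function(traj, frame = 1L, hbonds = NULL,
                      contact_cutoff = 0.7, selection = "all") {
  idx <- .resolve(traj, selection)
  if (length(idx) == 0L) stop("empty structure")
  at <- traj$atoms[idx, ]
  heavy <- at$element != "H"
  if (!any(heavy)) stop("no heavy atoms in selection")
  key_all <- paste(at$chain, at$resid, sep = "\r")
  node_keys <- unique(key_all)
  nodes <- data.frame(
    chain = at$chain[match(node_keys, key_all)],
    resid = at$resid[match(node_keys, key_all)],
    resname = at$resname[match(node_keys, key_all)],
    stringsAsFactors = FALSE
  )
  n <- nrow(nodes)
  hat <- which(heavy)
  coords <- matrix(traj$coords[idx[hat], , frame], length(hat), 3L)
  rid <- match(key_all[hat], node_keys)
  D <- .cross_dist(coords, coords)
  ei <- integer(0); ej <- integer(0); ed <- numeric(0)
  for (a in seq_len(n - 1L)) {
    ia <- which(rid == a)
    if (length(ia) == 0L) next
    for (b in seq((a + 1L), n)) {
      ib <- which(rid == b)
      if (length(ib) == 0L) next
      dmin <- min(D[ia, ib])
      if (dmin <= contact_cutoff) {
        ei <- c(ei, a); ej <- c(ej, b); ed <- c(ed, dmin)
      }
    }
  }
  edges <- data.frame(i = ei, j = ej, distance_nm = ed,
                      hbond_weight = integer(length(ei)))
  if (!is.null(hbonds) && nrow(hbonds) > 0L && nrow(edges) > 0L) {
    full_key <- paste(traj$atoms$chain, traj$atoms$resid, sep = "\r")
    rd <- match(full_key[hbonds$donor], node_keys)
    ra <- match(full_key[hbonds$acceptor], node_keys)
    ok <- !is.na(rd) & !is.na(ra) & rd != ra
    pk <- paste(pmin(rd[ok], ra[ok]), pmax(rd[ok], ra[ok]))
    cnt <- table(pk)
    epk <- paste(edges$i, edges$j)
    hit <- match(epk, names(cnt))
    edges$hbond_weight <- ifelse(is.na(hit), 0L, as.integer(cnt[hit]))
  }
  structure(list(nodes = nodes, edges = edges,
                 contact_cutoff = contact_cutoff),
            class = "residue_graph")
}

#' Construct a residue graph directly from node and edge tables
#'
#' @param nodes data frame with columns `chain`, `resid`, `resname`.
#' @param edges data frame with columns `i`, `j` (node indices) and
#'   optionally `hbond_weight`, `distance_nm`.
#' @param contact_cutoff recorded cutoff (nm).
#' @return a `residue_graph`.
#' @export
residue_graph <- function(nodes, edges, contact_cutoff = 0.7) {
  if (any(edges$i == edges$j)) stop("self-edges are not allowed")
  if (is.null(edges$hbond_weight)) edges$hbond_weight <- 0L
  if (any(edges$hbond_weight < 0)) stop("negative hbond_weight")
  if (is.null(edges$distance_nm)) edges$distance_nm <- NA_real_
  ii <- pmin(edges$i, edges$j); jj <- pmax(edges$i, edges$j)
  edges$i <- ii; edges$j <- jj
  edges <- edges[!duplicated(paste(ii, jj)), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges,
                 contact_cutoff = contact_cutoff),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("residue_graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (cutoff", x$contact_cutoff, "nm)\n")
  invisible(x)
}

# Adjacency list: for each node, matrix of (neighbor, edge length).
.adjacency <- function(graph, mode) {
  n <- nrow(graph$nodes)
  len <- switch(mode,
    unweighted = rep(1, nrow(graph$edges)),
    hbond_weighted = 1 / (1 + graph$edges$hbond_weight)
  )
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- cbind(integer(0), numeric(0))
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[e]; j <- graph$edges$j[e]
    adj[[i]] <- rbind(adj[[i]], c(j, len[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, len[e]))
  }
  adj
}

#' Betweenness centrality of a residue graph (Brandes algorithm)
#'
#' Single-source shortest-path accumulation over all sources, normalised
#' by `2 / ((N - 2)(N - 1))` so that the interior node of a 3-node path
#' and the centre of a star both score exactly 1.  In `unweighted` mode
#' shortest paths are hop counts; in `hbond_weighted` mode they are
#' Dijkstra paths with edge length `1 / (1 + hbond_weight)` (more
#' hydrogen bonds = shorter effective distance; this weighting is one
#' interpretation of a bond-count-weighted network, and the unweighted
#' mode is the default throughout the package).  Node pairs in different
#' components contribute nothing; the normalisation always uses the
#' global node count.
#'
#' @param graph a `residue_graph`.
#' @param mode `"unweighted"` (default) or `"hbond_weighted"`.
#' @return data frame with columns `chain`, `resid`, `resname`, `cb`
#'   (each in \[0, 1\]).
#' @export
betweenness_centrality <- function(graph,
                                   mode = c("unweighted",
                                            "hbond_weighted")) {
  mode <- match.arg(mode)
  n <- nrow(graph$nodes)
  if (n < 3L) stop("normalization requires at least 3 nodes")
  adj <- .adjacency(graph, mode)
  tol <- 1e-12
  cb <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- logical(n)
    order_popped <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0L) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      order_popped <- c(order_popped, u)
      nb <- adj[[u]]
      for (e in seq_len(nrow(nb))) {
        w <- nb[e, 1L]; alt <- dist[u] + nb[e, 2L]
        if (alt < dist[w] - tol) {
          dist[w] <- alt
          sigma[w] <- sigma[u]
          preds[[w]] <- u
        } else if (abs(alt - dist[w]) <= tol && !done[w]) {
          sigma[w] <- sigma[w] + sigma[u]
          preds[[w]] <- c(preds[[w]], u)
        }
      }
    }
    delta <- numeric(n)
    for (u in rev(order_popped)) {
      for (p in preds[[u]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[u] * (1 + delta[u])
      }
      if (u != s) cb[u] <- cb[u] + delta[u]
    }
  }
  # Brandes counts each unordered pair from both endpoints: divide by 2,
  # then apply the normalisation constant 2 / ((N - 2)(N - 1)).
  cb <- cb / ((n - 2) * (n - 1))
  data.frame(chain = graph$nodes$chain, resid = graph$nodes$resid,
             resname = graph$nodes$resname, cb = cb,
             stringsAsFactors = FALSE)
}

#' Select high-centrality residues
#'
#' @param table centrality table from [betweenness_centrality()].
#' @param threshold inclusive lower bound on `cb` (default 0.1).
#' @return the qualifying rows sorted by `cb` descending, then chain and
#'   resid.
#' @export
select_central <- function(table, threshold = 0.1) {
  out <- table[table$cb >= threshold, , drop = FALSE]
  out <- out[order(-out$cb, out$chain, out$resid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.node_key <- function(table) paste(table$chain, table$resid, sep = "\r")

#' Differential betweenness centrality
#'
#' Computes `|cb_ref - cb_alt|` per shared node and reports residues at
#' or above the threshold (default 0.05).  With several alternates the
#' intersection of the flagged residue sets (`common`) is also returned,
#' to quantify how much of the perturbation pattern the alternates share.
#'
#' @param table_ref reference centrality table.
#' @param table_alt one alternate table, or a named list of them.
#' @param threshold inclusive lower bound on `|delta|`.
#' @return for a single alternate, a data frame with columns `chain`,
#'   `resid`, `resname`, `cb_ref`, `cb_alt`, `delta`, `abs_delta` (rows
#'   with `abs_delta >= threshold`, sorted by `abs_delta` descending);
#'   for a list, `list(tables = <per-alternate data frames>, common =
#'   <data frame of residues flagged in every alternate>)`.
#' @export
differential_centrality <- function(table_ref, table_alt,
                                    threshold = 0.05) {
  one <- function(alt) {
    kr <- .node_key(table_ref); ka <- .node_key(alt)
    if (length(kr) != length(ka) || !setequal(kr, ka)) {
      miss <- c(setdiff(kr, ka), setdiff(ka, kr))
      stop("node sets differ; unmatched residues: ",
           paste(gsub("\r", ":", miss), collapse = ", "))
    }
    m <- match(kr, ka)
    delta <- alt$cb[m] - table_ref$cb
    out <- data.frame(chain = table_ref$chain, resid = table_ref$resid,
                      resname = table_ref$resname,
                      cb_ref = table_ref$cb, cb_alt = alt$cb[m],
                      delta = delta, abs_delta = abs(delta),
                      stringsAsFactors = FALSE)
    out <- out[out$abs_delta >= threshold, , drop = FALSE]
    out <- out[order(-out$abs_delta, out$chain, out$resid), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  if (is.data.frame(table_alt)) return(one(table_alt))
  tables <- lapply(table_alt, one)
  keys <- lapply(tables, .node_key)
  common_keys <- Reduce(intersect, keys)
  ref_keys <- .node_key(table_ref)
  common <- table_ref[ref_keys %in% common_keys,
                      c("chain", "resid", "resname"), drop = FALSE]
  rownames(common) <- NULL
  list(tables = tables, common = common)
}

#' Write a structure with centrality mapped to the B-factor column
#'
#' The B-factor column carries `100 * cb` (clipped to the column width)
#' and residues selected at the given threshold are listed in REMARK
#' records.
#'
#' @param traj an `md_trajectory`.
#' @param table centrality table covering residues of the structure.
#' @param path output PDB path.
#' @param frame frame to write.
#' @param threshold threshold used for the REMARK list.
#' @return the path, invisibly.
#' @export
map_centrality_to_structure <- function(traj, table, path, frame = 1L,
                                        threshold = 0.1) {
  atom_key <- paste(traj$atoms$chain, traj$atoms$resid, sep = "\r")
  hit <- match(.node_key(table), unique(atom_key))
  if (anyNA(hit)) {
    bad <- .node_key(table)[is.na(hit)]
    stop("residues not found in structure: ",
         paste(gsub("\r", ":", bad), collapse = ", "))
  }
  per_atom <- table$cb[match(atom_key, .node_key(table))]
  per_atom[is.na(per_atom)] <- 0
  b <- pmin(pmax(100 * per_atom, 0), 999.99)
  flagged <- select_central(table, threshold)
  remarks <- c(
    "B-FACTOR COLUMN CARRIES 100 * BETWEENNESS CENTRALITY",
    if (nrow(flagged) > 0L) {
      sprintf("CENTRAL RESIDUE %s %s%d CB %.3f", flagged$resname,
              flagged$chain, flagged$resid, flagged$cb)
    }
  )
  single <- subset_frames(traj, frame)
  write_pdb(single, path, bfactor = b, remarks = remarks)
}
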