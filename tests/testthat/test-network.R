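# Residue interaction networks and Brandes betweenness centrality.

test_that("contact edges follow the heavy-atom cutoff exactly", {
  # two residues with closest heavy atoms at 0.69 vs 0.71 nm
  at <- tiny_topology(c("N", "H", "O"), resids = c(1, 1, 2))
  tr_in <- one_frame(at, rbind(c(0, 0, 0), c(0.05, 0, 0), c(0.69, 0, 0)))
  g_in <- build_rin(tr_in)
  expect_equal(nrow(g_in$edges), 1L)
  tr_out <- one_frame(at, rbind(c(0, 0, 0), c(0.05, 0, 0), c(0.71, 0, 0)))
  expect_equal(nrow(build_rin(tr_out)$edges), 0L)
  # the hydrogen does not rescue a contact: H at 0.66 nm from residue 2
  tr_h <- one_frame(at, rbind(c(0, 0, 0), c(0.05, 0, 0), c(0.76, 0, 0)))
  expect_equal(nrow(build_rin(tr_h)$edges), 0L)
})

test_that("toy-complex edge set equals the exhaustive residue double loop", {
  cx <- toy_cache()
  tr <- cx$traj
  g <- build_rin(tr, contact_cutoff = 0.7)
  heavy <- tr$atoms$element != "H"
  key <- paste(tr$atoms$chain, tr$atoms$resid)
  nodes <- unique(key)
  co <- tr$coords[, , 1]
  want <- NULL
  for (a in seq_along(nodes)) {
    for (b in seq_len(a - 1L)) {
      ia <- which(key == nodes[a] & heavy)
      ib <- which(key == nodes[b] & heavy)
      dmin <- Inf
      for (i in ia) for (j in ib) {
        dmin <- min(dmin, sqrt(sum((co[i, ] - co[j, ])^2)))
      }
      if (dmin <= 0.7) want <- c(want, paste(nodes[b], nodes[a], sep = "|"))
    }
  }
  node_lab <- paste(g$nodes$chain, g$nodes$resid)
  got <- paste(node_lab[g$edges$i], node_lab[g$edges$j], sep = "|")
  expect_setequal(got, want)
  expect_true(all(g$edges$i != g$edges$j))
  expect_true(all(g$edges$distance_nm <= 0.7))
})

test_that("hydrogen bonds weight the edges they fall on", {
  cx <- toy_cache()
  tr <- cx$traj
  da <- infer_donors_acceptors(tr)
  hb <- detect_hbonds(tr$coords[, , 1], da$donors, da$acceptors)
  g <- build_rin(tr, hbonds = hb)
  node_lab <- paste(g$nodes$chain, g$nodes$resid)
  # every planted bond lands on an edge with weight >= 1
  for (r in seq_len(nrow(cx$planted))) {
    p <- cx$planted[r, ]
    lab <- sort(c(paste(p$donor_chain, p$donor_resid),
                  paste(p$acceptor_chain, p$acceptor_resid)))
    e <- which(node_lab[g$edges$i] == lab[1] &
                 node_lab[g$edges$j] == lab[2])
    expect_length(e, 1L)
    expect_gte(g$edges$hbond_weight[e], 1L)
  }
  expect_equal(sum(g$edges$hbond_weight),
               nrow(hb[paste(tr$atoms$chain[hb$donor],
                             tr$atoms$resid[hb$donor]) !=
                         paste(tr$atoms$chain[hb$acceptor],
                               tr$atoms$resid[hb$acceptor]), ]))
})

test_that("betweenness hits the analytic path, star and complete values", {
  path3 <- make_graph_fixture("path", 3)
  cb <- betweenness_centrality(path3)$cb
  expect_equal(cb, c(0, 1, 0))
  star5 <- make_graph_fixture("star", 5)
  cb5 <- betweenness_centrality(star5)$cb
  expect_equal(cb5, c(1, 0, 0, 0, 0))
  k5 <- make_graph_fixture("complete", 5)
  expect_true(all(betweenness_centrality(k5)$cb == 0))
  expect_error(betweenness_centrality(
    residue_graph(data.frame(chain = "A", resid = 1:2, resname = "GLY"),
                  data.frame(i = 1, j = 2))), "3 nodes")
})

test_that("Brandes equals exhaustive path enumeration on random graphs", {
  for (s in 1:12) {
    n <- sample(4:10, 1)
    g <- make_graph_fixture("random_connected", n, seed = s,
                            random_weights = TRUE)
    for (mode in c("unweighted", "hbond_weighted")) {
      got <- betweenness_centrality(g, mode)$cb
      expect_equal(got, brute_force_betweenness(g, mode),
                   tolerance = 1e-10,
                   info = sprintf("seed %d mode %s", s, mode))
    }
  }
})

test_that("Brandes agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  for (s in 21:25) {
    g <- make_graph_fixture("random_connected", 12, seed = s,
                            random_weights = TRUE)
    ig <- igraph::graph_from_edgelist(cbind(g$edges$i, g$edges$j),
                                      directed = FALSE)
    norm <- 2 / ((12 - 2) * (12 - 1))
    expect_equal(betweenness_centrality(g, "unweighted")$cb,
                 unname(igraph::betweenness(ig)) * norm,
                 tolerance = 1e-10)
    expect_equal(betweenness_centrality(g, "hbond_weighted")$cb,
                 unname(igraph::betweenness(
                   ig, weights = 1 / (1 + g$edges$hbond_weight))) * norm,
                 tolerance = 1e-10)
  }
})

test_that("centrality is invariant under node relabelling", {
  g <- make_graph_fixture("random_connected", 9, seed = 40,
                          random_weights = TRUE)
  cb <- betweenness_centrality(g)$cb
  set.seed(41)
  perm <- sample(9)
  g2 <- residue_graph(g$nodes[order(perm), ],
                      data.frame(i = perm[g$edges$i], j = perm[g$edges$j],
                                 hbond_weight = g$edges$hbond_weight))
  cb2 <- betweenness_centrality(g2)$cb
  expect_equal(cb2[perm], cb, tolerance = 1e-12)
})

test_that("uniform weights reduce the weighted mode to hop counts", {
  for (w in c(0L, 2L)) {
    g <- make_graph_fixture("random_connected", 10, seed = 50)
    g$edges$hbond_weight <- w
    expect_equal(betweenness_centrality(g, "hbond_weighted")$cb,
                 betweenness_centrality(g, "unweighted")$cb,
                 tolerance = 1e-10)
  }
})

test_that("bridging two clusters concentrates centrality on the bridge", {
  g <- make_graph_fixture("two_cluster_bridge", 10)
  cb <- betweenness_centrality(g)$cb
  expect_equal(which(cb == max(cb)), c(5L, 6L))  # the bridge endpoints
  expect_true(all(cb[c(1:4, 7:10)] < max(cb)))
  # disconnected components contribute nothing but N stays global
  g2 <- residue_graph(g$nodes,
                      g$edges[!(g$edges$i == 5 & g$edges$j == 6), ])
  cb2 <- betweenness_centrality(g2)$cb
  expect_true(all(cb2 == 0))
})

test_that("central-residue selection is threshold-inclusive and sorted", {
  tab <- data.frame(chain = "A", resid = 1:3, resname = "GLY",
                    cb = c(0.3, 0.1, 0.05))
  sel <- select_central(tab)
  expect_equal(sel$resid, c(1L, 2L))   # 0.1 boundary included
  expect_equal(select_central(tab, threshold = 0.5)$resid, integer(0))
  star <- betweenness_centrality(make_graph_fixture("star", 7))
  expect_equal(select_central(star)$resid, 1L)
})

test_that("differential centrality flags |delta| >= threshold and intersects", {
  tab <- function(cb) data.frame(chain = "A", resid = seq_along(cb),
                                 resname = "GLY", cb = cb)
  ref <- tab(c(0.5, 0.2, 0.1))
  expect_equal(nrow(differential_centrality(ref, ref)), 0L)
  alt <- tab(c(0.44, 0.2, 0.1))
  d <- differential_centrality(ref, alt)
  expect_equal(d$resid, 1L)           # |0.5 - 0.44| = 0.06 >= 0.05
  expect_equal(d$delta, -0.06, tolerance = 1e-12)
  # three constructed tables: flagged sets and their intersection
  alt1 <- tab(c(0.44, 0.30, 0.1))     # flags residues 1 and 2
  alt2 <- tab(c(0.40, 0.20, 0.18))    # flags residues 1 and 3
  res <- differential_centrality(ref, list(m1 = alt1, m2 = alt2))
  expect_setequal(res$tables$m1$resid, c(1L, 2L))
  expect_setequal(res$tables$m2$resid, c(1L, 3L))
  expect_equal(res$common$resid, 1L)
  # node-set mismatch is an explicit error
  expect_error(differential_centrality(ref, tab(c(0.1, 0.2))),
               "unmatched")
})

test_that("centrality maps onto the B-factor column and survives rereading", {
  cx <- toy_cache()
  g <- build_rin(cx$traj)
  tab <- betweenness_centrality(g)
  tab$cb[1] <- 0.25  # make at least one value nontrivial and known
  f <- withr::local_tempfile(fileext = ".pdb")
  map_centrality_to_structure(cx$traj, tab, f)
  back <- read_pdb(f)
  b <- attr(back, "bfactor")
  key <- paste(back$atoms$chain, back$atoms$resid)
  recovered <- b[match(paste(tab$chain, tab$resid), key)] / 100
  expect_lt(max(abs(recovered - tab$cb)), 1e-4 + 1e-12)
  expect_equal(b[1], 25)
  bad <- rbind(tab, data.frame(chain = "Z", resid = 999, resname = "GLY",
                               cb = 0.5))
  expect_error(map_centrality_to_structure(cx$traj, bad, f), "Z:999")
})
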