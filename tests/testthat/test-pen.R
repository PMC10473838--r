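# Interaction-energy matrices and the shortest-path-map network.

test_that("pairwise energies reproduce Coulomb and Lennard-Jones identities", {
  # two unit charges 3.320637 A apart: 332.0637 / 3.320637 = 100 kcal/mol
  co <- rbind(c(0, 0, 0), c(3.320637, 0, 0))
  pp <- data.frame(residue = 1:2, charge = c(1, -1), lj_eps = 0,
                   lj_sigma = 1)
  E <- pairwise_energy(co, pp)
  expect_equal(E[1, 2], -100, tolerance = 1e-9)
  expect_identical(E[1, 2], E[2, 1])
  expect_true(is.na(E[1, 1]))

  # beyond the cutoff: exactly zero
  co2 <- rbind(c(0, 0, 0), c(11.5, 0, 0))
  expect_identical(pairwise_energy(co2, pp, cutoff = 11)[1, 2], 0)

  # neutral beads at the LJ minimum r = 2^(1/6) sigma: energy -eps
  sig <- 3; eps <- 0.7
  co3 <- rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0))
  pp3 <- data.frame(residue = 1:2, charge = 0, lj_eps = eps, lj_sigma = sig)
  expect_equal(pairwise_energy(co3, pp3)[1, 2], -eps, tolerance = 1e-12)

  expect_error(pairwise_energy(rbind(c(0, 0, 0), c(0, 0, 0)), pp), "zero")
  expect_error(pairwise_energy(co, pp[, 1:2]), "missing")
})

test_that("Lorentz-Berthelot combining and residue aggregation are applied", {
  # two residues with two atoms each; hand-summed atom-pair energies
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(5, 0, 0), c(6.5, 0, 0))
  pp <- data.frame(residue = c(1, 1, 2, 2), charge = c(0.2, -0.1, 0.3, 0.1),
                   lj_eps = c(0.1, 0.2, 0.3, 0.4),
                   lj_sigma = c(2.5, 3.0, 3.5, 4.0))
  manual <- 0
  for (a in 1:2) for (b in 3:4) {
    r <- abs(co[a, 1] - co[b, 1])
    eps <- sqrt(pp$lj_eps[a] * pp$lj_eps[b])
    sig <- (pp$lj_sigma[a] + pp$lj_sigma[b]) / 2
    manual <- manual + 332.0637 * pp$charge[a] * pp$charge[b] / r +
      4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  expect_equal(pairwise_energy(co, pp)[1, 2], manual, tolerance = 1e-12)
})

test_that("mean IEM is the arithmetic frame average and matches a Monte-Carlo oracle", {
  rec <- small_receptor(seed = 2)
  f1 <- rec$coords
  f2 <- rec$coords + 0.2
  m1 <- pairwise_energy(f1, rec$params)
  m2 <- pairwise_energy(f2, rec$params)
  iem <- mean_iem(list(f1, f2), rec$params)
  expect_equal(iem$raw, (m1 + m2) / 2, tolerance = 1e-12)
  expect_equal(mean_iem(list(f1), rec$params)$raw, m1)

  # noisy ensemble mean within 3 SE of the zero-noise matrix for the
  # strong planted pairs
  ens <- generate_ensemble(rec, 300, noise_sd = 0.05, seed = 3)
  noisy <- mean_iem(ens)
  pe <- rec$path_edge_table
  for (k in seq_len(nrow(pe))) {
    i <- as.character(pe[k, 1]); j <- as.character(pe[k, 2])
    vals <- vapply(seq_len(60), function(f)
      pairwise_energy(ens$coords[, , f], rec$params)[i, j], numeric(1))
    se <- sd(vals) / sqrt(60)
    expect_lt(abs(noisy$raw[i, j] - m1[i, j]), max(3 * se, 0.05))
  }
  expect_error(mean_iem(list(f1, f1[1:10, ]), rec$params), "topology")
})

test_that("intra chain scope masks inter-chain pairs", {
  rec <- make_bead_receptor(two_chains = TRUE, seed = 4)
  both <- mean_iem(rec$coords, rec$params)
  intra <- mean_iem(rec$coords, rec$params, chain_scope = "intra")
  ch <- rec$residues$chain
  inter <- outer(ch, ch, `!=`)
  expect_true(all(is.na(intra$raw[inter])))
  same <- !inter
  diag(same) <- FALSE
  expect_equal(intra$raw[same], both$raw[same])
})

test_that("IEM processing clamps repulsion, takes magnitudes and normalises to [0, 1]", {
  raw <- rbind(c(NA, -2), c(-2, NA))
  p <- process_iem(raw)
  expect_equal(p[1, 2], 1)

  raw2 <- rbind(c(NA, 3.2, -4), c(3.2, NA, -2), c(-4, -2, NA))
  p2 <- process_iem(raw2)
  expect_identical(p2[1, 2], 0)  # repulsive pair clamped
  expect_equal(p2[1, 3], 1)
  expect_equal(p2[2, 3], 0.5)

  raw3 <- rbind(c(NA, -4, -1), c(-4, NA, -2), c(-1, -2, NA))
  p3 <- process_iem(raw3)
  expect_equal(sort(p3[upper.tri(p3)]), c(0.25, 0.5, 1))

  # all-repulsive degenerate case: flagged, all zero
  expect_warning(pz <- process_iem(rbind(c(NA, 2), c(2, NA))), "attractive")
  expect_true(all(pz[upper.tri(pz)] == 0))
  expect_true(attr(pz, "degenerate"))
})

test_that("the 3-node chain routes all traffic through the middle node", {
  p <- rbind(c(NA, 0.5, 0.05), c(0.5, NA, 0.5), c(0.05, 0.5, NA))
  dimnames(p) <- list(1:3, 1:3)
  spm <- build_spm(p, threshold = 0.1)
  expect_identical(nrow(spm$edges), 2L)           # 1-3 excluded (0.05 < 0.1)
  expect_equal(spm$edges$length, rep(-log(0.5), 2))
  # paths: 1>2, 1>2>3, 2>1, 2>3, 3>2, 3>2>1 -> node 2 on all six
  expect_identical(spm$nodes$usage[spm$nodes$residue == 2], 6L)
  expect_identical(spm$nodes$usage[spm$nodes$residue == 1], 4L)
  expect_identical(spm$edges$usage, c(4L, 4L))
  expect_identical(which.max(spm$nodes$usage),
                   which(spm$nodes$residue == 2))
})

test_that("unit-strength edges have zero length and the search still terminates", {
  p <- rbind(c(NA, 1, 0.3), c(1, NA, 0.3), c(0.3, 0.3, NA))
  dimnames(p) <- list(1:3, 1:3)
  spm <- build_spm(p)
  expect_identical(spm$edges$length[spm$edges$ie == 1], 0)
  expect_true(all(spm$nodes$usage > 0))
})

test_that("a complete graph with equal couplings spreads usage uniformly", {
  p <- matrix(0.6, 4, 4); diag(p) <- NA
  dimnames(p) <- list(1:4, 1:4)
  spm <- build_spm(p)
  expect_identical(length(unique(spm$nodes$usage)), 1L)
  expect_identical(length(unique(spm$edges$usage)), 1L)
})

test_that("empty graphs after thresholding are rejected", {
  p <- rbind(c(NA, 0.05), c(0.05, NA))
  dimnames(p) <- list(1:2, 1:2)
  expect_error(build_spm(p, threshold = 0.1), "empty")
})

test_that("shortest-path lengths equal exhaustive enumeration on 200 random graphs", {
  dijkstra <- get("dijkstra_dense", asNamespace("allosteer"))
  for (case in 1:200) {
    n <- 3 + case %% 6
    p <- random_processed(n, seed = case)
    len <- -log(p)
    len[p <= 0.1] <- NA
    for (origin in seq_len(n)) {
      sp <- dijkstra(len, origin)
      for (target in seq_len(n)) {
        if (target == origin) next
        expect_equal(sp$dist[target], enum_shortest(len, origin, target),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("shortest-path lengths agree with an independent graph library", {
  for (case in c(5, 17, 42)) {
    p <- random_processed(8, seed = case)
    len <- -log(p)
    len[p <= 0.1] <- NA
    idx <- which(upper.tri(len) & !is.na(len), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = idx[, 1], to = idx[, 2]), directed = FALSE,
      vertices = data.frame(name = 1:8))
    ref <- igraph::distances(g, weights = len[idx])
    dijkstra <- get("dijkstra_dense", asNamespace("allosteer"))
    for (origin in 1:8) {
      expect_equal(dijkstra(len, origin)$dist, unname(ref[origin, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("uniform edge-length rescaling (log-base change) leaves usage counts unchanged", {
  for (seed in 1:5) {
    p <- random_processed(7, seed = seed)
    s1 <- build_spm(p, threshold = 0.1)
    # squaring the couplings doubles every -log length; thresholding at the
    # squared cut keeps the same edge set
    s2 <- build_spm(p^2, threshold = 0.01)
    expect_identical(s1$nodes$usage, s2$nodes$usage)
    expect_identical(s1$edges$usage, s2$edges$usage)
    expect_equal(s2$edges$length, 2 * s1$edges$length, tolerance = 1e-12)
  }
})

test_that("raising the threshold never adds nodes or edges", {
  p <- random_processed(9, seed = 11)
  prev_nodes <- Inf; prev_edges <- Inf
  for (th in c(0.1, 0.3, 0.5, 0.7)) {
    s <- try(build_spm(p, threshold = th), silent = TRUE)
    if (inherits(s, "try-error")) {
      n_nodes <- 0; n_edges <- 0
    } else {
      n_nodes <- nrow(s$nodes); n_edges <- nrow(s$edges)
    }
    expect_lte(n_nodes, prev_nodes)
    expect_lte(n_edges, prev_edges)
    prev_nodes <- n_nodes; prev_edges <- n_edges
  }
})

test_that("usage counts are invariant under node relabelling", {
  p <- random_processed(7, seed = 21)
  s1 <- build_spm(p)
  perm <- c(3, 1, 7, 2, 6, 5, 4)
  pp <- p[perm, perm]
  dimnames(pp) <- dimnames(p)
  s2 <- build_spm(pp)
  # map permuted usage back to original labels
  u2 <- s2$nodes$usage[match(seq_len(7), perm)[s1$nodes$residue]]
  expect_identical(sort(s1$nodes$usage), sort(s2$nodes$usage))
  expect_identical(s1$nodes$usage, u2)
})

test_that("planted pathways dominate the usage ranking", {
  recov <- vapply(1:3, function(seed) {
    rec <- make_bead_receptor(seed = seed)
    ens <- generate_ensemble(rec, 40, noise_sd = 0.1, seed = seed)
    spm <- build_spm(process_iem(mean_iem(ens)))
    top_edge_recovery(spm, rec$path_edge_table)
  }, numeric(1))
  expect_gte(mean(recov), 0.9)
})

test_that("reference-set overlap reports captured and adjacent residues", {
  p <- rbind(c(NA, 0.9, 0.4), c(0.9, NA, 0.4), c(0.4, 0.4, NA))
  dimnames(p) <- list(c(5, 6, 7), c(5, 6, 7))
  spm <- build_spm(p)
  ov <- overlap_with_reference(spm, c(5, 6), all_residues = 1:10)
  expect_identical(ov$captured, c(5L, 6L))
  expect_identical(ov$adjacent, integer(0))
  expect_equal(ov$fraction_captured, 1)

  ov2 <- overlap_with_reference(spm, c(4, 9), all_residues = 1:10)
  expect_identical(ov2$captured, integer(0))
  expect_identical(ov2$adjacent, 4L)  # residue 4 is next to node 5

  ov3 <- overlap_with_reference(spm, integer(0), all_residues = 1:10)
  expect_identical(ov3$n_reference, 0L)
  expect_error(overlap_with_reference(spm, 99, all_residues = 1:10),
               "unknown")
})
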