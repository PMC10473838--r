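# Protein energy networks: per-frame pairwise residue interaction energies
# (Coulomb + Lennard-Jones with Lorentz-Berthelot combining), ensemble-mean
# interaction-energy matrices, the clamp/abs/normalize processing, and the
# shortest-path-map graph with path-count centralities.

#' Pairwise residue interaction energies of one frame
#'
#' Sums, over all atom pairs of two residues within `cutoff`, the Coulomb
#' term `332.0637 q_a q_b / r` and the Lennard-Jones term
#' `4 eps_ab ((sig_ab/r)^12 - (sig_ab/r)^6)` with Lorentz-Berthelot
#' combining (`sig_ab` arithmetic mean, `eps_ab` geometric mean).
#' Intra-residue terms are excluded; sequence-adjacent residue pairs are
#' included by default.
#'
#' @param coords n_atoms x 3 coordinates, Angstrom.
#' @param params Parameter table with one row per atom: columns `residue`,
#'   `charge`, `lj_eps`, `lj_sigma` (and optionally `chain`).
#' @param cutoff Interaction cutoff, Angstrom (default 11).
#' @param exclude_adjacent Drop 1-2 (sequence-adjacent, same chain) residue
#'   pairs.
#' @return Symmetric n_res x n_res matrix of energies (kcal/mol), diagonal
#'   `NA`.
#' @examples
#' co <- rbind(c(0, 0, 0), c(3.320637, 0, 0))
#' pp <- data.frame(residue = 1:2, charge = c(1, -1), lj_eps = 0,
#'                  lj_sigma = 1)
#' pairwise_energy(co, pp)[1, 2]  # -100 kcal/mol
#' @export
pairwise_energy <- function(coords, params, cutoff = 11,
                            exclude_adjacent = FALSE) {
  n_atoms <- nrow(coords)
  if (nrow(params) != n_atoms) stop2("one parameter row per atom is required")
  need <- c("residue", "charge", "lj_eps", "lj_sigma")
  if (!all(need %in% names(params))) {
    stop2("missing parameters: ", paste(setdiff(need, names(params)),
                                        collapse = ", "))
  }
  res_ids <- sort(unique(params$residue))
  n_res <- length(res_ids)
  res_of <- match(params$residue, res_ids)

  D <- as.matrix(stats::dist(coords))
  pair <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  E <- matrix(0, n_res, n_res)
  if (nrow(pair)) {
    a <- pair[, 1]; b <- pair[, 2]
    same_res <- res_of[a] == res_of[b]
    a <- a[!same_res]; b <- b[!same_res]
    if (length(a)) {
      r <- D[cbind(a, b)]
      if (any(r < 1e-9)) stop2("zero interatomic distance between atoms ",
                               a[which(r < 1e-9)[1]], " and ",
                               b[which(r < 1e-9)[1]])
      qq <- COULOMB * params$charge[a] * params$charge[b] / r
      eps <- sqrt(params$lj_eps[a] * params$lj_eps[b])
      sig <- (params$lj_sigma[a] + params$lj_sigma[b]) / 2
      sr6 <- (sig / r)^6
      e <- qq + 4 * eps * (sr6^2 - sr6)
      ij <- cbind(res_of[a], res_of[b])
      flip <- ij[, 1] > ij[, 2]
      ij[flip, ] <- ij[flip, c(2, 1)]
      agg <- rowsum(e, group = (ij[, 1] - 1) * n_res + ij[, 2])
      idx <- as.integer(rownames(agg))
      E[cbind((idx - 1) %/% n_res + 1, (idx - 1) %% n_res + 1)] <- agg[, 1]
      E <- E + t(E)
    }
  }
  if (exclude_adjacent) {
    chain <- params$chain[match(res_ids, params$residue)] %||% rep("A", n_res)
    for (i in seq_len(n_res - 1)) {
      if (res_ids[i + 1] - res_ids[i] == 1 && chain[i] == chain[i + 1]) {
        E[i, i + 1] <- E[i + 1, i] <- 0
      }
    }
  }
  diag(E) <- NA_real_
  dimnames(E) <- list(res_ids, res_ids)
  E
}

#' Ensemble-mean interaction-energy matrix (IEM)
#'
#' Unweighted arithmetic mean of per-frame [pairwise_energy()] matrices over
#' the supplied frames (state-split ensembles are averaged directly, without
#' bias reweighting). With `chain_scope = "intra"`, inter-chain residue pairs
#' are masked `NA`; the default keeps both intra- and inter-chain pairs.
#'
#' @param ensemble A `synthetic_ensemble`, atoms x 3 x frames array, or list
#'   of frames.
#' @param params Atom parameter table (taken from the ensemble if attached).
#' @param cutoff Angstrom.
#' @param chain_scope `"intra+inter"` (default) or `"intra"`.
#' @param exclude_adjacent Passed to [pairwise_energy()].
#' @return Object of class `iem` with `$raw` mean matrix, `$processed`
#'   (NULL until [process_iem()]), `$n_frames`, `$cutoff`, `$residues`.
#' @export
mean_iem <- function(ensemble, params = NULL, cutoff = 11,
                     chain_scope = c("intra+inter", "intra"),
                     exclude_adjacent = FALSE) {
  chain_scope <- match.arg(chain_scope)
  if (is.null(params) && inherits(ensemble, "synthetic_ensemble")) {
    params <- ensemble$params
  }
  if (is.null(params)) stop2("`params` is required")
  frames <- as_frame_list(ensemble)
  if (!length(frames)) stop2("at least one frame is required")
  n_atoms <- nrow(frames[[1]])
  acc <- NULL
  for (fr in frames) {
    if (nrow(fr) != n_atoms) stop2("inconsistent topology across frames")
    E <- pairwise_energy(fr, params, cutoff, exclude_adjacent)
    acc <- if (is.null(acc)) E else acc + E
  }
  raw <- acc / length(frames)
  if (chain_scope == "intra" && "chain" %in% names(params)) {
    res_ids <- as.integer(rownames(raw))
    chain <- params$chain[match(res_ids, params$residue)]
    inter <- outer(chain, chain, `!=`)
    raw[inter] <- NA_real_
  }
  structure(list(raw = raw, processed = NULL, n_frames = length(frames),
                 cutoff = cutoff, chain_scope = chain_scope,
                 residues = as.integer(rownames(raw))),
            class = "iem")
}

#' @export
print.iem <- function(x, ...) {
  cat(sprintf("Interaction-energy matrix: %d x %d residues, %d frame(s), cutoff %.1f A\n",
              nrow(x$raw), ncol(x$raw), x$n_frames, x$cutoff))
  att <- x$raw[upper.tri(x$raw)]
  cat(sprintf("  strongest attraction %.3f kcal/mol, %d attractive pairs%s\n",
              min(att, na.rm = TRUE), sum(att < 0, na.rm = TRUE),
              if (!is.null(x$processed)) " (processed)" else ""))
  invisible(x)
}

#' Clamp, absolute-value and normalise an interaction-energy matrix
#'
#' Repulsive (positive) mean energies are set to 0, attractive (negative)
#' ones are replaced by their absolute values, and the matrix is divided by
#' its global maximum so the processed couplings range between 0 and 1. A
#' matrix with no attractive pair yields all zeros and is flagged.
#'
#' @param iem An [mean_iem()] object, or a raw numeric matrix.
#' @return The `iem` with `$processed` filled (values in [0, 1], diagonal
#'   `NA`); attribute `degenerate` is TRUE when no attractive pair exists.
#' @export
process_iem <- function(iem) {
  raw <- if (inherits(iem, "iem")) iem$raw else as.matrix(iem)
  p <- pmin(raw, 0)
  p <- abs(p)
  mx <- max(p, na.rm = TRUE)
  degenerate <- !is.finite(mx) || mx <= 0
  if (degenerate) {
    warning("no attractive pair: processed matrix is all zero")
  } else {
    p <- p / mx
  }
  attr(p, "degenerate") <- degenerate
  if (inherits(iem, "iem")) {
    iem$processed <- p
    iem
  } else {
    p
  }
}

# Deterministic Dijkstra over a dense length matrix (NA = no edge).
# Tie-breaks: the unvisited node with the smallest distance is taken, lowest
# index first; among equal-length paths the predecessor with the lowest
# index is kept.
dijkstra_dense <- function(len, origin, tol = 1e-12) {
  n <- nrow(len)
  dist <- rep(Inf, n); pred <- rep(NA_integer_, n); done <- rep(FALSE, n)
  dist[origin] <- 0
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- which(!is.na(len[u, ]) & !done)
    for (v in nb) {
      alt <- dist[u] + len[u, v]
      if (alt < dist[v] - tol) {
        dist[v] <- alt; pred[v] <- u
      } else if (abs(alt - dist[v]) <= tol && !is.na(pred[v]) &&
                 u < pred[v]) {
        pred[v] <- u
      }
    }
  }
  list(dist = dist, pred = pred)
}

#' Build the shortest-path map (SPM) of a processed energy network
#'
#' Residue pairs whose normalised mean interaction energy exceeds
#' `threshold` become the nodes and edges of the protein energy network;
#' each edge gets the length `d_ij = -log(IE_ij)` (natural log; the base
#' only rescales all lengths uniformly and cannot change shortest paths).
#' A deterministic Dijkstra exploration then takes every node as origin and
#' finds the shortest path to every other reachable node; each origin-target
#' path increments a usage counter on the nodes and edges it traverses.
#' Node sizes and edge widths are these counts normalised by their maxima.
#'
#' @param processed A [process_iem()] result (`iem` object or matrix in
#'   [0, 1] with `NA` diagonal).
#' @param threshold Normalised-energy node threshold (default 0.1); only
#'   pairs strictly above it enter the graph.
#' @param include_endpoints Count the origin and target of each path in the
#'   node usage (default) or interior nodes only.
#' @return Object of class `spm`: `$nodes` (residue, usage, size),
#'   `$edges` (from, to, ie, length, usage, width), `$threshold`,
#'   `$lengths` dense matrix.
#' @export
build_spm <- function(processed, threshold = 0.1, include_endpoints = TRUE) {
  p <- if (inherits(processed, "iem")) {
    if (is.null(processed$processed)) stop2("run process_iem() first")
    processed$processed
  } else as.matrix(processed)
  res_ids <- as.integer(rownames(p) %||% seq_len(nrow(p)))
  keep <- !is.na(p) & p > threshold
  diag(keep) <- FALSE
  node_sel <- which(rowSums(keep) > 0)
  if (!length(node_sel)) stop2("no residue pair above the threshold: empty graph")
  p <- p[node_sel, node_sel, drop = FALSE]
  keep <- keep[node_sel, node_sel, drop = FALSE]
  ids <- res_ids[node_sel]
  n <- length(ids)
  len <- matrix(NA_real_, n, n)
  len[keep] <- -log(p[keep])
  node_usage <- integer(n)
  edge_usage <- matrix(0L, n, n)
  for (origin in seq_len(n)) {
    sp <- dijkstra_dense(len, origin)
    for (target in seq_len(n)) {
      if (target == origin || !is.finite(sp$dist[target])) next
      path <- target
      while (path[1] != origin) path <- c(sp$pred[path[1]], path)
      inc <- if (include_endpoints) path else path[-c(1, length(path))]
      node_usage[inc] <- node_usage[inc] + 1L
      for (e in seq_len(length(path) - 1)) {
        a <- min(path[e], path[e + 1]); b <- max(path[e], path[e + 1])
        edge_usage[a, b] <- edge_usage[a, b] + 1L
      }
    }
  }
  eidx <- which(upper.tri(len) & !is.na(len), arr.ind = TRUE)
  edges <- data.frame(from = ids[eidx[, 1]], to = ids[eidx[, 2]],
                      ie = p[eidx], length = len[eidx],
                      usage = edge_usage[eidx])
  edges$width <- if (max(edges$usage) > 0) edges$usage / max(edges$usage)
                 else 0
  nodes <- data.frame(residue = ids, usage = node_usage,
                      size = if (max(node_usage) > 0)
                        node_usage / max(node_usage) else 0)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 lengths = len, residue_ids = ids,
                 include_endpoints = include_endpoints), class = "spm")
}

#' @export
print.spm <- function(x, ...) {
  cat(sprintf("Shortest-path map: %d nodes, %d edges (IE > %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  top <- utils::head(x$edges[order(-x$edges$usage), ], 5)
  cat("  top edges by usage:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %d - %d  (usage %d, IE %.3f)\n", top$from[i], top$to[i],
                top$usage[i], top$ie[i]))
  }
  invisible(x)
}

#' @export
plot.spm <- function(x, coords = NULL, ...) {
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(x$edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = x$nodes$residue))
    igraph::plot.igraph(g, vertex.size = 5 + 15 * x$nodes$size,
                        edge.width = 0.5 + 4 * x$edges$width, ...)
  } else {
    graphics::plot(x$nodes$residue, x$nodes$usage, type = "h",
                   xlab = "residue", ylab = "node usage", ...)
  }
  invisible(x)
}

#' Overlap of network nodes with a reference residue set
#'
#' Reports which reference residues (e.g. experimentally identified
#' allosteric positions, or a planted pathway) are captured as network
#' nodes, and which lie adjacent to a node — within `seq_adjacency` sequence
#' positions, or within `spatial_cutoff` Angstrom when coordinates are
#' given.
#'
#' @param spm A [build_spm()] object.
#' @param reference Residue id vector.
#' @param all_residues Residue ids of the full topology (for validation).
#' @param seq_adjacency Sequence distance counted as adjacent (default 1).
#' @param coords,spatial_cutoff Optional coordinates (one row per residue of
#'   `all_residues`) and distance for spatial adjacency.
#' @return list: `captured`, `adjacent`, `fraction_captured`, `n_reference`.
#' @export
overlap_with_reference <- function(spm, reference, all_residues = NULL,
                                   seq_adjacency = 1, coords = NULL,
                                   spatial_cutoff = NULL) {
  reference <- unique(as.integer(reference))
  if (!is.null(all_residues) && !all(reference %in% all_residues)) {
    stop2("unknown reference residues: ",
          paste(setdiff(reference, all_residues), collapse = ", "))
  }
  nodes <- spm$nodes$residue
  captured <- intersect(reference, nodes)
  rest <- setdiff(reference, captured)
  adjacent <- integer(0)
  for (r in rest) {
    near_seq <- any(abs(nodes - r) <= seq_adjacency)
    near_sp <- FALSE
    if (!is.null(coords) && !is.null(spatial_cutoff)) {
      i <- match(r, all_residues)
      j <- match(nodes, all_residues)
      near_sp <- any(sqrt(rowSums((coords[j, , drop = FALSE] -
                                     matrix(coords[i, ], length(j), 3,
                                            byrow = TRUE))^2)) <=
                       spatial_cutoff)
    }
    if (near_seq || near_sp) adjacent <- c(adjacent, r)
  }
  list(captured = captured, adjacent = adjacent,
       fraction_captured = if (length(reference))
         length(captured) / length(reference) else NaN,
       n_reference = length(reference))
}
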