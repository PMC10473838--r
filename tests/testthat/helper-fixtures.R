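# Shared fixtures. Expensive landscape runs are memoised so the acceptance
# checks that share a trajectory (surface recovery and reweighting
# consistency) compute it once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Converged triple-well run shared by the landscape-recovery and
# reweighting-consistency checks.
triple_well_run <- function() {
  memo("triple_well_run", {
    pot <- make_potential("triple_well_2d")
    run <- run_wtmetad(pot, metad_params(steps_per_walker = 160000,
                                         seed = 11))
    tmax <- max(run$hills$time)
    grid <- make_fes_grid(pot$domain, pot$periodic, n = c(40, 90))
    fes <- reconstruct_fes(run$bias, grid = grid, bias_factor = 10,
                           average_checkpoints = seq(tmax / 2, tmax,
                                                     length.out = 8))
    list(pot = pot, run = run, fes = fes)
  })
}

# Small receptor + ensemble for network tests.
small_receptor <- function(seed = 1) make_bead_receptor(seed = seed)

# Independent shortest-path oracle: exhaustive enumeration of all simple
# paths on a small dense length matrix (NA = no edge).
enum_shortest <- function(len, from, to) {
  n <- nrow(len)
  best <- Inf
  recurse <- function(v, visited, acc) {
    if (v == to) {
      best <<- min(best, acc)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!visited[u] && !is.na(len[v, u])) {
        visited[u] <- TRUE
        recurse(u, visited, acc + len[v, u])
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  recurse(from, visited, 0)
  best
}

# Random symmetric processed-energy matrix (continuous values, tie-free).
random_processed <- function(n, p_edge = 0.6, seed = 1) {
  with_seed <- get("with_seed", asNamespace("allosteer"))
  with_seed(seed, {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        m[i, j] <- m[j, i] <- stats::runif(1, 0.11, 0.99)
      }
    }
    m <- m / max(max(m), 1e-9)
    diag(m) <- NA_real_
    rownames(m) <- colnames(m) <- seq_len(n)
    m
  })
}

top_edge_recovery <- function(spm, path_edges) {
  k <- nrow(path_edges)
  ord <- spm$edges[order(-spm$edges$usage), , drop = FALSE]
  top <- ord[seq_len(min(k, nrow(ord))), , drop = FALSE]
  mean(apply(path_edges, 1, function(e) {
    any(top$from == min(e) & top$to == max(e))
  }))
}
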