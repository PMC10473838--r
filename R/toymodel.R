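# Synthetic systems with planted ground truth: analytic CV-space potentials,
# bead-per-residue receptors carrying a designated communication pathway, and
# noisy conformational ensembles with controllable transient cavities.

# Run expr with a temporary RNG state seeded by `seed`, restoring the caller's
# state afterwards so generators never perturb the global RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Construct an analytic two-dimensional collective-variable potential
#'
#' Builds a differentiable toy energy surface over two collective variables —
#' an aperiodic, distance-like CV1 and a periodic, torsion-like CV2 — with
#' Gaussian wells of declared centers and depths sitting in a flat plateau.
#' Because the wells share widths and the plateau is flat, the free-energy
#' difference between basins is (for narrow wells) the difference of the
#' declared depths, and the exact value is available by numerical quadrature
#' via [basin_free_energies()].
#'
#' Templates:
#' \describe{
#'   \item{`triple_well_2d`}{three wells at staggered (CV1, CV2) positions,
#'     default depths 0, +1.0 and +0.5 kcal/mol.}
#'   \item{`symmetric_double_well_2d`}{two wells of equal depth; the basin
#'     free-energy difference is exactly zero by symmetry.}
#'   \item{`double_well_1d_harmonic`}{a double well along CV1 multiplied by a
#'     harmonic confinement in CV2 (CV2 treated as aperiodic); the cheapest
#'     template for convergence studies.}
#' }
#'
#' @param template Template name.
#' @param centers k x 2 matrix of well centers (CV1 in Angstrom-like units,
#'   CV2 in degrees). Defaults per template.
#' @param depths Well free-energy offsets in kcal/mol (0 = deepest).
#' @param widths Gaussian well standard deviations per CV.
#' @param barrier Plateau height above the shallowest well, kcal/mol (> 0).
#' @param domain 2 x 2 matrix of per-CV (lo, hi) bounds.
#' @param periodic Logical length 2; which CVs are periodic (360 degrees).
#' @param basin_halfwidth Half-width of the declared basin boxes per CV;
#'   defaults to 3 widths.
#' @return An object of class `analytic_potential` with vectorised `$energy`
#'   and `$gradient` closures, the declared `$basins` table, and the template
#'   parameters.
#' @examples
#' pot <- make_potential("triple_well_2d")
#' pot$energy(rbind(pot$centers[1, ]))
#' basin_free_energies(pot, temperature = 303.15)
#' @export
make_potential <- function(template = c("triple_well_2d",
                                        "symmetric_double_well_2d",
                                        "double_well_1d_harmonic"),
                           centers = NULL, depths = NULL,
                           widths = c(0.5, 16), barrier = 3,
                           domain = rbind(cv1 = c(0, 10), cv2 = c(-180, 180)),
                           periodic = c(FALSE, TRUE),
                           basin_halfwidth = NULL) {
  template <- match.arg(template)
  if (!is.numeric(barrier) || barrier <= 0) stop2("`barrier` must be > 0")
  harmonic_cv2 <- FALSE
  k_harm <- 0
  if (is.null(centers)) {
    centers <- switch(template,
      triple_well_2d = rbind(c(2, -120), c(5, 0), c(8, 120)),
      symmetric_double_well_2d = rbind(c(3, -90), c(7, 90)),
      double_well_1d_harmonic = rbind(c(3, 0), c(7, 0)))
  }
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (is.null(depths)) {
    depths <- switch(template,
      triple_well_2d = c(0, 1.0, 0.5),
      symmetric_double_well_2d = c(0, 0),
      double_well_1d_harmonic = c(0, 0.5))
  }
  if (length(depths) != k) stop2("one depth per well is required")
  if (template == "double_well_1d_harmonic") {
    harmonic_cv2 <- TRUE
    periodic <- c(FALSE, FALSE)
    k_harm <- 2e-4  # kcal/mol/deg^2 -> sd ~ 55 deg at 300 K
  }
  if (is.null(basin_halfwidth)) basin_halfwidth <- 3 * widths
  plateau <- max(depths) + barrier
  amplitudes <- plateau - depths
  if (any(amplitudes <= 0)) stop2("depths must lie below the plateau")

  basins <- data.frame(
    name = paste0("basin", seq_len(k)),
    cv1_lo = centers[, 1] - basin_halfwidth[1],
    cv1_hi = centers[, 1] + basin_halfwidth[1],
    cv2_lo = centers[, 2] - if (harmonic_cv2) 3 * sqrt(KB * 303.15 / k_harm) else basin_halfwidth[2],
    cv2_hi = centers[, 2] + if (harmonic_cv2) 3 * sqrt(KB * 303.15 / k_harm) else basin_halfwidth[2],
    stringsAsFactors = FALSE)
  # declared basin regions must not overlap
  if (k > 1) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (basins$cv1_lo[a] < basins$cv1_hi[b] && basins$cv1_lo[b] < basins$cv1_hi[a] &&
          basins$cv2_lo[a] < basins$cv2_hi[b] && basins$cv2_lo[b] < basins$cv2_hi[a]) {
        stop2("basin regions of wells ", a, " and ", b, " overlap")
      }
    }
  }

  # Calibrate well amplitudes so that the declared depths are exactly the
  # Boltzmann basin free-energy offsets at the reference temperature (the
  # quantity a landscape reconstruction measures), not bare minima: a
  # shallower Gaussian well is also wider-bottomed, which the bare amplitude
  # would otherwise fold into the basin entropy.
  ref_temp <- 303.15
  bt <- kbt(ref_temp)
  well_F <- function(A) {
    hw1 <- basin_halfwidth[1]
    x1 <- seq(-hw1, hw1, length.out = 121)
    if (harmonic_cv2) {
      g1 <- exp(-0.5 * (x1 / widths[1])^2)
      z <- sum(trapz_weights(x1) * exp(A * g1 / bt))
    } else {
      hw2 <- basin_halfwidth[2]
      x2 <- seq(-hw2, hw2, length.out = 121)
      g <- exp(A * outer(exp(-0.5 * (x1 / widths[1])^2),
                         exp(-0.5 * (x2 / widths[2])^2)) / bt)
      z <- as.numeric(t(trapz_weights(x1)) %*% g %*% trapz_weights(x2))
    }
    -bt * log(z)
  }
  ref_F <- well_F(amplitudes[which.min(depths)])
  for (i in seq_len(k)) {
    target <- ref_F + (depths[i] - min(depths))
    amplitudes[i] <- stats::uniroot(function(A) well_F(A) - target,
                                    c(1e-3, plateau + barrier),
                                    tol = 1e-10)$root
  }

  wall_k <- 10  # kcal/mol per (unit excess)^2, flat inside the domain
  dom <- domain
  per <- periodic

  gauss_parts <- function(x) {
    # returns list(g = n x k Gaussian values, d1, d2 = scaled displacements)
    n <- nrow(x)
    g <- matrix(0, n, k); d1 <- matrix(0, n, k); d2 <- matrix(0, n, k)
    for (i in seq_len(k)) {
      dd1 <- x[, 1] - centers[i, 1]
      if (per[1]) dd1 <- wrap_angle(dd1)
      dd2 <- x[, 2] - centers[i, 2]
      if (per[2]) dd2 <- wrap_angle(dd2)
      d1[, i] <- dd1; d2[, i] <- dd2
      arg <- 0.5 * (dd1 / widths[1])^2
      if (!harmonic_cv2) arg <- arg + 0.5 * (dd2 / widths[2])^2
      g[, i] <- exp(-arg)
    }
    list(g = g, d1 = d1, d2 = d2)
  }

  energy <- function(x) {
    x <- rbind(x)
    p <- gauss_parts(x)
    u <- plateau - as.vector(p$g %*% amplitudes)
    if (harmonic_cv2) u <- u + 0.5 * k_harm * x[, 2]^2
    for (d in 1:2) {
      if (!per[d]) {
        lo <- dom[d, 1]; hi <- dom[d, 2]
        u <- u + wall_k * pmax(0, lo - x[, d])^2 + wall_k * pmax(0, x[, d] - hi)^2
      }
    }
    u
  }
  gradient <- function(x) {
    x <- rbind(x)
    p <- gauss_parts(x)
    ag <- sweep(p$g, 2, amplitudes, `*`)
    g1 <- rowSums(ag * p$d1) / widths[1]^2
    g2 <- if (harmonic_cv2) k_harm * x[, 2] else rowSums(ag * p$d2) / widths[2]^2
    grad <- cbind(g1, g2, deparse.level = 0)
    for (d in 1:2) {
      if (!per[d]) {
        lo <- dom[d, 1]; hi <- dom[d, 2]
        grad[, d] <- grad[, d] - 2 * wall_k * pmax(0, lo - x[, d]) +
          2 * wall_k * pmax(0, x[, d] - hi)
      }
    }
    grad
  }

  structure(list(
    name = template, template = template, centers = centers, depths = depths,
    widths = widths, amplitudes = amplitudes, plateau = plateau,
    barrier = barrier, domain = domain, periodic = periodic, basins = basins,
    harmonic_cv2 = harmonic_cv2, k_harm = k_harm,
    energy = energy, gradient = gradient), class = "analytic_potential")
}

#' @export
print.analytic_potential <- function(x, ...) {
  cat("Analytic 2-D potential:", x$name, "\n")
  cat(sprintf("  %d wells, plateau %.2f kcal/mol, periodic CV2: %s\n",
              nrow(x$centers), x$plateau, x$periodic[2]))
  print(cbind(round(x$centers, 3), depth = x$depths))
  invisible(x)
}

#' Reference basin free energies by direct quadrature
#'
#' Integrates the Boltzmann weight of the analytic potential over each
#' declared basin box on a fine grid (2-D trapezoid rule) and returns
#' \eqn{F_b = -k_B T \ln \int_b e^{-U/k_B T}}. This is the independent ground
#' truth against which reconstructed free-energy surfaces are judged.
#'
#' @param potential An [make_potential()] object.
#' @param temperature Kelvin.
#' @param n_quad Quadrature points per axis.
#' @return data.frame with columns `name`, `F` (kcal/mol) and `F_rel`
#'   (relative to the deepest basin).
#' @export
basin_free_energies <- function(potential, temperature = 303.15, n_quad = 161) {
  bt <- kbt(temperature)
  b <- potential$basins
  Fb <- vapply(seq_len(nrow(b)), function(i) {
    x1 <- seq(b$cv1_lo[i], b$cv1_hi[i], length.out = n_quad)
    x2 <- seq(b$cv2_lo[i], b$cv2_hi[i], length.out = n_quad)
    g <- as.matrix(expand.grid(x1, x2))
    u <- matrix(potential$energy(g), n_quad, n_quad)
    w1 <- trapz_weights(x1); w2 <- trapz_weights(x2)
    z <- as.numeric(t(w1) %*% exp(-u / bt) %*% w2)
    -bt * log(z)
  }, numeric(1))
  data.frame(name = b$name, F = Fb, F_rel = Fb - min(Fb),
             stringsAsFactors = FALSE)
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- c(diff(x), 0) + c(0, diff(x))
  w / 2
}

#' Pairwise basin free-energy differences from quadrature
#'
#' @inheritParams basin_free_energies
#' @return Matrix `D` with `D[i, j] = F_i - F_j` in kcal/mol.
#' @export
basin_ddg <- function(potential, temperature = 303.15, n_quad = 161) {
  f <- basin_free_energies(potential, temperature, n_quad)
  d <- outer(f$F, f$F, `-`)
  dimnames(d) <- list(f$name, f$name)
  d
}

# ---------------------------------------------------------------------------
# Bead receptors

serpentine_cells <- function(n, dims) {
  nx <- dims[1]; ny <- dims[2]
  seq2d <- do.call(rbind, lapply(seq_len(ny) - 1L, function(j) {
    i <- if (j %% 2L == 0L) seq_len(nx) - 1L else rev(seq_len(nx) - 1L)
    cbind(i, j)
  }))
  cells <- do.call(rbind, lapply(seq_len(dims[3]) - 1L, function(k) {
    s <- if (k %% 2L == 0L) seq2d else seq2d[rev(seq_len(nrow(seq2d))), , drop = FALSE]
    cbind(s, k)
  }))
  cells[seq_len(n), , drop = FALSE]
}

#' Build a bead-per-residue receptor with a planted communication pathway
#'
#' Residues are single beads folded as a self-avoiding serpentine walk on a
#' cubic lattice (one bead per lattice cell, spacing `spacing` Angstrom), so
#' sequence-consecutive residues sit at contact distance. A planted
#' communication pathway — an ordered, spatially contiguous run of
#' lattice-adjacent residues between a designated "extracellular" origin and
#' "intracellular" terminus — is wired with strong attractive couplings:
#' consecutive pathway residues carry alternating partial charges of magnitude
#' `path_charge`, so their Coulomb attraction dominates the uniform weak
#' Lennard-Jones contacts that connect all lattice neighbours. After the
#' mean-interaction-energy processing this yields pathway couplings near 1 and
#' off-pathway contacts near `1/6` on the normalized scale, i.e. a planted
#' shortest-path backbone the network stage should recover.
#'
#' @param n_residues Number of residues (>= 8).
#' @param path_edges Number of edges of the planted pathway; the default is
#'   the lattice distance between the endpoints (a shortest staircase).
#'   Longer paths are built by parity-preserving detours, which may place
#'   path residues next to each other and create attractive shortcuts.
#' @param path_from,path_to Residue ids of the pathway endpoints; `path_to`
#'   defaults to the residue farthest from `path_from` in lattice steps.
#' @param two_chains Split residues into chains A and B at the midpoint; the
#'   pathway then crosses the chain boundary (checked).
#' @param seed Integer seed controlling the off-pathway charge jitter.
#' @param spacing Lattice constant in Angstrom.
#' @param path_charge Magnitude (e) of the alternating pathway charges.
#' @param hub_charge Magnitude (e) of the opposite charge given to the
#'   non-path neighbours of the two pathway endpoints, which makes the
#'   termini local communication hubs.
#' @param lj_eps,lj_sigma Lennard-Jones well depth (kcal/mol) and sigma
#'   (Angstrom) shared by all beads; the default sigma puts the pair minimum
#'   at the lattice spacing.
#' @param charge_jitter Uniform half-width of off-pathway charges (e).
#' @return Object of class `bead_receptor`: coordinates, residue/parameter
#'   tables, `planted_path` (ordered residue ids), `path_edge_table`,
#'   `reference_allosteric_set`, a suggested `cavity` (centred on the middle
#'   pathway residue) and bookkeeping fields.
#' @examples
#' rec <- make_bead_receptor(27, seed = 7)
#' rec$planted_path
#' @export
make_bead_receptor <- function(n_residues = 48, path_edges = NULL,
                               path_from = 1, path_to = NULL,
                               two_chains = FALSE, seed = 1,
                               spacing = 5, path_charge = 0.275,
                               hub_charge = 0.11,
                               lj_eps = 1.0, lj_sigma = spacing / 2^(1 / 6),
                               charge_jitter = 0.01) {
  n <- as.integer(n_residues)
  if (n < 8) stop2("`n_residues` must be >= 8")
  if (path_from < 1 || path_from > n ||
      (!is.null(path_to) && (path_to < 1 || path_to > n)))
    stop2("planted-path endpoints out of range")
  if (!is.null(path_edges) && path_edges >= n)
    stop2("planted path longer than the chain")
  if (is.null(seed)) stop2("a `seed` is required")
  nx <- ceiling(n^(1 / 3))
  ny <- ceiling(sqrt(n / nx))
  nz <- ceiling(n / (nx * ny))
  cells <- serpentine_cells(n, c(nx, ny, nz))
  coords <- unname(cells * spacing)
  contact <- spacing * 1.05

  # lattice adjacency among occupied cells
  adj <- lapply(seq_len(n), function(i) {
    d <- abs(sweep(cells, 2, cells[i, ]))
    which(rowSums(d) == 1L)
  })

  # default terminus: the residue farthest (in lattice steps) from the
  # origin residue, so the planted path is a shortest staircase and no two
  # non-consecutive path residues touch (shortcuts would dilute recovery)
  bfs_d <- bfs_distances(adj, path_from)
  if (is.null(path_to)) path_to <- which.max(bfs_d)
  if (is.null(path_edges)) path_edges <- bfs_d[path_to]

  path <- staircase_path(cells, adj, path_from, path_to)
  if (is.null(path) || length(path) - 1L != path_edges) {
    path <- plant_path(adj, path_from, path_to, path_edges)
  }

  chain <- rep("A", n)
  if (two_chains) {
    chain[seq_len(n) > n %/% 2] <- "B"
    cross <- chain[path[-length(path)]] != chain[path[-1]]
    if (!any(cross)) {
      stop2("planted path does not cross the chain boundary; ",
            "choose endpoints on opposite chains")
    }
  }

  charges <- with_seed(seed, charge_jitter * (2 * stats::runif(n) - 1))
  charges[path] <- path_charge * (-1)^(seq_along(path) - 1)
  # the pathway endpoints are local communication centers (the analogue of
  # the extracellular-loop and intracellular hubs): their non-path
  # neighbours carry a small opposite charge, so traffic from the terminal
  # regions funnels through the endpoints and the terminal pathway edges
  # carry through-traffic, not only paths ending at the termini
  for (e in c(path[1], path[length(path)])) {
    nbrs <- setdiff(adj[[e]], path)
    # members adjacent to interior path residues would bypass the terminal
    # edge instead of funnelling through the endpoint
    bypass <- vapply(nbrs, function(b)
      any(setdiff(path, e) %in% adj[[b]]), logical(1))
    nbrs <- nbrs[!bypass]
    charges[nbrs] <- charges[nbrs] - sign(charges[e]) * hub_charge
  }

  residues <- data.frame(residue = seq_len(n), chain = chain,
                         label = sprintf("R%03d", seq_len(n)),
                         stringsAsFactors = FALSE)
  params <- data.frame(residue = seq_len(n), chain = chain, atom = "CA",
                       charge = charges, lj_eps = lj_eps, lj_sigma = lj_sigma,
                       stringsAsFactors = FALSE)
  # cavity anchor: the path residue nearest the receptor centroid, so the
  # carved sphere is enclosed by beads on all sides
  ctr <- colMeans(coords)
  mid <- path[which.min(rowSums(sweep(coords[path, , drop = FALSE], 2,
                                      ctr)^2))]
  structure(list(
    residues = residues, coords = coords, params = params,
    atom_residue = seq_len(n),
    planted_path = as.integer(path),
    path_edge_table = cbind(from = path[-length(path)], to = path[-1]),
    reference_allosteric_set = path,
    cavity = list(center = coords[mid, ], radius = 6),
    contact_distance = contact, spacing = spacing,
    net_charge = sum(charges), seed = seed, two_chains = two_chains),
    class = "bead_receptor")
}

# Balanced monotone staircase between two lattice cells: each step moves one
# cell along the axis with the largest remaining deficit (ties -> lowest
# axis), keeping the path in the lattice interior rather than hugging edges.
# Returns NULL if a greedy step leaves the occupied cells.
staircase_path <- function(cells, adj, from, to, max_steps = 1000) {
  path <- from
  cur <- cells[from, ]
  tgt <- cells[to, ]
  cell_index <- function(p) {
    hit <- which(cells[, 1] == p[1] & cells[, 2] == p[2] & cells[, 3] == p[3])
    if (length(hit) == 1) hit else NA_integer_
  }
  for (step in seq_len(max_steps)) {
    deficit <- tgt - cur
    if (all(deficit == 0)) return(path)
    ord <- order(-abs(deficit), seq_along(deficit))
    moved <- FALSE
    for (ax in ord) {
      if (deficit[ax] == 0) next
      nxt <- cur
      nxt[ax] <- nxt[ax] + sign(deficit[ax])
      idx <- cell_index(nxt)
      if (!is.na(idx)) {
        path <- c(path, idx)
        cur <- nxt
        moved <- TRUE
        break
      }
    }
    if (!moved) return(NULL)
  }
  NULL
}

bfs_distances <- function(adj, from) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in sort(adj[[v]])) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L; queue <- c(queue, u)
      }
    }
  }
  dist
}

# Deterministic BFS shortest path over an adjacency list, lengthened by
# parity-preserving two-edge detours until it has `target_edges` edges.
plant_path <- function(adj, from, to, target_edges) {
  n <- length(adj)
  dist <- rep(NA_integer_, n); pred <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in sort(adj[[v]])) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L; pred[u] <- v; queue <- c(queue, u)
      }
    }
  }
  if (is.na(dist[to])) stop2("pathway endpoints are not connected")
  path <- to
  while (path[1] != from) path <- c(pred[path[1]], path)
  base <- length(path) - 1L
  if (target_edges < base) {
    stop2("requested path of ", target_edges, " edges but endpoints are ",
          base, " lattice steps apart")
  }
  if ((target_edges - base) %% 2L != 0L) {
    stop2("a lattice path between these endpoints must have the parity of ",
          base, " edges; ", target_edges, " is unreachable")
  }
  while (length(path) - 1L < target_edges) {
    extended <- FALSE
    for (e in seq_len(length(path) - 1L)) {
      a <- path[e]; b <- path[e + 1]
      # candidates x adjacent to a and y adjacent to b with x adjacent to y
      for (x in sort(setdiff(adj[[a]], path))) {
        y <- intersect(adj[[x]], setdiff(adj[[b]], path))
        y <- setdiff(y, x)
        if (length(y)) {
          path <- append(path, c(x, sort(y)[1]), after = e)
          extended <- TRUE
          break
        }
      }
      if (extended) break
    }
    if (!extended) stop2("cannot extend planted path to ", target_edges,
                         " edges on this lattice")
  }
  path
}

#' @export
print.bead_receptor <- function(x, ...) {
  cat(sprintf("Bead receptor: %d residues (%s), spacing %.1f A\n",
              nrow(x$residues),
              if (x$two_chains) "chains A+B" else "single chain", x$spacing))
  cat("  planted path:", paste(x$planted_path, collapse = " - "), "\n")
  cat(sprintf("  net charge %+.3f e, seed %d\n", x$net_charge, x$seed))
  invisible(x)
}

#' Dense bead shell fixture for cavity-detection checks
#'
#' A ball of beads on a fine cubic grid, dense enough that the only interior
#' empty space is whatever [carve_cavity()] carves out. Used to compare
#' detected cavity volumes against the analytic sphere volume.
#'
#' @param radius Ball radius, Angstrom.
#' @param spacing Bead grid spacing, Angstrom.
#' @param bead_radius Per-bead hard radius, Angstrom.
#' @return list with `coords` (n x 3) and `radii` (length n).
#' @export
make_bead_shell <- function(radius = 8, spacing = 1.6, bead_radius = 1.2) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- sqrt(rowSums(pts^2)) <= radius
  list(coords = pts[keep, , drop = FALSE],
       radii = rep(bead_radius, sum(keep)))
}

#' Carve a spherical cavity into a frame by radial displacement
#'
#' Beads whose hard sphere intrudes into the ball of `radius` around `center`
#' are pushed radially outward to `radius + bead radius`, so the carved ball
#' contains no atom while the atom count is unchanged (the trajectory model
#' requires frame-invariant topology).
#'
#' @param coords n x 3 coordinates (Angstrom).
#' @param radii Per-atom radii.
#' @param center Cavity center (length 3).
#' @param radius Cavity radius, Angstrom.
#' @return Displaced n x 3 coordinate matrix.
#' @export
carve_cavity <- function(coords, radii, center, radius) {
  d <- sweep(coords, 2, center)
  r <- sqrt(rowSums(d^2))
  hit <- which(r < radius + radii)
  for (i in hit) {
    u <- if (r[i] < 1e-9) c(1, 0, 0) else d[i, ] / r[i]
    coords[i, ] <- center + u * (radius + radii[i])
  }
  coords
}

#' Generate a noisy conformational ensemble of a bead receptor
#'
#' Frames are the receptor geometry plus isotropic, atom-uncorrelated
#' Gaussian displacement of standard deviation `noise_sd` per Cartesian
#' component; in a controlled fraction of frames a spherical cavity is carved
#' by [carve_cavity()]. The open/closed schedule is stored alongside the
#' frames so downstream pocket-recovery tests need no re-derivation.
#'
#' @param receptor A [make_bead_receptor()] object.
#' @param n_frames Number of frames (>= 1).
#' @param noise_sd Positional noise, Angstrom (>= 0).
#' @param cavity_fraction Fraction of frames with the cavity open, in [0, 1];
#'   the open count is `round(n_frames * cavity_fraction)` exactly.
#' @param cavity list(center, radius) or NULL for the receptor default.
#' @param seed Integer seed.
#' @return Object of class `synthetic_ensemble` with `coords`
#'   (atoms x 3 x frames array), `open` schedule, `radii`, and provenance.
#' @export
generate_ensemble <- function(receptor, n_frames, noise_sd = 0.1,
                              cavity_fraction = 0, cavity = NULL, seed = 1) {
  if (n_frames < 1) stop2("`n_frames` must be >= 1")
  if (noise_sd < 0) stop2("`noise_sd` must be >= 0")
  if (cavity_fraction < 0 || cavity_fraction > 1)
    stop2("`cavity_fraction` must be in [0, 1]")
  cavity <- cavity %||% receptor$cavity
  ext <- max(dist(receptor$coords))
  if (cavity_fraction > 0 && cavity$radius > ext)
    stop2("cavity radius exceeds the receptor extent")
  n_atoms <- nrow(receptor$coords)
  radii <- receptor$params$lj_sigma / 2
  n_open <- round(n_frames * cavity_fraction)
  with_seed(seed, {
    open <- rep(FALSE, n_frames)
    open[sample.int(n_frames, n_open)] <- TRUE
    coords <- array(0, dim = c(n_atoms, 3, n_frames))
    for (f in seq_len(n_frames)) {
      x <- receptor$coords
      if (noise_sd > 0) {
        x <- x + matrix(stats::rnorm(3 * n_atoms, sd = noise_sd), n_atoms, 3)
      }
      if (open[f]) x <- carve_cavity(x, radii, cavity$center, cavity$radius)
      coords[, , f] <- x
    }
    structure(list(coords = coords, open = open, radii = radii,
                   noise_sd = noise_sd, cavity = cavity, seed = seed,
                   frame_labels = NULL,
                   atom_residue = receptor$atom_residue,
                   params = receptor$params, residues = receptor$residues),
              class = "synthetic_ensemble")
  })
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf("Synthetic ensemble: %d frames x %d atoms, noise %.2f A\n",
              dim(x$coords)[3], dim(x$coords)[1], x$noise_sd))
  cat(sprintf("  cavity open in %d frames (radius %.1f A), seed %d\n",
              sum(x$open), x$cavity$radius, x$seed))
  invisible(x)
}

#' Write the planted ground truth of a synthetic system
#'
#' Saves the planted pathway, cavity schedule and basin table of a synthetic
#' setup as a YAML manifest so recovery tests can read the truth back rather
#' than re-derive it.
#'
#' @param path Output file.
#' @param receptor Optional [make_bead_receptor()] object.
#' @param ensemble Optional [generate_ensemble()] object.
#' @param potential Optional [make_potential()] object.
#' @param temperature Temperature used for the basin reference free energies.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(path, receptor = NULL, ensemble = NULL,
                               potential = NULL, temperature = 303.15) {
  truth <- list()
  if (!is.null(receptor)) {
    truth$planted_path <- as.integer(receptor$planted_path)
    truth$reference_allosteric_set <-
      as.integer(receptor$reference_allosteric_set)
    truth$net_charge <- receptor$net_charge
    truth$cavity <- list(center = as.numeric(receptor$cavity$center),
                         radius = receptor$cavity$radius)
  }
  if (!is.null(ensemble)) {
    truth$cavity_schedule <- as.logical(ensemble$open)
    truth$noise_sd <- ensemble$noise_sd
  }
  if (!is.null(potential)) {
    f <- basin_free_energies(potential, temperature)
    truth$basins <- lapply(seq_len(nrow(f)), function(i) {
      list(name = f$name[i], F_rel = f$F_rel[i])
    })
  }
  yaml::write_yaml(truth, path)
  invisible(path)
}
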