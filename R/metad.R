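# Well-tempered, multiple-walker metadynamics over a 2-D CV space, with
# overdamped Langevin dynamics directly in CV space, free-energy-surface
# reconstruction from the summed bias, convergence monitoring, constant-bias
# reweighting and block-averaged error estimation.

#' Metadynamics run parameters
#'
#' Bundles and validates the well-tempered multiple-walker settings. Defaults
#' follow the classic receptor-activation protocol shape — 0.5 kcal/mol
#' initial hills, bias factor 10, 10 interacting walkers — with hill widths,
#' pace and step counts scaled to the toy CV space (CV1 in Angstrom-like
#' units, CV2 in degrees).
#'
#' @param hill_height Initial Gaussian hill height w0, kcal/mol (> 0).
#' @param hill_widths Hill standard deviations (sigma1, sigma2) in CV units.
#' @param pace Steps between depositions (>= 1).
#' @param bias_factor Well-tempered bias factor gamma (> 1); hill heights
#'   decay as exp(-V_bias / (k_B (gamma - 1) T)).
#' @param temperature Kelvin.
#' @param n_walkers Number of interacting walkers sharing one bias.
#' @param steps_per_walker Langevin steps per walker.
#' @param timestep Integration step (arbitrary toy time unit).
#' @param diffusion Per-CV diffusion constants (CV unit^2 / time); the CV2
#'   default is scaled by the squared extent ratio of the two axes so both
#'   CVs diffuse at comparable relative rates.
#' @param sample_stride Steps between recorded CV samples (default `pace`).
#' @param seed Integer seed.
#' @return A validated `metad_params` list.
#' @export
metad_params <- function(hill_height = 0.5, hill_widths = c(0.2, 6),
                         pace = 100, bias_factor = 10, temperature = 303.15,
                         n_walkers = 10, steps_per_walker = 40000,
                         timestep = 0.005, diffusion = c(1, 1296),
                         sample_stride = pace, seed = 1) {
  if (hill_height <= 0) stop2("`hill_height` must be > 0")
  if (any(hill_widths <= 0)) stop2("`hill_widths` must be > 0")
  if (bias_factor <= 1) stop2("`bias_factor` must be > 1")
  if (pace < 1) stop2("`pace` must be >= 1")
  structure(list(hill_height = hill_height, hill_widths = hill_widths,
                 pace = as.integer(pace), bias_factor = bias_factor,
                 temperature = temperature, n_walkers = as.integer(n_walkers),
                 steps_per_walker = as.integer(steps_per_walker),
                 timestep = timestep, diffusion = diffusion,
                 sample_stride = as.integer(sample_stride),
                 seed = as.integer(seed)), class = "metad_params")
}

wt_hill_height <- function(v_bias, hill_height, bias_factor, temperature) {
  hill_height * exp(-v_bias / (KB * (bias_factor - 1) * temperature))
}

# Mirror-image copies of hills across the walls of aperiodic axes, so that
# the Gaussian mass of a hill deposited near a reflective boundary stays
# inside the domain (the bias seen by a reflected walker). Only hills
# within `nsigma` standard deviations of a wall get an image.
mirror_hills <- function(hills, periodic, domain, nsigma = 5) {
  if (is.null(domain) || is.null(hills) || nrow(hills) == 0) return(hills)
  out <- hills
  for (d in which(!periodic[1:2])) {
    cv <- paste0("cv", d)
    sig <- paste0("sigma", d)
    for (wall in domain[d, ]) {
      sel <- abs(hills[[cv]] - wall) <= nsigma * hills[[sig]]
      if (any(sel)) {
        img <- hills[sel, , drop = FALSE]
        img[[cv]] <- 2 * wall - img[[cv]]
        out <- rbind(out, img)
      }
    }
  }
  out
}

# Exact bias evaluation: sum of Gaussian hills at points (m x 2), with
# minimum-image displacement on periodic axes. Hills: data.frame with
# cv1, cv2, sigma1, sigma2, height.
eval_hills_at <- function(hills, points, periodic) {
  points <- rbind(points)
  if (is.null(hills) || nrow(hills) == 0) return(numeric(nrow(points)))
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    d1 <- points[p, 1] - hills$cv1
    if (periodic[1]) d1 <- wrap_angle(d1)
    d2 <- points[p, 2] - hills$cv2
    if (periodic[2]) d2 <- wrap_angle(d2)
    out[p] <- sum(hills$height *
                    exp(-0.5 * (d1 / hills$sigma1)^2 -
                          0.5 * (d2 / hills$sigma2)^2))
  }
  out
}

# Sum hills on the tensor grid x1 (x) x2; returns n1 x n2 matrix. Exploits
# the separability of each Gaussian into an outer product.
sum_hills_on_grid <- function(hills, x1, x2, periodic, value = NULL) {
  v <- value %||% matrix(0, length(x1), length(x2))
  if (is.null(hills) || nrow(hills) == 0) return(v)
  for (h in seq_len(nrow(hills))) {
    d1 <- x1 - hills$cv1[h]
    if (periodic[1]) d1 <- wrap_angle(d1)
    d2 <- x2 - hills$cv2[h]
    if (periodic[2]) d2 <- wrap_angle(d2)
    g1 <- exp(-0.5 * (d1 / hills$sigma1[h])^2)
    g2 <- exp(-0.5 * (d2 / hills$sigma2[h])^2)
    v <- v + hills$height[h] * outer(g1, g2)
  }
  v
}

#' Bias potential from a hill list
#'
#' @param hills data.frame with columns `time`, `cv1`, `cv2`, `sigma1`,
#'   `sigma2`, `height`, `biasf`, `walker` (globally time-ordered).
#' @param periodic Logical length 2.
#' @param domain Optional 2 x 2 CV domain.
#' @return A `bias_potential` object; evaluate with [bias_value()].
#' @export
bias_potential <- function(hills, periodic = c(FALSE, TRUE), domain = NULL) {
  need <- c("time", "cv1", "cv2", "sigma1", "sigma2", "height")
  if (!all(need %in% names(hills))) {
    stop2("hills need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(hills) == 0) stop2("empty hill list")
  hills <- hills[order(hills$time, hills$walker %||% 0), ]
  structure(list(hills = hills, periodic = periodic, domain = domain),
            class = "bias_potential")
}

#' Evaluate a bias potential at CV points
#'
#' Exact sum over the deposited Gaussian hills (minimum-image on periodic
#' axes), optionally restricted to hills deposited up to `t_max`.
#'
#' @param bias A [bias_potential()].
#' @param points m x 2 matrix (or length-2 vector) of CV points.
#' @param t_max Only hills with `time <= t_max` contribute.
#' @return Numeric vector of bias values, kcal/mol.
#' @export
bias_value <- function(bias, points, t_max = Inf) {
  h <- bias$hills
  if (is.finite(t_max)) h <- h[h$time <= t_max, , drop = FALSE]
  h <- mirror_hills(h, bias$periodic, bias$domain)
  eval_hills_at(h, points, bias$periodic)
}

#' @export
print.bias_potential <- function(x, ...) {
  cat(sprintf("Bias potential: %d hills from %d walker(s), time %g..%g\n",
              nrow(x$hills), length(unique(x$hills$walker %||% 0)),
              min(x$hills$time), max(x$hills$time)))
  invisible(x)
}

# Bilinear interpolation of grid values at points; periodic wrap on axis 2
# when requested, clamped on aperiodic axes.
interp_grid <- function(values, x1, x2, periodic2, p1, p2) {
  n1 <- length(x1); n2 <- length(x2)
  h1 <- x1[2] - x1[1]; h2 <- x2[2] - x2[1]
  f1 <- (p1 - x1[1]) / h1
  i <- pmin(pmax(floor(f1), 0), n1 - 2)
  t1 <- pmin(pmax(f1 - i, 0), 1)
  f2 <- (p2 - x2[1]) / h2
  if (periodic2) {
    j <- floor(f2) %% n2
    t2 <- f2 - floor(f2)
    j2 <- (j + 1) %% n2
  } else {
    j <- pmin(pmax(floor(f2), 0), n2 - 2)
    t2 <- pmin(pmax(f2 - j, 0), 1)
    j2 <- j + 1
  }
  id <- function(ii, jj) ii + jj * n1 + 1
  v00 <- values[id(i, j)]; v10 <- values[id(i + 1, j)]
  v01 <- values[id(i, j2)]; v11 <- values[id(i + 1, j2)]
  (1 - t1) * (1 - t2) * v00 + t1 * (1 - t2) * v10 +
    (1 - t1) * t2 * v01 + t1 * t2 * v11
}

#' Run well-tempered multiple-walker metadynamics on an analytic potential
#'
#' Overdamped Langevin dynamics directly in CV space on
#' `potential + shared bias`. Every `pace` steps each walker (in walker
#' order within the deposition round) deposits a Gaussian hill whose height
#' is the well-tempered rescaling `w0 * exp(-V_b(s) / (k_B (gamma-1) T))` of
#' the initial height, where `V_b` is the exact shared bias — including all
#' hills deposited earlier in the same round — evaluated at the walker's
#' current CV position. Periodic CVs use minimum-image displacements inside
#' every Gaussian; walkers leaving the aperiodic CV1 domain are reflected
#' and counted.
#'
#' @param potential An [make_potential()] object.
#' @param params A [metad_params()] list.
#' @param walker_starts n_walkers x 2 matrix of start points; defaults to the
#'   declared well centers recycled over walkers (a path of starting
#'   conformations spanning the landscape).
#' @param grid_n Internal bias-grid resolution used for the dynamics forces
#'   (hill heights always use the exact bias sum).
#' @return Object of class `wtmetad_run`: `$hills` (globally time-ordered
#'   deposition log), `$samples` (data.frame time, walker, cv1, cv2),
#'   `$bias` (a [bias_potential()]), `$reflections`, and the inputs.
#' @export
run_wtmetad <- function(potential, params = metad_params(),
                        walker_starts = NULL, grid_n = c(121, 121)) {
  stopifnot(inherits(potential, "analytic_potential"))
  nw <- params$n_walkers
  if (is.null(walker_starts)) {
    idx <- rep_len(seq_len(nrow(potential$centers)), nw)
    walker_starts <- potential$centers[idx, , drop = FALSE]
  }
  walker_starts <- as.matrix(walker_starts)
  if (nrow(walker_starts) != nw) {
    stop2("`walker_starts` must supply one row per walker")
  }
  dom <- potential$domain
  per <- potential$periodic
  in_dom <- walker_starts[, 1] >= dom[1, 1] & walker_starts[, 1] <= dom[1, 2]
  if (!all(per[1]) && !all(in_dom)) stop2("walker start outside the domain")

  bt <- kbt(params$temperature)
  dt <- params$timestep
  mob <- params$diffusion / bt          # mobility per CV
  noise_sd <- sqrt(2 * params$diffusion * dt)
  dG <- KB * (params$bias_factor - 1) * params$temperature

  # bias force grid (nodes): aperiodic axis spans the domain inclusively,
  # periodic axis covers [lo, hi) with wraparound
  x1 <- seq(dom[1, 1], dom[1, 2], length.out = grid_n[1])
  if (per[2]) {
    h2 <- (dom[2, 2] - dom[2, 1]) / grid_n[2]
    x2 <- dom[2, 1] + (seq_len(grid_n[2]) - 1) * h2
  } else {
    x2 <- seq(dom[2, 1], dom[2, 2], length.out = grid_n[2])
  }
  Vg <- matrix(0, grid_n[1], grid_n[2])
  G1 <- matrix(0, grid_n[1], grid_n[2])
  G2 <- matrix(0, grid_n[1], grid_n[2])

  n_dep_rounds <- params$steps_per_walker %/% params$pace
  n_hills_max <- n_dep_rounds * nw
  hills <- data.frame(time = numeric(n_hills_max), cv1 = numeric(n_hills_max),
                      cv2 = numeric(n_hills_max),
                      sigma1 = params$hill_widths[1],
                      sigma2 = params$hill_widths[2],
                      height = numeric(n_hills_max),
                      biasf = params$bias_factor,
                      walker = integer(n_hills_max))
  nh <- 0L
  # augmented center/height store including boundary mirror images, used
  # for the exact well-tempered height evaluation (flat vectors for speed)
  aug_c1 <- numeric(3 * n_hills_max)
  aug_c2 <- numeric(3 * n_hills_max)
  aug_h <- numeric(3 * n_hills_max)
  nha <- 0L
  n_samp <- params$steps_per_walker %/% params$sample_stride
  samples <- data.frame(time = numeric(n_samp * nw),
                        walker = integer(n_samp * nw),
                        cv1 = numeric(n_samp * nw),
                        cv2 = numeric(n_samp * nw))
  ns <- 0L
  reflections <- 0L
  s1 <- params$hill_widths[1]; s2 <- params$hill_widths[2]

  with_seed(params$seed, {
    X <- walker_starts
    for (step in seq_len(params$steps_per_walker)) {
      g_pot <- potential$gradient(X)
      f1 <- g_pot[, 1] + interp_grid(G1, x1, x2, per[2], X[, 1], X[, 2])
      f2 <- g_pot[, 2] + interp_grid(G2, x1, x2, per[2], X[, 1], X[, 2])
      X[, 1] <- X[, 1] - mob[1] * f1 * dt +
        stats::rnorm(nw, sd = noise_sd[1])
      X[, 2] <- X[, 2] - mob[2] * f2 * dt +
        stats::rnorm(nw, sd = noise_sd[2])
      for (d in 1:2) {
        if (per[d]) {
          X[, d] <- dom[d, 1] + (X[, d] - dom[d, 1]) %%
            (dom[d, 2] - dom[d, 1])
        } else {
          lo <- X[, d] < dom[d, 1]
          if (any(lo)) {
            reflections <- reflections + sum(lo)
            X[lo, d] <- 2 * dom[d, 1] - X[lo, d]
          }
          hi <- X[, d] > dom[d, 2]
          if (any(hi)) {
            reflections <- reflections + sum(hi)
            X[hi, d] <- 2 * dom[d, 2] - X[hi, d]
          }
          X[, d] <- pmin(pmax(X[, d], dom[d, 1]), dom[d, 2])
        }
      }
      t_now <- step * dt
      if (step %% params$pace == 0L) {
        for (w in seq_len(nw)) {
          vb <- if (nha == 0L) 0 else {
            dd1 <- X[w, 1] - aug_c1[seq_len(nha)]
            if (per[1]) dd1 <- wrap_angle(dd1)
            dd2 <- X[w, 2] - aug_c2[seq_len(nha)]
            if (per[2]) dd2 <- wrap_angle(dd2)
            sum(aug_h[seq_len(nha)] *
                  exp(-0.5 * (dd1 / s1)^2 - 0.5 * (dd2 / s2)^2))
          }
          hh <- wt_hill_height(vb, params$hill_height, params$bias_factor,
                               params$temperature)
          nh <- nh + 1L
          hills$time[nh] <- t_now
          hills$cv1[nh] <- X[w, 1]; hills$cv2[nh] <- X[w, 2]
          hills$height[nh] <- hh
          hills$walker[nh] <- w
          new_aug <- mirror_hills(hills[nh, , drop = FALSE], per, dom)
          rows <- nha + seq_len(nrow(new_aug))
          aug_c1[rows] <- new_aug$cv1
          aug_c2[rows] <- new_aug$cv2
          aug_h[rows] <- new_aug$height
          nha <- nha + nrow(new_aug)
          for (im in seq_len(nrow(new_aug))) {
            d1 <- x1 - new_aug$cv1[im]
            d2 <- if (per[2]) wrap_angle(x2 - new_aug$cv2[im])
                  else x2 - new_aug$cv2[im]
            g1 <- exp(-0.5 * (d1 / s1)^2)
            g2 <- exp(-0.5 * (d2 / s2)^2)
            Vg <- Vg + hh * outer(g1, g2)
            G1 <- G1 + hh * outer(-d1 / s1^2 * g1, g2)
            G2 <- G2 + hh * outer(g1, -d2 / s2^2 * g2)
          }
        }
      }
      if (step %% params$sample_stride == 0L) {
        rows <- ns + seq_len(nw)
        samples$time[rows] <- t_now
        samples$walker[rows] <- seq_len(nw)
        samples$cv1[rows] <- X[, 1]
        samples$cv2[rows] <- X[, 2]
        ns <- ns + nw
      }
    }
  })
  hills <- hills[seq_len(nh), , drop = FALSE]
  samples <- samples[seq_len(ns), , drop = FALSE]
  structure(list(hills = hills, samples = samples,
                 bias = bias_potential(hills, per, dom),
                 params = params, potential_name = potential$name,
                 domain = dom, periodic = per, reflections = reflections),
            class = "wtmetad_run")
}

#' @export
print.wtmetad_run <- function(x, ...) {
  cat(sprintf("WT-MetaD run: %d walkers, %d hills, %d CV samples\n",
              x$params$n_walkers, nrow(x$hills), nrow(x$samples)))
  cat(sprintf("  gamma %.1f, w0 %.2f kcal/mol, final height %.4f, %d reflections\n",
              x$params$bias_factor, x$params$hill_height,
              x$hills$height[nrow(x$hills)], x$reflections))
  invisible(x)
}

#' Unbiased overdamped Langevin sampling on an analytic potential
#'
#' Reference sampler (no bias) used for population landscapes and
#' detailed-balance checks.
#'
#' @inheritParams run_wtmetad
#' @param n_steps Number of steps.
#' @param start Length-2 CV start point.
#' @param sample_stride Steps between recorded samples.
#' @param timestep,diffusion,temperature,seed As in [metad_params()].
#' @return A [cv_series()] of the sampled CV positions.
#' @export
run_langevin <- function(potential, n_steps, start, timestep = 0.005,
                         diffusion = c(1, 1296), temperature = 303.15,
                         sample_stride = 10, seed = 1) {
  dom <- potential$domain; per <- potential$periodic
  mob <- diffusion / kbt(temperature)
  noise_sd <- sqrt(2 * diffusion * timestep)
  n_out <- n_steps %/% sample_stride
  out <- matrix(0, n_out, 2)
  times <- numeric(n_out)
  k <- 0L
  with_seed(seed, {
    x <- as.numeric(start)
    for (step in seq_len(n_steps)) {
      g <- potential$gradient(rbind(x))[1, ]
      x <- x - mob * g * timestep + stats::rnorm(2, sd = noise_sd)
      for (d in 1:2) {
        if (per[d]) {
          x[d] <- dom[d, 1] + (x[d] - dom[d, 1]) %% (dom[d, 2] - dom[d, 1])
        } else {
          if (x[d] < dom[d, 1]) x[d] <- 2 * dom[d, 1] - x[d]
          if (x[d] > dom[d, 2]) x[d] <- 2 * dom[d, 2] - x[d]
        }
      }
      if (step %% sample_stride == 0L) {
        k <- k + 1L
        out[k, ] <- x
        times[k] <- step * timestep
      }
    }
  })
  cv_series(times, out, periodic = per)
}

# --------------------------------------------------------------------------
# Free-energy surfaces

#' Build a rectangular CV-space grid for surface reconstruction
#'
#' @param domain 2 x 2 matrix of per-CV (lo, hi) bounds.
#' @param periodic Logical length 2.
#' @param n Bins per axis.
#' @return list of bin edges and midpoints used by [reconstruct_fes()].
#' @export
make_fes_grid <- function(domain, periodic, n = c(80, 90)) {
  e1 <- seq(domain[1, 1], domain[1, 2], length.out = n[1] + 1)
  e2 <- seq(domain[2, 1], domain[2, 2], length.out = n[2] + 1)
  list(edges1 = e1, edges2 = e2,
       mids1 = (e1[-1] + e1[-length(e1)]) / 2,
       mids2 = (e2[-1] + e2[-length(e2)]) / 2,
       periodic = periodic)
}

#' Reconstruct the free-energy surface from a well-tempered bias
#'
#' In the long-time limit of well-tempered metadynamics the free energy is
#' proportional to the accumulated bias:
#' `F(s) = -(gamma/(gamma-1)) * V_bias(s)`, anchored so the global minimum is
#' zero. `bias_factor = Inf` reduces to the untempered `-V_bias(s)` rule.
#'
#' The instantaneous estimate oscillates around the converged surface as
#' late hills keep being deposited; `average_checkpoints` reduces this noise
#' by averaging the min-anchored estimate over several late time points (the
#' usual time-averaged estimator for a well-tempered run).
#'
#' @param bias A [bias_potential()].
#' @param grid A grid from [make_fes_grid()], or NULL to build one over the
#'   bias domain (or the hill extent plus 3 sigma).
#' @param bias_factor Gamma used in the run.
#' @param temperature Kelvin (stored for downstream basin integration).
#' @param average_checkpoints Optional vector of deposition times; the
#'   surface is the mean of the min-anchored instantaneous estimates at
#'   those times instead of the final-bias estimate.
#' @return Object of class `fes`: `$F` matrix (kcal/mol, min 0), grid
#'   midpoints/edges, `$bias_factor`.
#' @export
reconstruct_fes <- function(bias, grid = NULL, bias_factor,
                            temperature = 303.15,
                            average_checkpoints = NULL) {
  h <- bias$hills
  if (is.null(grid)) {
    dom <- bias$domain
    if (is.null(dom)) {
      dom <- rbind(range(h$cv1) + c(-3, 3) * max(h$sigma1),
                   range(h$cv2) + c(-3, 3) * max(h$sigma2))
    }
    grid <- make_fes_grid(dom, bias$periodic)
  }
  # hills must sit inside the grid; tails beyond a domain wall are handled
  # by the mirror images, so only hill centers are checked
  if (!bias$periodic[1] &&
      (min(h$cv1) < min(grid$edges1) - 1e-9 ||
       max(h$cv1) > max(grid$edges1) + 1e-9)) {
    warning("grid does not cover all hill centers on CV1")
  }
  fac <- if (is.infinite(bias_factor)) 1 else bias_factor / (bias_factor - 1)
  if (is.null(average_checkpoints)) {
    hm <- mirror_hills(h, bias$periodic, bias$domain)
    vb <- sum_hills_on_grid(hm, grid$mids1, grid$mids2, bias$periodic)
    F <- -fac * vb
    F <- F - min(F)
  } else {
    cps <- sort(average_checkpoints)
    vb <- matrix(0, length(grid$mids1), length(grid$mids2))
    F <- 0
    t_prev <- -Inf
    for (cp in cps) {
      sel <- h$time > t_prev & h$time <= cp
      hm <- mirror_hills(h[sel, , drop = FALSE], bias$periodic, bias$domain)
      vb <- sum_hills_on_grid(hm, grid$mids1, grid$mids2, bias$periodic,
                              value = vb)
      t_prev <- cp
      Fi <- -fac * vb
      F <- F + (Fi - min(Fi)) / length(cps)
    }
    F <- F - min(F)
  }
  structure(list(mids1 = grid$mids1, mids2 = grid$mids2,
                 edges1 = grid$edges1, edges2 = grid$edges2,
                 F = F, bias_factor = bias_factor, periodic = bias$periodic,
                 temperature = temperature, error = NULL), class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  if (is.matrix(x$F)) {
    cat(sprintf("Free-energy surface: %d x %d bins, range 0..%.2f kcal/mol\n",
                nrow(x$F), ncol(x$F), max(x$F)))
  } else {
    cat(sprintf("Free-energy profile: %d bins, range 0..%.2f kcal/mol\n",
                length(x$F), max(x$F, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
plot.fes <- function(x, levels = NULL, ...) {
  if (is.matrix(x$F)) {
    graphics::filled.contour(x$mids1, x$mids2, x$F,
                             levels = levels %||% pretty(c(0, max(x$F)), 12),
                             color.palette = function(n)
                               grDevices::hcl.colors(n, "viridis"),
                             xlab = "CV1", ylab = "CV2", ...)
  } else {
    graphics::plot(x$mids1, x$F, type = "l", xlab = "CV1",
                   ylab = "F [kcal/mol]", ...)
  }
  invisible(x)
}

#' Boltzmann-integrated basin free energy on a reconstructed surface
#'
#' `F_basin = -k_B T ln sum_bins exp(-F/k_B T) dA` over the bins whose
#' midpoints fall inside the axis-aligned basin box. Robust to grid noise
#' compared with a single-minimum lookup.
#'
#' @param fes A 2-D [reconstruct_fes()] object.
#' @param basin One row of a basin table (`cv1_lo`, `cv1_hi`, `cv2_lo`,
#'   `cv2_hi`).
#' @param temperature Kelvin.
#' @return Basin free energy, kcal/mol (same anchoring as `fes$F`).
#' @export
fes_basin_free_energy <- function(fes, basin, temperature = fes$temperature) {
  bt <- kbt(temperature)
  in1 <- fes$mids1 >= basin$cv1_lo & fes$mids1 < basin$cv1_hi
  in2 <- fes$mids2 >= basin$cv2_lo & fes$mids2 < basin$cv2_hi
  if (!any(in1) || !any(in2)) stop2("basin has no grid coverage")
  da <- mean(diff(fes$edges1)) * mean(diff(fes$edges2))
  -bt * log(sum(exp(-fes$F[in1, in2] / bt)) * da)
}

#' Pairwise basin free-energy differences on a surface
#'
#' @inheritParams fes_basin_free_energy
#' @param basins Basin table (as in `potential$basins`).
#' @return Named matrix `D[i, j] = F_i - F_j`, kcal/mol.
#' @export
fes_basin_ddg <- function(fes, basins, temperature = fes$temperature) {
  f <- vapply(seq_len(nrow(basins)), function(i)
    fes_basin_free_energy(fes, basins[i, ], temperature), numeric(1))
  d <- outer(f, f, `-`)
  dimnames(d) <- list(basins$name, basins$name)
  d
}

#' Free-energy-difference convergence series
#'
#' At each checkpoint, reconstructs the surface from the hills deposited up
#' to that time and reports the Boltzmann-integrated free-energy difference
#' for every basin pair. A converged run shows the differences flattening in
#' time.
#'
#' @param bias A [bias_potential()].
#' @param basins Basin table with disjoint boxes (>= 2 rows).
#' @param checkpoints Accumulated-time points (defaults to 20 evenly spaced
#'   times over the deposition record).
#' @param bias_factor Gamma of the run.
#' @param temperature Kelvin.
#' @param grid Optional [make_fes_grid()].
#' @param estimator `"tail_mean"` (default): at each checkpoint t the
#'   reported difference is the mean of the instantaneous estimates over
#'   (t/2, t], which damps the late-time deposition oscillation of the
#'   instantaneous well-tempered estimate; or `"instantaneous"`.
#' @return Object of class `convergence_series`: data.frame `checkpoint`,
#'   `pair`, `ddg` (kcal/mol, chosen estimator), `ddg_inst` (instantaneous).
#' @export
delta_g_timeseries <- function(bias, basins, checkpoints = NULL, bias_factor,
                               temperature = 303.15, grid = NULL,
                               estimator = c("tail_mean", "instantaneous")) {
  estimator <- match.arg(estimator)
  if (nrow(basins) < 2) stop2("need at least two basins")
  h <- bias$hills
  if (is.null(checkpoints)) {
    checkpoints <- seq(min(h$time), max(h$time), length.out = 40)
  }
  if (is.null(grid)) {
    dom <- bias$domain %||% rbind(range(h$cv1) + c(-3, 3) * max(h$sigma1),
                                  range(h$cv2) + c(-3, 3) * max(h$sigma2))
    grid <- make_fes_grid(dom, bias$periodic)
  }
  fac <- if (is.infinite(bias_factor)) 1 else bias_factor / (bias_factor - 1)
  checkpoints <- sort(checkpoints)
  vb <- matrix(0, length(grid$mids1), length(grid$mids2))
  t_prev <- -Inf
  pairs <- utils::combn(basins$name, 2)
  out <- vector("list", length(checkpoints))
  for (ci in seq_along(checkpoints)) {
    sel <- h$time > t_prev & h$time <= checkpoints[ci]
    hm <- mirror_hills(h[sel, , drop = FALSE], bias$periodic, bias$domain)
    vb <- sum_hills_on_grid(hm, grid$mids1, grid$mids2,
                            bias$periodic, value = vb)
    t_prev <- checkpoints[ci]
    F <- -fac * vb
    F <- F - min(F)
    fes_cp <- structure(list(mids1 = grid$mids1, mids2 = grid$mids2,
                             edges1 = grid$edges1, edges2 = grid$edges2,
                             F = F, temperature = temperature), class = "fes")
    fb <- vapply(seq_len(nrow(basins)), function(i)
      fes_basin_free_energy(fes_cp, basins[i, ], temperature), numeric(1))
    names(fb) <- basins$name
    out[[ci]] <- data.frame(checkpoint = checkpoints[ci],
                            pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                            ddg_inst = fb[pairs[1, ]] - fb[pairs[2, ]],
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (estimator == "tail_mean") {
    res$ddg <- NA_real_
    for (p in unique(res$pair)) {
      sel <- res$pair == p
      cp <- res$checkpoint[sel]
      v <- res$ddg_inst[sel]
      res$ddg[sel] <- vapply(seq_along(cp), function(i)
        mean(v[cp > cp[i] / 2 & cp <= cp[i]]), numeric(1))
    }
  } else {
    res$ddg <- res$ddg_inst
  }
  structure(res[, c("checkpoint", "pair", "ddg", "ddg_inst")],
            class = c("convergence_series", "data.frame"))
}

#' @export
plot.convergence_series <- function(x, ...) {
  pairs <- unique(x$pair)
  cps <- unique(x$checkpoint)
  m <- sapply(pairs, function(p) x$ddg[x$pair == p])
  graphics::matplot(cps, m, type = "l", lty = 1, xlab = "accumulated time",
                    ylab = expression(Delta * Delta * G ~ "[kcal/mol]"), ...)
  graphics::legend("topright", legend = pairs, lty = 1,
                   col = seq_along(pairs), bty = "n")
  invisible(x)
}

#' Flattening drift of a convergence series
#'
#' Max minus min of each pair's free-energy difference over the last
#' `fraction` of the checkpoints; small drift indicates a flattened, i.e.
#' converged, series.
#'
#' @param series A [delta_g_timeseries()] result.
#' @param fraction Trailing fraction of checkpoints to examine.
#' @return Named vector of drifts per basin pair, kcal/mol.
#' @export
convergence_drift <- function(series, fraction = 0.25) {
  cps <- sort(unique(series$checkpoint))
  keep <- cps[cps >= cps[length(cps)] - fraction *
                (cps[length(cps)] - cps[1])]
  vapply(split(series, series$pair), function(d) {
    v <- d$ddg[d$checkpoint %in% keep]
    max(v) - min(v)
  }, numeric(1))
}

# --------------------------------------------------------------------------
# Reweighting and block errors

#' Constant-bias reweighting weights
#'
#' Per-sample weights `w_t` proportional to `exp(+V_b(s_t) / k_B T)` using
#' the bias at the end of the run, assumed constant over the whole
#' trajectory (the standard final-bias reweighting approximation).
#'
#' @param samples data.frame with `cv1`, `cv2` (e.g. `run$samples`) or an
#'   n x 2 matrix.
#' @param bias A [bias_potential()].
#' @param temperature Kelvin.
#' @return Numeric weights (max-normalised; only ratios matter).
#' @export
constant_bias_weights <- function(samples, bias, temperature = 303.15) {
  pts <- if (is.data.frame(samples)) cbind(samples$cv1, samples$cv2)
         else as.matrix(samples)
  vb <- bias_value(bias, pts)
  exp((vb - max(vb)) / kbt(temperature))
}

#' Reweighted free-energy profile of an observable
#'
#' Builds the weighted histogram of a per-frame observable under
#' [constant_bias_weights()] (or caller-supplied weights) and converts it to
#' `-k_B T ln(P_w / max P_w)`, anchored at zero. With zero bias everywhere
#' this reduces to the unweighted population landscape.
#'
#' @param samples As in [constant_bias_weights()]; defines the bias weights.
#' @param bias A [bias_potential()], or NULL if `weights` are given.
#' @param observable Per-sample observable: a vector (1-D result) or an
#'   n x 2 matrix (2-D result). Defaults to the samples' `cv1`.
#' @param edges1 Bin edges for the observable (first axis).
#' @param edges2 Bin edges for the second axis of a 2-D observable.
#' @param temperature Kelvin.
#' @param weights Optional explicit weights (overrides `bias`).
#' @return Object of class `fes` (1-D profile or 2-D surface) with the
#'   weights, observable and sample count attached for block-error analysis.
#' @export
reweight_constant_bias <- function(samples, bias = NULL, observable = NULL,
                                   edges1, edges2 = NULL,
                                   temperature = 303.15, weights = NULL) {
  if (is.null(weights)) {
    if (is.null(bias)) stop2("either `bias` or `weights` is required")
    weights <- constant_bias_weights(samples, bias, temperature)
  }
  if (is.null(observable)) {
    observable <- if (is.data.frame(samples)) samples$cv1 else samples[, 1]
  }
  if (sum(weights) <= 0) stop2("total weight is zero")
  bt <- kbt(temperature)
  if (is.matrix(observable) && ncol(observable) == 2) {
    if (is.null(edges2)) stop2("`edges2` required for a 2-D observable")
    i1 <- bin_index(observable[, 1], edges1)
    i2 <- bin_index(observable[, 2], edges2)
    ok <- !is.na(i1) & !is.na(i2)
    p <- matrix(0, length(edges1) - 1, length(edges2) - 1)
    for (s in which(ok)) p[i1[s], i2[s]] <- p[i1[s], i2[s]] + weights[s]
    p <- p / sum(p)
    F <- -bt * log(p / max(p))
    F[p == 0] <- NA_real_
    res <- structure(list(mids1 = (edges1[-1] + edges1[-length(edges1)]) / 2,
                          mids2 = (edges2[-1] + edges2[-length(edges2)]) / 2,
                          edges1 = edges1, edges2 = edges2, F = F,
                          temperature = temperature), class = "fes")
  } else {
    i1 <- bin_index(as.numeric(observable), edges1)
    ok <- !is.na(i1)
    p <- vapply(seq_len(length(edges1) - 1), function(b)
      sum(weights[ok][i1[ok] == b]), numeric(1))
    p <- p / sum(p)
    F <- -bt * log(p / max(p))
    F[p == 0] <- NA_real_
    res <- structure(list(mids1 = (edges1[-1] + edges1[-length(edges1)]) / 2,
                          edges1 = edges1, F = F,
                          temperature = temperature), class = "fes")
  }
  res$weights <- weights
  res$observable <- observable
  res
}

#' Marginalise a 2-D free-energy surface onto one axis
#'
#' `F_1(s1) = -k_B T ln sum_j exp(-F(s1, s2_j)/k_B T) ds2`, min-anchored.
#'
#' @param fes A 2-D `fes`.
#' @param axis Axis kept (1 or 2).
#' @param temperature Kelvin.
#' @return A 1-D `fes` profile.
#' @export
marginalize_fes <- function(fes, axis = 1, temperature = fes$temperature) {
  bt <- kbt(temperature)
  w <- exp(-fes$F / bt)
  d <- if (axis == 1) mean(diff(fes$edges2)) else mean(diff(fes$edges1))
  prof <- if (axis == 1) rowSums(w, na.rm = TRUE) else colSums(w, na.rm = TRUE)
  F <- -bt * log(prof * d)
  F <- F - min(F)
  structure(list(mids1 = if (axis == 1) fes$mids1 else fes$mids2,
                 edges1 = if (axis == 1) fes$edges1 else fes$edges2,
                 F = F, temperature = temperature), class = "fes")
}

#' Per-bin residuals between two free-energy profiles
#'
#' Free energies are defined only up to an additive constant; min-anchoring
#' ties that constant to the (noisy) minimum bin of each profile. For
#' comparing two estimates bin by bin, the arbitrary relative offset is
#' first removed by an inverse-variance weighted fit, and the residuals
#' `a - b - c*` are returned.
#'
#' @param a,b Free-energy vectors on the same bins (NA allowed).
#' @param errors Optional per-bin standard errors used as weights (and for
#'   excluding flagged bins).
#' @return list: `residual` per bin, `offset` removed, `ok` logical of bins
#'   compared.
#' @export
profile_residuals <- function(a, b, errors = NULL) {
  ok <- !is.na(a) & !is.na(b)
  if (!is.null(errors)) ok <- ok & !is.na(errors) & errors > 0
  w <- if (is.null(errors)) rep(1, sum(ok)) else 1 / errors[ok]^2
  offset <- sum(w * (a[ok] - b[ok])) / sum(w)
  res <- rep(NA_real_, length(a))
  res[ok] <- a[ok] - b[ok] - offset
  list(residual = res, offset = offset, ok = ok)
}

block_ids <- function(n, block_length = NULL, n_blocks = NULL) {
  if (is.null(block_length)) {
    if (is.null(n_blocks)) stop2("give `block_length` or `n_blocks`")
    block_length <- ceiling(n / n_blocks)
  }
  ((seq_len(n) - 1L) %/% as.integer(block_length)) + 1L
}

#' Block-averaged error of a (re)weighted free-energy histogram
#'
#' Splits the sample stream into contiguous blocks, computes each block's
#' weighted, normalised histogram and its free energies
#' `-k_B T ln p`, and reports the per-bin standard error across blocks
#' (`sd / sqrt(n_blocks)`). Bins with zero weight in any block are flagged
#' `NA` rather than given an error.
#'
#' @param observable Per-sample observable values (vector).
#' @param weights Per-sample weights (unit weights if NULL).
#' @param edges Histogram bin edges.
#' @param block_length Samples per contiguous block; or give `n_blocks`.
#' @param n_blocks Number of blocks.
#' @param temperature Kelvin.
#' @return list: `error` per bin (kcal/mol, NA where flagged), `n_blocks`,
#'   `block_length`.
#' @export
block_error <- function(observable, weights = NULL, edges,
                        block_length = NULL, n_blocks = NULL,
                        temperature = 303.15) {
  n <- length(observable)
  weights <- weights %||% rep(1, n)
  ids <- block_ids(n, block_length, n_blocks)
  B <- max(ids)
  if (B < 2) stop2("need at least two blocks")
  bt <- kbt(temperature)
  nb <- length(edges) - 1
  Fb <- matrix(NA_real_, B, nb)
  for (b in seq_len(B)) {
    sel <- ids == b
    o <- observable[sel]; w <- weights[sel]
    i <- bin_index(o, edges)
    ok <- !is.na(i)
    p <- vapply(seq_len(nb), function(k) sum(w[ok][i[ok] == k]), numeric(1))
    p <- p / sum(p)
    Fb[b, ] <- ifelse(p > 0, -bt * log(p), NA_real_)
  }
  err <- apply(Fb, 2, function(col) {
    if (anyNA(col)) NA_real_ else stats::sd(col) / sqrt(B)
  })
  list(error = err, n_blocks = B,
       block_length = block_length %||% ceiling(n / n_blocks))
}

#' Block-averaged error of basin free-energy differences
#'
#' Per contiguous block, the reweighted 2-D histogram gives each basin a
#' Boltzmann-integrated free energy; the standard error of each pair
#' difference across blocks is returned.
#'
#' @param samples data.frame with `cv1`, `cv2` (time-ordered).
#' @param weights Constant-bias weights (unit if NULL).
#' @param basins Basin table.
#' @param edges1,edges2 Histogram edges over the CV space.
#' @inheritParams block_error
#' @return Named vector of standard errors per basin pair ("a-b"),
#'   kcal/mol; NA for pairs unpopulated in some block.
#' @export
ddg_block_error <- function(samples, weights = NULL, basins, edges1, edges2,
                            block_length = NULL, n_blocks = 10,
                            temperature = 303.15) {
  n <- nrow(samples)
  weights <- weights %||% rep(1, n)
  ids <- block_ids(n, block_length, n_blocks)
  B <- max(ids)
  bt <- kbt(temperature)
  m1 <- (edges1[-1] + edges1[-length(edges1)]) / 2
  m2 <- (edges2[-1] + edges2[-length(edges2)]) / 2
  basin_bins <- lapply(seq_len(nrow(basins)), function(i) {
    list(i1 = which(m1 >= basins$cv1_lo[i] & m1 < basins$cv1_hi[i]),
         i2 = which(m2 >= basins$cv2_lo[i] & m2 < basins$cv2_hi[i]))
  })
  fb <- matrix(NA_real_, B, nrow(basins))
  for (b in seq_len(B)) {
    sel <- ids == b
    i1 <- bin_index(samples$cv1[sel], edges1)
    i2 <- bin_index(samples$cv2[sel], edges2)
    w <- weights[sel]
    ok <- !is.na(i1) & !is.na(i2)
    p <- matrix(0, length(m1), length(m2))
    for (s in which(ok)) p[i1[s], i2[s]] <- p[i1[s], i2[s]] + w[s]
    p <- p / sum(p)
    for (k in seq_len(nrow(basins))) {
      z <- sum(p[basin_bins[[k]]$i1, basin_bins[[k]]$i2])
      fb[b, k] <- if (z > 0) -bt * log(z) else NA_real_
    }
  }
  pairs <- utils::combn(seq_len(nrow(basins)), 2)
  err <- apply(pairs, 2, function(pr) {
    d <- fb[, pr[1]] - fb[, pr[2]]
    if (anyNA(d)) NA_real_ else stats::sd(d) / sqrt(B)
  })
  names(err) <- apply(pairs, 2, function(pr)
    paste(basins$name[pr[1]], basins$name[pr[2]], sep = "-"))
  err
}
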