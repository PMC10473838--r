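# Well-tempered multiple-walker engine: deposition bookkeeping, hill
# scaling, surface reconstruction, convergence, reweighting and block
# errors.

KB <- 0.0019872041

test_that("deposition count is walkers x floor(steps / pace)", {
  pot <- make_potential("double_well_1d_harmonic")
  run <- run_wtmetad(pot, metad_params(steps_per_walker = 2500, pace = 250,
                                       n_walkers = 10, seed = 1))
  expect_identical(nrow(run$hills), 10L * (2500L %/% 250L))
  expect_identical(sort(unique(run$hills$walker)), 1:10)
})

test_that("first hill has the full height; a repeat hill decays by the well-tempered factor", {
  pot <- make_potential("double_well_1d_harmonic")
  # a single frozen walker at the well bottom deposits twice at one point
  p <- metad_params(hill_height = 0.5, bias_factor = 10,
                    temperature = 303.15, pace = 1, steps_per_walker = 2,
                    n_walkers = 1, diffusion = c(1e-20, 1e-20), seed = 1)
  run <- run_wtmetad(pot, p, walker_starts = rbind(c(3, 0)))
  expect_identical(nrow(run$hills), 2L)
  expect_identical(run$hills$height[1], 0.5)
  expect_equal(run$hills$height[2],
               0.5 * exp(-0.5 / (KB * 9 * 303.15)), tolerance = 1e-12)
  # cross-check the scaling against the stored bias at the deposition point
  vb <- bias_value(bias_potential(run$hills[1, ], pot$periodic, pot$domain),
                   c(3, 0))
  expect_equal(run$hills$height[2], 0.5 * exp(-vb / (KB * 9 * 303.15)),
               tolerance = 1e-12)
})

test_that("bias evaluation equals an explicit sum over hills and wall images", {
  pot <- make_potential("symmetric_double_well_2d")
  run <- run_wtmetad(pot, metad_params(steps_per_walker = 2000, pace = 100,
                                       seed = 2))
  b <- run$bias
  set.seed(3)
  pts <- cbind(runif(20, 0, 10), runif(20, -180, 180))
  manual <- sapply(seq_len(nrow(pts)), function(i) {
    tot <- 0
    for (k in seq_len(nrow(b$hills))) {
      h <- b$hills[k, ]
      centers1 <- c(h$cv1, -h$cv1, 20 - h$cv1)  # real + wall images
      for (c1 in centers1) {
        d1 <- pts[i, 1] - c1
        d2 <- pts[i, 2] - h$cv2
        d2 <- d2 - 360 * round(d2 / 360)
        tot <- tot + h$height * exp(-0.5 * (d1 / h$sigma1)^2 -
                                      0.5 * (d2 / h$sigma2)^2)
      }
    }
    tot
  })
  expect_lt(max(abs(bias_value(b, pts) - manual)), 1e-10)
})

test_that("single hill at infinite bias factor reconstructs an inverted Gaussian", {
  hills <- data.frame(time = 1, cv1 = 5, cv2 = 0, sigma1 = 0.3, sigma2 = 8,
                      height = 0.4, biasf = Inf, walker = 1)
  b <- bias_potential(hills, periodic = c(FALSE, TRUE),
                      domain = rbind(c(0, 10), c(-180, 180)))
  fes <- reconstruct_fes(b, bias_factor = Inf)
  expect_equal(min(fes$F), 0)
  imin <- which(fes$F == 0, arr.ind = TRUE)  # grid symmetry may tie bins
  expect_true(any(abs(fes$mids1[imin[, 1]] - 5) < 0.1 &
                    abs(fes$mids2[imin[, 2]] - 0) < 3))
  # the far plateau sits one (grid-discretised) hill height above the dip
  expect_equal(max(fes$F), 0.4, tolerance = 0.06)
  expect_error(bias_potential(hills[0, ]), "empty")
})

test_that("a dense hill lattice yields a flat anchored surface in the interior", {
  centers <- expand.grid(cv1 = seq(0.25, 9.75, by = 0.5),
                         cv2 = seq(-180, 175, by = 10))
  hills <- data.frame(time = seq_len(nrow(centers)), cv1 = centers$cv1,
                      cv2 = centers$cv2, sigma1 = 1, sigma2 = 15,
                      height = 1, biasf = 10, walker = 1)
  b <- bias_potential(hills, periodic = c(FALSE, TRUE),
                      domain = rbind(c(0, 10), c(-180, 180)))
  set.seed(4)
  pts <- cbind(runif(200, 2, 8), runif(200, -180, 180))
  v <- bias_value(b, pts)
  expect_lt((max(v) - min(v)) / mean(v), 0.02)
})

test_that("seed reproducibility and per-walker hill-file merging are exact", {
  pot <- make_potential("symmetric_double_well_2d")
  p <- metad_params(steps_per_walker = 1500, pace = 100, seed = 4)
  run <- run_wtmetad(pot, p)
  expect_identical(run_wtmetad(pot, p)$hills, run$hills)

  files <- vapply(1:10, function(w) {
    f <- tempfile()
    write_hills(run$hills, f, walker = w)
    f
  }, character(1))
  merged <- do.call(rbind, lapply(files, read_hills))
  merged <- merged[order(merged$time, merged$walker), ]
  rownames(merged) <- NULL
  whole <- read_hills(write_hills(run$hills, tempfile()))
  expect_equal(merged, whole, tolerance = 1e-12)
  # identical surfaces from merged and shared logs
  f1 <- reconstruct_fes(bias_potential(merged, pot$periodic, pot$domain),
                        bias_factor = 10)
  f2 <- reconstruct_fes(bias_potential(whole, pot$periodic, pot$domain),
                        bias_factor = 10)
  expect_identical(f1$F, f2$F)
})

test_that("walkers leaving the aperiodic domain are reflected and counted", {
  pot <- make_potential("double_well_1d_harmonic")
  p <- metad_params(steps_per_walker = 2000, pace = 2000,
                    diffusion = c(80, 80), seed = 5)
  run <- run_wtmetad(pot, p, walker_starts = matrix(c(rep(0.2, 10),
                                                      rep(0, 10)), 10))
  expect_gt(run$reflections, 0)
  expect_true(all(run$samples$cv1 >= 0 & run$samples$cv1 <= 10))
})

test_that("unbiased Langevin sampling reproduces Boltzmann statistics", {
  pot <- make_potential("double_well_1d_harmonic")
  s <- run_langevin(pot, n_steps = 60000, start = c(3, 0),
                    sample_stride = 10, seed = 6)
  # harmonic CV2: sd = sqrt(kT / k)
  sd2_th <- sqrt(KB * 303.15 / pot$k_harm)
  expect_lt(abs(sd(s$values[, 2]) - sd2_th), 0.1 * sd2_th)
  # CV1 within the starting well: sd from direct quadrature
  x <- seq(1.5, 4.5, length.out = 2001)
  u <- pot$energy(cbind(x, 0))
  w <- exp(-u / (KB * 303.15)); w <- w / sum(w)
  mu <- sum(w * x)
  sd1_th <- sqrt(sum(w * (x - mu)^2))
  in_well <- s$values[, 1] > 1.5 & s$values[, 1] < 4.5
  expect_lt(abs(sd(s$values[in_well, 1]) - sd1_th), 0.15 * sd1_th)
})

test_that("free-energy differences start at zero bias and flatten on a symmetric landscape", {
  pot <- make_potential("symmetric_double_well_2d")
  run <- run_wtmetad(pot, metad_params(steps_per_walker = 20000, pace = 100,
                                       seed = 7))
  # a checkpoint before any hill reports the flat-surface estimate: zero
  # difference for equal-size basins
  conv <- delta_g_timeseries(run$bias, pot$basins,
                             checkpoints = c(1e-6, max(run$hills$time)),
                             bias_factor = 10)
  expect_equal(conv$ddg_inst[conv$checkpoint == 1e-6], 0, tolerance = 1e-9)
  expect_error(delta_g_timeseries(run$bias, pot$basins[1, , drop = FALSE],
                                  bias_factor = 10), "two basins")
  # basin with no grid coverage
  bad <- pot$basins
  bad$cv1_lo[1] <- 90; bad$cv1_hi[1] <- 91
  expect_error(delta_g_timeseries(run$bias, bad, bias_factor = 10,
                                  grid = make_fes_grid(pot$domain,
                                                       pot$periodic)),
               "coverage")
})

test_that("reconstruction error decreases with run length and ends below 0.5 kcal/mol", {
  pot <- make_potential("double_well_1d_harmonic")
  lens <- c(5000, 15000, 40000)
  rmse <- matrix(0, 5, 3)
  for (s in 1:5) for (li in seq_along(lens)) {
    run <- run_wtmetad(pot, metad_params(steps_per_walker = lens[li],
                                         seed = s))
    tm <- max(run$hills$time)
    fes <- reconstruct_fes(run$bias, bias_factor = 10,
                           average_checkpoints = seq(tm / 2, tm,
                                                     length.out = 5))
    U <- matrix(pot$energy(as.matrix(expand.grid(fes$mids1, fes$mids2))),
                length(fes$mids1))
    U <- U - min(U)
    sel <- U < 5
    rmse[s, li] <- sqrt(mean((fes$F[sel] - U[sel])^2))
  }
  avg <- colMeans(rmse)
  expect_true(all(diff(avg) < 0))
  expect_lt(avg[3], 0.5)
})

test_that("constant-bias reweighting reduces to the population landscape at zero bias", {
  set.seed(8)
  samples <- data.frame(cv1 = runif(500, 0, 10),
                        cv2 = runif(500, -180, 180))
  zero_hills <- data.frame(time = 1, cv1 = 5, cv2 = 0, sigma1 = 0.2,
                           sigma2 = 6, height = 0, biasf = 10, walker = 1)
  b0 <- bias_potential(zero_hills, c(FALSE, TRUE),
                       rbind(c(0, 10), c(-180, 180)))
  edges <- seq(0, 10, by = 1)
  rw <- reweight_constant_bias(samples, b0, edges1 = edges)
  pl <- population_landscape(cbind(samples$cv1, samples$cv2),
                             edges1 = edges, edges2 = c(-180, 180))
  expect_equal(rw$F, as.numeric(pl$neg_log), tolerance = 1e-9)
  # doubling all weights changes nothing (normalisation invariance)
  w <- constant_bias_weights(samples, b0)
  r1 <- reweight_constant_bias(samples, weights = w, edges1 = edges)
  r2 <- reweight_constant_bias(samples, weights = 2 * w, edges1 = edges)
  expect_identical(r1$F, r2$F)
  expect_error(reweight_constant_bias(samples, weights = rep(0, 500),
                                      edges1 = edges), "weight")
})

test_that("block errors match hand-computed identities", {
  edges <- c(0, 1, 2)
  # identical blocks: zero error everywhere
  obs <- rep(c(rep(0.5, 3), rep(1.5, 7)), 4)
  be <- block_error(obs, edges = edges, block_length = 10)
  expect_identical(be$n_blocks, 4L)
  expect_equal(be$error, c(0, 0))
  # two blocks with bin probabilities p and p(1+eps): the error is the
  # two-sample standard error of -kT ln p
  obs2 <- c(rep(0.5, 30), rep(1.5, 70), rep(0.5, 36), rep(1.5, 64))
  be2 <- block_error(obs2, edges = edges, block_length = 100,
                     temperature = 303.15)
  kbt <- KB * 303.15
  expect_equal(be2$error[1], abs(kbt * log(0.36 / 0.30)) / 2,
               tolerance = 1e-12)
  # 250 samples in blocks of 25: exactly 10 blocks
  expect_identical(block_error(runif(250), edges = c(0, 0.5, 1),
                               block_length = 25)$n_blocks, 10L)
  # a bin empty in one block is flagged, not given an error
  obs3 <- c(rep(0.5, 10), rep(c(0.5, 1.5), 5))
  be3 <- block_error(obs3, edges = edges, block_length = 10)
  expect_true(is.na(be3$error[2]))
  expect_error(block_error(1:5, edges = edges, block_length = 10),
               "two blocks")
})

test_that("HILLS logs round-trip exactly and idempotently", {
  pot <- make_potential("symmetric_double_well_2d")
  run <- run_wtmetad(pot, metad_params(steps_per_walker = 1000, pace = 20,
                                       seed = 9))
  expect_identical(nrow(run$hills), 500L)
  f1 <- tempfile(); f2 <- tempfile()
  write_hills(run$hills, f1)
  h <- read_hills(f1)
  expect_equal(h$height, run$hills$height, tolerance = 1e-12)
  expect_equal(h$cv1, run$hills$cv1, tolerance = 1e-12)
  write_hills(h, f2)
  expect_identical(readLines(f1), readLines(f2))
})
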