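# Grid-based pocket detection: probe + burial voxel criterion, frequency
# maps, iso-value extraction, lining residues and network overlap.

test_that("voxels inside atoms or in open bulk are never pocket voxels", {
  sh <- make_bead_shell(radius = 6, spacing = 1.6, bead_radius = 1.2)
  grid <- pocket_grid(sh$coords, spacing = 1.0, margin = 5)
  fl <- frame_pocket_voxels(sh$coords, sh$radii, grid, probe = 1.4,
                            burial_radius = 8, burial_min = 40)
  # the uncarved dense ball has no pocket anywhere: not inside atoms, not
  # in the bulk outside
  expect_identical(sum(fl), 0L)
  expect_error(frame_pocket_voxels(sh$coords, sh$radii,
                                   list(origin = c(0, 0, 0),
                                        spacing = 1, dims = c(3L, 3L, 3L))),
               "grid too small")
})

test_that("a carved cavity is recovered with the analytic sphere volume", {
  sh <- make_bead_shell(radius = 8, spacing = 1.6, bead_radius = 1.2)
  cc <- carve_cavity(sh$coords, sh$radii, c(0, 0, 0), 4)
  grid <- pocket_grid(cc, spacing = 1.0, margin = 4)
  fl <- frame_pocket_voxels(cc, sh$radii, grid, probe = 1.4,
                            burial_radius = 8, burial_min = 40)
  oracle <- 4 / 3 * pi * (4 - 1.4)^3
  expect_lt(abs(sum(fl) - oracle) / oracle, 0.25)
  # flagged voxels sit inside the carved ball
  idx <- which(fl, arr.ind = TRUE)
  centers <- sweep((idx - 1) * grid$spacing, 2, grid$origin, `+`)
  expect_true(all(sqrt(rowSums(centers^2)) <= 4))
})

test_that("frequency maps average frame flags exactly", {
  rec <- make_bead_receptor(seed = 1)
  ens <- generate_ensemble(rec, 20, noise_sd = 0.1, cavity_fraction = 0.4,
                           seed = 1)
  fmap <- frequency_map(ens, burial_radius = 10, burial_min = 6)
  g <- fmap$grid
  ci <- round((rec$cavity$center - g$origin) / g$spacing) + 1
  expect_equal(fmap$phi[ci[1], ci[2], ci[3]], 0.4)

  # permanent cavity: phi = 1; never open: phi = 0 at the core
  e1 <- generate_ensemble(rec, 10, 0.1, cavity_fraction = 1, seed = 2)
  f1 <- frequency_map(e1, burial_radius = 10, burial_min = 6)
  expect_equal(f1$phi[ci[1], ci[2], ci[3]], 1)
  e0 <- generate_ensemble(rec, 10, 0.1, cavity_fraction = 0, seed = 3)
  f0 <- frequency_map(e0, burial_radius = 10, burial_min = 6,
                      grid = fmap$grid)
  expect_equal(f0$phi[ci[1], ci[2], ci[3]], 0)

  # conservation: sum of phi equals the mean per-frame flagged count
  counts <- vapply(seq_len(20), function(f)
    sum(frame_pocket_voxels(ens$coords[, , f], ens$radii, fmap$grid,
                            burial_radius = 10, burial_min = 6)),
    numeric(1))
  expect_equal(sum(fmap$phi), mean(counts), tolerance = 1e-12)
})

test_that("voxel flags are covariant under translations and axis-aligned rotation", {
  rec <- make_bead_receptor(seed = 4)
  ens <- generate_ensemble(rec, 3, 0.1, cavity_fraction = 1, seed = 4)
  grid <- pocket_grid(ens$coords, spacing = 1.0, margin = 5)
  f0 <- frame_pocket_voxels(ens$coords[, , 1], ens$radii, grid,
                            burial_radius = 10, burial_min = 6)
  shift <- c(3.5, -2, 7)
  g2 <- grid; g2$origin <- grid$origin + shift
  f2 <- frame_pocket_voxels(sweep(ens$coords[, , 1], 2, -shift), ens$radii,
                            g2, burial_radius = 10, burial_min = 6)
  expect_identical(f0, f2)
  # 90-degree rotation about z together with the grid
  co <- ens$coords[, , 1]
  rot <- cbind(-co[, 2], co[, 1], co[, 3])
  g3 <- list(origin = c(-(grid$origin[2] + (grid$dims[2] - 1) *
                            grid$spacing), grid$origin[1], grid$origin[3]),
             spacing = grid$spacing,
             dims = grid$dims[c(2, 1, 3)])
  f3 <- frame_pocket_voxels(rot, ens$radii, g3, burial_radius = 10,
                            burial_min = 6)
  # the rotated flag array equals the original with axes swapped/reversed
  expect_identical(sum(f3), sum(f0))
  expect_identical(f3[, , 3], t(f0[, , 3])[rev(seq_len(dim(f0)[2])), ])
})

test_that("iso-value extraction finds the planted pockets and respects ordering", {
  rec <- make_bead_receptor(seed = 1)
  ens <- generate_ensemble(rec, 20, 0.1, cavity_fraction = 1, seed = 5)
  fmap <- frequency_map(ens, burial_radius = 10, burial_min = 6)
  pk <- extract_pockets(fmap, iso = 0.2)
  expect_identical(length(pk), 1L)
  expect_lt(sqrt(sum((colMeans(pk$pockets[[1]]$centers) -
                        rec$cavity$center)^2)), 2)
  # iso above the maximum phi: no pockets
  toy <- structure(list(phi = array(0.3, c(4, 4, 4)),
                        grid = list(origin = c(0, 0, 0), spacing = 1,
                                    dims = c(4L, 4L, 4L)),
                        probe = 1.4, burial_radius = 8, burial_min = 40,
                        n_frames = 10), class = "frequency_map")
  expect_identical(length(extract_pockets(toy, iso = 0.5)), 0L)
  expect_error(extract_pockets(fmap, iso = 0), "iso")

  # two separated cavities in a dense shell: two pockets, larger first
  sh <- make_bead_shell(radius = 10, spacing = 1.6, bead_radius = 1.2)
  cc <- carve_cavity(sh$coords, sh$radii, c(-4.5, 0, 0), 4)
  cc <- carve_cavity(cc, sh$radii, c(5, 0, 0), 3)
  grid <- pocket_grid(cc, spacing = 1.0, margin = 4)
  fl <- frame_pocket_voxels(cc, sh$radii, grid, burial_radius = 8,
                            burial_min = 40)
  fm2 <- structure(list(phi = fl * 1, grid = grid, probe = 1.4,
                        burial_radius = 8, burial_min = 40, n_frames = 1),
                   class = "frequency_map")
  pk2 <- extract_pockets(fm2, iso = 0.2)
  expect_identical(length(pk2), 2L)
  expect_gt(pk2$pockets[[1]]$volume, pk2$pockets[[2]]$volume)
})

test_that("pockets at a higher iso-value nest inside pockets at a lower one", {
  rec <- make_bead_receptor(seed = 6)
  ens <- generate_ensemble(rec, 20, 0.15, cavity_fraction = 0.5, seed = 6)
  fmap <- frequency_map(ens, burial_radius = 10, burial_min = 6)
  lo <- extract_pockets(fmap, iso = 0.2, min_voxels = 1)
  hi <- extract_pockets(fmap, iso = 0.4, min_voxels = 1)
  key <- function(vox) paste(vox[, 1], vox[, 2], vox[, 3])
  lo_keys <- lapply(lo$pockets, function(p) key(p$voxels))
  for (p in hi$pockets) {
    contained <- vapply(lo_keys, function(k) all(key(p$voxels) %in% k),
                       logical(1))
    expect_true(any(contained))
  }
})

test_that("halving the grid spacing changes the cavity volume estimate by < 15%", {
  rec <- make_bead_receptor(seed = 7)
  ens <- generate_ensemble(rec, 8, 0.05, cavity_fraction = 1, seed = 7)
  v <- vapply(c(1.0, 0.5), function(sp) {
    fmap <- frequency_map(ens, burial_radius = 10, burial_min = 6,
                          spacing = sp)
    pk <- extract_pockets(fmap, iso = 0.5)
    pk$pockets[[1]]$volume
  }, numeric(1))
  expect_lt(abs(v[2] - v[1]) / v[1], 0.15)
})

test_that("lining residues grow monotonically with contact distance and respect chains", {
  rec <- make_bead_receptor(seed = 1)
  ens <- generate_ensemble(rec, 10, 0.1, cavity_fraction = 1, seed = 8)
  fmap <- frequency_map(ens, burial_radius = 10, burial_min = 6)
  pk <- extract_pockets(fmap, iso = 0.2)
  prev <- integer(0)
  for (contact in c(3, 4.5, 6, 8)) {
    lin <- lining_residues(pk$pockets[[1]], rec$coords, rec$atom_residue,
                           contact = contact)
    expect_true(all(prev %in% lin))
    prev <- lin
  }
  # a far-away chain contributes no lining residues
  far <- rbind(rec$coords, rec$coords + 100)
  far_res <- c(rec$atom_residue, rec$atom_residue + 100)
  lin <- lining_residues(pk$pockets[[1]], far, far_res, contact = 6)
  expect_true(all(lin <= 48))
})

test_that("pocket-network overlap reports deterministic per-pocket rows", {
  rec <- make_bead_receptor(seed = 2)
  ens <- generate_ensemble(rec, 20, 0.1, cavity_fraction = 1, seed = 9)
  fmap <- frequency_map(ens, burial_radius = 10, burial_min = 6)
  pk <- extract_pockets(fmap, iso = 0.2)
  spm <- build_spm(process_iem(mean_iem(ens)))
  ov <- pocket_pen_overlap(pk, spm, rec$coords, rec$atom_residue)
  expect_identical(nrow(ov), length(pk))
  expect_true(all(ov$n_pen <= ov$n_lining))
  # duplicated pocket input gives identical rows
  pk2 <- pk
  pk2$pockets <- c(pk$pockets, pk$pockets)
  ov2 <- pocket_pen_overlap(pk2, spm, rec$coords, rec$atom_residue)
  expect_equal(ov2[1, -1], ov2[2, -1], ignore_attr = TRUE)
  # disjoint residue namespace: zero overlap
  spm_far <- spm
  spm_far$nodes$residue <- spm$nodes$residue + 1000
  ov3 <- pocket_pen_overlap(pk, spm_far, rec$coords, rec$atom_residue)
  expect_true(all(ov3$n_pen == 0))
})

test_that("Kabsch alignment undoes a rigid motion exactly", {
  set.seed(10)
  ref <- matrix(rnorm(60, sd = 4), 20, 3)
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  moved <- ref %*% t(R) + matrix(c(5, -3, 2), 20, 3, byrow = TRUE)
  expect_equal(kabsch_align(moved, ref), ref, tolerance = 1e-9)
  arr <- array(c(ref, moved), dim = c(20, 3, 2))
  aligned <- align_ensemble(arr)
  expect_equal(aligned[, , 2], ref, tolerance = 1e-9)
})
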