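# Grid-based transient-pocket detection: per-frame pocket voxels via a
# probe + burial criterion, ensemble frequency maps, iso-value pocket
# extraction with 26-connectivity, lining residues and pocket-network
# overlap.

#' Define a cubic detection grid around a structure
#'
#' @param coords n x 3 coordinates (or an ensemble; the union extent over
#'   frames is used).
#' @param spacing Voxel edge, Angstrom.
#' @param margin Padding beyond the atom extent, Angstrom; must be at least
#'   probe + burial radius for the burial criterion to see all neighbours.
#' @return list(origin, spacing, dims) describing voxel centers at
#'   `origin + (index - 1) * spacing`.
#' @export
pocket_grid <- function(coords, spacing = 1.0, margin = 4) {
  frames <- as_frame_list(coords)
  lo <- Reduce(pmin, lapply(frames, function(f) apply(f, 2, min)))
  hi <- Reduce(pmax, lapply(frames, function(f) apply(f, 2, max)))
  origin <- lo - margin
  dims <- pmax(2L, as.integer(ceiling((hi + margin - origin) / spacing)) + 1L)
  list(origin = origin, spacing = spacing, dims = dims)
}

voxel_centers <- function(grid) {
  ax <- lapply(1:3, function(d)
    grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$spacing)
  as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
}

#' Pocket voxels of a single frame
#'
#' A voxel is a pocket voxel iff (a) its center lies farther than
#' `atom radius + probe` from every atom center (the probe fits), and
#' (b) it is buried: at least `burial_min` atom centers lie within
#' `burial_radius`, and every one of the six axis-aligned 45-degree cones
#' around the voxel contains an atom center within `burial_radius`
#' (directional enclosure). Bulk voxels — even dense-surface-adjacent ones
#' with many neighbours — have at least one open cone and fail (b); voxels
#' inside atoms fail (a).
#'
#' @param coords n x 3 atom coordinates.
#' @param radii Per-atom radii, Angstrom.
#' @param grid A [pocket_grid()].
#' @param probe Probe radius, Angstrom (default 1.4, water-sized).
#' @param burial_radius Neighbourhood radius for the burial test (default 8).
#' @param burial_min Minimum atom neighbours for a buried voxel (default 40,
#'   tuned on the dense shell fixture; lower it for sparse bead systems).
#' @return Logical array of `grid$dims`.
#' @export
frame_pocket_voxels <- function(coords, radii, grid, probe = 1.4,
                                burial_radius = 8, burial_min = 40) {
  if (any(apply(coords, 2, min) < grid$origin) ||
      any(apply(coords, 2, max) >
            grid$origin + (grid$dims - 1) * grid$spacing)) {
    stop2("grid too small: atoms outside the voxel volume")
  }
  vc <- voxel_centers(grid)
  m <- nrow(vc)
  flag <- logical(m)
  chunk <- max(1L, floor(1e6 / nrow(coords)))
  at2 <- rowSums(coords^2)
  r2 <- burial_radius^2
  for (s in seq(1, m, by = chunk)) {
    rows <- s:min(s + chunk - 1, m)
    v <- vc[rows, , drop = FALSE]
    # squared distances voxel x atom
    d2 <- outer(rowSums(v^2), at2, `+`) - 2 * v %*% t(coords)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    free <- rowSums(sweep(d, 2, radii + probe, `<=`)) == 0
    near <- d2 <= r2
    buried <- rowSums(near) >= burial_min
    enclosed <- rep(TRUE, length(rows))
    for (ax in 1:3) {
      dxv <- outer(v[, ax], coords[, ax], `-`)  # voxel - atom, chunk x n
      cone <- (dxv^2 >= d2 / 2) & near          # 45-degree axis cone
      enclosed <- enclosed &
        rowSums(cone & (dxv < 0)) > 0 &   # an atom above the voxel
        rowSums(cone & (dxv > 0)) > 0     # and one below
    }
    flag[rows] <- free & buried & enclosed
  }
  array(flag, dim = grid$dims)
}

#' Normalised pocket-frequency map over an ensemble
#'
#' Per-voxel fraction of frames in which the voxel is a pocket voxel;
#' equally weighted frames, so a permanent cavity scores 1 and a transient
#' one its open fraction.
#'
#' @param ensemble A `synthetic_ensemble`, atoms x 3 x frames array, or list
#'   of frames.
#' @param radii Per-atom radii (taken from the ensemble when attached).
#' @param grid A [pocket_grid()]; built over all frames when NULL.
#' @inheritParams frame_pocket_voxels
#' @param spacing,margin Grid construction parameters when `grid` is NULL.
#' @return Object of class `frequency_map`: `$phi` array in [0, 1],
#'   `$grid`, detector parameters, `$n_frames`.
#' @export
frequency_map <- function(ensemble, radii = NULL, grid = NULL, probe = 1.4,
                          burial_radius = 8, burial_min = 40, spacing = 1.0,
                          margin = NULL) {
  if (is.null(radii) && inherits(ensemble, "synthetic_ensemble")) {
    radii <- ensemble$radii
  }
  frames <- as_frame_list(ensemble)
  if (!length(frames)) stop2("at least one frame is required")
  if (is.null(radii)) stop2("`radii` is required")
  if (is.null(grid)) {
    grid <- pocket_grid(frames, spacing,
                        margin %||% (probe + max(radii) + 1))
  }
  acc <- array(0, dim = grid$dims)
  for (fr in frames) {
    acc <- acc + frame_pocket_voxels(fr, radii, grid, probe,
                                     burial_radius, burial_min)
  }
  structure(list(phi = acc / length(frames), grid = grid, probe = probe,
                 burial_radius = burial_radius, burial_min = burial_min,
                 n_frames = length(frames)), class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("Pocket frequency map: %d x %d x %d voxels (%.2f A), %d frames\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$spacing, x$n_frames))
  cat(sprintf("  max phi %.2f; voxels with phi > 0: %d\n", max(x$phi),
              sum(x$phi > 0)))
  invisible(x)
}

#' @export
plot.frequency_map <- function(x, ...) {
  proj <- apply(x$phi, c(1, 2), max)
  graphics::image(seq_len(dim(proj)[1]), seq_len(dim(proj)[2]), proj,
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  xlab = "x voxel", ylab = "y voxel",
                  main = "max-projection of phi", ...)
  invisible(x)
}

# 26-connectivity offsets
conn26 <- local({
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

#' Extract pockets from a frequency map at an iso-value
#'
#' Thresholds the map at `phi >= iso`, labels connected components under
#' 26-connectivity, discards components below `min_voxels`, and returns
#' pockets ordered by descending volume.
#'
#' @param fmap A [frequency_map()].
#' @param iso Iso-value in (0, 1] (default 0.2, the conventional threshold
#'   for displaying transient pockets).
#' @param min_voxels Minimum component size.
#' @return Object of class `pocket_set`: list of pockets, each with
#'   `$voxels` (k x 3 indices), `$centers` (k x 3 coordinates), `$volume`
#'   (voxel count x spacing^3, A^3), `$phi` values and `$mean_phi`.
#' @export
extract_pockets <- function(fmap, iso = 0.2, min_voxels = 5) {
  if (iso <= 0 || iso > 1) stop2("`iso` must be in (0, 1]")
  dims <- fmap$grid$dims
  flagged <- which(fmap$phi >= iso)
  labels <- integer(length(fmap$phi))
  comp <- list()
  for (seed_vox in flagged) {
    if (labels[seed_vox] != 0L) next
    id <- length(comp) + 1L
    queue <- seed_vox
    labels[seed_vox] <- id
    members <- integer(0)
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, v)
      iv <- arrayInd(v, dims)
      nb <- sweep(conn26, 2, as.integer(iv), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nbl <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
        (nb[ok, 3] - 1) * dims[1] * dims[2]
      nbl <- nbl[fmap$phi[nbl] >= iso & labels[nbl] == 0L]
      labels[nbl] <- id
      queue <- c(queue, nbl)
    }
    comp[[id]] <- members
  }
  comp <- Filter(function(m) length(m) >= min_voxels, comp)
  pockets <- lapply(comp, function(m) {
    vox <- arrayInd(m, dims)
    centers <- sweep(sweep(vox - 1, 2, rep(fmap$grid$spacing, 3), `*`),
                     2, fmap$grid$origin, `+`)
    list(voxels = vox, centers = centers,
         volume = nrow(vox) * fmap$grid$spacing^3,
         phi = fmap$phi[m], mean_phi = mean(fmap$phi[m]))
  })
  pockets <- pockets[order(-vapply(pockets, `[[`, numeric(1), "volume"))]
  for (i in seq_along(pockets)) pockets[[i]]$id <- i
  structure(list(pockets = pockets, iso = iso, grid = fmap$grid,
                 min_voxels = min_voxels), class = "pocket_set")
}

#' @export
print.pocket_set <- function(x, ...) {
  cat(sprintf("Pockets at iso %.2f: %d found\n", x$iso, length(x$pockets)))
  for (p in x$pockets) {
    cat(sprintf("  pocket %d: %d voxels, %.0f A^3, mean phi %.2f\n",
                p$id, nrow(p$voxels), p$volume, p$mean_phi))
  }
  invisible(x)
}

#' @export
length.pocket_set <- function(x) length(x$pockets)

#' Residues lining a pocket
#'
#' Residues with any atom within `contact` Angstrom of any member voxel
#' center.
#'
#' @param pocket One element of a [extract_pockets()] set.
#' @param coords n x 3 atom coordinates (reference frame).
#' @param atom_residue Residue id per atom.
#' @param contact Contact distance, Angstrom (default probe + 2).
#' @param probe Probe radius used for the default contact.
#' @return Sorted residue id vector.
#' @export
lining_residues <- function(pocket, coords, atom_residue,
                            contact = probe + 2.0, probe = 1.4) {
  if (!nrow(pocket$voxels)) stop2("empty pocket")
  near <- logical(nrow(coords))
  for (k in seq_len(nrow(pocket$centers))) {
    d2 <- rowSums(sweep(coords, 2, pocket$centers[k, ])^2)
    near <- near | d2 <= contact^2
  }
  sort(unique(atom_residue[near]))
}

#' Overlap between pockets and a protein energy network
#'
#' For each pocket: the lining residues that are network nodes, their count,
#' and the summed node usage of those residues (an energy-coupling score for
#' the pocket).
#'
#' @param pockets A [extract_pockets()] set.
#' @param spm A [build_spm()] object.
#' @param coords,atom_residue Reference structure for lining assignment.
#' @inheritParams lining_residues
#' @return data.frame: pocket, volume, n_lining, n_pen, usage_score,
#'   pen_residues (comma string).
#' @export
pocket_pen_overlap <- function(pockets, spm, coords, atom_residue,
                               contact = 3.4) {
  rows <- lapply(pockets$pockets, function(p) {
    lin <- lining_residues(p, coords, atom_residue, contact = contact)
    pen <- intersect(lin, spm$nodes$residue)
    usage <- sum(spm$nodes$usage[match(pen, spm$nodes$residue)])
    data.frame(pocket = p$id, volume = p$volume, n_lining = length(lin),
               n_pen = length(pen), usage_score = usage,
               pen_residues = paste(pen, collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(pocket = integer(0), volume = numeric(0),
                      n_lining = integer(0), n_pen = integer(0),
                      usage_score = numeric(0), pen_residues = character(0)))
  }
  do.call(rbind, rows)
}

#' Kabsch superposition of one frame onto a reference
#'
#' Least-squares rigid alignment (rotation + translation) of `frame` onto
#' `ref` over the selected atoms; returns the transformed full frame.
#'
#' @param frame,ref n x 3 coordinate matrices.
#' @param sel Atom indices used for the fit (default all).
#' @return Aligned n x 3 matrix.
#' @export
kabsch_align <- function(frame, ref, sel = seq_len(nrow(ref))) {
  P <- frame[sel, , drop = FALSE]
  Q <- ref[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(frame, 2, cp) %*% t(R), 2, cq, `+`)
}

#' Rigidly align all frames of an ensemble onto the first frame
#'
#' @param ensemble atoms x 3 x frames array or list of frames.
#' @param sel Atom indices for the fit.
#' @return Array of aligned frames (atoms x 3 x frames).
#' @export
align_ensemble <- function(ensemble, sel = NULL) {
  frames <- as_frame_list(ensemble)
  ref <- frames[[1]]
  sel <- sel %||% seq_len(nrow(ref))
  out <- array(0, dim = c(nrow(ref), 3, length(frames)))
  out[, , 1] <- ref
  for (f in seq_along(frames)[-1]) {
    out[, , f] <- kabsch_align(frames[[f]], ref, sel)
  }
  out
}
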