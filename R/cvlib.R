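# Collective variables on coordinate frames: a torsion-like dihedral CV, a
# center-of-mass distance CV, plain pair distances, and population
# landscapes over a 2-D CV grid.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four atoms
#'
#' Torsion of atoms `idx[1]-idx[2]-idx[3]-idx[4]` using the right-handed
#' atan2 convention (cis = 0, trans = 180; a right-handed rotation of the
#' distal bond about the central-bond axis increases the angle). The value is
#' wrapped to (-180, 180] degrees.
#'
#' @param frame n x 3 coordinate matrix, Angstrom.
#' @param idx Four distinct atom indices.
#' @return Angle in degrees in (-180, 180].
#' @examples
#' trans <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
#' cv_dihedral(trans, 1:4)  # 180
#' @export
cv_dihedral <- function(frame, idx) {
  if (length(idx) != 4 || anyDuplicated(idx)) stop2("need 4 distinct atoms")
  p <- frame[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  if (any(c(sum(b1^2), sum(b2^2), sum(b3^2)) < 1e-16))
    stop2("coincident consecutive atoms: dihedral undefined")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop2("collinear atom triplet: dihedral plane undefined")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Distance between the (mass-weighted) centroids of two atom groups
#'
#' @param frame n x 3 coordinate matrix, Angstrom.
#' @param groupA,groupB Atom index vectors (nonempty; need not be disjoint).
#' @param massesA,massesB Optional positive masses; when omitted the
#'   unweighted centroid is used.
#' @return Euclidean COM distance in Angstrom.
#' @examples
#' fr <- rbind(c(0, 0, 0), c(3, 4, 0))
#' cv_com_distance(fr, 1, 2)  # 5
#' @export
cv_com_distance <- function(frame, groupA, groupB,
                            massesA = NULL, massesB = NULL) {
  com <- function(idx, m) {
    if (!length(idx)) stop2("empty atom group")
    x <- frame[idx, , drop = FALSE]
    if (is.null(m)) return(colMeans(x))
    if (any(m <= 0)) stop2("masses must be positive")
    colSums(x * m) / sum(m)
  }
  a <- com(groupA, massesA)
  b <- com(groupB, massesB)
  sqrt(sum((a - b)^2))
}

#' Distance between two atoms
#' @inheritParams cv_com_distance
#' @param i,j Atom indices.
#' @return Distance in Angstrom.
#' @export
cv_pair_distance <- function(frame, i, j) {
  sqrt(sum((frame[i, ] - frame[j, ])^2))
}

#' Define a collective variable
#'
#' @param kind One of `"dihedral"`, `"com_distance"`, `"pair_distance"`.
#' @param ... Selector arguments passed to the corresponding `cv_*` function:
#'   `idx` for dihedrals, `groupA`/`groupB` (and optional masses) for COM
#'   distances, `i`/`j` for pair distances.
#' @param name Label used in COLVAR tables.
#' @return A `cv_definition` object.
#' @export
cv_definition <- function(kind = c("dihedral", "com_distance",
                                   "pair_distance"), ..., name = kind) {
  kind <- match.arg(kind)
  sel <- list(...)
  ok <- switch(kind,
    dihedral = length(sel$idx) == 4,
    com_distance = length(sel$groupA) >= 1 && length(sel$groupB) >= 1,
    pair_distance = length(sel$i) == 1 && length(sel$j) == 1)
  if (!isTRUE(ok)) stop2("incomplete selectors for kind '", kind, "'")
  structure(list(kind = kind, selectors = sel, name = name,
                 periodic = kind == "dihedral"), class = "cv_definition")
}

eval_cv_one <- function(def, frame) {
  s <- def$selectors
  switch(def$kind,
    dihedral = cv_dihedral(frame, s$idx),
    com_distance = cv_com_distance(frame, s$groupA, s$groupB,
                                   s$massesA, s$massesB),
    pair_distance = cv_pair_distance(frame, s$i, s$j))
}

#' Construct a CV time series
#'
#' @param times Sample times (any monotone unit).
#' @param values n x k matrix of CV values, one column per CV.
#' @param periodic Logical length k; periodic columns are wrapped to
#'   (-180, 180].
#' @param names Column labels.
#' @return A `cv_series` object.
#' @export
cv_series <- function(times, values, periodic = NULL, names = NULL) {
  values <- as.matrix(values)
  if (length(times) != nrow(values)) stop2("times/values length mismatch")
  k <- ncol(values)
  periodic <- periodic %||% rep(FALSE, k)
  for (j in which(periodic)) values[, j] <- wrap_angle(values[, j])
  colnames(values) <- names %||% colnames(values) %||% paste0("cv", seq_len(k))
  structure(list(times = as.numeric(times), values = values,
                 periodic = periodic), class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("CV series: %d samples x %d CVs (%s)\n", nrow(x$values),
              ncol(x$values), paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' Evaluate collective variables over an ensemble
#'
#' Applies each CV definition to every frame, preserving frame order.
#'
#' @param ensemble A `synthetic_ensemble`, an atoms x 3 x frames array, or a
#'   list of n x 3 frames.
#' @param defs List of [cv_definition()] objects.
#' @param times Optional sample times (default frame index).
#' @return A [cv_series()].
#' @export
evaluate_cvs <- function(ensemble, defs, times = NULL) {
  frames <- as_frame_list(ensemble)
  if (inherits(defs, "cv_definition")) defs <- list(defs)
  vals <- vapply(frames, function(fr) {
    vapply(defs, eval_cv_one, numeric(1), frame = fr)
  }, numeric(length(defs)))
  vals <- if (length(defs) == 1) cbind(as.numeric(vals)) else t(vals)
  cv_series(times %||% seq_along(frames), vals,
            periodic = vapply(defs, `[[`, logical(1), "periodic"),
            names = vapply(defs, `[[`, character(1), "name"))
}

as_frame_list <- function(ensemble) {
  if (inherits(ensemble, "synthetic_ensemble")) ensemble <- ensemble$coords
  if (is.array(ensemble) && length(dim(ensemble)) == 3) {
    lapply(seq_len(dim(ensemble)[3]), function(f) ensemble[, , f])
  } else if (is.list(ensemble)) {
    ensemble
  } else if (is.matrix(ensemble)) {
    list(ensemble)
  } else stop2("cannot interpret ensemble frames")
}

# Half-open binning [lo, hi); the last bin is closed so the data maximum
# still falls inside the grid.
bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  i[x < edges[1] | x > edges[length(edges)]] <- NA_integer_
  i
}

#' Population landscape over a 2-D CV grid
#'
#' Histograms a CV series on a rectangular grid and converts bin populations
#' to a free-energy-like score, \eqn{-k_B T \ln(P/P_{max})}, anchored so the
#' most populated bin is 0. Empty bins are masked (NA), never imputed.
#'
#' @param series A [cv_series()] with at least 2 CVs, or an n x 2 matrix.
#' @param edges1,edges2 Bin edge vectors covering the data range.
#' @param temperature Kelvin.
#' @return A `population_landscape`: counts matrix, masked `neg_log` matrix
#'   (kcal/mol), bin edges and midpoints.
#' @export
population_landscape <- function(series, edges1, edges2,
                                 temperature = 303.15) {
  v <- if (inherits(series, "cv_series")) series$values else as.matrix(series)
  if (nrow(v) < 1) stop2("at least one sample is required")
  i1 <- bin_index(v[, 1], edges1)
  i2 <- bin_index(v[, 2], edges2)
  ok <- !is.na(i1) & !is.na(i2)
  if (!any(ok)) stop2("all samples fall outside the grid")
  n1 <- length(edges1) - 1L; n2 <- length(edges2) - 1L
  counts <- matrix(0L, n1, n2)
  tab <- table(factor(i1[ok], levels = seq_len(n1)),
               factor(i2[ok], levels = seq_len(n2)))
  counts[] <- as.integer(tab)
  p <- counts / sum(counts)
  neg_log <- -kbt(temperature) * log(p / max(p))
  neg_log[counts == 0L] <- NA_real_
  structure(list(edges1 = edges1, edges2 = edges2,
                 mids1 = (edges1[-1] + edges1[-length(edges1)]) / 2,
                 mids2 = (edges2[-1] + edges2[-length(edges2)]) / 2,
                 counts = counts, neg_log = neg_log,
                 temperature = temperature, n = sum(counts)),
            class = "population_landscape")
}

#' @export
print.population_landscape <- function(x, ...) {
  cat(sprintf("Population landscape: %d x %d bins, %d samples, T = %.2f K\n",
              nrow(x$counts), ncol(x$counts), x$n, x$temperature))
  cat(sprintf("  occupied bins: %d, max -kT ln(P/Pmax) = %.3f kcal/mol\n",
              sum(x$counts > 0), max(x$neg_log, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.population_landscape <- function(x, ...) {
  z <- x$neg_log
  graphics::image(x$mids1, x$mids2, z, col = grDevices::hcl.colors(64),
                  xlab = "CV1", ylab = "CV2",
                  main = "-kT ln(P / Pmax) [kcal/mol]", ...)
  invisible(x)
}
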