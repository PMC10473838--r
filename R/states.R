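# Conformational-state assignment: named axis-aligned regions in CV space
# (half-open boxes, optionally unions of boxes per state), frame labelling
# and per-state subsampling.

#' Declare named state regions in CV space
#'
#' Regions are axis-aligned half-open boxes `[lo, hi)` in (CV1, CV2); a
#' state may own several rows (a union of boxes). Boxes belonging to
#' different states must be pairwise disjoint — overlap is rejected at
#' construction, not at assignment time.
#'
#' @param regions data.frame with columns `state`, `cv1_lo`, `cv1_hi`,
#'   `cv2_lo`, `cv2_hi`; or a named list of `c(cv1_lo, cv1_hi, cv2_lo,
#'   cv2_hi)` vectors.
#' @return Validated `state_regions` data.frame.
#' @export
state_regions <- function(regions) {
  if (!is.data.frame(regions)) {
    regions <- do.call(rbind, lapply(names(regions), function(nm) {
      v <- regions[[nm]]
      data.frame(state = nm, cv1_lo = v[1], cv1_hi = v[2],
                 cv2_lo = v[3], cv2_hi = v[4], stringsAsFactors = FALSE)
    }))
  }
  need <- c("state", "cv1_lo", "cv1_hi", "cv2_lo", "cv2_hi")
  if (!all(need %in% names(regions))) {
    stop2("regions need columns: ", paste(need, collapse = ", "))
  }
  if (any(regions$cv1_lo >= regions$cv1_hi) ||
      any(regions$cv2_lo >= regions$cv2_hi)) {
    stop2("degenerate region: lo must be < hi on both CVs")
  }
  n <- nrow(regions)
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (regions$state[a] == regions$state[b]) next
      if (regions$cv1_lo[a] < regions$cv1_hi[b] &&
          regions$cv1_lo[b] < regions$cv1_hi[a] &&
          regions$cv2_lo[a] < regions$cv2_hi[b] &&
          regions$cv2_lo[b] < regions$cv2_hi[a]) {
        stop2("regions of states '", regions$state[a], "' and '",
              regions$state[b], "' overlap")
      }
    }
  }
  structure(regions, class = c("state_regions", "data.frame"))
}

#' Assign frames to conformational states by CV-space region
#'
#' Point-in-box assignment under the half-open `[lo, hi)` convention, so a
#' frame on a shared boundary of adjacent boxes belongs to exactly one
#' state. Frames outside every region are labelled `"unassigned"`.
#'
#' @param series A [cv_series()] (first two CVs used) or n x 2 matrix.
#' @param regions A [state_regions()] table.
#' @return Object of class `state_partition`: `$labels` (character per
#'   frame), `$counts`, `$regions`.
#' @export
assign_states <- function(series, regions) {
  regions <- state_regions(regions)
  v <- if (inherits(series, "cv_series")) series$values else as.matrix(series)
  labels <- rep("unassigned", nrow(v))
  for (r in seq_len(nrow(regions))) {
    hit <- v[, 1] >= regions$cv1_lo[r] & v[, 1] < regions$cv1_hi[r] &
           v[, 2] >= regions$cv2_lo[r] & v[, 2] < regions$cv2_hi[r]
    labels[hit] <- regions$state[r]
  }
  counts <- table(factor(labels, levels = c(unique(regions$state),
                                            "unassigned")))
  structure(list(labels = labels, counts = counts, regions = regions,
                 n_frames = nrow(v)), class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("State partition: %d frames\n", x$n_frames))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-14s %6d (%.1f%%)\n", nm, x$counts[[nm]],
                100 * x$counts[[nm]] / x$n_frames))
  }
  invisible(x)
}

#' Per-state frame indices with stride subsampling
#'
#' Order-preserving subsampling of each state's frames: every `stride`-th
#' frame (so `m` frames yield `ceiling(m / stride)`), or a fraction.
#'
#' @param partition A [assign_states()] object.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @param fraction Alternative to `stride`: keep about this fraction
#'   (stride = round(1/fraction)).
#' @param include_unassigned Also return the unassigned frames.
#' @return Named list of integer frame-index vectors, one per state. States
#'   left empty after subsampling are returned empty with a warning.
#' @export
subsample_states <- function(partition, stride = 1, fraction = NULL,
                             include_unassigned = FALSE) {
  if (!is.null(fraction)) stride <- max(1L, round(1 / fraction))
  if (stride < 1) stop2("`stride` must be >= 1")
  states <- unique(partition$regions$state)
  if (include_unassigned) states <- c(states, "unassigned")
  out <- lapply(states, function(s) {
    idx <- which(partition$labels == s)
    if (!length(idx)) {
      warning("state '", s, "' is empty after subsampling")
      return(integer(0))
    }
    idx[seq(1, length(idx), by = stride)]
  })
  names(out) <- states
  out
}
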