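# Text file formats: COLVAR / HILLS whitespace tables with `#! FIELDS`
# headers, XYZ and multi-model PDB trajectories, parameter tables, dense /
# long interaction-energy matrices, gridded free-energy surfaces, voxel
# grids (native + OpenDX dialect) and the YAML run configuration. All
# writers format deterministically, so write -> read -> write is
# byte-identical.

fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 17))

# Parse numeric tokens allowing literal "NA" (masked bins, diagonals).
parse_nums <- function(tokens) {
  out <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(out) & tokens != "NA")) {
    stop2("non-numeric token: '", tokens[is.na(out) & tokens != "NA"][1], "'")
  }
  out
}

parse_error <- function(path, line, msg) {
  stop2(basename(path), ":", line, ": ", msg)
}

#' Write / read a COLVAR-dialect CV table
#'
#' Whitespace table with a `#! FIELDS time <cv names>` header line.
#'
#' @param series A [cv_series()].
#' @param path File path.
#' @return `path` (write) or a [cv_series()] (read), with periodicity
#'   restored from a `#! PERIODIC` comment when present.
#' @export
write_colvar <- function(series, path) {
  nm <- colnames(series$values)
  lines <- c(paste("#! FIELDS time", paste(nm, collapse = " ")),
             paste("#! PERIODIC", paste(as.integer(series$periodic),
                                        collapse = " ")),
             vapply(seq_along(series$times), function(i) {
               paste(c(fmt_num(series$times[i]),
                       fmt_num(series$values[i, ])), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#! FIELDS")) {
    parse_error(path, 1, "missing '#! FIELDS' header")
  }
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  if (fields[1] != "time") parse_error(path, 1, "first field must be 'time'")
  periodic <- NULL
  body_start <- 2
  if (length(lines) >= 2 && startsWith(lines[2], "#! PERIODIC")) {
    periodic <- as.logical(as.integer(
      strsplit(sub("^#! PERIODIC\\s+", "", lines[2]), "\\s+")[[1]]))
    body_start <- 3
  }
  body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  m <- matrix(NA_real_, length(body), length(fields))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) != length(fields) || anyNA(v)) {
      parse_error(path, body_start + i - 1, "malformed record")
    }
    m[i, ] <- v
  }
  cv_series(m[, 1], m[, -1, drop = FALSE], periodic = periodic,
            names = fields[-1])
}

#' Write / read a HILLS-dialect deposition log
#'
#' One hill per line under the header
#' `#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf walker`;
#' per-walker logs can be concatenated and re-read, the hills are re-sorted
#' by time (then walker) on read.
#'
#' @param hills Hill data.frame (as in `run$hills`) or a [bias_potential()].
#' @param path File path.
#' @param walker Restrict the write to one walker id.
#' @return `path` (write) or a hills data.frame (read).
#' @export
write_hills <- function(hills, path, walker = NULL) {
  if (inherits(hills, "bias_potential")) hills <- hills$hills
  if (!is.null(walker)) hills <- hills[hills$walker %in% walker, ]
  lines <- c("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf walker",
             vapply(seq_len(nrow(hills)), function(i) {
               paste(c(fmt_num(hills$time[i]), fmt_num(hills$cv1[i]),
                       fmt_num(hills$cv2[i]), fmt_num(hills$sigma1[i]),
                       fmt_num(hills$sigma2[i]), fmt_num(hills$height[i]),
                       fmt_num(hills$biasf[i]),
                       as.integer(hills$walker[i])), collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "#! FIELDS"))
  if (!length(hdr)) parse_error(path, 1, "missing '#! FIELDS' header")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cols <- c("time", "cv1", "cv2", "sigma1", "sigma2", "height", "biasf",
            "walker")
  m <- matrix(NA_real_, length(body), length(cols))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) != length(cols) || anyNA(v)) {
      parse_error(path, which(lines == body[i])[1], "malformed hill record")
    }
    m[i, ] <- v
  }
  h <- as.data.frame(m)
  names(h) <- cols
  h$walker <- as.integer(h$walker)
  h[order(h$time, h$walker), , drop = FALSE]
}

#' Write / read an XYZ trajectory
#'
#' Standard multi-frame XYZ: atom count, comment, then `name x y z` lines.
#'
#' @param frames atoms x 3 x n array, list of frames, or single matrix.
#' @param path File path.
#' @param names Atom names (default "C").
#' @return `path` (write) or list(coords = atoms x 3 x n array,
#'   names) (read).
#' @export
write_xyz <- function(frames, path, names = NULL) {
  frames <- as_frame_list(frames)
  n <- nrow(frames[[1]])
  names <- names %||% rep("C", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    writeLines(c(as.character(n), paste("frame", f)), con)
    writeLines(sprintf("%s %s %s %s", names, fmt_num(frames[[f]][, 1]),
                       fmt_num(frames[[f]][, 2]), fmt_num(frames[[f]][, 3])),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); nm <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) parse_error(path, i, "expected atom count")
    if (i + 1 + n > length(lines)) parse_error(path, i, "truncated frame")
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) != 4)
    if (length(bad)) parse_error(path, i + 1 + bad[1], "malformed atom line")
    co <- t(vapply(parts, function(p)
      suppressWarnings(as.numeric(p[2:4])), numeric(3)))
    if (anyNA(co)) {
      bad_row <- which(apply(co, 1, anyNA))[1]
      parse_error(path, i + 1 + bad_row, "non-numeric coordinate")
    }
    this_nm <- vapply(parts, `[[`, character(1), 1)
    if (is.null(nm)) nm <- this_nm
    else if (!identical(nm, this_nm)) parse_error(path, i, "mixed topologies")
    frames[[length(frames) + 1]] <- co
    i <- i + 2 + n
  }
  coords <- array(0, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  list(coords = coords, names = nm)
}

#' Write / read a multi-model PDB trajectory
#'
#' Minimal fixed-width ATOM records wrapped in MODEL/ENDMDL blocks, one
#' block per frame; bead residues are written as CA atoms.
#'
#' @param frames atoms x 3 x n array, list of frames, or single matrix.
#' @param path File path.
#' @param residue Residue id per atom.
#' @param chain Chain id per atom.
#' @return `path` (write) or list(coords array, residue, chain) (read).
#' @export
write_pdb_frames <- function(frames, path, residue = NULL, chain = NULL) {
  frames <- as_frame_list(frames)
  n <- nrow(frames[[1]])
  residue <- residue %||% seq_len(n)
  chain <- chain %||% rep("A", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), chain, residue, frames[[f]][, 1], frames[[f]][, 2],
      frames[[f]][, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_pdb_frames
#' @export
read_pdb_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); cur <- NULL
  residue <- NULL; chain <- NULL; first <- TRUE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "MODEL")) {
      cur <- list()
    } else if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) {
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (anyNA(c(x, y, z))) parse_error(path, i, "bad ATOM coordinates")
      if (is.null(cur)) cur <- list()  # headerless single-model file
      cur[[length(cur) + 1]] <- c(x, y, z)
      if (first) {
        residue <- c(residue, as.integer(substr(ln, 23, 26)))
        chain <- c(chain, trimws(substr(ln, 22, 22)))
      }
    } else if (startsWith(ln, "ENDMDL")) {
      if (is.null(cur)) parse_error(path, i, "ENDMDL without MODEL")
      frames[[length(frames) + 1]] <- do.call(rbind, cur)
      cur <- NULL
      first <- FALSE
    }
  }
  if (!is.null(cur) && length(cur)) {
    frames[[length(frames) + 1]] <- do.call(rbind, cur)
  }
  if (!length(frames)) parse_error(path, length(lines), "no frames found")
  n <- vapply(frames, nrow, integer(1))
  if (length(unique(n)) != 1) parse_error(path, 1, "mixed topologies")
  coords <- array(0, dim = c(n[1], 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  list(coords = coords, residue = residue, chain = chain)
}

#' Write / read an atom parameter table
#'
#' Tab-separated table of residue id, chain, atom name, partial charge,
#' Lennard-Jones depth and sigma; round-trips without loss.
#'
#' @param params Parameter data.frame.
#' @param path File path.
#' @return `path` (write) or the parameter data.frame (read).
#' @export
write_param_table <- function(params, path) {
  cols <- c("residue", "chain", "atom", "charge", "lj_eps", "lj_sigma")
  out <- params[, intersect(cols, names(params)), drop = FALSE]
  for (cc in intersect(c("charge", "lj_eps", "lj_sigma"), names(out))) {
    out[[cc]] <- fmt_num(out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_param_table
#' @export
read_param_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a gridded free-energy surface as text
#'
#' Dense matrix with bin-edge header comments; 1-D profiles are written as
#' two columns.
#'
#' @param fes A `fes` object.
#' @param path File path.
#' @return `path` (write) or a `fes` (read).
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# edges1:", paste(fmt_num(fes$edges1), collapse = " ")),
             con)
  if (is.matrix(fes$F)) {
    writeLines(paste("# edges2:", paste(fmt_num(fes$edges2), collapse = " ")),
               con)
    writeLines(vapply(seq_len(nrow(fes$F)), function(i)
      paste(fmt_num(fes$F[i, ]), collapse = " "), character(1)), con)
  } else {
    writeLines(paste(fmt_num(fes$mids1), fmt_num(fes$F)), con)
  }
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  e1 <- as.numeric(strsplit(sub("^# edges1:\\s*", "", lines[1]), "\\s+")[[1]])
  if (startsWith(lines[2], "# edges2:")) {
    e2 <- as.numeric(strsplit(sub("^# edges2:\\s*", "", lines[2]),
                              "\\s+")[[1]])
    body <- lines[-(1:2)]
    F <- do.call(rbind, lapply(body, function(l)
      parse_nums(strsplit(trimws(l), "\\s+")[[1]])))
    structure(list(mids1 = (e1[-1] + e1[-length(e1)]) / 2,
                   mids2 = (e2[-1] + e2[-length(e2)]) / 2,
                   edges1 = e1, edges2 = e2, F = F,
                   temperature = NA_real_), class = "fes")
  } else {
    body <- lines[-1]
    m <- do.call(rbind, lapply(body, function(l)
      parse_nums(strsplit(trimws(l), "\\s+")[[1]])))
    structure(list(mids1 = m[, 1], edges1 = e1, F = m[, 2],
                   temperature = NA_real_), class = "fes")
  }
}

#' Write / read an interaction-energy matrix
#'
#' `format = "dense"` writes the full matrix with residue-id headers;
#' `format = "long"` writes the three-column `residue_i residue_j energy`
#' table (upper triangle).
#'
#' @param iem An `iem` object or plain matrix.
#' @param path File path.
#' @param format `"dense"` or `"long"`.
#' @param which `"raw"` or `"processed"` layer of an `iem` object.
#' @return `path` (write) or a matrix with residue-id dimnames (read).
#' @export
write_iem <- function(iem, path, format = c("dense", "long"),
                      which = c("raw", "processed")) {
  format <- match.arg(format); which <- match.arg(which)
  m <- if (inherits(iem, "iem")) iem[[which]] else as.matrix(iem)
  ids <- rownames(m) %||% seq_len(nrow(m))
  if (format == "dense") {
    lines <- c(paste("#", paste(ids, collapse = " ")),
               vapply(seq_len(nrow(m)), function(i)
                 paste(fmt_num(m[i, ]), collapse = " "), character(1)))
  } else {
    ut <- which(upper.tri(m), arr.ind = TRUE)
    lines <- c("# residue_i residue_j energy",
               sprintf("%s %s %s", ids[ut[, 1]], ids[ut[, 2]],
                       fmt_num(m[ut])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_iem
#' @export
read_iem <- function(path, format = c("dense", "long")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "dense") {
    ids <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
    m <- do.call(rbind, lapply(lines[-1], function(l)
      parse_nums(strsplit(trimws(l), "\\s+")[[1]])))
    dimnames(m) <- list(ids, ids)
    m
  } else {
    d <- utils::read.table(path, comment.char = "#",
                           col.names = c("residue_i", "residue_j", "energy"))
    ids <- sort(unique(c(d$residue_i, d$residue_j)))
    m <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
    i <- match(d$residue_i, ids); j <- match(d$residue_j, ids)
    m[cbind(i, j)] <- d$energy
    m[cbind(j, i)] <- d$energy
    m
  }
}

#' Export a shortest-path map as flat tables (and optionally GraphML)
#'
#' @param spm A [build_spm()] object.
#' @param node_path,edge_path Output TSVs.
#' @param graphml_path Optional GraphML export (requires igraph).
#' @return Invisibly, the paths written.
#' @export
write_spm_tables <- function(spm, node_path, edge_path,
                             graphml_path = NULL) {
  utils::write.table(spm$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(spm$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(node_path, edge_path)
  if (!is.null(graphml_path)) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      warning("igraph not available: GraphML export skipped")
    } else {
      g <- igraph::graph_from_data_frame(
        spm$edges[, c("from", "to", "ie", "length", "usage", "width")],
        directed = FALSE,
        vertices = data.frame(name = spm$nodes$residue,
                              usage = spm$nodes$usage,
                              size = spm$nodes$size))
      igraph::write_graph(g, graphml_path, format = "graphml")
      written <- c(written, graphml_path)
    }
  }
  invisible(written)
}

#' Write / read a voxel frequency map
#'
#' Native text format: origin / spacing / dims header plus flattened values
#' in column-major order. [write_dx()] emits the OpenDX dialect understood
#' by molecular viewers.
#'
#' @param fmap A [frequency_map()].
#' @param path File path.
#' @return `path` (write) or a `frequency_map` (read).
#' @export
write_frequency_map <- function(fmap, path) {
  g <- fmap$grid
  lines <- c(paste("# origin:", paste(fmt_num(g$origin), collapse = " ")),
             paste("# spacing:", fmt_num(g$spacing)),
             paste("# dims:", paste(g$dims, collapse = " ")),
             paste("# n_frames:", fmap$n_frames),
             fmt_num(as.numeric(fmap$phi)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_frequency_map
#' @export
read_frequency_map <- function(path) {
  lines <- readLines(path)
  origin <- as.numeric(strsplit(sub("^# origin:\\s*", "", lines[1]),
                                "\\s+")[[1]])
  spacing <- as.numeric(sub("^# spacing:\\s*", "", lines[2]))
  dims <- as.integer(strsplit(sub("^# dims:\\s*", "", lines[3]),
                              "\\s+")[[1]])
  n_frames <- as.integer(sub("^# n_frames:\\s*", "", lines[4]))
  phi <- parse_nums(lines[-(1:4)])
  structure(list(phi = array(phi, dim = dims),
                 grid = list(origin = origin, spacing = spacing,
                             dims = dims),
                 probe = NA_real_, burial_radius = NA_real_,
                 burial_min = NA_integer_, n_frames = n_frames),
            class = "frequency_map")
}

#' @rdname write_frequency_map
#' @param ... unused.
#' @export
write_dx <- function(fmap, path, ...) {
  g <- fmap$grid
  n <- prod(g$dims)
  # OpenDX stores the last index fastest; our arrays store the first fastest
  vals <- aperm(fmap$phi, c(3, 2, 1))
  head <- c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.4f %.4f %.4f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.4f 0 0", g$spacing),
    sprintf("delta 0 %.4f 0", g$spacing),
    sprintf("delta 0 0 %.4f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n))
  v <- as.numeric(vals)
  pad <- (3 - length(v) %% 3) %% 3
  v <- c(v, rep(NA_real_, pad))
  rows <- matrix(v, ncol = 3, byrow = TRUE)
  body <- apply(rows, 1, function(r)
    paste(formatC(r[!is.na(r)], format = "e", digits = 5), collapse = " "))
  writeLines(c(head, body,
               'attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), path)
  invisible(path)
}
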