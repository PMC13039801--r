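#' Read (multi-frame) XYZ files
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` line per atom; frames may be concatenated. Coordinates are
#' Angstrom.
#'
#' @param path file path.
#' @return list of [geometry()] objects (empty list for an empty file).
#' @export
read_xyz <- function(path) {
  frames <- parse_xyz_frames(path)
  lapply(frames, function(fr) {
    geometry(fr$elements, fr$coords,
             tag = if (nzchar(fr$comment)) fr$comment else NULL)
  })
}

# shared frame scanner: returns element symbols, coordinate matrix, extra
# per-atom columns (as a character matrix) and the comment line
parse_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed atom-count line at line ", i, ": '", lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("truncated frame at line ", i, ": expected ", n, " atom lines")
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 4L))
      stop("malformed atom line at line ", i + 1L + which(nt < 4L)[1L])
    elements <- vapply(toks, `[[`, "", 1L)
    coords <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      v
    }, numeric(3)))
    if (anyNA(coords))
      stop("non-numeric coordinate in frame starting at line ", i)
    extra <- NULL
    if (all(nt >= 5L)) {
      ncol_extra <- min(nt) - 4L
      extra <- t(vapply(toks, function(t) t[5:(4 + ncol_extra)],
                        character(ncol_extra)))
      if (ncol_extra == 1L) extra <- matrix(extra, ncol = 1L)
    }
    frames[[length(frames) + 1L]] <-
      list(elements = elements, coords = coords, comment = comment,
           extra = extra, first_line = i)
    i <- i + 2L + n
  }
  frames
}

#' Write geometries to an XYZ file
#'
#' @param geometries a [geometry()] or list of them.
#' @param path output file path.
#' @param comments optional character vector of per-frame comment lines
#'   (defaults to each geometry's tag).
#' @export
write_xyz <- function(geometries, path, comments = NULL) {
  if (inherits(geometries, "geometry")) geometries <- list(geometries)
  out <- character(0)
  for (k in seq_along(geometries)) {
    g <- geometries[[k]]
    cm <- if (!is.null(comments)) comments[[k]] else
      if (!is.null(g$tag)) g$tag else ""
    out <- c(out, as.character(n_atoms(g)), cm,
             sprintf("%s %.12g %.12g %.12g", g$elements,
                     g$coords[, 1], g$coords[, 2], g$coords[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a labeled dataset (extended-XYZ dialect)
#'
#' Each frame's comment line carries `E_ref=<Hartree>`; each atom line carries
#' two trailing columns: the raw atomic energy and the absolute integration
#' error (both Hartree).
#'
#' @param path file path.
#' @return list of [labeled_config()] objects.
#' @export
read_labeled_dataset <- function(path) {
  frames <- parse_xyz_frames(path)
  lapply(frames, function(fr) {
    m <- regmatches(fr$comment,
                    regexec("E_ref=([-+0-9.eEdD]+)", fr$comment))[[1]]
    if (length(m) < 2L)
      stop("frame starting at line ", fr$first_line,
           " lacks an E_ref=<value> entry in its comment line")
    eref <- as.numeric(m[2])
    if (is.na(eref)) stop("non-numeric E_ref in frame at line ", fr$first_line)
    if (is.null(fr$extra) || ncol(fr$extra) < 2L)
      stop("frame starting at line ", fr$first_line,
           " lacks the per-atom E_raw and L_abs columns")
    eraw <- suppressWarnings(as.numeric(fr$extra[, 1]))
    labs <- suppressWarnings(as.numeric(fr$extra[, 2]))
    if (anyNA(eraw) || anyNA(labs))
      stop("non-numeric per-atom field in frame at line ", fr$first_line)
    labeled_config(geometry(fr$elements, fr$coords), eraw, labs, eref)
  })
}

#' Write a labeled dataset (extended-XYZ dialect)
#'
#' Floats are written with 12 significant digits so write/read round-trips
#' are lossless at that precision.
#'
#' @param configs list of [labeled_config()] objects.
#' @param path output file path.
#' @param corrected optional list of per-config corrected atomic energies; if
#'   given, an extra `E_corr` column is appended per atom.
#' @export
write_labeled_dataset <- function(configs, path, corrected = NULL) {
  if (inherits(configs, "labeled_config")) configs <- list(configs)
  out <- character(0)
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    g <- cfg$geometry
    lines <- sprintf("%s %.12g %.12g %.12g %.12g %.12g", g$elements,
                     g$coords[, 1], g$coords[, 2], g$coords[, 3],
                     cfg$raw_atomic_energies, cfg$abs_integration_errors)
    if (!is.null(corrected))
      lines <- sprintf("%s %.12g", lines, corrected[[k]])
    out <- c(out, as.character(n_atoms(g)),
             sprintf("E_ref=%.12g", cfg$ref_molecular_energy), lines)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a trajectory
#'
#' Frames go to an extended-XYZ file (with per-atom force columns in
#' Hartree/Bohr when available); per-step scalars go to a CSV sidecar.
#'
#' @param traj an `md_trajectory` as returned by [run_md()].
#' @param path output XYZ path; the scalar CSV is written next to it with a
#'   `.csv` extension.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  out <- character(0)
  for (k in seq_along(traj$frames)) {
    g <- traj$frames[[k]]
    f <- traj$forces[[k]]
    lines <- if (is.null(f))
      sprintf("%s %.12g %.12g %.12g", g$elements,
              g$coords[, 1], g$coords[, 2], g$coords[, 3])
    else
      sprintf("%s %.12g %.12g %.12g %.12g %.12g %.12g", g$elements,
              g$coords[, 1], g$coords[, 2], g$coords[, 3],
              f[, 1], f[, 2], f[, 3])
    out <- c(out, as.character(n_atoms(g)),
             sprintf("step=%d", traj$scalars$step[k]), lines)
  }
  writeLines(out, path)
  utils::write.csv(traj$scalars, sub("\\.[^.]*$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Save / load a trained molecular model
#'
#' The archive is a single self-describing, versioned file; a load of a saved
#' model reproduces predictions bit-identically.
#'
#' @param model a `molecular_gpr` model.
#' @param path archive path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "molecular_gpr"))
  saveRDS(list(format = "alfgpr-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `molecular_gpr` model.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model archive '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "alfgpr-model"))
    stop("'", path, "' is not an alfgpr model archive")
  if (!identical(obj$version, 1L))
    stop("unsupported model archive version: ", obj$version)
  obj$model
}
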