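#' Read a GRO coordinate file
#'
#' Parses a single-frame fixed-width GRO file (positions in nm). Velocities,
#' if present, are ignored.
#'
#' @param path File path.
#' @return A list with `atoms` (tibble: `resid`, `resname`, `atom`, `atomnum`,
#'   `x`, `y`, `z`), `box` (length-3 numeric, nm) and `title`.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) abort(paste0("read_gro(): no such file: ", path))
  lines <- readLines(path)
  if (length(lines) < 3L) abort("read_gro(): truncated file (need title, count, box)")
  title <- lines[1]
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0L) abort("read_gro(): line 2 is not an atom count")
  if (length(lines) < 2L + n + 1L) {
    abort(paste0("read_gro(): file truncated: expected ", n,
                 " atom records plus a box line"))
  }
  rec <- lines[seq_len(n) + 2L]
  parse_field <- function(s, from, to) substr(s, from, to)
  num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(paste0("read_gro(): malformed ", what, " at line ", ln[bad[1]]))
    }
    v
  }
  ln <- seq_len(n) + 2L
  if (n > 0L && any(nchar(rec) < 44L)) {
    abort(paste0("read_gro(): malformed fixed-width record at line ",
                 ln[which(nchar(rec) < 44L)[1]]))
  }
  atoms <- tibble(
    resid = if (n) as.integer(num(parse_field(rec, 1, 5), ln, "residue number")) else integer(),
    resname = if (n) trimws(parse_field(rec, 6, 10)) else character(),
    atom = if (n) trimws(parse_field(rec, 11, 15)) else character(),
    atomnum = if (n) as.integer(num(parse_field(rec, 16, 20), ln, "atom number")) else integer(),
    x = if (n) num(parse_field(rec, 21, 28), ln, "x coordinate") else numeric(),
    y = if (n) num(parse_field(rec, 29, 36), ln, "y coordinate") else numeric(),
    z = if (n) num(parse_field(rec, 37, 44), ln, "z coordinate") else numeric()
  )
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]]))
  if (length(boxv) < 3L || anyNA(boxv[1:3])) {
    abort(paste0("read_gro(): missing or malformed box line at line ", n + 3L))
  }
  list(atoms = atoms, box = boxv[1:3], title = title)
}

#' Write a GRO coordinate file
#'
#' @param atoms Tibble with columns `resid`, `resname`, `atom`, `x`, `y`, `z`
#'   (nm). An `atomnum` column is used if present, else sequential.
#' @param box Length-3 box (nm).
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(atoms, box, path, title = "memscape frame") {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("write_gro(): non-finite coordinates refused")
  if (any(abs(xyz) >= 9999.999)) {
    abort("write_gro(): coordinate exceeds GRO field width")
  }
  n <- nrow(atoms)
  atomnum <- if ("atomnum" %in% names(atoms)) atoms$atomnum else seq_len(n)
  body <- if (n) sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         atoms$resid %% 100000L,
                         substr(atoms$resname, 1, 5),
                         substr(atoms$atom, 1, 5),
                         atomnum %% 100000L,
                         xyz[, 1], xyz[, 2], xyz[, 3]) else character()
  writeLines(c(title, sprintf("%5d", n), body,
               sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  invisible(path)
}

#' GRO atom table for a topology + coordinate frame
#'
#' @param topology A [cg_topology()].
#' @param coords n_beads x 3 matrix (nm).
#' @return Tibble suitable for [write_gro()]: lipids get their molecule index
#'   as residue id and species as residue name; protein beads get their
#'   residue number and `PROA`, `PROB`, ... residue names per protein.
#' @export
gro_atoms <- function(topology, coords) {
  b <- topology$beads
  resname <- ifelse(b$kind == "lipid", b$species,
                    paste0("PRO", LETTERS[pmin(b$protein_id, 26L)]))
  resid <- ifelse(b$kind == "lipid", b$mol_id, b$residue)
  tibble(resid = as.integer(resid), resname = resname, atom = b$bead,
         atomnum = b$bead_id,
         x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

#' Read a concatenated multi-frame GRO file
#'
#' @param path File path.
#' @return List of single-frame results as from [read_gro()].
#' @export
read_gro_multi <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) abort(paste0("read_gro_multi(): bad atom count at line ", i + 1L))
    last <- i + 2L + n
    if (last > length(lines)) {
      abort(paste0("read_gro_multi(): frame starting at line ", i, " truncated"))
    }
    tmp <- tempfile(fileext = ".gro")
    writeLines(lines[i:last], tmp)
    frames[[length(frames) + 1L]] <- read_gro(tmp)
    unlink(tmp)
    i <- last + 1L
  }
  frames
}

#' Write / read the flat binary frame stack
#'
#' The frame stack is the package's compact multi-frame store: a single JSON
#' header line (bead count, frame count, times, box, replica) followed by the
#' raw little-endian doubles of all coordinates, frame-major.
#'
#' @param traj A [cg_trajectory()].
#' @param path File path.
#' @param topology Topology to attach on read.
#' @return `write_frame_stack()`: `path` invisibly. `read_frame_stack()`:
#'   a `cg_trajectory`.
#' @export
write_frame_stack <- function(traj, path) {
  hdr <- jsonlite::toJSON(list(
    n_beads = dim(traj$coords)[1], n_frames = n_frames(traj),
    times = traj$times, box = traj$topology$box, replica = traj$replica
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeBin(as.numeric(traj$coords), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path, topology) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
  nb <- hdr$n_beads; nf <- hdr$n_frames
  vals <- readBin(con, what = "numeric", n = nb * 3L * nf, size = 8L,
                  endian = "little")
  if (length(vals) != nb * 3L * nf) abort("read_frame_stack(): truncated stack")
  cg_trajectory(topology, array(vals, c(nb, 3L, nf)), times = hdr$times,
                replica = hdr$replica %||% 1L)
}

#' Write a trajectory as concatenated GRO frames
#'
#' @param traj A [cg_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gro_traj <- function(traj, path) {
  tmp <- vapply(seq_len(n_frames(traj)), function(f) {
    p <- tempfile(fileext = ".gro")
    write_gro(gro_atoms(traj$topology, frame_coords(traj, f)),
              traj$topology$box, p,
              title = sprintf("memscape t= %.3f ns", traj$times[f]))
    p
  }, character(1))
  file.create(path)
  for (p in tmp) {
    file.append(path, p)
    unlink(p)
  }
  invisible(path)
}
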