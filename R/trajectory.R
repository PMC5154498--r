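#' Construct a trajectory
#'
#' A trajectory holds an ordered stack of coordinate frames for a fixed
#' topology: a beads x 3 x frames array of positions (nm), the frame times
#' (ns, strictly increasing with constant stride) and a replica id.
#'
#' @param topology A [cg_topology()].
#' @param coords Numeric array `n_beads x 3 x n_frames` (nm).
#' @param times Numeric frame times (ns).
#' @param replica Replica id (integer, default 1).
#' @return Object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(topology, coords, times, replica = 1L) {
  stopifnot(inherits(topology, "cg_topology"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[3] == length(times))
  if (dim(coords)[1] != nrow(topology$beads)) {
    abort("cg_trajectory(): coords rows must match topology beads")
  }
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) abort("cg_trajectory(): times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * max(dt)) {
      abort("cg_trajectory(): time stride must be constant")
    }
  }
  if (!all(is.finite(coords))) abort("cg_trajectory(): non-finite coordinates")
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         replica = as.integer(replica)),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<cg_trajectory> ", d[3], " frames x ", d[1], " beads, t = ",
      signif(x$times[1], 4), "..", signif(x$times[d[3]], 4), " ns (replica ",
      x$replica, ")\n", sep = "")
  invisible(x)
}

#' Number of frames / frame stride
#' @param traj A `cg_trajectory`.
#' @return Integer count / stride in ns.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
frame_stride <- function(traj) {
  if (n_frames(traj) < 2L) return(NA_real_)
  traj$times[2] - traj$times[1]
}

#' Coordinates of one frame
#' @param traj A `cg_trajectory`.
#' @param frame Frame index (1-based).
#' @return n_beads x 3 matrix (nm).
#' @export
frame_coords <- function(traj, frame) {
  traj$coords[, , frame, drop = TRUE]
}

#' Tidy view of a trajectory
#'
#' @param x A `cg_trajectory`.
#' @param frames Frame indices to include (default all).
#' @param bead_ids Bead ids to include (default all).
#' @param ... Unused.
#' @return A tibble with one row per bead per frame joining the bead table
#'   with `frame`, `time`, `x`, `y`, `z`.
#' @method as_tibble cg_trajectory
#' @export
as_tibble.cg_trajectory <- function(x, frames = NULL, bead_ids = NULL, ...) {
  frames <- frames %||% seq_len(n_frames(x))
  b <- x$topology$beads
  if (!is.null(bead_ids)) b <- b[match(bead_ids, b$bead_id), ]
  rows <- lapply(frames, function(f) {
    cc <- x$coords[b$bead_id, , f, drop = FALSE]
    mutate(b, frame = f, time = x$times[f],
           x = cc[, 1, 1], y = cc[, 2, 1], z = cc[, 3, 1])
  })
  bind_rows(rows)
}

# instantaneous bilayer midplane: mean z of all lipid reference beads
midplane_z <- function(coords, topology) {
  ids <- ref_bead_ids(topology)
  mean(coords[ids, 3])
}

# COM of one protein (backbone beads only by default) in one frame
protein_com <- function(coords, topology, protein_id, backbone_only = TRUE) {
  ids <- if (backbone_only) bb_bead_ids(topology, protein_id) else
    topology$beads$bead_id[topology$beads$kind == "protein" &
                             topology$beads$protein_id == protein_id]
  center_of_mass(coords[ids, , drop = FALSE], topology$box)
}

# xy COMs of all proteins in one frame: n_protein x 3 matrix
all_protein_coms <- function(coords, topology, backbone_only = TRUE) {
  t(vapply(topology$proteins$protein_id,
           function(p) protein_com(coords, topology, p, backbone_only),
           numeric(3)))
}

# internal reference direction of a protein in one frame: unit xy vector
# along COM -> TM1-COM (the phi/alpha convention)
protein_ref_direction <- function(coords, topology, protein_id) {
  com <- protein_com(coords, topology, protein_id)
  tm1 <- bb_bead_ids(topology, protein_id, helix = "TM1")
  com1 <- center_of_mass(coords[tm1, , drop = FALSE], topology$box)
  d <- min_image_displacement(com, com1, topology$box)
  v <- d[1:2]
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("protein_ref_direction(): degenerate TM1 direction")
  v / n
}
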