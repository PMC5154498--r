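#' Grid specification for 2D fields
#'
#' @param origin Length-2 lower-left corner (nm).
#' @param bin_side Square bin side (nm). The order/thickness grids default
#'   to 0.175 nm bins; receptor-centred density maps use 50 x 50 bins of
#'   0.2 nm.
#' @param nx,ny Bin counts per axis.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(origin = c(0, 0), bin_side = 0.175, nx, ny = nx) {
  stopifnot(bin_side > 0, nx >= 1, ny >= 1)
  structure(list(origin = as.numeric(origin), bin_side = bin_side,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' Grid covering a box
#' @param box Length >= 2 box (nm).
#' @param bin_side Bin side (nm).
#' @return A [grid_spec()] whose bins tile `[0, Lx) x [0, Ly)`.
#' @export
grid_for_box <- function(box, bin_side = 0.175) {
  grid_spec(c(0, 0), bin_side,
            nx = max(1L, floor(box[1] / bin_side)),
            ny = max(1L, floor(box[2] / bin_side)))
}

# xy -> linear bin index, wrapping by the grid extent (xy periodicity)
grid_index <- function(grid, x, y) {
  ix <- floor((x - grid$origin[1]) / grid$bin_side) %% grid$nx
  iy <- floor((y - grid$origin[2]) / grid$bin_side) %% grid$ny
  as.integer(ix + grid$nx * iy + 1L)
}

new_scalar_field2d <- function(grid, sum, count, mode) {
  structure(list(origin = grid$origin, bin_side = grid$bin_side,
                 nx = grid$nx, ny = grid$ny, sum = sum, count = count,
                 mode = mode),
            class = "scalar_field2d")
}

#' Accumulate point samples into a gridded field
#'
#' Bins samples into square xy bins and keeps per-bin value sums and sample
#' counts. In `"mean-field"` mode the field value is the per-bin mean and
#' empty bins are missing (never zero); in `"normalized-density"` mode the
#' value is the bin count divided by the total count, so occupied bins sum
#' to 1. Samples outside the grid are wrapped by the grid extent (the
#' membrane is xy-periodic), never dropped.
#'
#' @param samples Data frame with columns `x`, `y` and (for mean fields)
#'   the value column.
#' @param grid A [grid_spec()].
#' @param value Name of the value column (default `"chi"`).
#' @param mode `"mean-field"` or `"normalized-density"`.
#' @return A `scalar_field2d`.
#' @export
accumulate_field <- function(samples, grid, value = "chi",
                             mode = c("mean-field", "normalized-density")) {
  mode <- match.arg(mode)
  idx <- grid_index(grid, samples$x, samples$y)
  nb <- grid$nx * grid$ny
  cnt <- tabulate(idx, nbins = nb)
  if (mode == "mean-field") {
    v <- samples[[value]]
    sm <- numeric(nb)
    agg <- rowsum(v, idx)
    sm[as.integer(rownames(agg))] <- agg[, 1]
  } else {
    sm <- cnt
  }
  new_scalar_field2d(grid, matrix(sm, grid$nx, grid$ny),
                     matrix(cnt, grid$nx, grid$ny), mode)
}

#' Field values as a matrix
#'
#' @param field A `scalar_field2d`.
#' @return nx x ny matrix: per-bin mean (NA where empty) for mean fields,
#'   normalized probability for density fields.
#' @export
field_values <- function(field) {
  if (field$mode == "mean-field") {
    v <- field$sum / field$count
    v[field$count == 0] <- NA_real_
    v
  } else {
    field$sum / sum(field$sum)
  }
}

#' @export
print.scalar_field2d <- function(x, ...) {
  cat("<scalar_field2d> ", x$nx, " x ", x$ny, " bins of ", x$bin_side,
      " nm (", x$mode, "), ", sum(x$count > 0), " occupied\n", sep = "")
  invisible(x)
}

#' @method as_tibble scalar_field2d
#' @export
as_tibble.scalar_field2d <- function(x, ...) {
  v <- field_values(x)
  ij <- expand.grid(ix = seq_len(x$nx), iy = seq_len(x$ny))
  xc <- x$origin[1] + (ij$ix - 0.5) * x$bin_side
  yc <- x$origin[2] + (ij$iy - 0.5) * x$bin_side
  vals <- as.vector(v)
  cnts <- as.vector(x$count)
  tibble(ix = ij$ix, iy = ij$iy, x = xc, y = yc, value = vals, n = cnts)
}

#' Write / read a field as dense matrix text
#'
#' Plain-text format with a 3-line header (`# origin`, `# bin / shape`,
#' `# mode`) followed by the dense value matrix, row per x-bin.
#'
#' @param field A `scalar_field2d`.
#' @param path File path.
#' @return `write_field()`: `path` invisibly; `read_field()`: a list with
#'   `values`, `origin`, `bin_side`, `mode`.
#' @export
write_field <- function(field, path) {
  v <- field_values(field)
  hdr <- c(
    sprintf("# origin %.6f %.6f", field$origin[1], field$origin[2]),
    sprintf("# bin %.6f shape %d %d", field$bin_side, field$nx, field$ny),
    sprintf("# mode %s", field$mode))
  writeLines(c(hdr, apply(v, 1, function(r) paste(format(r, digits = 10),
                                                  collapse = "\t"))), path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  org <- as.numeric(strsplit(lines[1], " ")[[1]][3:4])
  hd2 <- strsplit(lines[2], " ")[[1]]
  bin <- as.numeric(hd2[3]); nx <- as.integer(hd2[5]); ny <- as.integer(hd2[6])
  mode <- strsplit(lines[3], " ")[[1]][3]
  vals <- t(vapply(lines[-(1:3)],
                   function(l) as.numeric(strsplit(l, "\t")[[1]]),
                   numeric(ny), USE.NAMES = FALSE))
  list(values = matrix(vals, nx, ny), origin = org, bin_side = bin,
       mode = mode)
}

#' Bilayer thickness map
#'
#' Local thickness is the difference between the average z of the first
#' linker beads (GL1/AM1) of the upper and lower leaflets, on the same
#' square grid as the order field. Only non-flipping species contribute;
#' leaflet assignment is by the sign of the reference-bead z relative to
#' the instantaneous midplane. Bins missing either leaflet are missing.
#'
#' @param traj A [cg_trajectory()].
#' @param grid A [grid_spec()]; defaults to 0.175 nm bins over the box.
#' @param frames Frame indices (default all).
#' @return A `scalar_field2d` whose values are thickness (nm).
#' @export
thickness_map <- function(traj, grid = grid_for_box(traj$topology$box),
                          frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  ids <- ref_bead_ids(top, flipping = FALSE)
  if (!length(ids)) abort("thickness_map(): no non-flipping lipids")
  nb <- grid$nx * grid$ny
  sum_u <- cnt_u <- sum_l <- cnt_l <- numeric(nb)
  for (f in frames) {
    cc <- matrix(traj$coords[ids, , f], ncol = 3L)
    mz <- midplane_z(frame_coords(traj, f), top)
    up <- cc[, 3] >= mz
    idx <- grid_index(grid, cc[, 1], cc[, 2])
    for (side in c(TRUE, FALSE)) {
      sel <- up == side
      if (!any(sel)) next
      cnt <- tabulate(idx[sel], nbins = nb)
      agg <- rowsum(cc[sel, 3], idx[sel])
      sm <- numeric(nb)
      sm[as.integer(rownames(agg))] <- agg[, 1]
      if (side) { sum_u <- sum_u + sm; cnt_u <- cnt_u + cnt }
      else { sum_l <- sum_l + sm; cnt_l <- cnt_l + cnt }
    }
  }
  both <- cnt_u > 0 & cnt_l > 0
  val <- ifelse(both, sum_u / pmax(cnt_u, 1) - sum_l / pmax(cnt_l, 1), 0)
  fld <- new_scalar_field2d(grid, matrix(val * both, grid$nx, grid$ny),
                            matrix(as.numeric(both), grid$nx, grid$ny),
                            "mean-field")
  fld$count <- matrix(pmin(cnt_u, cnt_l), grid$nx, grid$ny)
  fld$sum <- matrix(ifelse(both, val, 0), grid$nx, grid$ny) * fld$count
  fld
}

#' Receptor-centred lipid density map
#'
#' Normalized 2D probability distribution of the reference beads of one
#' lipid species (or headgroup class) around a protomer, in the protomer's
#' own frame: each qualifying frame is translated to the protein COM and
#' rotated so the COM to TM1-COM direction points along +x. For free
#' receptors only frames where the protomer is monomeric (COM at least
#' `min_sep` nm from every other protein COM) qualify.
#'
#' @param traj A [cg_trajectory()].
#' @param species Species name(s) whose reference beads are binned.
#' @param protomer Protein id.
#' @param grid Receptor-centred grid; default 50 x 50 bins of 0.2 nm.
#' @param monomer_only Keep only frames where the protomer is monomeric.
#' @param min_sep Monomer criterion distance (nm, default 5).
#' @param frames Frame indices (default all).
#' @return A `scalar_field2d` in `"normalized-density"` mode (sums to 1).
#' @export
density_map <- function(traj, species, protomer,
                        grid = grid_spec(c(-5, -5), 0.2, 50L, 50L),
                        monomer_only = TRUE, min_sep = 5, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  ids <- ref_bead_ids(top, species = species)
  if (!length(ids)) abort(paste0("density_map(): no lipids of species ",
                                 paste(species, collapse = "/")))
  nb <- grid$nx * grid$ny
  cnt <- numeric(nb)
  used <- 0L
  for (f in frames) {
    cc <- frame_coords(traj, f)
    if (monomer_only && nrow(top$proteins) > 1L) {
      coms <- all_protein_coms(cc, top)
      d <- min_image_dist(coms[protomer, c(1, 2, 3), drop = FALSE], coms, box)
      d[protomer] <- Inf
      # lateral separation only: proteins share the membrane plane
      if (min(d) < min_sep) next
    }
    com <- protein_com(cc, top, protomer)
    u <- protein_ref_direction(cc, top, protomer)
    d <- min_image_displacement(com, cc[ids, , drop = FALSE], box)
    d <- matrix(d, ncol = 3L)
    # rotate so u -> +x
    rx <- u[1] * d[, 1] + u[2] * d[, 2]
    ry <- -u[2] * d[, 1] + u[1] * d[, 2]
    inx <- floor((rx - grid$origin[1]) / grid$bin_side)
    iny <- floor((ry - grid$origin[2]) / grid$bin_side)
    ok <- inx >= 0 & inx < grid$nx & iny >= 0 & iny < grid$ny
    if (any(ok)) {
      cnt <- cnt + tabulate(inx[ok] + grid$nx * iny[ok] + 1L, nbins = nb)
    }
    used <- used + 1L
  }
  if (used == 0L) abort("density_map(): no qualifying (monomeric) frames")
  new_scalar_field2d(grid, matrix(cnt, grid$nx, grid$ny),
                     matrix(cnt, grid$nx, grid$ny), "normalized-density")
}

#' Per-residue lipid contact probability
#'
#' For every receptor residue, the fraction of (frame, protomer) samples in
#' which any reference bead of the chosen species lies within `cutoff` of
#' any bead of that residue.
#'
#' @param traj A [cg_trajectory()].
#' @param species Lipid species (default `"CHOL"`, whose ROH bead is its
#'   reference bead).
#' @param cutoff Contact cutoff (nm, default 0.7).
#' @param frames Frame indices (default all).
#' @return Tibble with `residue`, `helix`, `contact_prob`.
#' @export
residue_contact_probability <- function(traj, species = "CHOL",
                                        cutoff = 0.7, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  lip <- ref_bead_ids(top, species = species)
  b <- top$beads
  prot <- b[b$kind == "protein", ]
  residues <- sort(unique(prot$residue))
  hx <- prot$helix[match(residues, prot$residue)]
  hits <- numeric(length(residues))
  nsamp <- 0L
  for (f in frames) {
    cc <- frame_coords(traj, f)
    for (p in top$proteins$protein_id) {
      pb <- prot[prot$protein_id == p, ]
      d <- min_image_dist(cc[pb$bead_id, , drop = FALSE],
                          cc[lip, , drop = FALSE], box)
      contact <- apply(d <= cutoff, 1, any)
      byres <- tapply(contact, pb$residue, any)
      hits <- hits + as.numeric(byres[as.character(residues)])
      nsamp <- nsamp + 1L
    }
  }
  tibble(residue = residues, helix = hx, contact_prob = hits / nsamp)
}
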