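#' Per-lipid tail order samples
#'
#' The order metric is the folded angle chi between the membrane normal (z)
#' and the vector from the linker bead (GL1/AM1 for tail 1, GL2/AM2 for
#' tail 2) to the last bead of the tail: `chi = acos(|v_z| / ||v||)`, in
#' `[0, pi/2]`. 0 means a tail parallel to the normal (fully ordered);
#' pi/2 means a tail lying flat in the membrane plane. Folding the z
#' component makes the two leaflets share one scale. Flip-capable species
#' (CHOL, CER, DAG) are excluded by default; CHOL gets its own routine with
#' z-zone labels ([chol_order_samples()]).
#'
#' @param traj A [cg_trajectory()].
#' @param frames Frame indices (default all).
#' @param include_flipping Include flip-capable species (default FALSE).
#' @return Tibble with one row per tail per lipid per frame: `mol_id`,
#'   `species`, `tail`, `chi` (radians), `x`, `y` (reference-bead
#'   position), `frame`.
#' @export
lipid_order_samples <- function(traj, frames = NULL,
                                include_flipping = FALSE) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  b <- top$beads
  box <- top$box
  fc <- top$species$species[top$species$flip_capable]
  lip <- b[b$kind == "lipid" &
             (include_flipping | !(b$species %in% fc)), ]
  if (!nrow(lip)) {
    return(tibble(mol_id = integer(), species = character(),
                  tail = integer(), chi = numeric(), x = numeric(),
                  y = numeric(), frame = integer()))
  }
  tails <- lip[lip$role == "tail-end", ]
  link <- lip[lip$role %in% c("linker", "sterol-hydroxyl"), ]
  # linker for tail k is the k-th linker bead of the molecule (falls back
  # to the last available when a species has fewer linkers than tails)
  link_rank <- stats::ave(seq_len(nrow(link)), link$mol_id, FUN = seq_along)
  nlink <- table(link$mol_id)
  use_rank <- pmin(tails$tail,
                   as.integer(nlink[as.character(tails$mol_id)]))
  lrow <- link$bead_id[match(paste(tails$mol_id, use_rank),
                             paste(link$mol_id, link_rank))]
  missing_link <- is.na(lrow)
  if (any(missing_link)) {
    warn(paste0("lipid_order_samples(): skipping ", sum(missing_link),
                " tails with no matching linker bead"))
    tails <- tails[!missing_link, ]
    lrow <- lrow[!missing_link]
  }
  ref <- lip[lip$is_ref, ]
  refrow <- ref$bead_id[match(tails$mol_id, ref$mol_id)]
  out <- lapply(frames, function(f) {
    cc <- frame_coords(traj, f)
    v <- min_image_displacement(cc[lrow, , drop = FALSE],
                                cc[tails$bead_id, , drop = FALSE], box)
    v <- matrix(v, ncol = 3L)
    nrm <- sqrt(rowSums(v^2))
    tibble(mol_id = tails$mol_id, species = tails$species,
           tail = tails$tail,
           chi = acos(pmin(abs(v[, 3]) / nrm, 1)),
           x = cc[refrow, 1], y = cc[refrow, 2], frame = f)
  })
  bind_rows(out)
}

#' CHOL orientation samples with z-zone labels
#'
#' CHOL has no glycerol tail; its order angle is measured from the ROH
#' (sterol hydroxyl) bead to the final bead. The bilayer is split into
#' three zones by the ROH z-coordinate relative to the instantaneous
#' midplane: the middle of the bilayer is 1.6 nm thick (half-width 0.8 nm),
#' flanked by the upper and lower headgroup regions.
#'
#' @param traj A [cg_trajectory()].
#' @param frames Frame indices (default all).
#' @return Tibble with `mol_id`, `chi`, `x`, `y`, `z_rel` (nm from
#'   midplane), `zone` (`"upper-head"`, `"middle"`, `"lower-head"`),
#'   `frame`.
#' @export
chol_order_samples <- function(traj, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  b <- top$beads
  box <- top$box
  roh <- b[b$kind == "lipid" & b$species == "CHOL" &
             b$role == "sterol-hydroxyl", ]
  if (!nrow(roh)) abort("chol_order_samples(): no CHOL present")
  fin <- b[b$kind == "lipid" & b$species == "CHOL" & b$role == "tail-end", ]
  fin <- fin[match(roh$mol_id, fin$mol_id), ]
  out <- lapply(frames, function(f) {
    cc <- frame_coords(traj, f)
    mz <- midplane_z(cc, top)
    v <- min_image_displacement(cc[roh$bead_id, , drop = FALSE],
                                cc[fin$bead_id, , drop = FALSE], box)
    v <- matrix(v, ncol = 3L)
    nrm <- sqrt(rowSums(v^2))
    zr <- cc[roh$bead_id, 3] - mz
    tibble(mol_id = roh$mol_id,
           chi = acos(pmin(abs(v[, 3]) / nrm, 1)),
           x = cc[roh$bead_id, 1], y = cc[roh$bead_id, 2],
           z_rel = zr,
           zone = ifelse(abs(zr) < 0.8, "middle",
                         ifelse(zr > 0, "upper-head", "lower-head")),
           frame = f)
  })
  bind_rows(out)
}

#' Species occupancy of ordered vs disordered regions
#'
#' Builds the mean order field over the trajectory, then scores each
#' species' reference-bead samples by whether they fall in grid bins more
#' ordered (bin mean chi below the field average) or less ordered than the
#' average. The two fractions sum to 1 per species. A sphingomyelin-order
#' coupling shows up as `p_high_order > 0.5` for SM while other species
#' stay near 50/50.
#'
#' @param traj A [cg_trajectory()].
#' @param grid Grid for the order field (default 0.175 nm bins over the
#'   box).
#' @param frames Frame indices (default all).
#' @return Tibble with `species`, `p_high_order`, `p_low_order`, `n`
#'   (samples scored).
#' @export
sm_order_enrichment <- function(traj, grid = grid_for_box(traj$topology$box),
                                frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  samples <- lipid_order_samples(traj, frames = frames)
  fld <- accumulate_field(samples, grid, value = "chi")
  v <- field_values(fld)
  avg <- mean(v, na.rm = TRUE)
  top <- traj$topology
  b <- top$beads
  ref <- b[b$kind == "lipid" & b$is_ref, ]
  out <- lapply(frames, function(f) {
    cc <- frame_coords(traj, f)
    idx <- grid_index(grid, cc[ref$bead_id, 1], cc[ref$bead_id, 2])
    tibble(species = ref$species, bin_chi = as.vector(v)[idx])
  })
  bind_rows(out) |>
    filter(!is.na(.data$bin_chi)) |>
    group_by(.data$species) |>
    summarise(p_high_order = mean(.data$bin_chi < avg),
              p_low_order = mean(.data$bin_chi >= avg),
              n = dplyr::n(), .groups = "drop")
}

#' Normalized order-angle distribution
#'
#' @param trajs A [cg_trajectory()] or list of them (replicas).
#' @param breaks Histogram breaks over `[0, pi/2]` (default 50 bins).
#' @param frames Frame indices (default all).
#' @return Tibble with `replica`, `bin_mid`, `density`; replica `"mean"`
#'   rows hold the average of the per-replica normalized histograms.
#' @export
order_distribution <- function(trajs, breaks = seq(0, pi / 2,
                                                   length.out = 51L),
                               frames = NULL) {
  if (inherits(trajs, "cg_trajectory")) trajs <- list(trajs)
  per <- lapply(seq_along(trajs), function(r) {
    s <- lipid_order_samples(trajs[[r]], frames = frames)
    h <- graphics::hist(pmin(pmax(s$chi, min(breaks)), max(breaks)),
                        breaks = breaks, plot = FALSE)
    tibble(replica = as.character(r), bin_mid = h$mids,
           density = h$density)
  })
  per <- bind_rows(per)
  pooled <- per |>
    group_by(.data$bin_mid) |>
    summarise(density = mean(.data$density), .groups = "drop") |>
    mutate(replica = "mean")
  bind_rows(per, pooled[, c("replica", "bin_mid", "density")])
}

#' Thickness-order correlation across grid bins
#'
#' Pairs the per-bin averages of two fields on the same grid and reports
#' the Pearson correlation (a fully extended ordered tail projects further
#' onto z, so order and thickness are expected to correlate: low chi with
#' large thickness).
#'
#' @param order_field,thickness_field `scalar_field2d`s on identical grids.
#' @return List with `pairs` (tibble `ix`, `iy`, `order`, `thickness` over
#'   bins occupied in both) and `r` (Pearson correlation; NA with a
#'   warning when fewer than 2 paired bins).
#' @export
thickness_order_correlation <- function(order_field, thickness_field) {
  same <- identical(order_field$nx, thickness_field$nx) &&
    identical(order_field$ny, thickness_field$ny) &&
    isTRUE(all.equal(order_field$origin, thickness_field$origin)) &&
    isTRUE(all.equal(order_field$bin_side, thickness_field$bin_side))
  if (!same) abort("thickness_order_correlation(): fields on different grids")
  vo <- field_values(order_field)
  vt <- field_values(thickness_field)
  both <- !is.na(vo) & !is.na(vt)
  ij <- which(both, arr.ind = TRUE)
  pairs <- tibble(ix = ij[, 1], iy = ij[, 2],
                  order = vo[both], thickness = vt[both])
  if (nrow(pairs) < 2L || sd(pairs$order) == 0 || sd(pairs$thickness) == 0) {
    warn("thickness_order_correlation(): correlation undefined")
    r <- NA_real_
  } else {
    r <- cor(pairs$order, pairs$thickness)
  }
  list(pairs = pairs, r = r)
}
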