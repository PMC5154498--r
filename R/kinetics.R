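#' Lipid residence (dwell) intervals at a helix
#'
#' For every lipid of a species, the maximal runs of consecutive frames in
#' which any of its beads lies within `cutoff` of any sidechain bead of
#' the helix (of any protomer). Dwell time is run length times the frame
#' stride; a single out-of-contact frame ends a dwell.
#'
#' @param traj A [cg_trajectory()].
#' @param species Lipid species.
#' @param helix Helix name (e.g. `"TM6"`).
#' @param cutoff Contact cutoff (nm, default 1.2).
#' @param frames Frame indices (default all).
#' @return Tibble with one row per dwell: `mol_id`, `protein_id`,
#'   `start_frame`, `dwell` (ns). Attributes `mean` and `sd` summarise the
#'   dwell distribution (NA when empty).
#' @export
dwell_intervals <- function(traj, species, helix, cutoff = 1.2,
                            frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  stride <- frame_stride(traj)
  if (is.na(stride)) stride <- 1
  b <- top$beads
  sc <- b[b$kind == "protein" & b$role == "sidechain" &
            !is.na(b$helix) & b$helix == helix, ]
  if (!nrow(sc)) abort(paste0("dwell_intervals(): helix ", helix,
                              " has no sidechain beads"))
  ref <- ref_bead_ids(top, species = species)
  mols <- b$mol_id[match(ref, b$bead_id)]
  prots <- unique(sc$protein_id)
  out <- list()
  # in-contact indicator per (lipid, protein, frame)
  for (p in prots) {
    scp <- sc$bead_id[sc$protein_id == p]
    contact <- matrix(FALSE, length(ref), length(frames))
    for (fi in seq_along(frames)) {
      cc <- frame_coords(traj, frames[fi])
      d <- min_image_dist(cc[ref, , drop = FALSE],
                          cc[scp, , drop = FALSE], box)
      contact[, fi] <- apply(d <= cutoff, 1, any)
    }
    for (m in seq_along(ref)) {
      r <- rle(contact[m, ])
      if (!any(r$values)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ii <- which(r$values)
      out[[length(out) + 1L]] <- tibble(
        mol_id = mols[m], protein_id = p,
        start_frame = frames[starts[ii]],
        dwell = r$lengths[ii] * stride)
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(mol_id = integer(), protein_id = integer(),
           start_frame = integer(), dwell = numeric())
  attr(res, "mean") <- if (nrow(res)) mean(res$dwell) else NA_real_
  attr(res, "sd") <- if (nrow(res) > 1) sd(res$dwell) else NA_real_
  res
}

#' Summarise dwell distributions over replicas
#'
#' @param dwell_list List of [dwell_intervals()] results, one per replica.
#' @return Tibble with the per-replica means and the replica mean and
#'   standard deviation of the mean dwell time.
#' @export
summarise_dwells <- function(dwell_list) {
  means <- vapply(dwell_list, function(d)
    if (nrow(d)) mean(d$dwell) else NA_real_, numeric(1))
  tibble(replica = seq_along(dwell_list), mean_dwell = means) |>
    mutate(grand_mean = mean(means, na.rm = TRUE),
           grand_sd = sd(means[!is.na(means)]))
}

# zone classification of z relative to midplane: 1 upper head, 0 middle,
# -1 lower head (middle zone is 1.6 nm thick)
z_zone <- function(z_rel, half_width = 0.8) {
  ifelse(z_rel >= half_width, 1L, ifelse(z_rel <= -half_width, -1L, 0L))
}

#' Detect leaflet flip-flop events
#'
#' Three-zone scheme with hysteresis: the bilayer is split into upper
#' head, middle (1.6 nm thick about the midplane) and lower head zones by
#' the reference-bead z. A flip event is recorded at the first frame a
#' molecule enters the head zone opposite to its last-committed head zone;
#' excursions into the middle that return to the same side never count.
#'
#' @param traj A [cg_trajectory()].
#' @param species Flip-capable species (CHOL, CER or DAG).
#' @param frames Frame indices (default all).
#' @return Tibble with `mol_id`, `frame`, `direction`
#'   (`"up-down"`/`"down-up"`).
#' @export
detect_flips <- function(traj, species = "CHOL", frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  fc <- top$species$species[top$species$flip_capable]
  if (!all(species %in% fc)) {
    abort("detect_flips(): species is not flip-capable")
  }
  ref <- ref_bead_ids(top, species = species)
  mols <- top$beads$mol_id[match(ref, top$beads$bead_id)]
  # z relative to midplane, molecules x frames
  zrel <- vapply(frames, function(f) {
    cc <- frame_coords(traj, f)
    cc[ref, 3] - midplane_z(cc, top)
  }, numeric(length(ref)))
  zrel <- matrix(zrel, nrow = length(ref))
  zones <- z_zone(zrel)
  out <- list()
  for (m in seq_along(ref)) {
    zn <- zones[m, ]
    headed <- which(zn != 0L)
    if (!length(headed)) next
    committed <- zn[headed[1]]
    for (k in headed[-1]) {
      if (zn[k] != committed) {
        out[[length(out) + 1L]] <- tibble(
          mol_id = mols[m], frame = frames[k],
          direction = if (committed > 0) "up-down" else "down-up")
        committed <- zn[k]
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(mol_id = integer(), frame = integer(), direction = character())
}

#' Flip-flop rate estimate
#'
#' Per replica, rate = events / (N_molecules x T_observed) with T in
#' seconds of simulation time (no coarse-grained time rescaling applied);
#' the reported rate is the replica mean with its standard error (n-1).
#' With zero events the rate is 0 and a one-sided 95% Poisson upper bound
#' `3/(N x T)` is reported.
#'
#' @param events Event table from [detect_flips()], or a list of them
#'   (replicas).
#' @param trajs The matching [cg_trajectory()] or list.
#' @param species Species the events belong to (for the molecule count).
#' @return Tibble with one row: `rate` (s^-1), `se`, `n_events`,
#'   `rate_upper95`, `n_molecules`, `t_total` (s per molecule set).
#' @export
flip_rate <- function(events, trajs, species = "CHOL") {
  if (inherits(trajs, "cg_trajectory")) {
    trajs <- list(trajs)
    events <- list(events)
  }
  rates <- ne <- numeric(length(trajs))
  nm <- tt <- numeric(length(trajs))
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    nmol <- length(ref_bead_ids(tr$topology, species = species))
    tobs <- (tail(tr$times, 1) - tr$times[1]) * 1e-9   # ns -> s
    if (nmol == 0 || tobs <= 0) abort("flip_rate(): zero observation time")
    ne[r] <- nrow(events[[r]])
    nm[r] <- nmol; tt[r] <- tobs
    rates[r] <- ne[r] / (nmol * tobs)
  }
  se <- if (length(rates) > 1) sd(rates) / sqrt(length(rates)) else NA_real_
  tibble(rate = mean(rates), se = se, n_events = sum(ne),
         rate_upper95 = if (sum(ne) == 0)
           3 / (sum(nm * tt)) else NA_real_,
         n_molecules = sum(nm), t_total = sum(tt))
}

#' z versus minimum protein distance density
#'
#' Normalized 2D histogram of (z of the species' reference bead relative
#' to the midplane, minimum distance to any protein backbone bead).
#'
#' @param traj A [cg_trajectory()].
#' @param species Lipid species (default `"CHOL"`).
#' @param z_breaks,d_breaks Histogram breaks (nm).
#' @param frames Frame indices (default all).
#' @return Tibble with `z_mid`, `d_mid`, `density` (sums to 1 over
#'   occupied cells).
#' @export
z_mindist_density <- function(traj, species = "CHOL",
                              z_breaks = seq(-2.5, 2.5, by = 0.1),
                              d_breaks = seq(0, 10, by = 0.25),
                              frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  ref <- ref_bead_ids(top, species = species)
  bb <- top$beads$bead_id[top$beads$kind == "protein" &
                            top$beads$bead == "BB"]
  if (!length(bb)) abort("z_mindist_density(): no protein backbone beads")
  nz <- length(z_breaks) - 1L
  nd <- length(d_breaks) - 1L
  cnt <- matrix(0, nz, nd)
  for (f in frames) {
    cc <- frame_coords(traj, f)
    zr <- cc[ref, 3] - midplane_z(cc, top)
    dmin <- apply(min_image_dist(cc[ref, , drop = FALSE],
                                 cc[bb, , drop = FALSE], box), 1, min)
    iz <- findInterval(zr, z_breaks, rightmost.closed = TRUE)
    id <- findInterval(dmin, d_breaks, rightmost.closed = TRUE)
    ok <- iz >= 1 & iz <= nz & id >= 1 & id <= nd
    if (any(ok)) {
      for (k in which(ok)) cnt[iz[k], id[k]] <- cnt[iz[k], id[k]] + 1
    }
  }
  tot <- sum(cnt)
  if (tot == 0) warn("z_mindist_density(): no samples in range")
  g <- expand.grid(iz = seq_len(nz), id = seq_len(nd))
  tibble(z_mid = ((z_breaks[-1] + head(z_breaks, -1)) / 2)[g$iz],
         d_mid = ((d_breaks[-1] + head(d_breaks, -1)) / 2)[g$id],
         density = as.vector(cnt) / max(tot, 1))
}
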