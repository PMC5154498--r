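#' Interface window specification for pair profiles
#'
#' @param alpha0,beta0 Orientation window centres (radians) for the two
#'   protomers; presets: 0 for the TM1,2,H8 face, `-3*pi/4` for the
#'   TM5,6 face.
#' @param window Angular half-width (radians, default pi/6).
#' @param r0 Average protomer radius (nm, default 1.7); lipids are
#'   accepted within `|n| < r0` of the line of centres and `d` in
#'   `[r0, r - r0]`, and frames with any third protein within `r0` of the
#'   segment are rejected.
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(alpha0 = 0, beta0 = alpha0, window = pi / 6,
                      r0 = 1.7) {
  structure(list(alpha0 = alpha0, beta0 = beta0, window = window, r0 = r0),
            class = "pair_spec")
}

#' Protomer orientation angle relative to an axis
#'
#' `alpha` is the signed angle from the unit axis `v_d` (in the membrane
#' plane) to the protomer's internal reference direction (the COM to
#' TM1-COM projection), in `(-pi, pi]`.
#'
#' @param traj A [cg_trajectory()].
#' @param protein Protein id.
#' @param axis Length-2 unit vector in the xy plane.
#' @param frame Frame index (default 1).
#' @return Angle in radians.
#' @export
protomer_orientation <- function(traj, protein, axis, frame = 1L) {
  cc <- frame_coords(traj, frame)
  u <- protein_ref_direction(cc, traj$topology, protein)
  wrap_angle(atan2(u[2], u[1]) - atan2(axis[2], axis[1]))
}

# per-frame qualifying pairs for one frame's COM matrix
qualifying_pairs <- function(coms, dirs, box, spec) {
  np <- nrow(coms)
  out <- list()
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (i == j) next
      d12 <- min_image_displacement(coms[i, ], coms[j, ], box)
      r <- sqrt(sum(d12[1:2]^2))
      if (r < 1e-9) next
      th <- atan2(d12[2], d12[1])
      alpha <- wrap_angle(dirs[i] - th)
      beta <- wrap_angle(dirs[j] - th - pi)
      if (abs(wrap_angle(alpha - spec$alpha0)) > spec$window) next
      if (abs(wrap_angle(beta - spec$beta0)) > spec$window) next
      # line-of-centres occlusion by any third protomer
      u <- d12[1:2] / r
      occluded <- FALSE
      for (k in seq_len(np)) {
        if (k == i || k == j) next
        dk <- min_image_displacement(coms[i, ], coms[k, ], box)[1:2]
        t <- min(max(sum(dk * u), 0), r)
        perp <- sqrt(sum((dk - t * u)^2))
        if (perp < spec$r0) { occluded <- TRUE; break }
      }
      if (!occluded) {
        out[[length(out) + 1L]] <- tibble(p1 = i, p2 = j, r = r,
                                          alpha = alpha, beta = beta)
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(p1 = integer(), p2 = integer(), r = numeric(),
           alpha = numeric(), beta = numeric())
}

#' Select frames and protomer pairs matching an interface window
#'
#' A (frame, ordered pair) qualifies when protomer 1's orientation alpha
#' and protomer 2's orientation beta (measured from the line of centres,
#' pointing 1 to 2) fall inside the spec windows, and no third protein COM
#' lies within `r0` of the COM-COM segment.
#'
#' @param traj A [cg_trajectory()].
#' @param spec A [pair_spec()].
#' @param frames Frame indices (default all).
#' @return Tibble with `frame`, `p1`, `p2`, `r`, `alpha`, `beta`.
#' @export
select_pair_frames <- function(traj, spec, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  if (nrow(top$proteins) < 2L) abort("select_pair_frames(): need >= 2 proteins")
  out <- lapply(frames, function(f) {
    cc <- frame_coords(traj, f)
    coms <- all_protein_coms(cc, top)
    dirs <- vapply(top$proteins$protein_id, function(p) {
      u <- protein_ref_direction(cc, top, p)
      atan2(u[2], u[1])
    }, numeric(1))
    q <- qualifying_pairs(coms, dirs, top$box, spec)
    if (nrow(q)) mutate(q, frame = f) else q
  })
  bind_rows(out)
}

#' Accumulate a pair membrane-modulation profile
#'
#' For each qualifying (frame, pair), every non-flipping lipid reference
#' bead is decomposed as `d*v_d + n*n_d` in the frame anchored at protomer
#' 1's COM with `v_d` pointing toward protomer 2; samples with `|n| < r0`
#' and `d` in `[r0, r - r0]` contribute the lipid's order angle and the
#' local (gridded) thickness into (r, d) bins.
#'
#' @param traj A [cg_trajectory()].
#' @param spec A [pair_spec()].
#' @param r_edges,d_edges Bin edges (nm); defaults 0.25 nm steps, r over
#'   [3, 12].
#' @param frames Frame indices (default all).
#' @return A `pair_profile`: list with the edges, per-bin accumulators,
#'   and the spec; see [as_tibble.pair_profile()].
#' @export
accumulate_pair_profile <- function(traj, spec,
                                    r_edges = seq(3, 12, by = 0.25),
                                    d_edges = seq(0, 12, by = 0.25),
                                    frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  sel <- select_pair_frames(traj, spec, frames = frames)
  nr <- length(r_edges) - 1L
  nd <- length(d_edges) - 1L
  acc <- list(order_sum = matrix(0, nr, nd), order_n = matrix(0, nr, nd),
              thick_sum = matrix(0, nr, nd), thick_n = matrix(0, nr, nd))
  if (nrow(sel) == 0L) {
    warn("accumulate_pair_profile(): no qualifying frames; empty profile")
  } else {
    tgrid <- grid_for_box(box)
    tfield <- thickness_map(traj, tgrid, frames = frames)
    tvals <- field_values(tfield)
    samples <- lipid_order_samples(traj, frames = frames)
    # mean chi per molecule per frame
    mol_chi <- samples |>
      group_by(.data$frame, .data$mol_id) |>
      summarise(chi = mean(.data$chi), x = .data$x[1], y = .data$y[1],
                .groups = "drop")
    for (rw in seq_len(nrow(sel))) {
      f <- sel$frame[rw]
      cc <- frame_coords(traj, f)
      com1 <- protein_com(cc, top, sel$p1[rw])
      com2 <- protein_com(cc, top, sel$p2[rw])
      d12 <- min_image_displacement(com1, com2, box)
      r <- sqrt(sum(d12[1:2]^2))
      if (r < r_edges[1] || r >= r_edges[length(r_edges)]) next
      u <- d12[1:2] / r
      nvec <- c(-u[2], u[1])
      mc <- mol_chi[mol_chi$frame == f, ]
      disp <- matrix(min_image_displacement(com1, cbind(mc$x, mc$y, 0), box),
                     ncol = 3L)
      dd <- disp[, 1] * u[1] + disp[, 2] * u[2]
      nn <- disp[, 1] * nvec[1] + disp[, 2] * nvec[2]
      keep <- abs(nn) < spec$r0 & dd >= spec$r0 & dd <= r - spec$r0
      if (!any(keep)) next
      ir <- findInterval(r, r_edges)
      id <- findInterval(dd[keep], d_edges, rightmost.closed = TRUE)
      ok <- id >= 1L & id <= nd
      id <- id[ok]
      chi_k <- mc$chi[keep][ok]
      tk <- tvals[grid_index(tgrid, mc$x[keep][ok], mc$y[keep][ok])]
      for (b in seq_along(id)) {
        acc$order_sum[ir, id[b]] <- acc$order_sum[ir, id[b]] + chi_k[b]
        acc$order_n[ir, id[b]] <- acc$order_n[ir, id[b]] + 1
        if (!is.na(tk[b])) {
          acc$thick_sum[ir, id[b]] <- acc$thick_sum[ir, id[b]] + tk[b]
          acc$thick_n[ir, id[b]] <- acc$thick_n[ir, id[b]] + 1
        }
      }
    }
  }
  structure(list(r_edges = r_edges, d_edges = d_edges,
                 order_sum = acc$order_sum, order_n = acc$order_n,
                 thick_sum = acc$thick_sum, thick_n = acc$thick_n,
                 spec = spec, n_pairs = nrow(sel)),
            class = "pair_profile")
}

#' @export
print.pair_profile <- function(x, ...) {
  cat("<pair_profile> ", sum(x$order_n), " order samples over ",
      x$n_pairs, " qualifying (frame, pair) records\n", sep = "")
  invisible(x)
}

#' Tidy view of a pair profile
#' @param x A `pair_profile`.
#' @param ... Unused.
#' @return Tibble with bin centres `r`, `d` and per-bin `order`,
#'   `thickness` means (NA where unsampled) and counts.
#' @method as_tibble pair_profile
#' @export
as_tibble.pair_profile <- function(x, ...) {
  rmid <- (x$r_edges[-1] + head(x$r_edges, -1)) / 2
  dmid <- (x$d_edges[-1] + head(x$d_edges, -1)) / 2
  g <- expand.grid(ir = seq_along(rmid), id = seq_along(dmid))
  idx <- g$ir + (g$id - 1L) * length(rmid)
  ordv <- ifelse(x$order_n > 0, x$order_sum / pmax(x$order_n, 1), NA_real_)
  thv <- ifelse(x$thick_n > 0, x$thick_sum / pmax(x$thick_n, 1), NA_real_)
  tibble(r = rmid[g$ir], d = dmid[g$id],
         order = as.vector(ordv)[idx],
         thickness = as.vector(thv)[idx],
         n_order = as.vector(x$order_n)[idx],
         n_thickness = as.vector(x$thick_n)[idx])
}

#' Write a pair profile as matrix text
#'
#' Three companion files: thickness, order and counts over the (r, d)
#' grid, each with a 3-line header.
#'
#' @param profile A `pair_profile`.
#' @param stem Output path stem; writes `<stem>_{order,thickness,counts}.tsv`.
#' @return The three paths, invisibly.
#' @export
write_pair_profile <- function(profile, stem) {
  hdr <- c(
    sprintf("# r_edges %s", paste(profile$r_edges, collapse = " ")),
    sprintf("# d_edges %s", paste(profile$d_edges, collapse = " ")),
    sprintf("# alpha0 %.6f beta0 %.6f r0 %.3f", profile$spec$alpha0,
            profile$spec$beta0, profile$spec$r0))
  wr <- function(m, path) {
    writeLines(c(hdr, apply(m, 1, paste, collapse = "\t")), path)
    path
  }
  paths <- c(
    wr(profile$order_sum / pmax(profile$order_n, 1),
       paste0(stem, "_order.tsv")),
    wr(profile$thick_sum / pmax(profile$thick_n, 1),
       paste0(stem, "_thickness.tsv")),
    wr(profile$order_n, paste0(stem, "_counts.tsv")))
  invisible(paths)
}
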