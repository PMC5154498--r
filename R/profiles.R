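#' Helix-resolved azimuthal profile of order and thickness
#'
#' Lipids whose reference bead lies within `r_cut` of a protein COM are
#' binned by their azimuth around the COM, measured in the protein's
#' internal frame (relative to the COM to TM1-COM direction) so helices of
#' different protomers align. Per-azimuth-bin mean order and thickness are
#' reported; the helix-COM azimuths are attached as tick marks, since the
#' helix-index axis is geometric (azimuthal), not ordinal.
#'
#' @param traj A [cg_trajectory()].
#' @param r_cut Inclusion radius around the protein COM (nm, default
#'   3.125; a lipid at larger lateral distance is excluded).
#' @param bin_width Azimuth bin width (radians; default 5 degrees).
#' @param frames Frame indices (default all).
#' @param proteins Protein ids (default all).
#' @return Tibble with `azimuth` (bin centre, radians in (-pi, pi]),
#'   `mean_order`, `n_order`, `mean_thickness`, `n_thickness`; helix marks
#'   in `attr(, "helix_marks")` (tibble `helix`, `conformation`,
#'   `azimuth`).
#' @export
helix_azimuth_profile <- function(traj, r_cut = 3.125,
                                  bin_width = 5 * pi / 180,
                                  frames = NULL, proteins = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  proteins <- proteins %||% top$proteins$protein_id
  nbin <- max(1L, round(2 * pi / bin_width))
  edges <- seq(-pi, pi, length.out = nbin + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  ord_sum <- ord_n <- numeric(nbin)
  zu_sum <- zu_n <- zl_sum <- zl_n <- numeric(nbin)
  add <- function(acc, v, sel, idx) {
    if (!any(sel)) return(acc)
    m <- rowsum(v[sel], idx[sel], reorder = FALSE)
    k <- as.integer(rownames(m))
    acc[k] <- acc[k] + m[, 1]
    acc
  }

  samples <- lipid_order_samples(traj, frames = frames)
  ref_nonflip <- ref_bead_ids(top, flipping = FALSE)
  b <- top$beads
  ref_tbl <- b[match(ref_nonflip, b$bead_id), ]

  for (f in frames) {
    cc <- frame_coords(traj, f)
    mz <- midplane_z(cc, top)
    s_f <- samples[samples$frame == f, ]
    for (p in proteins) {
      com <- protein_com(cc, top, p)
      uref <- protein_ref_direction(cc, top, p)
      a0 <- atan2(uref[2], uref[1])
      # order samples near the COM
      d <- min_image_displacement(com, cbind(s_f$x, s_f$y, 0), box)
      d <- matrix(d, ncol = 3L)
      rr <- sqrt(d[, 1]^2 + d[, 2]^2)
      keep <- rr <= r_cut
      if (any(keep)) {
        az <- wrap_angle(atan2(d[keep, 2], d[keep, 1]) - a0)
        ib <- pmin(findInterval(az, edges, rightmost.closed = TRUE), nbin)
        ord_sum <- add(ord_sum, s_f$chi[keep], rep(TRUE, sum(keep)), ib)
        ord_n <- ord_n + tabulate(ib, nbins = nbin)
      }
      # thickness contributions from reference beads by leaflet
      rc <- cc[ref_nonflip, , drop = FALSE]
      d2 <- matrix(min_image_displacement(com, rc, box), ncol = 3L)
      rr2 <- sqrt(d2[, 1]^2 + d2[, 2]^2)
      keep2 <- rr2 <= r_cut
      if (any(keep2)) {
        az2 <- wrap_angle(atan2(d2[keep2, 2], d2[keep2, 1]) - a0)
        ib2 <- pmin(findInterval(az2, edges, rightmost.closed = TRUE), nbin)
        zz <- rc[keep2, 3] - mz
        up <- zz >= 0
        zu_sum <- add(zu_sum, zz, up, ib2)
        zu_n <- add(zu_n, rep(1, length(zz)), up, ib2)
        zl_sum <- add(zl_sum, zz, !up, ib2)
        zl_n <- add(zl_n, rep(1, length(zz)), !up, ib2)
      }
    }
  }
  thick <- ifelse(zu_n > 0 & zl_n > 0,
                  zu_sum / pmax(zu_n, 1) - zl_sum / pmax(zl_n, 1), NA_real_)
  out <- tibble(
    azimuth = mids,
    mean_order = ifelse(ord_n > 0, ord_sum / pmax(ord_n, 1), NA_real_),
    n_order = ord_n,
    mean_thickness = thick,
    n_thickness = pmin(zu_n, zl_n)
  )
  marks <- lapply(unique(top$proteins$conformation), function(cf) {
    hg <- protein_template(cf)
    hm <- helix_map()
    tibble(helix = hm$helix, conformation = cf,
           azimuth = vapply(hm$helix, function(h) {
             sel <- !is.na(hg$helix) & hg$helix == h
             atan2(mean(hg$bb_y[sel]), mean(hg$bb_x[sel]))
           }, numeric(1)))
  })
  attr(out, "helix_marks") <- bind_rows(marks)
  out
}

#' Summarise azimuthal profiles over replicas
#'
#' @param profiles List of [helix_azimuth_profile()] results (replicas).
#' @return Tibble with per-bin replica mean and standard error (n-1
#'   denominator) for order and thickness.
#' @export
summarise_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  all <- bind_rows(lapply(seq_along(profiles), function(r) {
    mutate(profiles[[r]], replica = r)
  }))
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    sd(v) / sqrt(length(v))
  }
  out <- all |>
    group_by(.data$azimuth) |>
    summarise(order = mean(.data$mean_order, na.rm = TRUE),
              order_se = se(.data$mean_order),
              thickness = mean(.data$mean_thickness, na.rm = TRUE),
              thickness_se = se(.data$mean_thickness),
              .groups = "drop")
  attr(out, "helix_marks") <- attr(profiles[[1]], "helix_marks")
  out
}

#' Protomer tilt angles
#'
#' The protein principal axis is the dominant eigenvector of the backbone
#' bead position covariance, oriented extracellular-up. `theta` is its
#' angle from the membrane normal; `phi` is the angle between its xy
#' projection and the projection of the COM to TM1-COM vector (reported as
#' 0 by convention for an exactly vertical axis).
#'
#' @param traj A [cg_trajectory()].
#' @param frames Frame indices (default all).
#' @param proteins Protein ids (default all).
#' @return Tibble with `protein_id`, `frame`, `theta`, `phi` (radians).
#' @export
protomer_tilt <- function(traj, frames = NULL, proteins = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  proteins <- proteins %||% top$proteins$protein_id
  out <- list()
  for (f in frames) {
    cc <- frame_coords(traj, f)
    for (p in proteins) {
      ids <- bb_bead_ids(top, p)
      if (length(ids) < 3L) abort("protomer_tilt(): need >= 3 backbone beads")
      com <- protein_com(cc, top, p, backbone_only = TRUE)
      d <- matrix(min_image_displacement(com, cc[ids, , drop = FALSE], box),
                  ncol = 3L)
      cv <- crossprod(d) / nrow(d)
      if (any(!is.finite(cv)) || qr(cv)$rank < 1L) {
        abort("protomer_tilt(): degenerate covariance")
      }
      ev <- eigen(cv, symmetric = TRUE)
      ax <- ev$vectors[, 1]
      if (ax[3] < 0) ax <- -ax
      theta <- acos(pmin(pmax(ax[3], -1), 1))
      uref <- protein_ref_direction(cc, top, p)
      pxy <- sqrt(ax[1]^2 + ax[2]^2)
      phi <- if (pxy < 1e-9) 0 else
        wrap_angle(atan2(ax[2], ax[1]) - atan2(uref[2], uref[1]))
      out[[length(out) + 1L]] <- tibble(protein_id = p, frame = f,
                                        theta = theta, phi = phi)
    }
  }
  bind_rows(out)
}
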