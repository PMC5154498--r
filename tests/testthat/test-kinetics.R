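test_that("dwell intervals are maximal runs times the stride", {
  res <- small_system(seed = 71, n_frames = 8, n_proteins = 1,
                      d_protein = 0, d_rot = 0)
  tr <- res$trajectory
  top <- tr$topology
  # engineer one CHOL's contact series with TM6: in,in,in,out,in,out,in,in
  sc <- top$beads[top$beads$kind == "protein" & top$beads$role == "sidechain" &
                    !is.na(top$beads$helix) & top$beads$helix == "TM6", ]
  chol <- memscape:::ref_bead_ids(top, species = "CHOL")
  target <- sc$bead_id[1]
  series <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  for (f in 1:8) {
    cc <- frame_coords(tr, f)
    # park all CHOL far from the protein, then glue/detach the first
    tr$coords[chol, 1:2, f] <- 1
    tr$coords[chol, 3, f] <- 8.5
    off <- if (series[f]) c(0.5, 0, 0) else c(5, 0, 0)
    tr$coords[chol[1], , f] <- cc[target, ] + off
  }
  dw <- dwell_intervals(tr, "CHOL", "TM6", cutoff = 1.2)
  mine <- dw[dw$mol_id == top$beads$mol_id[match(chol[1], top$beads$bead_id)], ]
  expect_equal(sort(mine$dwell), c(1, 2, 3))
  # sum of dwell lengths equals total in-contact frames
  expect_equal(sum(mine$dwell), sum(series) * 1)
})

test_that("never-in-contact species yields an empty dwell table with
          flagged summary", {
  res <- small_system(seed = 73, n_frames = 3, n_proteins = 1)
  tr <- res$trajectory
  chol <- memscape:::ref_bead_ids(tr$topology, species = "CHOL")
  for (f in 1:3) {
    tr$coords[chol, 1:2, f] <- 0.5
    tr$coords[chol, 3, f] <- 9.5
  }
  dw <- dwell_intervals(tr, "CHOL", "TM3")
  expect_equal(nrow(dw), 0L)
  expect_true(is.na(attr(dw, "mean")))
})

test_that("flip detection honours three-zone hysteresis", {
  # synthetic one-CHOL trajectory with a scripted z path
  mk_traj <- function(zpath) {
    beads <- memscape:::lipid_bead_template("CHOL")
    beads$kind <- "lipid"; beads$mol_id <- 1L; beads$species <- "CHOL"
    beads$is_ref <- beads$role == "sterol-hydroxyl"
    te <- cumsum(beads$role == "tail-end")
    beads$tail <- ifelse(beads$role == "tail-end", te, NA_integer_)
    beads$leaflet <- "upper"; beads$protein_id <- NA_integer_
    beads$conformation <- NA_character_; beads$residue <- NA_integer_
    beads$helix <- NA_character_
    beads$bead_id <- seq_len(nrow(beads))
    # two ghost lipids pin the midplane at z = 5.5
    ghost <- beads[rep(1, 2), ]
    ghost$mol_id <- c(2L, 3L)
    ghost$bead_id <- c(3L, 4L)
    all_beads <- dplyr::bind_rows(beads, ghost)
    top <- cg_topology(all_beads,
                       tibble::tibble(protein_id = integer(),
                                      conformation = character()),
                       box = c(10, 10, 11))
    nf <- length(zpath)
    cc <- array(5, c(4, 3, nf))
    cc[1, 3, ] <- 5.5 + zpath
    cc[2, 3, ] <- 5.5 + zpath - 0.5
    # ghosts positioned so the three reference beads always average 5.5
    cc[3, 3, ] <- 5.5 + 2 - zpath / 2
    cc[4, 3, ] <- 5.5 - 2 - zpath / 2
    cg_trajectory(top, cc, times = seq_len(nf) - 1)
  }
  # aborted crossing: up -> middle -> up
  expect_equal(nrow(detect_flips(mk_traj(c(1.5, 0.2, 1.4)), "CHOL")), 0L)
  # committed crossing: one up-down event
  ev <- detect_flips(mk_traj(c(1.5, 0.2, -1.2)), "CHOL")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "up-down")
  expect_equal(ev$frame, 3L)
  # time reversal preserves the count with swapped direction
  ev_rev <- detect_flips(mk_traj(rev(c(1.5, 0.2, -1.2))), "CHOL")
  expect_equal(nrow(ev_rev), 1L)
  expect_equal(ev_rev$direction, "down-up")
  # non-flip-capable species are refused
  res <- small_system(n_frames = 2)
  expect_error(detect_flips(res$trajectory, "PC"), "flip-capable")
})

test_that("midplane pinning in the scripted trajectory is sound", {
  # the ghost construction must keep the midplane near 5.5
  res <- chol_system(n_frames = 3, n_chol = 40)
  cc <- frame_coords(res$trajectory, 1)
  mz <- memscape:::midplane_z(cc, res$trajectory$topology)
  expect_lt(abs(mz - res$trajectory$topology$box[3] / 2), 0.3)
})

test_that("flip rates follow events / (molecules x time) with a Poisson
          bound at zero events", {
  res <- chol_system(seed = 81, n_frames = 1001, n_chol = 1, rate = 0)
  tr <- res$trajectory
  ev <- detect_flips(tr, "CHOL")
  fr <- flip_rate(ev, tr, "CHOL")
  expect_equal(fr$rate, 0)
  # upper bound 3 / (N x T) with N molecules observed for 1 us
  expect_equal(fr$rate_upper95, 3 / (fr$n_molecules * 1e-6),
               tolerance = 1e-6)
  # a single crossing per molecule-microsecond is 1e6 per second
  fake <- tibble::tibble(mol_id = 1L, frame = 500L, direction = "up-down")
  fr1 <- flip_rate(fake, tr, "CHOL")
  expect_equal(fr1$rate, 1e6 / fr1$n_molecules, tolerance = 1e-9)
})

test_that("the planted flip rate is recovered within 3 standard errors", {
  res <- chol_system(seed = 83, n_frames = 2000, n_chol = 150, rate = 5e6)
  ev <- detect_flips(res$trajectory, "CHOL")
  fr <- flip_rate(ev, res$trajectory, "CHOL")
  se <- sqrt(fr$n_events) / (fr$n_molecules * fr$t_total)
  expect_lt(abs(fr$rate - 5e6), 3 * se)
})

test_that("z vs minimum-distance density normalizes and matches brute
          force on a toy frame", {
  res <- small_system(seed = 87, n_frames = 2, n_proteins = 2)
  zd <- z_mindist_density(res$trajectory, "CHOL")
  expect_equal(sum(zd$density), 1, tolerance = 1e-12)
  # brute-force the minimum distances on frame 1
  tr <- res$trajectory
  top <- tr$topology
  cc <- frame_coords(tr, 1)
  ref <- memscape:::ref_bead_ids(top, species = "CHOL")
  bb <- top$beads$bead_id[top$beads$kind == "protein" &
                            top$beads$bead == "BB"]
  box <- top$box
  for (i in ref[1:3]) {
    best <- Inf
    for (j in bb) {
      d <- cc[j, ] - cc[i, ]
      for (ix in -1:1) for (iy in -1:1) {
        v <- d + c(ix * box[1], iy * box[2], 0)
        best <- min(best, sqrt(sum(v^2)))
      }
    }
    got <- min(memscape:::min_image_dist(cc[i, , drop = FALSE],
                                         cc[bb, , drop = FALSE], box))
    expect_equal(got, best, tolerance = 1e-12)
  }
})
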