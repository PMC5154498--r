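# two restrained protomers at a controlled pose plus a third for occlusion
posed_pair_system <- function(third_offset = NULL, seed = 61, n_frames = 3,
                              patch = 30) {
  n <- if (is.null(third_offset)) 2L else 3L
  p <- membrane_params(patch_side = patch, n_proteins = n,
                       n_lipids_upper = 250, n_lipids_lower = 230,
                       n_frames = n_frames, seed = seed, d_protein = 0,
                       d_rot = 0,
                       interfaces = default_interfaces()[0, ])
  sys <- build_system(p)
  # reposition protomers deterministically: pair along x, 10 nm apart
  st <- sys$state
  st$proteins$cx[1] <- 10; st$proteins$cy[1] <- 15
  st$proteins$cx[2] <- 20; st$proteins$cy[2] <- 15
  st$proteins$psi[1] <- 0      # reference direction +x, toward protomer 2
  st$proteins$psi[2] <- pi     # facing back
  if (!is.null(third_offset)) {
    st$proteins$cx[3] <- 15 + third_offset[1]
    st$proteins$cy[3] <- 15 + third_offset[2]
  }
  sys$state <- st
  sys$frame0 <- memscape:::assemble_coords(sys$topology, st, p)
  list(sys = sys, params = p)
}

posed_traj <- function(...) {
  ps <- posed_pair_system(...)
  simulate_membrane(ps$sys, ps$params)$trajectory
}

test_that("protomer orientation is the signed angle from the axis to the
          reference direction and is rotation-equivariant", {
  tr <- posed_traj()
  a1 <- protomer_orientation(tr, 1, axis = c(1, 0))
  expect_lt(abs(a1), 0.15)
  a2 <- protomer_orientation(tr, 2, axis = c(1, 0))
  expect_lt(abs(abs(a2) - pi), 0.15)
  a3 <- protomer_orientation(tr, 1, axis = c(0, 1))
  expect_equal(a3, memscape:::wrap_angle(a1 - pi / 2), tolerance = 1e-9)
})

test_that("pair selection applies the angular windows and the
          line-of-centres occlusion rule", {
  spec <- pair_spec(alpha0 = 0, beta0 = 0)
  # no third protein: the aligned pair qualifies in both orderings
  sel <- select_pair_frames(posed_traj(), spec, frames = 1)
  expect_equal(nrow(sel), 2L)
  expect_equal(sort(c(sel$p1[1], sel$p2[1])), c(1, 2))
  expect_equal(sel$r, rep(10, 2), tolerance = 0.05)
  # third protein on the midline at 1.0 nm perpendicular: excluded
  sel_block <- select_pair_frames(posed_traj(third_offset = c(0, 1.0)),
                                  spec, frames = 1)
  expect_equal(nrow(sel_block[sel_block$p1 %in% 1:2 &
                                sel_block$p2 %in% 1:2, ]), 0L)
  # at 2.0 nm (> r0 = 1.7): included
  sel_ok <- select_pair_frames(posed_traj(third_offset = c(0, 2.0)),
                               spec, frames = 1)
  expect_gt(nrow(sel_ok[sel_ok$p1 %in% 1:2 & sel_ok$p2 %in% 1:2, ]), 0L)
  # orientation window: an offset of pi/5 from the window centre exceeds
  # the pi/6 half-width, so the pair is rejected
  spec_off <- pair_spec(alpha0 = pi / 5, beta0 = 0, window = pi / 6 - 0.05)
  expect_equal(nrow(select_pair_frames(posed_traj(),
                                       spec_off, frames = 1)), 0L)
})

test_that("pair profile decomposition matches brute-force geometry on a
          toy trajectory", {
  tr <- posed_traj(n_frames = 3)
  spec <- pair_spec(alpha0 = 0, beta0 = 0)
  r_edges <- seq(3, 12, by = 0.5)
  d_edges <- seq(0, 12, by = 0.5)
  prof <- accumulate_pair_profile(tr, spec, r_edges, d_edges)
  # admissible d range [r0, r - r0]
  df <- as_tibble(prof)
  occupied <- df[df$n_order > 0, ]
  expect_true(all(occupied$d >= spec$r0 - 0.5))
  expect_true(all(occupied$d <= max(occupied$r) - spec$r0 + 0.5))

  # brute force: recompute the order accumulation directly
  top <- tr$topology
  box <- top$box
  sel <- select_pair_frames(tr, spec)
  samples <- lipid_order_samples(tr)
  bf_sum <- matrix(0, length(r_edges) - 1, length(d_edges) - 1)
  bf_n <- matrix(0, length(r_edges) - 1, length(d_edges) - 1)
  for (rw in seq_len(nrow(sel))) {
    f <- sel$frame[rw]
    cc <- frame_coords(tr, f)
    com1 <- memscape:::protein_com(cc, top, sel$p1[rw])
    com2 <- memscape:::protein_com(cc, top, sel$p2[rw])
    d12 <- memscape:::min_image_displacement(com1, com2, box)
    r <- sqrt(sum(d12[1:2]^2))
    u <- d12[1:2] / r
    nv <- c(-u[2], u[1])
    sf <- samples[samples$frame == f, ]
    agg <- aggregate(chi ~ mol_id, data = sf, FUN = mean)
    pos <- sf[!duplicated(sf$mol_id), c("mol_id", "x", "y")]
    agg <- merge(agg, pos, by = "mol_id")
    for (i in seq_len(nrow(agg))) {
      disp <- memscape:::min_image_displacement(
        com1, c(agg$x[i], agg$y[i], 0), box)
      dd <- disp[1] * u[1] + disp[2] * u[2]
      nn <- disp[1] * nv[1] + disp[2] * nv[2]
      if (abs(nn) < spec$r0 && dd >= spec$r0 && dd <= r - spec$r0) {
        ir <- findInterval(r, r_edges)
        id <- findInterval(dd, d_edges)
        bf_sum[ir, id] <- bf_sum[ir, id] + agg$chi[i]
        bf_n[ir, id] <- bf_n[ir, id] + 1
      }
    }
  }
  expect_equal(unname(prof$order_n), bf_n)
  expect_equal(unname(prof$order_sum), bf_sum, tolerance = 1e-9)
})

test_that("a lipid on the axis midpoint decomposes to d = r/2, n = 0", {
  tr <- posed_traj(n_frames = 1)
  top <- tr$topology
  cc <- frame_coords(tr, 1)
  com1 <- memscape:::protein_com(cc, top, 1)
  com2 <- memscape:::protein_com(cc, top, 2)
  d12 <- memscape:::min_image_displacement(com1, com2, top$box)
  r <- sqrt(sum(d12[1:2]^2))
  u <- d12[1:2] / r
  mid <- com1[1:2] + u * r / 2
  disp <- memscape:::min_image_displacement(com1, c(mid, 0), top$box)
  expect_equal(disp[1] * u[1] + disp[2] * u[2], r / 2, tolerance = 1e-9)
  expect_equal(disp[1] * -u[2] + disp[2] * u[1], 0, tolerance = 1e-9)
})

test_that("swapping protomer labels maps (alpha, beta, d) to
          (beta, alpha, r - d) for symmetric specs", {
  tr <- posed_traj(n_frames = 2)
  spec <- pair_spec(alpha0 = 0, beta0 = 0)
  sel <- select_pair_frames(tr, spec, frames = 1)
  fwd <- sel[sel$p1 == 1 & sel$p2 == 2, ]
  rev <- sel[sel$p1 == 2 & sel$p2 == 1, ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_equal(fwd$alpha, rev$beta, tolerance = 1e-9)
  expect_equal(fwd$beta, rev$alpha, tolerance = 1e-9)
  expect_equal(fwd$r, rev$r, tolerance = 1e-9)
})
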