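# hand-built one-lipid topology for geometric order checks
one_lipid_traj <- function(tail_vec, species = "PC", leaf = "upper") {
  beads <- memscape:::lipid_bead_template(species)
  beads$kind <- "lipid"; beads$mol_id <- 1L; beads$species <- species
  beads$is_ref <- beads$role == "sterol-hydroxyl" |
    (beads$role == "linker" & !duplicated(beads$role))
  te <- cumsum(beads$role == "tail-end")
  beads$tail <- ifelse(beads$role == "tail-end", te, NA_integer_)
  beads$leaflet <- leaf; beads$protein_id <- NA_integer_
  beads$conformation <- NA_character_; beads$residue <- NA_integer_
  beads$helix <- NA_character_
  beads$bead_id <- seq_len(nrow(beads))
  top <- cg_topology(beads, tibble::tibble(protein_id = integer(),
                                           conformation = character()),
                     box = c(10, 10, 11))
  cc <- matrix(0, nrow(beads), 3)
  base <- c(5, 5, 7)
  cc[, 1] <- base[1]; cc[, 2] <- base[2]; cc[, 3] <- base[3]
  for (t in which(!is.na(beads$tail))) {
    cc[t, ] <- base + tail_vec
  }
  cg_trajectory(top, cc, times = 0)
}

test_that("order angle chi follows the folded-vector geometry", {
  s <- lipid_order_samples(one_lipid_traj(c(0, 0, -1.5)))
  expect_equal(s$chi, rep(0, 2), tolerance = 1e-12)
  s <- lipid_order_samples(one_lipid_traj(c(1, 0, 0)))
  expect_equal(s$chi, rep(pi / 2, 2), tolerance = 1e-12)
  s <- lipid_order_samples(one_lipid_traj(c(1, 0, 1)))
  expect_equal(s$chi, rep(pi / 4, 2), tolerance = 1e-12)
  # folding: v and -v give the same chi (leaflet symmetry)
  s2 <- lipid_order_samples(one_lipid_traj(c(-1, 0, -1)))
  expect_equal(s2$chi, s$chi, tolerance = 1e-12)
})

test_that("flip-capable species are excluded from tail order by default", {
  res <- small_system(n_frames = 3)
  s <- lipid_order_samples(res$trajectory, frames = 1)
  expect_false(any(s$species %in% c("CHOL", "CER", "DAG")))
  s2 <- lipid_order_samples(res$trajectory, frames = 1,
                            include_flipping = TRUE)
  expect_true(any(s2$species == "CHOL"))
})

test_that("CHOL zones split at 0.8 nm from the midplane and chi is
          leaflet-independent for a vertical sterol", {
  res <- chol_system(n_frames = 5, n_chol = 30)
  co <- chol_order_samples(res$trajectory, frames = 1)
  expect_true(all(co$zone[abs(co$z_rel) < 0.8] == "middle"))
  expect_true(all(co$zone[co$z_rel >= 0.8] == "upper-head"))
  expect_true(all(co$zone[co$z_rel <= -0.8] == "lower-head"))
  expect_true(all(co$chi >= 0 & co$chi <= pi / 2))
})

test_that("field accumulation equals a brute-force double loop", {
  set.seed(5)
  n <- 10000
  samples <- tibble::tibble(x = runif(n, -2, 14), y = runif(n, -3, 15),
                            chi = runif(n))
  grid <- grid_spec(c(0, 0), 0.5, 24L, 24L)
  fld <- accumulate_field(samples, grid)
  v <- field_values(fld)
  # brute force with explicit wrapping
  sums <- matrix(0, 24, 24); cnts <- matrix(0, 24, 24)
  for (i in seq_len(n)) {
    ix <- (floor(samples$x[i] / 0.5) %% 24) + 1
    iy <- (floor(samples$y[i] / 0.5) %% 24) + 1
    sums[ix, iy] <- sums[ix, iy] + samples$chi[i]
    cnts[ix, iy] <- cnts[ix, iy] + 1
  }
  expect_equal(unname(fld$sum), sums)
  expect_equal(unname(fld$count), cnts)
  expect_equal(v[cnts > 0], (sums / cnts)[cnts > 0])
  expect_true(all(is.na(v[cnts == 0])))
  # two samples in one bin average; a single sample is its own mean
  g1 <- grid_spec(c(0, 0), 1, 4L, 4L)
  f1 <- accumulate_field(tibble::tibble(x = 0.5, y = 0.5, chi = 0.3), g1)
  expect_equal(field_values(f1)[1, 1], 0.3)
  expect_equal(sum(!is.na(field_values(f1))), 1L)
  f2 <- accumulate_field(tibble::tibble(x = c(0.4, 0.6), y = c(0.5, 0.5),
                                        chi = c(0.2, 0.4)), g1)
  expect_equal(field_values(f2)[1, 1], 0.3)
})

test_that("thickness of a planted flat bilayer is recovered exactly and a
          sinusoidal leaflet to second order in the bin size", {
  res <- small_system(seed = 17, n_frames = 1, order_relax = 0,
                      d_lipid = 0)
  tr <- res$trajectory
  top <- tr$topology
  ids <- memscape:::ref_bead_ids(top, flipping = FALSE)
  cc <- frame_coords(tr, 1)
  mz <- memscape:::midplane_z(cc, top)
  # force flat leaflets at +/- 2 nm
  cc[ids, 3] <- ifelse(cc[ids, 3] >= mz, mz + 2, mz - 2)
  tr$coords[, , 1] <- cc
  tm <- thickness_map(tr, grid_spec(c(0, 0), 1, 20L, 20L))
  v <- field_values(tm)
  expect_equal(v[!is.na(v)], rep(4, sum(!is.na(v))))
  # sinusoidal upper leaflet over a flat lower one
  amp <- 0.3; Lx <- top$box[1]
  up <- ids[cc[ids, 3] > mz]
  cc2 <- cc
  cc2[up, 3] <- mz + 2 + amp * sin(2 * pi * cc2[up, 1] / Lx)
  tr$coords[, , 1] <- cc2
  grid <- grid_spec(c(0, 0), 0.5, 40L, 40L)
  tm2 <- thickness_map(tr, grid)
  df <- as_tibble(tm2)
  df <- df[!is.na(df$value), ]
  pred <- 4 + amp * sin(2 * pi * df$x / Lx)
  # discretization error is O(bin^2) plus the in-bin spread of samples
  expect_lt(max(abs(df$value - pred)), amp * (2 * pi * 0.5 / Lx) + 1e-6)
})

test_that("density maps normalize, localize a glued lipid, and are
          equivariant under global 90-degree rotations", {
  res <- small_system(seed = 23, n_frames = 6, n_proteins = 1,
                      d_protein = 0, d_rot = 0)
  tr <- res$trajectory
  dm <- density_map(tr, "PC", 1, monomer_only = FALSE)
  expect_equal(sum(field_values(dm)), 1, tolerance = 1e-12)
  # a single restrained lipid and protein -> one occupied bin
  top <- tr$topology
  pc_ids <- memscape:::ref_bead_ids(top, species = "PC")
  tr2 <- tr
  for (f in seq_len(n_frames(tr))) {
    com <- memscape:::protein_com(frame_coords(tr, f), top, 1)
    tr2$coords[pc_ids, 1, f] <- com[1] + 2.05
    tr2$coords[pc_ids, 2, f] <- com[2]
  }
  dm1 <- density_map(tr2, "PC", 1, monomer_only = FALSE)
  expect_equal(max(field_values(dm1)), 1)
  # rotate the whole frame (and thus the protein) by 90 degrees: the
  # receptor-aligned map is unchanged up to numerical noise
  tr3 <- tr
  box <- top$box
  for (f in seq_len(n_frames(tr))) {
    cc <- frame_coords(tr, f)
    rot <- cbind(box[2] - cc[, 2], cc[, 1], cc[, 3])
    tr3$coords[, , f] <- rot
  }
  dm3 <- density_map(tr3, "PC", 1, monomer_only = FALSE)
  expect_equal(field_values(dm3), field_values(dm), tolerance = 1e-12)
})

test_that("density map demands qualifying monomeric frames", {
  idim <- tibble::tibble(i = 1L, j = 2L, interface = 1L)
  res <- small_system(seed = 29, n_frames = 3, n_proteins = 2,
                      initial_dimers = idim, d_protein = 0, d_rot = 0)
  expect_error(density_map(res$trajectory, "PC", 1, monomer_only = TRUE),
               "qualifying")
})

test_that("residue contact probabilities hit 1 for a glued lipid and 0
          for an absent one", {
  res <- small_system(seed = 37, n_frames = 4, n_proteins = 1,
                      d_protein = 0, d_rot = 0)
  tr <- res$trajectory
  top <- tr$topology
  chol_ids <- memscape:::ref_bead_ids(top, species = "CHOL")
  target <- top$beads[top$beads$kind == "protein" &
                        top$beads$residue == 200 &
                        top$beads$bead == "BB", ]
  tr2 <- tr
  for (f in seq_len(n_frames(tr))) {
    cc <- frame_coords(tr, f)
    tr2$coords[chol_ids[1], , f] <- cc[target$bead_id, ] + c(0.3, 0, 0)
    # park the other CHOL far away
    tr2$coords[chol_ids[-1], 1:2, f] <- 1
    tr2$coords[chol_ids[-1], 3, f] <- 7
  }
  cp <- residue_contact_probability(tr2, "CHOL", cutoff = 0.7)
  expect_equal(cp$contact_prob[cp$residue == 200], 1)
  far <- cp$contact_prob[cp$residue %in% 260:300]
  expect_true(all(far %in% c(0, 1)))
})

test_that("order distributions integrate to 1 and pool linearly", {
  res1 <- small_system(seed = 41, n_frames = 4)
  res2 <- small_system(seed = 43, n_frames = 4)
  od <- order_distribution(list(res1$trajectory, res2$trajectory),
                           frames = 1:4)
  bw <- diff(seq(0, pi / 2, length.out = 51))[1]
  for (r in unique(od$replica)) {
    expect_equal(sum(od$density[od$replica == r]) * bw, 1,
                 tolerance = 1e-9)
  }
  m <- od[od$replica == "mean", ]
  r1 <- od[od$replica == "1", ]
  r2 <- od[od$replica == "2", ]
  expect_equal(m$density, (r1$density + r2$density) / 2, tolerance = 1e-12)
})

test_that("thickness-order correlation recovers a constructed linear
          relation and flags degenerate inputs", {
  grid <- grid_spec(c(0, 0), 1, 10L, 10L)
  set.seed(8)
  xy <- tibble::tibble(x = runif(500, 0, 10), y = runif(500, 0, 10),
                       chi = runif(500, 0, 1.5))
  of <- accumulate_field(xy, grid)
  tf <- of
  tf$sum <- (4 - 0.5 * (of$sum / pmax(of$count, 1))) * of$count
  out <- thickness_order_correlation(of, tf)
  expect_equal(out$r, -1, tolerance = 1e-9)
  # grid mismatch errors
  expect_error(thickness_order_correlation(
    of, accumulate_field(xy, grid_spec(c(0, 0), 1, 5L, 5L))), "grid")
  # single occupied bin -> undefined, flagged
  f1 <- accumulate_field(tibble::tibble(x = 0.5, y = 0.5, chi = 0.3), grid)
  expect_warning(out1 <- thickness_order_correlation(f1, f1), "undefined")
  expect_true(is.na(out1$r))
  # independent noise decorrelates
  n <- 4000
  g2 <- grid_spec(c(0, 0), 1, 64L, 64L)
  a <- accumulate_field(tibble::tibble(
    x = runif(n, 0, 64), y = runif(n, 0, 64), chi = rnorm(n)), g2)
  b <- accumulate_field(tibble::tibble(
    x = runif(n, 0, 64), y = runif(n, 0, 64), chi = rnorm(n)), g2)
  outn <- thickness_order_correlation(a, b)
  expect_lt(abs(outn$r), 0.1)
})
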