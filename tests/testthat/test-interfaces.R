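test_that("contacts follow the 0.8 nm backbone cutoff and brute force on
          a toy pair", {
  idim <- tibble::tibble(i = 1L, j = 2L, interface = 1L)
  res <- small_system(seed = 105, n_frames = 2, n_proteins = 2,
                      initial_dimers = idim, d_protein = 0, d_rot = 0)
  tr <- res$trajectory
  m <- contact_map(tr, c(1L, 2L), frame = 1)
  # brute-force a residue subset
  top <- tr$topology
  cc <- frame_coords(tr, 1)
  b <- top$beads
  for (r1 in seq(65, 352, by = 41)) {
    for (r2 in seq(70, 352, by = 53)) {
      i1 <- b$bead_id[b$kind == "protein" & b$protein_id == 1 &
                        b$bead == "BB" & b$residue == r1]
      i2 <- b$bead_id[b$kind == "protein" & b$protein_id == 2 &
                        b$bead == "BB" & b$residue == r2]
      d <- memscape:::min_image_dist(cc[i1, , drop = FALSE],
                                     cc[i2, , drop = FALSE], top$box)
      expect_equal(m[as.character(r1), as.character(r2)],
                   as.numeric(d[1] <= 0.8))
    }
  }
  # transposing the protomer order transposes the map
  m2 <- contact_map(tr, c(2L, 1L), frame = 1)
  expect_equal(unclass(m2), t(unclass(m)), ignore_attr = TRUE)
  # contact maps are invariant under a global translation
  tr2 <- tr
  tr2$coords[, 1, ] <- (tr2$coords[, 1, ] + 7.1) %% top$box[1]
  m3 <- contact_map(tr2, c(1L, 2L), frame = 1)
  expect_equal(unclass(m3), unclass(m), ignore_attr = TRUE)
})

test_that("exact cutoff boundary: 0.79 nm is a contact, 0.81 nm is not", {
  # two single-residue protomers at a controlled distance
  mk <- function(sep) {
    beads <- tibble::tibble(
      bead = "BB", role = "backbone", residue = c(100L, 100L),
      helix = "TM1", kind = "protein", mol_id = 1:2,
      species = NA_character_, is_ref = FALSE, tail = NA_integer_,
      leaflet = NA_character_, protein_id = 1:2,
      conformation = "inactive", bead_id = 1:2)
    top <- cg_topology(beads,
                       tibble::tibble(protein_id = 1:2,
                                      conformation = "inactive"),
                       box = c(10, 10, 11))
    cc <- rbind(c(2, 5, 5.5), c(2 + sep, 5, 5.5))
    contact_map(cg_trajectory(top, cc, times = 0), c(1L, 2L))
  }
  expect_equal(sum(mk(0.79)), 1)
  expect_equal(sum(mk(0.81)), 0)
})

test_that("dimer criterion needs ten contact residues on each side", {
  maps_needed <- planted_contact_map(rows = 65:74, cols = 65:74)
  expect_equal(sum(rowSums(maps_needed) > 0), 10)
  # generator-planted dimer passes; detuned system with no dimer fails
  idim <- tibble::tibble(i = 1L, j = 2L, interface = 1L)
  res <- small_system(seed = 107, n_frames = 3, n_proteins = 3,
                      initial_dimers = idim, d_protein = 0, d_rot = 0)
  dd <- detect_dimers(res$trajectory, frame = 2)
  expect_equal(nrow(dd), 1L)
  expect_true(all(dd$n1 >= 10 & dd$n2 >= 10))
  # 9 residues on one side is not a dimer even with 30 on the other:
  # verified on the rule directly
  m <- planted_contact_map(rows = 65:94, cols = 65:73)
  expect_equal(sum(colSums(m) > 0), 9)
  expect_lt(sum(colSums(m) > 0), 10)
})

test_that("interface naming lists helices with >= 3 contact residues in
          TM order and canonicalizes sides", {
  # TM1 x 4, TM2 x 3, H8 x 5 against TM4 x 6
  m <- planted_contact_map(rows = c(65:68, 105:107, 338:342),
                           cols = 182:187)
  expect_equal(as.character(name_interface(m)), "TM1,2,H8/TM4")
  # the transposed map canonicalizes to the same name
  mt <- structure(t(unclass(m)), class = c("contact_map", "matrix"),
                  pair = c(2L, 1L), conformations = c("inactive", "inactive"),
                  frame = 1L)
  expect_equal(as.character(name_interface(mt)), "TM1,2,H8/TM4")
  # a helix with only 2 contact residues is omitted
  m2 <- planted_contact_map(rows = c(65:68, 226:227), cols = 182:187)
  expect_equal(as.character(name_interface(m2)), "TM1/TM4")
  # symmetric maps give a palindromic name
  m3 <- planted_contact_map(rows = c(65:68, 105:108, 338:341),
                            cols = c(65:68, 105:108, 338:341))
  expect_equal(as.character(name_interface(m3)), "TM1,2,H8/TM1,2,H8")
  # weak side: no helix reaches 3 residues -> largest-contact helix + flag
  m4 <- planted_contact_map(rows = c(65, 66, 105), cols = 182:192)
  nm <- name_interface(m4)
  expect_true(attr(nm, "weak"))
})

test_that("the clustering dissimilarity is a metric on binary maps", {
  set.seed(11)
  mk <- function() planted_contact_map(
    rows = sample(65:352, 8), cols = sample(65:352, 8), noise = 0.002)
  for (i in 1:10) {
    a <- mk(); b <- mk(); cc <- mk()
    dab <- memscape:::map_dissimilarity(a, b)
    expect_equal(memscape:::map_dissimilarity(a, a), 0)
    expect_equal(dab, memscape:::map_dissimilarity(b, a))
    expect_lte(dab, memscape:::map_dissimilarity(a, cc) +
                 memscape:::map_dissimilarity(cc, b) + 1e-9)
  }
  # maps differing in m cells have squared dissimilarity m (same ordering)
  a <- planted_contact_map(rows = 65:70, cols = 65:70)
  b <- a
  b[1:2, 1] <- 1 - b[1:2, 1]
  b[5, 8] <- 1 - b[5, 8]
  expect_lte(memscape:::map_dissimilarity(a, b), 3)
  expect_equal(sum((unclass(a) - unclass(b))^2), 3)
})

test_that("planted contact-map archetypes are recovered at ARI >= 0.9", {
  set.seed(13)
  arch <- list(
    list(rows = 65:80, cols = 182:195),     # TM1-ish vs TM4
    list(rows = 226:240, cols = 226:240),   # TM5 vs TM5
    list(rows = c(65:70, 338:344), cols = 270:282))  # TM1,H8 vs TM6
  labels <- rep(1:3, each = 20)
  maps <- lapply(labels, function(k) {
    planted_contact_map(rows = arch[[k]]$rows, cols = arch[[k]]$cols,
                        noise = 0.05 * 156 / (288 * 288))
  })
  # noise rate scaled so ~5% of the archetype cells flip per map
  cl <- cluster_interfaces(maps, k_range = 2:6)
  expect_gte(adjusted_rand_index(cl$cluster, labels), 0.9)
})

test_that("k exceeding the sample count is refused", {
  maps <- list(planted_contact_map(65:74, 65:74),
               planted_contact_map(65:74, 65:74))
  expect_error(cluster_interfaces(maps, k_range = 5:6), "sample")
})

test_that("monomer counting uses the inclusive 5 nm COM rule", {
  # two single-bead proteins at exactly 5.0 nm: both monomeric
  mk <- function(sep) {
    beads <- tibble::tibble(
      bead = "BB", role = "backbone", residue = c(100L, 100L),
      helix = "TM1", kind = "protein", mol_id = 1:2,
      species = NA_character_, is_ref = FALSE, tail = NA_integer_,
      leaflet = NA_character_, protein_id = 1:2,
      conformation = "inactive", bead_id = 1:2)
    top <- cg_topology(beads,
                       tibble::tibble(protein_id = 1:2,
                                      conformation = "inactive"),
                       box = c(20, 20, 11))
    cc <- rbind(c(2, 5, 5.5), c(2 + sep, 5, 5.5))
    count_monomers(cg_trajectory(top, cc, times = 0))
  }
  expect_equal(mk(5.0)$n_monomers, 2L)
  expect_equal(mk(4.99)$n_monomers, 0L)
  # a planted permanent dimer removes two monomers
  idim <- tibble::tibble(i = 1L, j = 2L, interface = 1L)
  res <- small_system(seed = 109, n_frames = 3, n_proteins = 4,
                      patch = 24, initial_dimers = idim, d_protein = 0,
                      d_rot = 0)
  cm <- count_monomers(res$trajectory, frames = 1)
  expect_lte(cm$n_monomers, 2L)
})

test_that("oligomer detection reports connected components of size >= 3
          with labelled edges", {
  # chain A-B, B-C from two planted dimers
  idim <- tibble::tibble(i = c(1L, 2L), j = c(2L, 3L), interface = c(1L, 2L))
  res <- small_system(seed = 111, n_frames = 2, n_proteins = 4,
                      patch = 30, initial_dimers = idim, d_protein = 0,
                      d_rot = 0)
  dd <- detect_dimers(res$trajectory, frame = 1)
  expect_gte(nrow(dd), 2L)
  ol <- detect_oligomers(dd)
  expect_equal(unique(ol$size), 3L)
  expect_setequal(unique(c(ol$p1, ol$p2)), 1:3)
  expect_equal(nrow(ol), 2L)
  expect_true(all(grepl("/", ol$interface)))
  # no edges -> no oligomers
  expect_equal(nrow(detect_oligomers(dd[0, ])), 0L)
})

test_that("interface RMSD is zero for rigid copies and matches the
          hand-computed single-displacement value", {
  set.seed(17)
  A <- matrix(rnorm(150), 50, 3)
  expect_equal(interface_rmsd(A, A), 0, tolerance = 1e-9)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(interface_rmsd(A %*% R + 2, A), 0, tolerance = 1e-9)
  # one bead displaced by 0.1 nm in an otherwise aligned 50-bead set:
  # naive RMSD sqrt(0.01/50) nm = 0.1414 A; refitting can only reduce it
  B <- A; B[1, 1] <- B[1, 1] + 0.1
  r <- interface_rmsd(A, B)
  expect_lte(r, sqrt(0.01 / 50) * 10 + 1e-9)
  expect_gte(r, 0.9 * sqrt(0.01 / 50) * 10)
  expect_error(interface_rmsd(A[1:2, ], A[1:2, ]), ">= 3")
})

test_that("interface RMSD agrees with an independent superposition
          (bio3d) on random structures", {
  skip_if_not_installed("bio3d")
  set.seed(19)
  A <- matrix(rnorm(90), 30, 3)
  B <- A + matrix(rnorm(90, 0, 0.05), 30, 3)
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)), mobile = as.vector(t(A))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) -
                                   B)^2)))
  expect_equal(interface_rmsd(A, B), ref_rmsd * 10, tolerance = 1e-6)
})

test_that("dimer interface coordinates feed the RMSD of a planted dimer
          against itself as zero", {
  idim <- tibble::tibble(i = 1L, j = 2L, interface = 1L)
  res <- small_system(seed = 113, n_frames = 2, n_proteins = 2,
                      initial_dimers = idim, d_protein = 0, d_rot = 0)
  co <- dimer_interface_coords(res$trajectory, c(1L, 2L),
                               helices1 = c("TM1", "H8"), frame = 1)
  co2 <- dimer_interface_coords(res$trajectory, c(1L, 2L),
                                helices1 = c("TM1", "H8"), frame = 2)
  expect_equal(interface_rmsd(co, co2), 0, tolerance = 1e-6)
})
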