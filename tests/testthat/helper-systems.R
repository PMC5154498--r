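# shared fixtures, all generated in code

# small mixed membrane with proteins
small_system <- function(seed = 7, n_frames = 20, n_proteins = 4,
                         patch = 20, ...) {
  p <- membrane_params(patch_side = patch, n_proteins = n_proteins,
                       n_lipids_upper = 150, n_lipids_lower = 140,
                       n_frames = n_frames, seed = seed, ...)
  simulate_membrane(build_system(p))
}

# CHOL-only protein-free membrane for kinetics
chol_system <- function(seed = 11, n_frames = 400, n_chol = 100,
                        rate = 5e6, ...) {
  p <- membrane_params(
    patch_side = 15, n_proteins = 0,
    composition = list(upper = c(CHOL = 1), lower = c(CHOL = 1)),
    n_lipids_upper = n_chol, n_lipids_lower = n_chol,
    flip_rates = c(CHOL = rate), n_frames = n_frames, seed = seed, ...)
  simulate_membrane(build_system(p))
}

# hand-built topology: one protein template at a pose, optional lipids
toy_protein_topology <- function(n_proteins = 1, box = c(20, 20, 11),
                                 conformation = "inactive") {
  p <- membrane_params(patch_side = box[1], n_proteins = n_proteins,
                       n_lipids_upper = 20, n_lipids_lower = 20,
                       n_frames = 1, seed = 1, lz = box[3],
                       conformation = conformation)
  build_system(p)
}

# synthetic contact map with given residue blocks in contact
planted_contact_map <- function(rows, cols, residues = 65:352,
                                noise = 0, conformations = c("inactive",
                                                             "inactive")) {
  n <- length(residues)
  m <- matrix(0, n, n)
  m[match(rows, residues), match(cols, residues)] <- 1
  if (noise > 0) {
    flip <- matrix(runif(n * n) < noise, n, n)
    m <- abs(m - flip)
  }
  dimnames(m) <- list(residues, residues)
  structure(m, class = c("contact_map", "matrix"), pair = c(1L, 2L),
            conformations = conformations, frame = 1L)
}

# adjusted Rand index between two label vectors
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  exp_idx <- si * sj / comb2(n)
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
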