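#' Residue-residue contact map between two protomers
#'
#' Binary matrix D over (residue of protomer 1) x (residue of protomer 2)
#' with `D[i, j] = 1` when the backbone beads of residues i and j lie
#' within `cutoff` (minimum image). Transposing the protomer order
#' transposes D.
#'
#' @param traj A [cg_trajectory()].
#' @param pair Length-2 protein ids.
#' @param cutoff Contact cutoff (nm, default 0.8).
#' @param frame Frame index (default 1).
#' @return Object of class `contact_map`: the binary matrix with residue
#'   dimnames plus `pair`, `conformations`, `frame` attributes.
#' @export
contact_map <- function(traj, pair, cutoff = 0.8, frame = 1L) {
  top <- traj$topology
  cc <- frame_coords(traj, frame)
  b <- top$beads
  b1 <- b[b$kind == "protein" & b$protein_id == pair[1] & b$bead == "BB", ]
  b2 <- b[b$kind == "protein" & b$protein_id == pair[2] & b$bead == "BB", ]
  if (!nrow(b1) || !nrow(b2)) abort("contact_map(): missing protomer")
  d <- min_image_dist(cc[b1$bead_id, , drop = FALSE],
                      cc[b2$bead_id, , drop = FALSE], top$box)
  D <- (d <= cutoff) + 0
  dimnames(D) <- list(b1$residue, b2$residue)
  structure(D, class = c("contact_map", "matrix"),
            pair = pair,
            conformations = top$proteins$conformation[
              match(pair, top$proteins$protein_id)],
            frame = frame)
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> pair (", paste(attr(x, "pair"), collapse = ", "),
      ") frame ", attr(x, "frame"), ": ", sum(x), " contacts, ",
      sum(rowSums(x) > 0), "/", sum(colSums(x) > 0),
      " residues per side\n", sep = "")
  invisible(x)
}

#' Detect dimers in a frame
#'
#' A dimer is formed when at least `min_residues` residues on each
#' protomer form contacts with the other protomer.
#'
#' @param traj A [cg_trajectory()].
#' @param frame Frame index.
#' @param cutoff Contact cutoff (nm, default 0.8).
#' @param min_residues Per-side residue threshold (default 10).
#' @param max_com_dist Skip pairs with COM separation beyond this (nm,
#'   default 8; a speed cutoff only, far pairs cannot touch).
#' @return Tibble with `p1`, `p2`, `frame`, `n1`, `n2` (contact residue
#'   counts per side) and the contact maps in a list column `map`.
#' @export
detect_dimers <- function(traj, frame = 1L, cutoff = 0.8,
                          min_residues = 10L, max_com_dist = 8) {
  top <- traj$topology
  cc <- frame_coords(traj, frame)
  ids <- top$proteins$protein_id
  if (length(ids) < 2L) {
    return(tibble(p1 = integer(), p2 = integer(), frame = integer(),
                  n1 = integer(), n2 = integer(), map = list()))
  }
  coms <- all_protein_coms(cc, top)
  out <- list()
  for (a in seq_along(ids)[-length(ids)]) {
    for (bb in (a + 1L):length(ids)) {
      d <- min_image_displacement(coms[a, ], coms[bb, ], top$box)
      if (sqrt(sum(d^2)) > max_com_dist) next
      m <- contact_map(traj, c(ids[a], ids[bb]), cutoff = cutoff,
                       frame = frame)
      n1 <- sum(rowSums(m) > 0)
      n2 <- sum(colSums(m) > 0)
      if (n1 >= min_residues && n2 >= min_residues) {
        out[[length(out) + 1L]] <- tibble(p1 = ids[a], p2 = ids[bb],
                                          frame = frame, n1 = n1, n2 = n2,
                                          map = list(m))
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(p1 = integer(), p2 = integer(), frame = integer(),
           n1 = integer(), n2 = integer(), map = list())
}

# helices ordered TM1..TM7, H8
helix_order <- function() c(paste0("TM", 1:7), "H8")

# per-side helix contact-residue counts for a contact map
side_helix_counts <- function(map, helices, margin) {
  res <- as.integer(dimnames(map)[[margin]])
  contact <- if (margin == 1L) rowSums(map) > 0 else colSums(map) > 0
  hx <- rep(NA_character_, length(res))
  for (i in seq_len(nrow(helices))) {
    hx[res >= helices$res_start[i] & res <= helices$res_end[i]] <-
      helices$helix[i]
  }
  tab <- table(hx[contact])
  setNames(as.integer(tab), names(tab))
}

# "TM1,2,H8" style label from a set of helices
helix_set_label <- function(hs) {
  hs <- intersect(helix_order(), hs)
  if (!length(hs)) return("")
  tm <- hs[startsWith(hs, "TM")]
  lab <- character()
  if (length(tm)) lab <- paste0("TM", paste(sub("TM", "", tm), collapse = ","))
  if ("H8" %in% hs) lab <- if (length(lab)) paste0(lab, ",H8") else "H8"
  lab
}

#' Name a dimer interface
#'
#' Helices with three or more contact-forming residues on a side enter
#' that side's name, listed in TM1..TM7, H8 order; the two sides are
#' joined by "/". The side whose lowest-index contacting helix is smaller
#' is put first (with the inactive side first as a tie-break for mixed
#' conformation pairs). If no helix reaches 3 residues on a side, the side
#' is named by its largest-contact helix and the result is flagged.
#'
#' @param map A [contact_map()].
#' @param helices Helix map (default [helix_map()]).
#' @return The interface name string; attribute `weak` is TRUE when a
#'   side fell back to its largest-contact helix.
#' @export
name_interface <- function(map, helices = helix_map()) {
  sides <- lapply(1:2, function(mg) side_helix_counts(map, helices, mg))
  weak <- FALSE
  labs <- character(2)
  keysets <- list()
  for (s in 1:2) {
    cnt <- sides[[s]]
    hs <- names(cnt)[cnt >= 3L]
    if (!length(hs)) {
      weak <- TRUE
      hs <- names(cnt)[which.max(cnt)]
    }
    keysets[[s]] <- hs
    labs[s] <- helix_set_label(hs)
  }
  ord <- helix_order()
  low <- vapply(keysets, function(hs)
    if (length(hs)) min(match(hs, ord)) else length(ord) + 1L, numeric(1))
  confs <- attr(map, "conformations") %||% c(NA, NA)
  flip <- if (low[2] < low[1]) TRUE
    else if (low[2] == low[1] && labs[2] < labs[1]) TRUE
    else if (labs[1] == labs[2] && !anyNA(confs) &&
               confs[1] == "active" && confs[2] == "inactive") TRUE
    else FALSE
  nm <- if (flip) paste(labs[2], labs[1], sep = "/") else
    paste(labs[1], labs[2], sep = "/")
  structure(nm, weak = weak)
}

# ordering-minimized squared dissimilarity Tr(t(D) D) between two maps
# (mismatch count for binary maps), minimized over the protomer ordering
map_dissimilarity <- function(a, b) {
  d1 <- sum((a - b)^2)
  d2 <- if (all(dim(a) == rev(dim(b)))) sum((a - t(b))^2) else Inf
  min(d1, d2)
}

# canonicalize a map's protomer order: side with the smaller lowest-index
# contacting helix first
canonical_map <- function(map, helices = helix_map()) {
  ord <- helix_order()
  low <- vapply(1:2, function(mg) {
    cnt <- side_helix_counts(map, helices, mg)
    hs <- names(cnt)[cnt >= 3L]
    if (!length(hs) && length(cnt)) hs <- names(cnt)[which.max(cnt)]
    if (length(hs)) min(match(hs, ord)) else length(ord) + 1L
  }, numeric(1))
  if (low[2] < low[1]) {
    tm <- t(unclass(map))
    structure(tm, class = c("contact_map", "matrix"),
              pair = rev(attr(map, "pair")),
              conformations = rev(attr(map, "conformations")),
              frame = attr(map, "frame"))
  } else map
}

#' Cluster dimer contact maps
#'
#' k-means over the vectorized (canonically ordered) contact maps with the
#' squared Euclidean norm `Tr(t(D) D)` of the map difference as the
#' dissimilarity (the mismatch count for binary maps); the protomer
#' ordering ambiguity is removed by canonicalizing every map first. k is
#' chosen by mean silhouette width over `k_range`, computed with the
#' ordering-minimized metric; clusters sharing an identical majority
#' interface name are merged for reporting.
#'
#' @param maps List of [contact_map()]s.
#' @param k_range Candidate cluster counts (default 2:12).
#' @param helices Helix map.
#' @return Tibble with one row per map: `cluster`, `interface` (cluster
#'   majority name), `name` (the map's own name); attribute `k` holds the
#'   selected k, `silhouette` its mean width.
#' @export
cluster_interfaces <- function(maps, k_range = 2:12,
                               helices = helix_map()) {
  if (length(maps) < 2L) abort("cluster_interfaces(): need >= 2 maps")
  cmaps <- lapply(maps, canonical_map, helices = helices)
  X <- t(vapply(cmaps, function(m) as.numeric(m), numeric(length(cmaps[[1]]))))
  names_i <- vapply(cmaps, function(m) as.character(name_interface(m, helices)),
                    character(1))
  k_range <- k_range[k_range < nrow(X)]
  if (!length(k_range)) abort("cluster_interfaces(): k exceeds sample count")
  dd <- matrix(0, length(cmaps), length(cmaps))
  for (i in seq_along(cmaps)) {
    for (j in seq_len(i - 1L)) {
      dd[i, j] <- dd[j, i] <- map_dissimilarity(cmaps[[i]], cmaps[[j]])
    }
  }
  best <- NULL
  for (k in k_range) {
    km <- kmeans(X, centers = k, iter.max = 50L, nstart = 10L)
    sil <- cluster::silhouette(km$cluster, dmatrix = dd)
    sw <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else -1
    if (is.null(best) || sw > best$sw) best <- list(km = km, sw = sw, k = k)
  }
  cl <- best$km$cluster
  maj <- vapply(seq_len(best$k), function(g) {
    nn <- names_i[cl == g]
    names(sort(table(nn), decreasing = TRUE))[1]
  }, character(1))
  # merge clusters sharing a majority name
  merged <- match(maj, unique(maj))
  out <- tibble(cluster = merged[cl], interface = maj[cl], name = names_i)
  attr(out, "k") <- best$k
  attr(out, "silhouette") <- best$sw
  out
}

#' Count monomeric receptors per frame
#'
#' A receptor is monomeric when its COM is at least `min_sep` (inclusive)
#' from every other protein COM.
#'
#' @param traj A [cg_trajectory()].
#' @param min_sep Monomer criterion (nm, default 5).
#' @param frames Frame indices (default all).
#' @return Tibble with `frame`, `time`, `n_monomers`.
#' @export
count_monomers <- function(traj, min_sep = 5, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  out <- lapply(frames, function(f) {
    cc <- frame_coords(traj, f)
    coms <- all_protein_coms(cc, top)
    n <- nrow(coms)
    mono <- vapply(seq_len(n), function(i) {
      d <- min_image_dist(coms[i, , drop = FALSE],
                          coms[-i, , drop = FALSE], top$box)
      all(d >= min_sep)
    }, logical(1))
    tibble(frame = f, time = traj$times[f], n_monomers = sum(mono))
  })
  bind_rows(out)
}

#' Detect oligomers from a dimer list
#'
#' Builds the graph with proteins as nodes and detected dimer interfaces
#' as edges, and reports connected components of size >= 3 with per-edge
#' interface names and protomer subscripts (A, B, C, ...).
#'
#' @param dimers Tibble from [detect_dimers()] (single frame or already
#'   filtered), with `p1`, `p2` and the `map` list column.
#' @param helices Helix map.
#' @return Tibble with one row per oligomer edge: `oligomer`, `size`,
#'   `p1`, `p2`, `label1`, `label2` (subscripts), `interface`.
#' @export
detect_oligomers <- function(dimers, helices = helix_map()) {
  if (!nrow(dimers)) {
    return(tibble(oligomer = integer(), size = integer(), p1 = integer(),
                  p2 = integer(), label1 = character(),
                  label2 = character(), interface = character()))
  }
  verts <- sort(unique(c(dimers$p1, dimers$p2)))
  g <- igraph::graph_from_data_frame(
    dimers[, c("p1", "p2")], directed = FALSE,
    vertices = tibble(name = as.character(verts)))
  comp <- igraph::components(g)
  memb <- comp$membership
  out <- list()
  oligo_id <- 0L
  for (ci in which(comp$csize >= 3L)) {
    oligo_id <- oligo_id + 1L
    members <- as.integer(names(memb)[memb == ci])
    lab <- setNames(LETTERS[seq_along(members)], members)
    sel <- dimers$p1 %in% members & dimers$p2 %in% members
    for (r in which(sel)) {
      nm <- as.character(name_interface(dimers$map[[r]], helices))
      out[[length(out) + 1L]] <- tibble(
        oligomer = oligo_id, size = length(members),
        p1 = dimers$p1[r], p2 = dimers$p2[r],
        label1 = lab[[as.character(dimers$p1[r])]],
        label2 = lab[[as.character(dimers$p2[r])]],
        interface = nm)
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(oligomer = integer(), size = integer(), p1 = integer(),
           p2 = integer(), label1 = character(), label2 = character(),
           interface = character())
}

# Kabsch least-squares superposition: rotation + translation mapping
# moving onto fixed (n x 3 each)
kabsch <- function(moving, fixed) {
  mc <- colMeans(moving); fc <- colMeans(fixed)
  A <- sweep(moving, 2, mc); B <- sweep(fixed, 2, fc)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = fc - as.numeric(R %*% mc))
}

#' Interface RMSD against a reference dimer
#'
#' Optimal rigid-body superposition (least squares rotation +
#' translation) of the full dimer on the backbone beads of the helices
#' participating in the interface, then the RMSD over those beads,
#' reported in Angstrom (nm x 10). Backbone beads stand in for the
#' C-alpha atoms of an atomistic reference.
#'
#' @param coords,ref n x 3 matrices (nm) of matched backbone beads of the
#'   two dimers (same residue correspondence, interface helices only).
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(coords, ref) {
  coords <- matrix(coords, ncol = 3L)
  ref <- matrix(ref, ncol = 3L)
  if (nrow(coords) != nrow(ref)) abort("interface_rmsd(): size mismatch")
  if (nrow(coords) < 3L) abort("interface_rmsd(): need >= 3 matched beads")
  fit <- kabsch(coords, ref)
  moved <- t(fit$R %*% t(coords) + fit$t)
  sqrt(mean(rowSums((moved - ref)^2))) * 10
}

#' Interface-helix backbone coordinates of a dimer
#'
#' Convenience extractor for [interface_rmsd()]: stacked backbone-bead
#' coordinates of the listed helices for the two protomers of a dimer,
#' unwrapped about the first protomer's COM.
#'
#' @param traj A [cg_trajectory()].
#' @param pair Length-2 protein ids.
#' @param helices1,helices2 Helix names participating on each side.
#' @param frame Frame index.
#' @return n x 3 matrix (nm).
#' @export
dimer_interface_coords <- function(traj, pair, helices1, helices2 = helices1,
                                   frame = 1L) {
  top <- traj$topology
  cc <- frame_coords(traj, frame)
  ids <- c(bb_bead_ids(top, pair[1], helix = helices1),
           bb_bead_ids(top, pair[2], helix = helices2))
  com <- protein_com(cc, top, pair[1])
  d <- matrix(min_image_displacement(com, cc[ids, , drop = FALSE], top$box),
              ncol = 3L)
  sweep(d, 2, com, `+`)
}
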