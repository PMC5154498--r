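#' Default lipid species table
#'
#' One row per headgroup class of the multi-component plasma-membrane model.
#' Each species carries its charge, whether it can flip between leaflets
#' (only the sterol CHOL and the small neutral lipids CER and DAG do), and
#' the rule for its per-molecule reference bead: the sterol hydroxyl bead
#' (ROH) for CHOL, otherwise the first linker bead (GL1 or AM1).
#'
#' @return A tibble with columns `species`, `class`, `charge`,
#'   `flip_capable`, `ref_bead`, `n_tails`.
#' @export
species_table <- function() {
  tibble(
    species      = c("PC", "PE", "SM", "CHOL", "GM", "PS", "PI",
                     "PIP1", "PIP2", "PIP3", "PA", "CER", "DAG", "LPC"),
    class        = c("PC", "PE", "SM", "CHOL", "GM", "PS", "PI",
                     "PIP1", "PIP2", "PIP3", "PA", "CER", "DAG", "LPC"),
    charge       = c(0, 0, 0, 0, -1, -1, -1, -3, -5, -7, -1, 0, 0, 0),
    flip_capable = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    ref_bead     = c("GL1", "GL1", "AM1", "ROH", "AM1", "GL1", "GL1",
                     "GL1", "GL1", "GL1", "GL1", "AM1", "GL1", "GL1"),
    n_tails      = c(2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L)
  )
}

# per-species bead layout: name + role, in declared order.
# roles: headgroup, linker, tail-end, sterol-hydroxyl
lipid_bead_template <- function(species) {
  sph <- species %in% c("SM", "GM", "CER")
  l1 <- if (sph) "AM1" else "GL1"
  l2 <- if (sph) "AM2" else "GL2"
  switch(species,
    CHOL = tibble(bead = c("ROH", "C2"),
                  role = c("sterol-hydroxyl", "tail-end")),
    LPC  = tibble(bead = c("NC3", "GL1", "C4A"),
                  role = c("headgroup", "linker", "tail-end")),
    CER  = tibble(bead = c("AM1", "AM2", "C4A", "C4B"),
                  role = c("linker", "linker", "tail-end", "tail-end")),
    DAG  = tibble(bead = c("GL1", "GL2", "C4A", "C4B"),
                  role = c("linker", "linker", "tail-end", "tail-end")),
    tibble(bead = c("HEAD", l1, l2, "C4A", "C4B"),
           role = c("headgroup", "linker", "linker", "tail-end", "tail-end"))
  )
}

#' Default transmembrane helix map
#'
#' Residue ranges of the seven transmembrane helices and the intracellular
#' helix 8 for the receptor construct spanning residues 65-352. Ranges are
#' disjoint; residues between ranges belong to loops.
#'
#' @return Tibble with columns `helix`, `res_start`, `res_end`.
#' @export
helix_map <- function() {
  tibble(
    helix     = c("TM1", "TM2", "TM3", "TM4", "TM5", "TM6", "TM7", "H8"),
    res_start = c(65L, 105L, 138L, 182L, 226L, 270L, 306L, 338L),
    res_end   = c(98L, 133L, 173L, 208L, 264L, 300L, 332L, 352L)
  )
}

# azimuth (radians, internal frame) and axis radius (nm) of each helix in the
# idealized 8-helix bundle. The internal reference direction (used for the
# orientation angle alpha and the tilt azimuth phi) is COM -> TM1-COM, i.e.
# azimuth 0. TM5/TM6 face the -3*pi/4 sector, matching the interface presets.
helix_geometry <- function(conformation = "inactive") {
  g <- tibble(
    helix   = c("TM1", "TM2", "TM3", "TM4", "TM5", "TM6", "TM7", "H8"),
    azimuth = -c(0, 51, 103, 150, 200, 250, 310, 0) * pi / 180,
    radius  = c(1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.9)
  )
  if (identical(conformation, "active")) {
    # outward swing of TM6 in the activated receptor
    i <- g$helix == "TM6"
    g$azimuth[i] <- g$azimuth[i] - 10 * pi / 180
    g$radius[i] <- g$radius[i] + 0.3
  }
  g
}

# Idealized rigid protomer template in its internal frame: x axis along the
# COM->TM1 direction, z along the membrane normal, origin at the xy COM of the
# backbone beads. One backbone bead per residue (65-352); helical residues lie
# on their helix axis, loop residues on top/bottom caps, H8 runs radially
# outward at the intracellular face. One sidechain bead per residue, 0.25 nm
# outward of the backbone.
protein_template <- function(conformation = c("inactive", "active"),
                             half_height = 1.7) {
  conformation <- match.arg(conformation)
  hm <- helix_map()
  hg <- helix_geometry(conformation)
  res <- 65:352
  hx <- rep(NA_character_, length(res))
  for (i in seq_len(nrow(hm))) {
    hx[res >= hm$res_start[i] & res <= hm$res_end[i]] <- hm$helix[i]
  }
  x <- y <- z <- numeric(length(res))
  for (i in seq_len(nrow(hm))) {
    sel <- which(hx == hm$helix[i])
    n <- length(sel)
    az <- hg$azimuth[hg$helix == hm$helix[i]]
    rad <- hg$radius[hg$helix == hm$helix[i]]
    if (hm$helix[i] == "H8") {
      # intracellular amphipathic helix, horizontal, pointing outward
      rr <- seq(1.4, 2.6, length.out = n)
      x[sel] <- rr * cos(az); y[sel] <- rr * sin(az); z[sel] <- -half_height - 0.2
    } else {
      zz <- seq(half_height, -half_height, length.out = n)
      if (i %% 2 == 0) zz <- rev(zz)   # antiparallel bundle
      x[sel] <- rad * cos(az); y[sel] <- rad * sin(az); z[sel] <- zz
    }
  }
  loops <- which(is.na(hx))
  if (length(loops)) {
    # park loop residues on alternating caps near the bundle rim
    ang <- seq(0, 2 * pi, length.out = length(loops) + 1L)[-1L]
    x[loops] <- 1.0 * cos(ang); y[loops] <- 1.0 * sin(ang)
    z[loops] <- ifelse(seq_along(loops) %% 2 == 0, half_height + 0.3,
                       -half_height - 0.3)
  }
  # recentre xy so the template COM sits at the origin
  x <- x - mean(x); y <- y - mean(y)
  rsc <- sqrt(x^2 + y^2)
  scale <- ifelse(rsc > 1e-9, (rsc + 0.25) / rsc, 1)
  tibble(
    residue = res, helix = hx,
    bb_x = x, bb_y = y, bb_z = z,
    sc_x = x * scale, sc_y = y * scale, sc_z = z
  )
}

#' Construct a system topology
#'
#' Bundles the static description of a coarse-grained membrane-receptor
#' system: the lipid species table, one row per bead (lipids and proteins),
#' the protein table, the helix map and the box.
#'
#' @param beads Tibble of beads (see Details).
#' @param proteins Tibble with `protein_id`, `conformation`.
#' @param box Numeric length-3 box (nm); periodic in x and y only.
#' @param species Species table, defaults to [species_table()].
#' @param helices Helix map, defaults to [helix_map()].
#' @return An object of class `cg_topology`.
#' @details The beads tibble has one row per bead with columns `bead_id`,
#'   `kind` ("lipid"/"protein"), `mol_id`, `species`, `bead`, `role`,
#'   `is_ref`, `leaflet` (leaflet of origin), `tail` (1/2/NA), `protein_id`,
#'   `conformation`, `residue`, `helix`. Every lipid molecule has exactly one
#'   reference bead (ROH for CHOL, first linker bead otherwise).
#' @export
cg_topology <- function(beads, proteins, box,
                        species = species_table(), helices = helix_map()) {
  stopifnot(length(box) == 3L, all(box > 0))
  nref <- beads |>
    filter(.data$kind == "lipid") |>
    group_by(.data$mol_id) |>
    summarise(n = sum(.data$is_ref), .groups = "drop")
  if (nrow(nref) && any(nref$n != 1L)) {
    abort("cg_topology(): every lipid molecule needs exactly one reference bead")
  }
  structure(
    list(species = species, beads = beads, proteins = proteins,
         helices = helices, box = as.numeric(box)),
    class = "cg_topology"
  )
}

#' @export
print.cg_topology <- function(x, ...) {
  nl <- length(unique(x$beads$mol_id[x$beads$kind == "lipid"]))
  cat("<cg_topology> ", nl, " lipids, ", nrow(x$proteins), " proteins, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm\n", sep = "")
  invisible(x)
}

# bead ids of lipid reference beads, optionally restricted
ref_bead_ids <- function(topology, species = NULL, flipping = NULL) {
  b <- topology$beads
  sel <- b$kind == "lipid" & b$is_ref
  if (!is.null(species)) sel <- sel & b$species %in% species
  if (!is.null(flipping)) {
    fc <- topology$species$species[topology$species$flip_capable]
    sel <- sel & if (flipping) b$species %in% fc else !(b$species %in% fc)
  }
  b$bead_id[sel]
}

# backbone bead ids of one protein (helical residues only if helix_only)
bb_bead_ids <- function(topology, protein_id, helix = NULL) {
  b <- topology$beads
  sel <- b$kind == "protein" & b$protein_id == protein_id & b$bead == "BB"
  if (!is.null(helix)) sel <- sel & b$helix %in% helix
  b$bead_id[sel]
}

#' Write / read a topology sidecar
#'
#' The sidecar is a structured YAML text file carrying the species table, the
#' bead table, the protein table, the helix map and the box, so that a
#' trajectory stored as coordinate frames can be re-analysed without the
#' generator.
#'
#' @param topology A `cg_topology`.
#' @param path File path.
#' @return `write_topology()` returns `path` invisibly; `read_topology()`
#'   returns a `cg_topology`.
#' @export
write_topology <- function(topology, path) {
  obj <- list(
    box = topology$box,
    species = lapply(seq_len(nrow(topology$species)), function(i)
      as.list(topology$species[i, ])),
    proteins = lapply(seq_len(nrow(topology$proteins)), function(i)
      as.list(topology$proteins[i, ])),
    helices = lapply(seq_len(nrow(topology$helices)), function(i)
      as.list(topology$helices[i, ])),
    beads = as.list(topology$beads)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- yaml::read_yaml(path)
  fix <- function(rows) bind_rows(lapply(rows, as_tibble))
  beads <- as_tibble(lapply(obj$beads, function(col) {
    col[vapply(col, is.null, logical(1))] <- NA
    unlist(col, use.names = FALSE) %||% col
  }))
  cg_topology(
    beads = beads,
    proteins = fix(obj$proteins),
    box = as.numeric(obj$box),
    species = fix(obj$species),
    helices = fix(obj$helices)
  )
}
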