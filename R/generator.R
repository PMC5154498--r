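#' Default leaflet compositions
#'
#' Mole fractions per headgroup class for the two leaflets of the idealized
#' plasma-membrane mimetic: the upper leaflet carries 5% GM, about 30%
#' CHOL and the minor species CER/LPC/DAG, the lower leaflet carries the
#' charged species (PA + PI + PS + PIP totalling 19%); the PC/PE/SM
#' remainder is split so each leaflet's zwitterionic total matches the
#' model membrane (60% upper, 53% lower).
#'
#' @return List with named numeric vectors `upper` and `lower`, each
#'   summing to 1.
#' @export
default_composition <- function() {
  list(
    upper = c(PC = 0.330, PE = 0.080, SM = 0.219, CHOL = 0.300, GM = 0.050,
              CER = 0.007, LPC = 0.010, DAG = 0.004),
    lower = c(PC = 0.270, PE = 0.200, SM = 0.060, CHOL = 0.274, PS = 0.090,
              PI = 0.069, PIP1 = 0.008, PIP2 = 0.005, PIP3 = 0.003,
              PA = 0.015, CER = 0.001, DAG = 0.005)
  )
}

#' Default planted dimer interface library
#'
#' Each row is a bound pose: orientation window centres `alpha0`/`beta0`
#' (radians; the angle conventions of [protomer_orientation()]), the bound
#' centre-of-mass distance, the capture radius and angular half-width within
#' which binding may fire, and first-order on/off rates (per ns). The two
#' presets face the TM1/H8 sector (`alpha0 = 0`) and the TM5/TM6 sector
#' (`alpha0 = -3*pi/4`).
#'
#' @return Tibble with one row per planted interface.
#' @export
default_interfaces <- function() {
  tibble(
    alpha0 = c(0, -3 * pi / 4),
    beta0 = c(0, -3 * pi / 4),
    com_dist = c(3.1, 3.0),
    capture = c(4.5, 4.5),
    window = c(pi / 6, pi / 6),
    k_on = c(0.05, 0.05),
    k_off = c(0, 0)
  )
}

#' Generator parameters
#'
#' Collects every knob of the synthetic membrane-receptor trajectory
#' generator with defaults matching the study conditions: a 25 x 25 nm
#' patch with 16 receptors (the high receptor density set-up), leaflet
#' lipid counts from the 1:200-per-upper-leaflet construction rule at
#' 50 nm scaled by area, the default composition, a 1 ns frame stride, and
#' a planted CHOL flip rate of 7.23e6 per second.
#'
#' @param patch_side Membrane patch side (nm).
#' @param n_proteins Number of protomers (placed on a regular grid).
#' @param conformation "inactive", "active" or "mixed".
#' @param mixed_fraction Fraction of inactive protomers when mixed.
#' @param composition List with `upper`/`lower` named mole-fraction vectors.
#' @param n_lipids_upper,n_lipids_lower Leaflet lipid counts; when `NULL`
#'   they follow the construction rule `round(n_proteins * 200 *
#'   (patch_side/50)^2)` for the upper leaflet and 3000/3200 of that for the
#'   lower leaflet.
#' @param d_lipid,d_protein Lateral diffusion coefficients (nm^2/ns).
#' @param d_rot Protein rotational diffusion (rad^2/ns).
#' @param order_baseline Baseline mean order angle chi (rad).
#' @param order_bias Named per-helix bias amplitudes (rad) added to the
#'   local mean order near those helices (negative = more ordered).
#' @param order_corr_length Gaussian correlation length of the planted
#'   order field (nm).
#' @param order_sd Stationary spread of chi about its local mean (rad).
#' @param order_relax Mean-reversion rate of chi (1/ns).
#' @param sm_coupling SM-order coupling strength: drift of SM molecules
#'   down the gradient of the planted mean-order field (nm^2/ns per
#'   rad/nm); 0 decouples SM from order.
#' @param flip_rates Named planted flip rates (s^-1) for flip-capable
#'   species.
#' @param flip_transit Frames over which the z-coordinate crosses to the
#'   destination leaflet after a flip fires.
#' @param interfaces Planted interface library, see [default_interfaces()].
#' @param initial_dimers Optional tibble (`i`, `j`, `interface`) of pairs
#'   bound from frame 1.
#' @param stride Frame stride (ns).
#' @param n_frames Number of frames.
#' @param lz Box height (nm).
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A list of class `membrane_params`.
#' @export
membrane_params <- function(patch_side = 25, n_proteins = 16L,
                            conformation = c("inactive", "active", "mixed"),
                            mixed_fraction = 0.5,
                            composition = default_composition(),
                            n_lipids_upper = NULL, n_lipids_lower = NULL,
                            d_lipid = 0.02, d_protein = 0.002, d_rot = 0.005,
                            order_baseline = 0.5,
                            order_bias = c(TM1 = -0.08, TM4 = 0.12,
                                           TM5 = -0.12, TM6 = -0.12),
                            order_corr_length = 1.5,
                            order_sd = 0.15, order_relax = 0.5,
                            sm_coupling = 1.0,
                            flip_rates = c(CHOL = 7.23e6, DAG = 6.34e6,
                                           CER = 1e4),
                            flip_transit = 2L,
                            interfaces = default_interfaces(),
                            initial_dimers = NULL,
                            stride = 1, n_frames = 100L, lz = 11,
                            seed = 1L) {
  conformation <- match.arg(conformation)
  for (lf in c("upper", "lower")) {
    s <- sum(composition[[lf]])
    if (abs(s - 1) > 1e-9) {
      abort(paste0("membrane_params(): ", lf,
                   " leaflet mole fractions sum to ", s, ", not 1"))
    }
    if (any(composition[[lf]] < 0)) abort("membrane_params(): negative fraction")
  }
  if (any(flip_rates < 0)) abort("membrane_params(): flip rates must be >= 0")
  if (is.null(n_lipids_upper)) {
    n_lipids_upper <- round(n_proteins * 200 * (patch_side / 50)^2)
  }
  if (is.null(n_lipids_lower)) {
    n_lipids_lower <- round(n_lipids_upper * 3000 / 3200)
  }
  structure(
    list(patch_side = patch_side, n_proteins = as.integer(n_proteins),
         conformation = conformation, mixed_fraction = mixed_fraction,
         composition = composition,
         n_lipids_upper = as.integer(n_lipids_upper),
         n_lipids_lower = as.integer(n_lipids_lower),
         d_lipid = d_lipid, d_protein = d_protein, d_rot = d_rot,
         order_baseline = order_baseline, order_bias = order_bias,
         order_corr_length = order_corr_length, order_sd = order_sd,
         order_relax = order_relax, sm_coupling = sm_coupling,
         flip_rates = flip_rates, flip_transit = as.integer(flip_transit),
         interfaces = interfaces, initial_dimers = initial_dimers,
         stride = stride, n_frames = as.integer(n_frames), lz = lz,
         seed = as.integer(seed)),
    class = "membrane_params"
  )
}

# head-region depth of the reference bead (nm from midplane) per species
ref_depth <- function(species) {
  ifelse(species == "CHOL", 1.4, 1.5)
}

# deterministic largest-remainder apportionment of n among fractions
apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

# planted mean-order field at points (x, y): baseline + per-helix Gaussian
# bumps centred on the (moving) helix xy COMs. centers: matrix [n_bumps, 3]
# with columns x, y, amplitude.
order_field_mu <- function(x, y, centers, baseline, sigma, box) {
  mu <- rep(baseline, length(x))
  gx <- gy <- numeric(length(x))
  if (!is.null(centers) && nrow(centers)) {
    for (b in seq_len(nrow(centers))) {
      dx <- x - centers[b, 1]; dy <- y - centers[b, 2]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      w <- centers[b, 3] * exp(-(dx * dx + dy * dy) / (2 * sigma^2))
      mu <- mu + w
      gx <- gx - w * dx / sigma^2
      gy <- gy - w * dy / sigma^2
    }
  }
  list(mu = mu, gx = gx, gy = gy)
}

# bump centres for the current protein poses: helix xy COMs of the biased
# helices, in the lab frame
bias_centers <- function(pstate, templates, order_bias, n_prot) {
  if (n_prot == 0L || !length(order_bias)) return(NULL)
  out <- list()
  for (p in seq_len(n_prot)) {
    tpl <- templates[[pstate$conf[p]]]
    cs <- cos(pstate$psi[p]); sn <- sin(pstate$psi[p])
    for (h in names(order_bias)) {
      sel <- !is.na(tpl$helix) & tpl$helix == h
      hx <- mean(tpl$bb_x[sel]); hy <- mean(tpl$bb_y[sel])
      out[[length(out) + 1L]] <- c(pstate$cx[p] + cs * hx - sn * hy,
                                   pstate$cy[p] + sn * hx + cs * hy,
                                   order_bias[[h]])
    }
  }
  do.call(rbind, out)
}

#' Build a synthetic membrane-receptor system
#'
#' Places `n_proteins` rigid protomers on a regular grid with independent
#' random z-axis rotations, apportions lipids to the two leaflets following
#' the construction rule and the requested composition (largest-remainder
#' rounding, deterministic given the seed), and scatters them uniformly
#' outside the protein footprints.
#'
#' @param params A [membrane_params()] object.
#' @return A list of class `cg_system` with elements `topology`
#'   ([cg_topology()]), `frame0` (bead coordinate matrix, nm), and the
#'   internal generator `state`.
#' @export
build_system <- function(params) {
  stopifnot(inherits(params, "membrane_params"))
  set.seed(params$seed)
  L <- params$patch_side
  box <- c(L, L, params$lz)
  np <- params$n_proteins
  sp_tab <- species_table()

  # ---- proteins on a grid, random rotations
  conf <- character(np)
  if (np > 0) {
    conf <- switch(params$conformation,
      inactive = rep("inactive", np),
      active = rep("active", np),
      mixed = {
        k <- round(np * params$mixed_fraction)
        sample(c(rep("inactive", k), rep("active", np - k)))
      })
    ng <- ceiling(sqrt(np))
    gx <- ((seq_len(ng)) - 0.5) * L / ng
    grid <- expand.grid(x = gx, y = gx)[seq_len(np), ]
    psi <- runif(np, -pi, pi)
    pstate <- list(cx = grid$x, cy = grid$y, psi = psi, conf = conf)
  } else {
    pstate <- list(cx = numeric(), cy = numeric(), psi = numeric(),
                   conf = character())
  }

  # ---- lipid counts per leaflet and species
  counts <- list()
  for (lf in c("upper", "lower")) {
    fr <- params$composition[[lf]]
    n <- if (lf == "upper") params$n_lipids_upper else params$n_lipids_lower
    cnt <- apportion(fr, n)
    counts[[lf]] <- setNames(cnt, names(fr))
  }
  n_lip <- sum(unlist(counts))

  # rough footprint feasibility check (0.45 nm^2 per lipid per leaflet)
  free_area <- L^2 - np * pi * 1.7^2
  if (max(params$n_lipids_upper, params$n_lipids_lower) * 0.45 > free_area) {
    abort("build_system(): patch too small for the requested lipid count")
  }

  species <- character(n_lip)
  leaf <- numeric(n_lip)
  i <- 1L
  for (lf in c("upper", "lower")) {
    for (s in names(counts[[lf]])) {
      k <- counts[[lf]][[s]]
      if (k > 0) {
        species[i:(i + k - 1L)] <- s
        leaf[i:(i + k - 1L)] <- if (lf == "upper") 1 else -1
        i <- i + k
      }
    }
  }

  # uniform placement outside protein footprints
  place <- function(n) {
    x <- runif(n, 0, L); y <- runif(n, 0, L)
    if (np > 0) {
      for (it in 1:50) {
        dmin <- rep(Inf, n)
        for (p in seq_len(np)) {
          dx <- x - pstate$cx[p]; dy <- y - pstate$cy[p]
          dx <- dx - L * round(dx / L); dy <- dy - L * round(dy / L)
          dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
        }
        bad <- dmin < 1.7
        if (!any(bad)) break
        x[bad] <- runif(sum(bad), 0, L); y[bad] <- runif(sum(bad), 0, L)
      }
    }
    cbind(x, y)
  }
  xy <- place(n_lip)

  flip_capable <- species %in% sp_tab$species[sp_tab$flip_capable]
  templates <- list(inactive = protein_template("inactive"),
                    active = protein_template("active"))
  centers <- bias_centers(pstate, templates, params$order_bias, np)
  fld <- order_field_mu(xy[, 1], xy[, 2], centers, params$order_baseline,
                        params$order_corr_length, box)
  chi <- pmin(pmax(rnorm(n_lip, fld$mu, params$order_sd), 0.02), pi / 2 - 0.02)
  chi[flip_capable] <- pmin(pmax(rnorm(sum(flip_capable), 0.3, 0.1), 0.02),
                            pi / 2 - 0.02)

  lstate <- list(
    x = xy[, 1], y = xy[, 2], leaf = leaf, species = species,
    chi = chi, phi = runif(n_lip, -pi, pi),
    flip_capable = flip_capable, depth = ref_depth(species),
    transit = integer(n_lip), z_from = numeric(n_lip), z_to = numeric(n_lip),
    z_rel = numeric(n_lip)
  )
  lstate$z_rel <- ifelse(flip_capable, leaf * lstate$depth,
                         leaf * (1.2 + 0.5 * cos(chi)))

  # ---- bonds (initially from initial_dimers)
  bonds <- tibble(i = integer(), j = integer(), interface = integer(),
                  since = integer())
  if (!is.null(params$initial_dimers) && nrow(params$initial_dimers)) {
    for (r in seq_len(nrow(params$initial_dimers))) {
      di <- params$initial_dimers$i[r]; dj <- params$initial_dimers$j[r]
      k <- params$initial_dimers$interface[r]
      iface <- params$interfaces[k, ]
      th <- pstate$psi[di] - iface$alpha0
      pstate$cx[dj] <- (pstate$cx[di] + iface$com_dist * cos(th)) %% L
      pstate$cy[dj] <- (pstate$cy[di] + iface$com_dist * sin(th)) %% L
      pstate$psi[dj] <- th + pi + iface$beta0
      bonds <- bind_rows(bonds, tibble(i = di, j = dj, interface = k,
                                       since = 1L))
    }
  }

  topology <- build_topology(lstate, pstate, box, templates)
  layout <- build_layout(topology, lstate)
  state <- list(lipids = lstate, proteins = pstate, bonds = bonds,
                templates = templates, layout = layout)
  frame0 <- assemble_coords(topology, state, params)
  structure(list(topology = topology, frame0 = frame0, state = state,
                 params = params),
            class = "cg_system")
}

# bead table for the current system
build_topology <- function(lstate, pstate, box, templates) {
  n_lip <- length(lstate$x)
  lip_rows <- lapply(unique(lstate$species), function(s) {
    tpl <- lipid_bead_template(s)
    tpl$is_ref <- tpl$role == "sterol-hydroxyl" |
      (tpl$role == "linker" & !duplicated(tpl$role))
    te <- cumsum(tpl$role == "tail-end")
    tpl$tail <- ifelse(tpl$role == "tail-end", te, NA_integer_)
    mols <- which(lstate$species == s)
    k <- nrow(tpl)
    out <- tpl[rep(seq_len(k), times = length(mols)), ]
    out$kind <- "lipid"
    out$mol_id <- rep(mols, each = k)
    out$species <- s
    out$leaflet <- rep(ifelse(lstate$leaf[mols] > 0, "upper", "lower"),
                       each = k)
    out$protein_id <- NA_integer_
    out$conformation <- NA_character_
    out$residue <- NA_integer_
    out$helix <- NA_character_
    out
  })
  beads <- bind_rows(lip_rows) |> arrange(.data$mol_id)
  np <- length(pstate$cx)
  if (np > 0) {
    prot_rows <- lapply(seq_len(np), function(p) {
      tpl <- templates[[pstate$conf[p]]]
      bind_rows(
        tibble(bead = "BB", role = "backbone", residue = tpl$residue,
               helix = tpl$helix),
        tibble(bead = "SC1", role = "sidechain", residue = tpl$residue,
               helix = tpl$helix)
      ) |>
        mutate(kind = "protein", mol_id = n_lip + p, species = NA_character_,
               is_ref = FALSE, tail = NA_integer_, leaflet = NA_character_,
               protein_id = p, conformation = pstate$conf[p])
    })
    beads <- bind_rows(beads, bind_rows(prot_rows))
  }
  beads$bead_id <- seq_len(nrow(beads))
  proteins <- tibble(protein_id = seq_len(np), conformation = pstate$conf)
  cg_topology(beads = beads, proteins = proteins, box = box)
}

# precomputed index vectors for fast per-frame coordinate assembly
build_layout <- function(topology, lstate) {
  b <- topology$beads
  lip <- b$kind == "lipid"
  role_code <- integer(nrow(b))
  role_code[lip & b$is_ref] <- 1L
  role_code[lip & b$role == "headgroup"] <- 2L
  role_code[lip & b$role == "linker" & !b$is_ref] <- 3L
  role_code[lip & b$role == "tail-end" & !is.na(b$tail) & b$tail == 1L] <- 4L
  role_code[lip & b$role == "tail-end" & !is.na(b$tail) & b$tail == 2L] <- 5L
  tail_len <- ifelse(lip & b$species == "CHOL", 1.0, 1.4)
  list(lip = which(lip), mol = b$mol_id[lip], role = role_code[lip],
       tail_len = tail_len[lip],
       prot_rows = lapply(seq_len(nrow(topology$proteins)), function(p) {
         which(b$kind == "protein" & b$protein_id == p)
       }))
}

# assemble a coordinate matrix from the generator state
assemble_coords <- function(topology, state, params) {
  box <- topology$box
  midz <- box[3] / 2
  ls <- state$lipids; ps <- state$proteins; ly <- state$layout
  coords <- matrix(0, nrow(topology$beads), 3)

  m <- ly$mol
  xr <- ls$x[m]; yr <- ls$y[m]; zr <- ls$z_rel[m]
  chi <- ls$chi[m]; phi <- ls$phi[m]
  dirz <- ifelse(zr >= 0, -1, 1)       # tails point toward the midplane
  lt <- ly$tail_len
  role <- ly$role
  px <- xr; py <- yr; pz <- midz + zr
  h <- role == 2L
  pz[h] <- pz[h] + 0.35 * sign(zr[h] + 1e-12)
  l2 <- role == 3L
  px[l2] <- px[l2] + 0.25
  for (tl in c(4L, 5L)) {
    tt <- role == tl
    ph <- phi[tt] + if (tl == 5L) 0.7 else 0
    px[tt] <- px[tt] + lt[tt] * sin(chi[tt]) * cos(ph)
    py[tt] <- py[tt] + lt[tt] * sin(chi[tt]) * sin(ph)
    pz[tt] <- pz[tt] + dirz[tt] * lt[tt] * cos(chi[tt])
  }
  coords[ly$lip, ] <- cbind(px %% box[1], py %% box[2], pz)

  np <- length(ps$cx)
  if (np > 0) {
    for (p in seq_len(np)) {
      tpl <- state$templates[[ps$conf[p]]]
      cs <- cos(ps$psi[p]); sn <- sin(ps$psi[p])
      bx <- c(tpl$bb_x, tpl$sc_x); by <- c(tpl$bb_y, tpl$sc_y)
      bz <- c(tpl$bb_z, tpl$sc_z)
      coords[ly$prot_rows[[p]], ] <- cbind(
        (ps$cx[p] + cs * bx - sn * by) %% box[1],
        (ps$cy[p] + sn * bx + cs * by) %% box[2],
        midz + bz)
    }
  }
  coords
}

#' Simulate a synthetic trajectory
#'
#' Evolves the system state frame by frame: lipids take Brownian xy steps
#' and carry a latent order angle relaxing toward the planted field; SM
#' molecules drift down the local mean-order gradient; flip-capable lipids
#' switch leaflets as a telegraph process at the planted rates with a
#' continuous z-path through the midplane; protomers diffuse and rotate
#' rigidly, and pairs whose relative pose falls inside a planted interface
#' window bind and unbind at the planted rates, locking into the exact
#' planted pose while bound.
#'
#' @param system A `cg_system` from [build_system()].
#' @param params The same [membrane_params()] (defaults to
#'   `system$params`).
#' @return List with `trajectory` (a [cg_trajectory()]) and `truth`, the
#'   realized ground truth (class `membrane_truth`): flip-event and dimer
#'   episode tables, the per-lipid order-angle series, and protein pose
#'   series.
#' @export
simulate_membrane <- function(system, params = system$params) {
  stopifnot(inherits(system, "cg_system"))
  nf <- params$n_frames
  if (nf < 1L) abort("simulate_membrane(): zero frames requested")
  set.seed(params$seed + 1L)
  topology <- system$topology
  box <- topology$box
  L <- box[1]
  dt <- params$stride
  ls <- system$state$lipids
  ps <- system$state$proteins
  bonds <- system$state$bonds
  templates <- system$state$templates
  layout <- system$state$layout
  state <- list(lipids = ls, proteins = ps, bonds = bonds,
                templates = templates, layout = layout)

  n_lip <- length(ls$x)
  np <- length(ps$cx)
  coords <- array(NA_real_, c(nrow(topology$beads), 3, nf))
  coords[, , 1] <- assemble_coords(topology, state, params)

  # per-frame flip probabilities per molecule
  pflip <- rep(0, n_lip)
  for (s in names(params$flip_rates)) {
    pflip[ls$species == s] <- 1 - exp(-params$flip_rates[[s]] * dt * 1e-9)
  }
  sig_l <- sqrt(2 * params$d_lipid * dt)
  sig_chi <- params$order_sd * sqrt(2 * params$order_relax * dt)
  K <- params$flip_transit
  is_sm <- ls$species == "SM"

  flips <- list()
  episodes <- list()
  open_ep <- bonds
  store_truth <- (as.numeric(n_lip) * nf) <= 5e6
  chi_series <- if (store_truth) matrix(NA_real_, n_lip, nf) else NULL
  if (store_truth) chi_series[, 1] <- ls$chi
  pose <- list(cx = matrix(NA_real_, max(np, 1L), nf),
               cy = matrix(NA_real_, max(np, 1L), nf),
               psi = matrix(NA_real_, max(np, 1L), nf))
  if (np > 0) {
    pose$cx[, 1] <- ps$cx; pose$cy[, 1] <- ps$cy; pose$psi[, 1] <- ps$psi
  }

  cluster_of <- function(bonds, np) {
    if (np == 0L) return(integer())
    g <- igraph::graph_from_data_frame(
      d = if (nrow(bonds)) bonds[, c("i", "j")] else tibble(i = 1, j = 1)[0, ],
      directed = FALSE,
      vertices = tibble(name = as.character(seq_len(np))))
    comp <- igraph::components(g)$membership
    comp[as.character(seq_len(np))]
  }

  for (f in seq_len(nf)[-1]) {
    # ---- lipid lateral diffusion
    if (params$d_lipid > 0) {
      ls$x <- (ls$x + rnorm(n_lip, 0, sig_l)) %% L
      ls$y <- (ls$y + rnorm(n_lip, 0, sig_l)) %% L
    }
    # ---- order field and chi dynamics
    centers <- bias_centers(ps, templates, params$order_bias, np)
    fld <- order_field_mu(ls$x, ls$y, centers, params$order_baseline,
                          params$order_corr_length, box)
    mu <- fld$mu
    # CHOL relaxes toward upright in the head regions, tilted in the middle
    mu[ls$flip_capable] <- ifelse(abs(ls$z_rel[ls$flip_capable]) < 0.8,
                                  1.2, 0.3)
    if (params$order_relax > 0) {
      ls$chi <- ls$chi + params$order_relax * (mu - ls$chi) * dt +
        rnorm(n_lip, 0, sig_chi)
      ls$chi <- pmin(pmax(ls$chi, 0.02), pi / 2 - 0.02)
      ls$phi <- ls$phi + rnorm(n_lip, 0, 0.4)
    }
    # ---- SM-order coupling: drift toward ordered (low-mu) regions
    if (params$sm_coupling > 0 && any(is_sm)) {
      ls$x[is_sm] <- (ls$x[is_sm] - params$sm_coupling * fld$gx[is_sm] * dt) %% L
      ls$y[is_sm] <- (ls$y[is_sm] - params$sm_coupling * fld$gy[is_sm] * dt) %% L
    }
    # ---- flip-flop telegraph with continuous z-path
    fc <- which(ls$flip_capable)
    if (length(fc)) {
      settled <- fc[ls$transit[fc] == 0L]
      if (length(settled)) {
        fire <- settled[runif(length(settled)) < pflip[settled]]
        if (length(fire)) {
          ls$transit[fire] <- K + 1L
          ls$z_from[fire] <- ls$leaf[fire] * ls$depth[fire]
          ls$z_to[fire] <- -ls$z_from[fire]
        }
      }
      moving <- fc[ls$transit[fc] > 0L]
      if (length(moving)) {
        step <- (K + 2L) - ls$transit[moving]
        ls$z_rel[moving] <- ls$z_from[moving] +
          (ls$z_to[moving] - ls$z_from[moving]) * step / (K + 1L)
        done <- moving[ls$transit[moving] == 1L]
        ls$transit[moving] <- ls$transit[moving] - 1L
        if (length(done)) {
          dirn <- ifelse(ls$leaf[done] > 0, "up-down", "down-up")
          ls$leaf[done] <- -ls$leaf[done]
          ls$z_rel[done] <- ls$leaf[done] * ls$depth[done]
          flips[[length(flips) + 1L]] <- tibble(
            mol_id = done, species = ls$species[done], frame = f,
            direction = dirn)
        }
      }
    }
    # settled non-flipping lipids track the order-thickness coupling
    nonfc <- !ls$flip_capable
    ls$z_rel[nonfc] <- ls$leaf[nonfc] * (1.2 + 0.5 * cos(ls$chi[nonfc]))

    # ---- protein motion
    if (np > 0) {
      comp <- cluster_of(bonds, np)
      for (cl in unique(comp)) {
        mem <- which(comp == cl)
        sig <- sqrt(2 * params$d_protein * dt / length(mem))
        dx <- rnorm(1, 0, sig); dy <- rnorm(1, 0, sig)
        ps$cx[mem] <- (ps$cx[mem] + dx) %% L
        ps$cy[mem] <- (ps$cy[mem] + dy) %% L
        if (length(mem) == 1L && params$d_rot > 0) {
          ps$psi[mem] <- ps$psi[mem] +
            rnorm(1, 0, sqrt(2 * params$d_rot * dt))
        }
      }
      # ---- unbinding
      if (nrow(bonds)) {
        koff <- params$interfaces$k_off[bonds$interface]
        off <- runif(nrow(bonds)) < (1 - exp(-koff * dt))
        if (any(off)) {
          for (r in which(off)) {
            bi <- bonds$i[r]; bj <- bonds$j[r]
            u <- min_image_displacement(
              c(ps$cx[bi], ps$cy[bi], 0), c(ps$cx[bj], ps$cy[bj], 0), box)
            u <- u[1:2] / max(sqrt(sum(u[1:2]^2)), 1e-9)
            ps$cx[bj] <- (ps$cx[bj] + 0.9 * u[1]) %% L
            ps$cy[bj] <- (ps$cy[bj] + 0.9 * u[2]) %% L
            episodes[[length(episodes) + 1L]] <- mutate(
              open_ep[open_ep$i == bi & open_ep$j == bj, ],
              frame_off = f - 1L)
          }
          open_ep <- open_ep[!(paste(open_ep$i, open_ep$j) %in%
                                 paste(bonds$i[off], bonds$j[off])), ]
          bonds <- bonds[!off, ]
        }
      }
      # ---- binding
      comp <- cluster_of(bonds, np)
      deg <- tabulate(c(bonds$i, bonds$j), nbins = np)
      for (bi in seq_len(np - 1L)) {
        for (bj in (bi + 1L):np) {
          if (comp[bi] == comp[bj]) next
          if (deg[bi] >= 2L || deg[bj] >= 1L) next
          d <- min_image_displacement(c(ps$cx[bi], ps$cy[bi], 0),
                                      c(ps$cx[bj], ps$cy[bj], 0), box)
          r <- sqrt(sum(d[1:2]^2))
          ifs <- params$interfaces
          cand <- which(r < ifs$capture & ifs$k_on > 0)
          if (!length(cand)) next
          th <- atan2(d[2], d[1])
          alpha <- wrap_angle(ps$psi[bi] - th)
          beta <- wrap_angle(ps$psi[bj] - th - pi)
          for (k in cand) {
            if (abs(wrap_angle(alpha - ifs$alpha0[k])) > ifs$window[k]) next
            if (abs(wrap_angle(beta - ifs$beta0[k])) > ifs$window[k]) next
            if (runif(1) >= 1 - exp(-ifs$k_on[k] * dt)) next
            # lock into the planted pose without touching protomer bi
            th2 <- ps$psi[bi] - ifs$alpha0[k]
            ps$cx[bj] <- (ps$cx[bi] + ifs$com_dist[k] * cos(th2)) %% L
            ps$cy[bj] <- (ps$cy[bi] + ifs$com_dist[k] * sin(th2)) %% L
            ps$psi[bj] <- th2 + pi + ifs$beta0[k]
            bonds <- bind_rows(bonds, tibble(i = bi, j = bj,
                                             interface = k, since = f))
            open_ep <- bind_rows(open_ep, tibble(i = bi, j = bj,
                                                 interface = k, since = f))
            deg[bi] <- deg[bi] + 1L; deg[bj] <- deg[bj] + 1L
            comp <- cluster_of(bonds, np)
            break
          }
        }
      }
      pose$cx[, f] <- ps$cx; pose$cy[, f] <- ps$cy; pose$psi[, f] <- ps$psi
    }

    state$lipids <- ls; state$proteins <- ps; state$bonds <- bonds
    coords[, , f] <- assemble_coords(topology, state, params)
    if (store_truth) chi_series[, f] <- ls$chi
  }

  if (nrow(open_ep)) {
    episodes[[length(episodes) + 1L]] <- mutate(open_ep, frame_off = nf)
  }
  ep <- if (length(episodes)) bind_rows(episodes) else
    tibble(i = integer(), j = integer(), interface = integer(),
           since = integer(), frame_off = integer())
  ep <- rename(ep, frame_on = "since")

  traj <- cg_trajectory(topology, coords,
                        times = params$stride * (seq_len(nf) - 1),
                        replica = 1L)
  truth <- structure(
    list(params = params,
         flips = if (length(flips)) bind_rows(flips) else
           tibble(mol_id = integer(), species = character(),
                  frame = integer(), direction = character()),
         dimer_episodes = ep,
         chi_series = chi_series,
         pose = if (np > 0) pose else NULL),
    class = "membrane_truth")
  list(trajectory = traj, truth = truth)
}

#' Export ground-truth event tables
#'
#' @param truth A `membrane_truth` from [simulate_membrane()].
#' @return List of tibbles keyed by frame index: `flips` (one row per
#'   leaflet-crossing event) and `dimers` (one row per bound episode with
#'   its planted interface index and frame range).
#' @export
replay_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "membrane_truth"))
  list(flips = truth$flips, dimers = truth$dimer_episodes)
}
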