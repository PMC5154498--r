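#' Per-frame CHOL contact fingerprints
#'
#' For every CHOL molecule and frame: a binary contact vector against the
#' protein residues (ROH bead within `cutoff` of the residue's backbone
#' bead, any protomer) concatenated with a one-hot z-zone indicator
#' (upper head / middle / lower head).
#'
#' @param traj A [cg_trajectory()].
#' @param cutoff Contact cutoff (nm, default 0.7).
#' @param frames Frame indices (default all).
#' @return List with `features` (samples x (residues + 3) 0/1 matrix),
#'   `index` (tibble `mol_id`, `frame`, `zone`), and `residues`.
#' @export
featurize_chol <- function(traj, cutoff = 0.7, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box <- top$box
  ref <- ref_bead_ids(top, species = "CHOL")
  if (!length(ref)) abort("featurize_chol(): no CHOL present")
  mols <- top$beads$mol_id[match(ref, top$beads$bead_id)]
  bb <- top$beads[top$beads$kind == "protein" & top$beads$bead == "BB", ]
  residues <- sort(unique(bb$residue))
  feats <- list()
  idx <- list()
  for (f in frames) {
    cc <- frame_coords(traj, f)
    zr <- cc[ref, 3] - midplane_z(cc, top)
    zone <- z_zone(zr)
    contacts <- matrix(0, length(ref), length(residues))
    if (nrow(bb)) {
      d <- min_image_dist(cc[ref, , drop = FALSE],
                          cc[bb$bead_id, , drop = FALSE], box)
      hit <- d <= cutoff
      if (any(hit)) {
        rescol <- match(bb$residue, residues)
        for (m in which(rowSums(hit) > 0)) {
          contacts[m, unique(rescol[hit[m, ]])] <- 1
        }
      }
    }
    zo <- cbind(zone == 1L, zone == 0L, zone == -1L) + 0
    feats[[length(feats) + 1L]] <- cbind(contacts, zo)
    idx[[length(idx) + 1L]] <- tibble(mol_id = mols, frame = f, zone = zone)
  }
  list(features = do.call(rbind, feats), index = bind_rows(idx),
       residues = residues)
}

#' Build the cholesterol kinetic network
#'
#' Geometric k-means clustering of the contact/zone fingerprints into
#' microstates, a sliding-window transition count matrix at the chosen
#' lag, a detailed-balance-symmetrized maximum-likelihood transition
#' matrix restricted to the largest connected set, and spectral lumping of
#' the microstates into `n_macro` macrostates (k-means on the top right
#' eigenvector components). Microstates visited fewer than 10 times are
#' merged into their nearest retained centroid.
#'
#' @param fingerprints Result of [featurize_chol()].
#' @param n_micro Number of k-means microstates (default 100; capped at
#'   the number of distinct fingerprints).
#' @param lag Lag time in frames (default 5).
#' @param n_macro Number of macrostates (default 8).
#' @param stride Frame stride (ns) used for implied timescales (default 1).
#' @return Object of class `chol_msm`: microstate centers and assignments,
#'   count and transition matrices, stationary distribution, macrostate
#'   partition and coarse matrices, and implied timescales.
#' @export
build_chol_msm <- function(fingerprints, n_micro = 100L, lag = 5L,
                           n_macro = 8L, stride = 1) {
  X <- fingerprints$features
  idx <- fingerprints$index
  uniq <- unique(X)
  k <- min(n_micro, nrow(uniq))
  if (k < 2L) abort("build_chol_msm(): fewer than 2 distinct fingerprints")
  km <- kmeans(X, centers = uniq[sample(nrow(uniq), k), , drop = FALSE],
               iter.max = 50L, nstart = 1L)
  assign <- km$cluster
  # merge sparse microstates into the nearest retained centroid
  cnt <- tabulate(assign, nbins = k)
  keep <- which(cnt >= 10L)
  if (length(keep) < 2L) keep <- order(cnt, decreasing = TRUE)[1:2]
  if (length(keep) < k) {
    lost <- setdiff(seq_len(k), keep)
    for (s in lost) {
      d2 <- colSums((t(km$centers[keep, , drop = FALSE]) -
                       km$centers[s, ])^2)
      assign[assign == s] <- keep[which.min(d2)]
    }
  }
  relab <- match(assign, sort(unique(assign)))
  centers <- km$centers[sort(unique(assign)), , drop = FALSE]
  n <- max(relab)

  # sliding-window transition counts within each molecule
  C <- matrix(0, n, n)
  ord <- order(idx$mol_id, idx$frame)
  s_ord <- relab[ord]
  m_ord <- idx$mol_id[ord]
  from <- s_ord[seq_len(length(s_ord) - lag)]
  to <- s_ord[-seq_len(lag)]
  same <- m_ord[seq_len(length(m_ord) - lag)] == m_ord[-seq_len(lag)]
  for (r in which(same)) C[from[r], to[r]] <- C[from[r], to[r]] + 1
  if (sum(C) == 0) abort("build_chol_msm(): no transitions at this lag")

  # largest connected set on the symmetrized counts
  Cs <- (C + t(C)) / 2
  g <- igraph::graph_from_adjacency_matrix((Cs > 0) + 0, mode = "undirected")
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  if (length(big) < n) {
    warn("build_chol_msm(): disconnected chain; restricting to largest set")
  }
  Cs <- Cs[big, big, drop = FALSE]
  C <- C[big, big, drop = FALSE]
  centers <- centers[big, , drop = FALSE]
  n <- length(big)
  state_of <- rep(NA_integer_, max(relab))
  state_of[big] <- seq_len(n)
  micro <- state_of[relab]

  Tm <- Cs / rowSums(Cs)
  pi_s <- rowSums(Cs) / sum(Cs)

  # spectral decomposition via the pi-symmetrized similarity transform
  Dh <- sqrt(pi_s)
  S <- Tm * outer(Dh, 1 / Dh)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values
  psi <- es$vectors / Dh     # right eigenvectors of Tm, columns
  nm <- min(n_macro, n)
  if (nm < n) {
    Y <- psi[, seq_len(nm), drop = FALSE]
    kmac <- kmeans(Y, centers = nm, iter.max = 100L, nstart = 10L)
    macro_of <- kmac$cluster
  } else {
    macro_of <- seq_len(n)
  }
  Cmac <- rowsum(t(rowsum(Cs, macro_of)), macro_of)
  Tmac <- Cmac / rowSums(Cmac)
  pi_mac <- rowSums(Cmac) / sum(Cmac)

  its <- -lag * stride / log(pmax(pmin(lam[-1], 1 - 1e-12), 1e-12))
  its[lam[-1] <= 0] <- NA_real_

  structure(
    list(centers = centers, micro = micro, index = idx,
         counts = C, transition = Tm, pi = pi_s,
         macro_of = macro_of, macro_transition = Tmac, macro_pi = pi_mac,
         lag = lag, stride = stride, n_macro = nm,
         implied_timescales = its,
         residues = fingerprints$residues),
    class = "chol_msm")
}

#' @export
print.chol_msm <- function(x, ...) {
  cat("<chol_msm> ", nrow(x$transition), " microstates -> ", x$n_macro,
      " macrostates, lag ", x$lag, " frames; slowest timescale ",
      signif(x$implied_timescales[1], 4), " ns\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy macrostate summary of a cholesterol kinetic network
#'
#' @param x A `chol_msm`.
#' @param ... Unused.
#' @return Tibble per macrostate: stationary weight, mean z-zone and mean
#'   residue-contact count of its member microstates (weighted by pi).
#' @method tidy chol_msm
#' @export
tidy.chol_msm <- function(x, ...) {
  nres <- length(x$residues)
  zone_val <- x$centers[, nres + 1] * 1 + x$centers[, nres + 2] * 0 +
    x$centers[, nres + 3] * (-1)
  ncontact <- rowSums(x$centers[, seq_len(nres), drop = FALSE])
  tibble(macrostate = seq_len(x$n_macro)) |>
    mutate(
      pi = as.numeric(x$macro_pi[.data$macrostate]),
      mean_zone = vapply(.data$macrostate, function(m) {
        w <- x$pi[x$macro_of == m]
        sum(w * zone_val[x$macro_of == m]) / sum(w)
      }, numeric(1)),
      mean_contacts = vapply(.data$macrostate, function(m) {
        w <- x$pi[x$macro_of == m]
        sum(w * ncontact[x$macro_of == m]) / sum(w)
      }, numeric(1)))
}

#' @rdname tidy.chol_msm
#' @method glance chol_msm
#' @export
glance.chol_msm <- function(x, ...) {
  tibble(n_micro = nrow(x$transition), n_macro = x$n_macro, lag = x$lag,
         slowest_timescale = x$implied_timescales[1],
         total_counts = sum(x$counts))
}

# protein-free bulk macrostates in the upper/lower leaflets
bulk_macrostates <- function(model) {
  td <- tidy(model)
  up <- td |> filter(.data$mean_zone > 0.5, .data$mean_contacts < 0.5)
  lo <- td |> filter(.data$mean_zone < -0.5, .data$mean_contacts < 0.5)
  if (!nrow(up) || !nrow(lo)) {
    abort("bulk_macrostates(): could not identify bulk leaflet macrostates")
  }
  c(source = up$macrostate[which.max(up$pi)],
    sink = lo$macrostate[which.max(lo$pi)])
}

#' Forward committor probabilities
#'
#' Probability of reaching the sink set before the source set from each
#' state of a Markov chain.
#'
#' @param transition Row-stochastic transition matrix.
#' @param source,sink State indices.
#' @return Numeric committor vector (0 on source, 1 on sink).
#' @export
committor <- function(transition, source, sink) {
  n <- nrow(transition)
  q <- numeric(n)
  q[sink] <- 1
  U <- setdiff(seq_len(n), c(source, sink))
  if (length(U)) {
    A <- diag(length(U)) - transition[U, U, drop = FALSE]
    bvec <- rowSums(transition[U, sink, drop = FALSE])
    q[U] <- solve(A, bvec)
  }
  q
}

#' Reactive flux pathway decomposition
#'
#' Transition-path theory on a kinetic model: forward committors are
#' solved from the transition matrix, the net reactive flux
#' `f_ij = max(0, pi_i (1-q_i) T_ij q_j - pi_j (1-q_j) T_ji q_i)` is
#' assembled, and the top-k pathways are peeled off by iterative
#' bottleneck (widest-path) decomposition.
#'
#' @param model A `chol_msm` (uses the macrostate matrix) or a list with
#'   elements `transition` and `pi`.
#' @param source,sink Macrostate indices; for a `chol_msm` they default to
#'   the protein-free upper- and lower-leaflet bulk macrostates.
#' @param k Maximum number of pathways (default 5).
#' @return Tibble with `rank`, `path` (state sequence as a string),
#'   `flux`, `fraction` (of the total source to sink flux); total flux in
#'   `attr(, "total_flux")`.
#' @export
flux_pathways <- function(model, source = NULL, sink = NULL, k = 5L) {
  if (inherits(model, "chol_msm")) {
    Tm <- model$macro_transition
    pi_s <- model$macro_pi
    if (is.null(source) || is.null(sink)) {
      b <- bulk_macrostates(model)
      source <- source %||% b[["source"]]
      sink <- sink %||% b[["sink"]]
    }
  } else {
    Tm <- model$transition
    pi_s <- model$pi
  }
  if (identical(source, sink)) abort("flux_pathways(): source == sink")
  n <- nrow(Tm)
  qp <- committor(Tm, source, sink)
  qm <- 1 - qp
  F <- outer(pi_s * qm, qp) * Tm - t(outer(pi_s * qm, qp) * Tm)
  F <- pmax(F, 0)
  diag(F) <- 0
  total <- sum(F[source, ])
  paths <- list()
  Fw <- F
  for (r in seq_len(k)) {
    # widest path source -> sink on current flux graph
    width <- rep(-Inf, n)
    width[source] <- Inf
    prev <- rep(NA_integer_, n)
    visited <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which(!visited & width > -Inf)
      if (!length(u)) break
      u <- u[which.max(width[u])]
      visited[u] <- TRUE
      if (u == sink) break
      for (v in which(Fw[u, ] > 0)) {
        w <- min(width[u], Fw[u, v])
        if (w > width[v]) { width[v] <- w; prev[v] <- u }
      }
    }
    if (!is.finite(width[sink]) || width[sink] <= 1e-15) break
    path <- sink
    while (path[1] != source) path <- c(prev[path[1]], path)
    bot <- width[sink]
    for (e in seq_len(length(path) - 1L)) {
      Fw[path[e], path[e + 1L]] <- Fw[path[e], path[e + 1L]] - bot
    }
    paths[[r]] <- tibble(rank = r,
                         path = paste(path, collapse = "->"),
                         flux = bot)
  }
  out <- if (length(paths)) bind_rows(paths) else
    tibble(rank = integer(), path = character(), flux = numeric())
  if (!nrow(out)) warn("flux_pathways(): zero source->sink flux")
  out <- mutate(out, fraction = .data$flux / max(total, 1e-300))
  attr(out, "total_flux") <- total
  out
}
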