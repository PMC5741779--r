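## The static catalytic field. For an aligned substrate (S) / transition
## state (TS) pair, delta_s(r) = -(V_TS(r) - V_S(r)) is the activation-barrier
## lowering produced by a unit positive point charge at r, and an environment
## of point charges {q_i, r_i} changes the barrier by
## Delta = sum_i q_i (V_TS(r_i) - V_S(r_i)),
## the electrostatic leading term of differential transition-state
## stabilization. Negative Delta means catalysis.

#' Bundle an aligned substrate / transition-state pair
#'
#' @param substrate_mol,substrate_mps Substrate-state geometry and multipoles.
#' @param transition_mol,transition_mps Transition-state geometry and
#'   multipoles, **already superposed** into the substrate frame (use
#'   [kabsch_superpose()] + [apply_transform()] first, or pass `pairing` to
#'   align here).
#' @param direction_label Free label, e.g. `"forward"` or `"reverse"`. For a
#'   reverse reaction construct a second pair whose substrate is the opposite
#'   reaction-path endpoint; do not sign-flip the forward field (the two
#'   agree only when both wells share one TS geometry).
#' @param pairing If non-`NULL`, a Kabsch superposition of the transition
#'   state onto the substrate is performed over this atom pairing (see
#'   [kabsch_superpose()]) before storing.
#' @return Object of class `reactant_pair` with fields `substrate`,
#'   `transition` (each `list(mol, mps)`), `direction_label`, `transform`
#'   (the recorded superposition, identity if pre-aligned) and `align_rmsd`.
#' @export
reactant_pair <- function(substrate_mol, substrate_mps,
                          transition_mol, transition_mps,
                          direction_label = "forward", pairing = NULL) {
  stopifnot(inherits(substrate_mol, "molecule"),
            inherits(substrate_mps, "multipole_set"),
            inherits(transition_mol, "molecule"),
            inherits(transition_mps, "multipole_set"))
  if (length(substrate_mps$q) != n_atoms(substrate_mol) ||
      length(transition_mps$q) != n_atoms(transition_mol))
    stop("multipole set / molecule atom-count mismatch")
  tf <- rigid_transform()
  arms <- NA_real_
  if (!is.null(pairing)) {
    fit <- kabsch_superpose(transition_mol, substrate_mol, pairing)
    transition_mol <- apply_transform(transition_mol, fit$transform)
    tf <- fit$transform
    arms <- fit$rmsd
  }
  structure(list(substrate = list(mol = substrate_mol, mps = substrate_mps),
                 transition = list(mol = transition_mol, mps = transition_mps),
                 direction_label = as.character(direction_label)[1],
                 transform = tf, align_rmsd = arms),
            class = "reactant_pair")
}

#' @export
print.reactant_pair <- function(x, ...) {
  cat(sprintf("<reactant_pair> %s: S %d atoms (order %d), TS %d atoms (order %d)\n",
              x$direction_label, n_atoms(x$substrate$mol), x$substrate$mps$order,
              n_atoms(x$transition$mol), x$transition$mps$order))
  invisible(x)
}

.empty_probes <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             site_index = integer(0), site_label = character(0),
             kind = character(0), stringsAsFactors = FALSE)
}

#' Place bond-directed probe points at hydrogen substitution sites
#'
#' For each candidate substitution site (a hydrogen atom) a probe is placed
#' at `distance` Å beyond the hydrogen along the heavy-atom→H bond vector —
#' roughly where a substituent's charge centre would sit. The 1.5 Å default
#' matches the standard probe offset for substitution-site fields.
#'
#' @param mol A [molecule()] (the substrate-frame geometry).
#' @param site_indices 1-based indices of hydrogen atoms.
#' @param distance Probe offset from the hydrogen, Å (default 1.5).
#' @return Data frame of probes: `x,y,z` (Å), `site_index`, `site_label`,
#'   `kind = "bond_directed"`.
#' @export
place_bond_probes <- function(mol, site_indices, distance = 1.5) {
  stopifnot(inherits(mol, "molecule"))
  site_indices <- as.integer(site_indices)
  if (!length(site_indices)) return(.empty_probes())
  if (any(site_indices < 1L | site_indices > n_atoms(mol)))
    stop("site index out of bounds")
  out <- .empty_probes()
  heavy <- which(mol$elements != "H")
  for (i in site_indices) {
    if (mol$elements[i] != "H")
      stop(sprintf("site %d is %s, not a hydrogen", i, mol$elements[i]))
    dvec <- sweep(mol$xyz[heavy, , drop = FALSE], 2, mol$xyz[i, ])
    dd <- sqrt(rowSums(dvec^2))
    nb <- heavy[dd <= 1.3]
    if (length(nb) != 1L)
      stop(sprintf("site %d has %d heavy-atom neighbours within 1.3 Å (need exactly 1)",
                   i, length(nb)))
    u <- mol$xyz[i, ] - mol$xyz[nb, ]
    u <- u / sqrt(sum(u^2))
    p <- mol$xyz[i, ] + distance * u
    lab <- if (!is.null(mol$labels)) mol$labels[i] else as.character(i)
    out <- rbind(out, data.frame(x = p[1], y = p[2], z = p[3],
                                 site_index = i, site_label = lab,
                                 kind = "bond_directed",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# Deterministic Fibonacci spherical lattice: n unit vectors, well spread.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Place probe points on the solvent-accessible surface
#'
#' Samples each atom's sphere of radius `r_vdW + probe_radius` with a
#' deterministic Fibonacci lattice and keeps only points outside every other
#' atom's enlarged sphere — the solvent-accessible surface traced by a probe
#' of the given radius rolling on the van der Waals envelope. Buried atoms
#' contribute no points.
#'
#' @param mol A [molecule()]; every element must have a Bondi radius
#'   ([vdw_radii()]).
#' @param probe_radius Solvent probe radius, Å (default 1.4, water).
#' @param density Target point density, points per Å² of sphere area
#'   (default 1.0).
#' @return Data frame of probes: `x,y,z` (Å), `site_index = NA`,
#'   `site_label` (`"surf_<atom>_<k>"`), `kind = "surface"`, plus an `atom`
#'   column recording the parent atom index.
#' @export
place_surface_probes <- function(mol, probe_radius = 1.4, density = 1.0) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  if (n == 0L) stop("empty molecule")
  radii <- unname(.BONDI_RADII[mol$elements]) + probe_radius
  res <- vector("list", n)
  for (a in seq_len(n)) {
    npts <- max(1L, as.integer(round(density * 4 * pi * radii[a]^2)))
    pts <- sweep(.fibonacci_sphere(npts) * radii[a], 2, mol$xyz[a, ], `+`)
    keep <- rep(TRUE, npts)
    for (b in seq_len(n)[-a]) {
      db <- sqrt(rowSums(sweep(pts, 2, mol$xyz[b, ])^2))
      keep <- keep & (db > radii[b] - 1e-6)
      if (!any(keep)) break
    }
    if (any(keep)) {
      pts <- pts[keep, , drop = FALSE]
      res[[a]] <- data.frame(
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        site_index = NA_integer_,
        site_label = sprintf("surf_%d_%d", a, seq_len(nrow(pts))),
        kind = "surface", atom = a, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- cbind(.empty_probes(), atom = integer(0))
  rownames(out) <- NULL
  out
}

#' Compute the static catalytic field at probe points
#'
#' Evaluates V_S and V_TS at each probe and returns
#' `delta_s = -(V_TS - V_S)`: the activation-barrier lowering (kcal mol^-1)
#' produced by a unit positive point charge at that probe. Positive delta_s
#' means a +1 e charge there is catalytic; a -1 e charge is catalytic where
#' delta_s is negative.
#'
#' @param pair A [reactant_pair()] (TS already in the substrate frame).
#' @param probes Probe data frame from [place_bond_probes()] /
#'   [place_surface_probes()], or any data frame with `x,y,z` columns in Å.
#' @param order Multipole truncation order; defaults to the lesser of the
#'   two sets' orders.
#' @return The probe data frame with columns `V_S`, `V_TS`, `delta_s`
#'   appended (kcal mol^-1 e^-1).
#' @export
compute_catalytic_field <- function(pair, probes,
                                    order = min(pair$substrate$mps$order,
                                                pair$transition$mps$order)) {
  stopifnot(inherits(pair, "reactant_pair"), is.data.frame(probes))
  if (!all(c("x", "y", "z") %in% names(probes)))
    stop("probes must have x, y, z columns")
  pts <- as.matrix(probes[, c("x", "y", "z")])
  vs <- potential_on_grid(pair$substrate$mol, pair$substrate$mps, pts, order)$V
  vt <- potential_on_grid(pair$transition$mol, pair$transition$mps, pts, order)$V
  out <- probes
  if (!"site_label" %in% names(out))
    out$site_label <- as.character(seq_len(nrow(out)))
  out$V_S <- vs
  out$V_TS <- vt
  out$delta_s <- -(vt - vs)
  out
}

#' Barrier change from an environment of point charges
#'
#' The additive point-charge estimate of the activation-barrier change caused
#' by a molecular environment:
#' `Delta = sum_i q_i (V_TS(r_i) - V_S(r_i))` in kcal mol^-1. Negative
#' values mean the environment lowers the barrier (catalysis). For a single
#' unit charge this reduces to `-q * delta_s` at that point.
#'
#' @param pair A [reactant_pair()].
#' @param env Data frame of environment charges: columns `x,y,z` (Å) and
#'   `q` (e). Zero rows give `Delta = 0`.
#' @param order Multipole truncation order (default as in
#'   [compute_catalytic_field()]).
#' @return Barrier change Delta in kcal mol^-1.
#' @export
environment_barrier_change <- function(pair, env,
                                       order = min(pair$substrate$mps$order,
                                                   pair$transition$mps$order)) {
  stopifnot(inherits(pair, "reactant_pair"), is.data.frame(env))
  if (nrow(env) == 0L) return(0)
  if (!all(c("x", "y", "z", "q") %in% names(env)))
    stop("env must have x, y, z, q columns")
  if (any(!is.finite(env$q))) stop("environment charges must be finite")
  pts <- as.matrix(env[, c("x", "y", "z")])
  vs <- potential_on_grid(pair$substrate$mol, pair$substrate$mps, pts, order)$V
  vt <- potential_on_grid(pair$transition$mol, pair$transition$mps, pts, order)$V
  sum(env$q * (vt - vs))
}
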