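## Molecular electrostatic potential (MEP) from atom-centred multipoles.
## Evaluation is in atomic units: atom->point vectors are converted Å -> bohr,
## the truncated expansion
##   V = sum_a [ q_a/R + mu_a.Rhat/R^2 + sum_ij Theta_ij (3 R_i R_j - R^2 d_ij)/(2 R^5) ]
## is summed (Theta traceless, so the quadrupole term equals
## (3/2) Rhat' Theta Rhat / R^3), and the result is converted to
## kcal mol^-1 e^-1. Vacuum potential: no screening, no periodicity.

.PROXIMITY_GUARD_BOHR <- 0.3

# Core evaluator: points is m x 3 in Å; returns potential in kcal/mol/e.
# The multipole series diverges at the centres, so points inside the 0.3 bohr
# guard raise an error naming the offending atom (and point).
.mep_eval <- function(mol, mps, points, order) {
  m <- nrow(points)
  n <- n_atoms(mol)
  V <- numeric(m)
  pos_b <- mol$xyz * .ANGSTROM_BOHR
  pts_b <- points * .ANGSTROM_BOHR
  use_mu <- order >= 1L
  use_th <- order >= 2L
  for (k in seq_len(m)) {
    Rv <- matrix(pts_b[k, ], n, 3, byrow = TRUE) - pos_b   # atom -> point, n x 3
    R2 <- rowSums(Rv^2)
    R <- sqrt(R2)
    close_i <- which(R <= .PROXIMITY_GUARD_BOHR)
    if (length(close_i))
      stop(sprintf(
        "point %d is %.3f bohr from atom %d (%s): inside the %.1f bohr expansion guard",
        k, R[close_i[1]], close_i[1], mol$elements[close_i[1]],
        .PROXIMITY_GUARD_BOHR))
    v <- sum(mps$q / R)
    if (use_mu)
      v <- v + sum(rowSums(mps$mu * Rv) / (R2 * R))
    if (use_th) {
      th <- mps$theta
      quad <- (th[1, 1, ] * Rv[, 1]^2 + th[2, 2, ] * Rv[, 2]^2 +
               th[3, 3, ] * Rv[, 3]^2 +
               2 * (th[1, 2, ] * Rv[, 1] * Rv[, 2] +
                    th[1, 3, ] * Rv[, 1] * Rv[, 3] +
                    th[2, 3, ] * Rv[, 2] * Rv[, 3]))
      # traceless form: sum_ij Theta_ij (3 R_i R_j - R^2 d_ij) / (2 R^5)
      # = (3/2) * (R' Theta R) / R^5 since trace(Theta) = 0
      v <- v + sum(1.5 * quad / (R2^2 * R))
    }
    V[k] <- v
  }
  V * .HARTREE_KCALMOL
}

#' Electrostatic potential at a single point
#'
#' Evaluates the truncated atom-centred multipole expansion of the molecular
#' electrostatic potential at one point.
#'
#' @param mol A [molecule()] (coordinates in Å).
#' @param mps Its [multipole_set()] (atomic units).
#' @param point Length-3 numeric vector, Å. Must lie more than 0.3 bohr from
#'   every atom centre (the expansion diverges at the centres).
#' @param order Truncation order 0, 1 or 2; defaults to the set's own order.
#' @return Potential in kcal mol^-1 e^-1 (per unit positive probe charge).
#' @examples
#' m <- molecule("H", matrix(c(0, 0, 0), 1))
#' s <- multipole_set(q = 1)
#' potential_at_point(m, s, c(1, 0, 0))   # 332.0637
#' @export
potential_at_point <- function(mol, mps, point, order = mps$order) {
  stopifnot(inherits(mol, "molecule"), inherits(mps, "multipole_set"),
            length(point) == 3L)
  if (length(mps$q) != n_atoms(mol))
    stop("multipole set and molecule have different atom counts")
  .mep_eval(mol, mps, matrix(as.numeric(point), 1, 3), as.integer(order))
}

#' Electrostatic potential at a batch of points
#'
#' Element-wise identical to repeated [potential_at_point()] calls.
#'
#' @inheritParams potential_at_point
#' @param points m x 3 numeric matrix of points in Å (zero rows allowed).
#' @return Data frame with columns `x`, `y`, `z`, `V` (kcal mol^-1 e^-1).
#' @export
potential_on_grid <- function(mol, mps, points, order = mps$order) {
  stopifnot(inherits(mol, "molecule"), inherits(mps, "multipole_set"))
  points <- as.matrix(points)
  if (nrow(points) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      V = numeric(0)))
  if (ncol(points) != 3L) stop("points must be an m x 3 matrix")
  storage.mode(points) <- "double"
  V <- .mep_eval(mol, mps, points, as.integer(order))
  data.frame(x = points[, 1], y = points[, 2], z = points[, 3], V = V)
}

#' Total molecular moments of a multipole set about an origin
#'
#' Diagnostic aggregate of an atomic multipole set: total charge, total
#' dipole and total traceless quadrupole referred to a common origin, with
#' the standard origin-shift terms (atomic dipoles contribute to the total
#' quadrupole, monopoles to both).
#'
#' @inheritParams potential_at_point
#' @param origin Length-3 origin in Å (default the Cartesian origin).
#' @return List with `origin` (Å), `Q` (e), `D` (length-3, e·bohr) and
#'   `Theta` (3 x 3 traceless, e·bohr²).
#' @export
molecular_moments <- function(mol, mps, origin = c(0, 0, 0)) {
  stopifnot(inherits(mol, "molecule"), inherits(mps, "multipole_set"))
  origin <- as.numeric(origin)
  d <- sweep(mol$xyz, 2, origin) * .ANGSTROM_BOHR   # n x 3, bohr
  Q <- sum(mps$q)
  D <- unname(colSums(mps$mu + mps$q * d))
  # quadrupole convention: detraced second moment, theta = sum q (r r' - r^2 I/3),
  # matching the potential formula sum_ij theta_ij (3R_iR_j - R^2 d_ij)/(2R^5)
  Th <- matrix(0, 3, 3)
  n <- n_atoms(mol)
  for (a in seq_len(n)) {
    da <- unname(d[a, ])
    mua <- unname(mps$mu[a, ])
    Th <- Th + mps$theta[, , a] +
      (outer(mua, da) + outer(da, mua)) - (2 / 3) * sum(mua * da) * diag(3) +
      mps$q[a] * (outer(da, da) - (sum(da * da) / 3) * diag(3))
  }
  Th <- Th - (sum(diag(Th)) / 3) * diag(3)   # numerical detrace
  list(origin = origin, Q = Q, D = D, Theta = Th)
}
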