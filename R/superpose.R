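## Rigid-body least-squares superposition (Kabsch) over a chosen atom subset.
## The transition state is conventionally the mobile structure; probe points
## live in the substrate (reference) frame.

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 proper orthogonal matrix (det +1).
#' @param translation Length-3 numeric vector, Å.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthogonal within 1e-8")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation determinant is not +1 within 1e-8 (improper rotation)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% t$translation))
}

# Validate/normalize an atom pairing: a 2-column matrix (mobile, reference)
# of 1-based indices, or NULL meaning identity pairing over all atoms.
as_pairing <- function(pairing, mobile, reference) {
  if (is.null(pairing)) {
    n <- min(n_atoms(mobile), n_atoms(reference))
    pairing <- cbind(seq_len(n), seq_len(n))
  }
  pairing <- as.matrix(pairing)
  if (ncol(pairing) != 2L) stop("pairing must have two columns (mobile, reference)")
  storage.mode(pairing) <- "integer"
  if (any(pairing[, 1] < 1L) || any(pairing[, 1] > n_atoms(mobile)) ||
      any(pairing[, 2] < 1L) || any(pairing[, 2] > n_atoms(reference)))
    stop("pairing indices out of bounds")
  if (anyDuplicated(pairing[, 1]) || anyDuplicated(pairing[, 2]))
    stop("duplicate atom indices in pairing")
  pairing
}

#' Optimal rigid superposition of one structure onto another
#'
#' Finds the rotation + translation minimizing the RMSD between paired atoms
#' (Kabsch algorithm via SVD of the covariance matrix). The reflection branch
#' is corrected by flipping the smallest singular vector when the determinant
#' is negative, so the result is always a proper rotation.
#'
#' @param mobile The [molecule()] to be moved (conventionally the transition
#'   state).
#' @param reference The fixed [molecule()] (conventionally the substrate).
#' @param pairing Two-column matrix of 1-based `(mobile, reference)` atom
#'   index pairs, or `NULL` to pair all atoms by index. At least 3
#'   non-collinear reference atoms are required.
#' @return List with `transform` (a [rigid_transform()] mapping mobile into
#'   the reference frame) and `rmsd` (the minimized RMSD in Å).
#' @export
kabsch_superpose <- function(mobile, reference, pairing = NULL) {
  stopifnot(inherits(mobile, "molecule"), inherits(reference, "molecule"))
  pairing <- as_pairing(pairing, mobile, reference)
  if (nrow(pairing) < 3L)
    stop("degenerate geometry: need at least 3 atom pairs for a unique rotation")
  P <- mobile$xyz[pairing[, 1], , drop = FALSE]
  Q <- reference$xyz[pairing[, 2], , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_ref <- svd(Qc)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    stop("degenerate geometry: reference pairing atoms are collinear")
  H <- crossprod(Pc, Qc)               # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- cq - as.numeric(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd)
}

#' Apply a rigid transform to a molecule
#'
#' Maps every atom position x to `R x + t`; atom order, elements and labels
#' are unchanged.
#'
#' @param mol A [molecule()].
#' @param t A [rigid_transform()].
#' @return The transformed [molecule()].
#' @export
apply_transform <- function(mol, t) {
  stopifnot(inherits(mol, "molecule"), inherits(t, "rigid_transform"))
  xyz <- mol$xyz %*% t(t$rotation)
  xyz <- sweep(xyz, 2, t$translation, `+`)
  out <- mol
  out$xyz <- xyz
  dimnames(out$xyz) <- list(NULL, c("x", "y", "z"))
  out
}

#' Root-mean-square deviation between paired atoms (no alignment)
#'
#' @param a,b Two [molecule()]s.
#' @param pairing Two-column `(a, b)` index matrix, or `NULL` for identity
#'   pairing over `min(n_a, n_b)` atoms.
#' @return RMSD in Å.
#' @export
rmsd <- function(a, b, pairing = NULL) {
  stopifnot(inherits(a, "molecule"), inherits(b, "molecule"))
  pairing <- as_pairing(pairing, a, b)
  if (nrow(pairing) == 0L) stop("empty pairing")
  d <- a$xyz[pairing[, 1], , drop = FALSE] - b$xyz[pairing[, 2], , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}
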