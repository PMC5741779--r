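## Atom-centred multipole sets: the per-atom monopole/dipole/quadrupole
## parameters that generate the molecular electrostatic potential. Units are
## atomic: q in e, mu in e*bohr, theta in e*bohr^2 (Buckingham traceless
## convention). Geometry stays in Å; electrostatics converts internally.

# theta storage: 3 x 3 x n array of symmetric traceless tensors.

.theta_from_cols <- function(df) {
  n <- nrow(df)
  th <- array(0, dim = c(3, 3, n))
  th[1, 1, ] <- df$qxx; th[2, 2, ] <- df$qyy; th[3, 3, ] <- df$qzz
  th[1, 2, ] <- th[2, 1, ] <- df$qxy
  th[1, 3, ] <- th[3, 1, ] <- df$qxz
  th[2, 3, ] <- th[3, 2, ] <- df$qyz
  th
}

detrace_theta <- function(theta) {
  # subtract trace/3 from the diagonal of each 3x3 slice
  tr <- theta[1, 1, ] + theta[2, 2, ] + theta[3, 3, ]
  for (k in 1:3) theta[k, k, ] <- theta[k, k, ] - tr / 3
  theta
}

theta_traces <- function(theta) theta[1, 1, ] + theta[2, 2, ] + theta[3, 3, ]

#' Construct an atomic multipole set
#'
#' Holds per-atom cumulative multipole moments truncated at a chosen order:
#' 0 = monopoles only, 1 = + dipoles, 2 = + traceless quadrupoles.
#'
#' @param q Numeric vector of atomic monopole charges (e).
#' @param mu Optional n x 3 matrix of atomic dipoles (e·bohr).
#' @param theta Optional 3 x 3 x n array of symmetric atomic quadrupoles
#'   (e·bohr²). Must be traceless unless `detrace = TRUE`.
#' @param order Truncation order in 0:2; inferred from the arguments supplied
#'   when `NULL`.
#' @param detrace If `TRUE`, traced quadrupoles are detraced (trace/3
#'   subtracted from the diagonal) instead of rejected.
#' @return An object of class `multipole_set` with fields `order`, `q`, `mu`,
#'   `theta`.
#' @export
multipole_set <- function(q, mu = NULL, theta = NULL, order = NULL,
                          detrace = FALSE) {
  q <- as.numeric(q)
  n <- length(q)
  if (n < 1L) stop("multipole set needs at least one atom")
  if (is.null(order))
    order <- if (!is.null(theta)) 2L else if (!is.null(mu)) 1L else 0L
  order <- as.integer(order)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  if (is.null(mu)) mu <- matrix(0, n, 3)
  mu <- as.matrix(mu); storage.mode(mu) <- "double"
  if (!identical(dim(mu), c(n, 3L)) && !identical(dim(mu), as.integer(c(n, 3))))
    stop("mu must be an n x 3 matrix")
  if (is.null(theta)) theta <- array(0, dim = c(3, 3, n))
  if (!identical(dim(theta), as.integer(c(3, 3, n))))
    stop("theta must be a 3 x 3 x n array")
  storage.mode(theta) <- "double"
  if (any(!is.finite(q)) || any(!is.finite(mu)) || any(!is.finite(theta)))
    stop("multipole entries must be finite")
  if (order < 2L && any(theta != 0))
    stop("theta entries must be zero for order < 2")
  if (order < 1L && any(mu != 0))
    stop("mu entries must be zero for order < 1")
  # symmetry + tracelessness
  for (a in seq_len(n)) {
    if (max(abs(theta[, , a] - t(theta[, , a]))) > 1e-10)
      stop("theta slice ", a, " is not symmetric")
  }
  tr <- theta_traces(theta)
  if (any(abs(tr) > 1e-10)) {
    if (detrace) theta <- detrace_theta(theta)
    else stop(sprintf("quadrupole trace up to %.3e exceeds 1e-10; pass detrace = TRUE",
                      max(abs(tr))))
  }
  structure(list(order = order, q = q, mu = mu, theta = theta),
            class = "multipole_set")
}

#' @export
print.multipole_set <- function(x, ...) {
  cat(sprintf("<multipole_set> order %d, %d atoms, net charge %+.4f e\n",
              x$order, length(x$q), sum(x$q)))
  invisible(x)
}

#' Read a per-atom multipole table (CSV)
#'
#' The table must have a header, a required column `q` (e) and optional
#' columns `mux,muy,muz` (e·bohr) and `qxx,qxy,qxz,qyy,qyz,qzz` (e·bohr²),
#' one row per atom in the order of `mol`. The truncation order is inferred
#' from the columns present. Traced quadrupoles are detraced on load with a
#' warning when |trace| > 1e-8.
#'
#' @param path Path to the CSV file.
#' @param mol The [molecule()] the table parameterizes (used to check the
#'   row count).
#' @return A [multipole_set()].
#' @export
read_multipole_table <- function(path, mol) {
  stopifnot(inherits(mol, "molecule"))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse multipole table '",
                                          path, "': ", conditionMessage(e)))
  if (!"q" %in% names(df)) stop("multipole table must have a 'q' column")
  if (nrow(df) != n_atoms(mol))
    stop(sprintf("multipole table has %d rows but molecule has %d atoms",
                 nrow(df), n_atoms(mol)))
  mu_cols <- c("mux", "muy", "muz")
  th_cols <- c("qxx", "qxy", "qxz", "qyy", "qyz", "qzz")
  has_mu <- all(mu_cols %in% names(df))
  has_th <- all(th_cols %in% names(df))
  num_cols <- c("q", if (has_mu) mu_cols, if (has_th) th_cols)
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d of '%s'",
                   cc, bad[1], path))
    df[[cc]] <- v
  }
  order <- if (has_th) 2L else if (has_mu) 1L else 0L
  mu <- if (has_mu) as.matrix(df[mu_cols]) else NULL
  theta <- NULL
  if (has_th) {
    theta <- .theta_from_cols(df)
    tr <- theta_traces(theta)
    if (any(abs(tr) > 1e-8))
      warning(sprintf("quadrupole trace up to %.3e in '%s'; detracing on load",
                      max(abs(tr)), path))
  }
  multipole_set(df$q, mu = mu, theta = theta, order = order, detrace = TRUE)
}

#' Write a per-atom multipole table (CSV)
#'
#' Inverse of [read_multipole_table()]: emits only the columns the set's
#' order requires, at full double precision.
#'
#' @param mps A [multipole_set()].
#' @param path Output path.
#' @export
write_multipole_table <- function(mps, path) {
  stopifnot(inherits(mps, "multipole_set"))
  df <- data.frame(q = mps$q)
  if (mps$order >= 1L) {
    df$mux <- mps$mu[, 1]; df$muy <- mps$mu[, 2]; df$muz <- mps$mu[, 3]
  }
  if (mps$order >= 2L) {
    df$qxx <- mps$theta[1, 1, ]; df$qxy <- mps$theta[1, 2, ]
    df$qxz <- mps$theta[1, 3, ]; df$qyy <- mps$theta[2, 2, ]
    df$qyz <- mps$theta[2, 3, ]; df$qzz <- mps$theta[3, 3, ]
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
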