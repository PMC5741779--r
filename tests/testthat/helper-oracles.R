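# Independent oracles and small generators shared across the test files.
# Everything here deliberately avoids the package's own evaluation paths:
# potentials are direct Coulomb loops, rotations come from quaternions, the
# brute-force aligner searches rotation space without an SVD.

.k <- catfield::field_constants()

# Direct Coulomb sum (kcal/mol/e) over explicit point charges; xyz in Å.
coulomb_sum <- function(xyz, q, point) {
  d <- sqrt(rowSums(sweep(as.matrix(xyz), 2, point)^2)) * .k$angstrom_to_bohr
  sum(q / d) * .k$hartree_to_kcalmol
}

# Random well-separated molecule for geometry tests (elements all C).
random_test_molecule <- function(n, seed, box = 8, min_sep = 1.0) {
  withr::with_seed(seed, {
    xyz <- matrix(NA_real_, n, 3)
    placed <- 0
    while (placed < n) {
      cand <- runif(3, 0, box)
      if (placed == 0 ||
          min(sqrt(rowSums(sweep(xyz[seq_len(placed), , drop = FALSE],
                                 2, cand)^2))) >= min_sep) {
        placed <- placed + 1
        xyz[placed, ] <- cand
      }
    }
    catfield::molecule(rep("C", n), xyz, name = sprintf("test n=%d", n))
  })
}

# Expand a (molecule, multipole_set) into an explicit finite point-charge
# cluster reproducing q/mu/theta at each centre: the dipole as a +/- pair
# 0.01 bohr either side of the centre, the traceless quadrupole
# (detraced-second-moment convention, theta = sum q (r r' - r^2 I/3)) as
# three +/- pairs along its eigenvectors with charges lambda_k / (2 a^2).
# Returns list(xyz [Å], q [e]).
multipole_charge_cluster <- function(mol, mps, a = 0.01) {
  ab <- .k$angstrom_to_bohr
  ba <- .k$bohr_to_angstrom
  xs <- NULL; qs <- NULL
  for (i in seq_len(catfield::n_atoms(mol))) {
    rb <- mol$xyz[i, ] * ab          # centre in bohr
    xs <- rbind(xs, rb); qs <- c(qs, mps$q[i])
    if (mps$order >= 1) {
      mu <- mps$mu[i, ]
      mabs <- sqrt(sum(mu^2))
      if (mabs > 0) {
        u <- mu / mabs
        qd <- mabs / (2 * a)
        xs <- rbind(xs, rb + a * u, rb - a * u)
        qs <- c(qs, qd, -qd)
      }
    }
    if (mps$order >= 2) {
      eig <- eigen(mps$theta[, , i], symmetric = TRUE)
      for (kk in 1:3) {
        qq <- eig$values[kk] / (2 * a^2)
        v <- eig$vectors[, kk]
        xs <- rbind(xs, rb + a * v, rb - a * v)
        qs <- c(qs, qq, qq)
      }
    }
  }
  list(xyz = xs * ba, q = qs)
}

# Quaternion -> rotation matrix (unit quaternion assumed after normalizing).
quat_to_rot <- function(qt) {
  qt <- qt / sqrt(sum(qt^2))
  w <- qt[1]; x <- qt[2]; y <- qt[3]; z <- qt[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, quat_to_rot(rnorm(4)))
}

# Axis-angle exponential map.
expmap <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Brute-force minimum RMSD over rotations: coarse random-quaternion search
# followed by Nelder-Mead refinement in axis-angle coordinates. Translation
# is eliminated exactly by centroid matching. Independent of the SVD route.
brute_force_min_rmsd <- function(P, Q, n_coarse = 4000, seed = 999) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj_R <- function(R) sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  best <- Inf; bestR <- diag(3)
  withr::with_seed(seed, {
    for (i in seq_len(n_coarse)) {
      R <- quat_to_rot(rnorm(4))
      v <- obj_R(R)
      if (v < best) { best <- v; bestR <- R }
    }
  })
  obj_w <- function(w) obj_R(bestR %*% expmap(w))
  opt <- stats::optim(c(0, 0, 0), obj_w, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 3000))
  opt <- stats::optim(opt$par, obj_w, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 3000))
  min(best, opt$value)
}

# Closed-form OLS (normal equations by direct loops), with/without intercept.
ols_direct <- function(x, y, intercept = TRUE) {
  n <- length(x)
  if (intercept) {
    sx <- 0; sy <- 0; sxx <- 0; sxy <- 0
    for (i in seq_len(n)) {
      sx <- sx + x[i]; sy <- sy + y[i]
      sxx <- sxx + x[i]^2; sxy <- sxy + x[i] * y[i]
    }
    slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
    inter <- (sy - slope * sx) / n
    p <- 2
  } else {
    sxx <- 0; sxy <- 0
    for (i in seq_len(n)) { sxx <- sxx + x[i]^2; sxy <- sxy + x[i] * y[i] }
    slope <- sxy / sxx
    inter <- 0
    p <- 1
  }
  r <- y - slope * x - inter
  rsd <- if (n > p) sqrt(sum(r^2) / (n - p)) else 0
  list(slope = slope, intercept = inter, residual_sd = rsd)
}
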