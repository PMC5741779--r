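## Deterministic synthetic test systems. Point-charge-only fixtures are the
## primary oracle (their potentials are exactly summable by hand); random
## multipole clouds exercise the order-1/2 code paths; the linear dataset
## emulates the field-vs-barrier-change regression structure. All draws go
## through withr::with_seed, so fixtures are pure functions of (spec, seed)
## and never touch global random state.

#' Proton-shift substrate/transition-state pair
#'
#' An abstract single proton transfer: a +1 e proton moving between two
#' anchored -0.5 e acceptor sites (a minimal neutral model of an
#' intramolecular enol↔keto proton shift). The anchors sit at x = 0 and
#' x = `separation`; the substrate and transition-state proton positions are
#' placed symmetrically about the anchor midpoint at
#' x = (separation ∓ shift)/2, so the transition state displaces the proton
#' by `shift` Å toward the acceptor and delta_s vanishes on the
#' perpendicular bisector plane by mirror symmetry. Monopole-only (order 0),
#' deterministic geometry.
#'
#' @param separation Anchor–anchor distance, Å (default 2.5, a typical
#'   donor–acceptor O···O distance in a strong intramolecular H-bond).
#' @param shift Proton displacement from substrate to transition state, Å
#'   (default 0.5, about half the transfer path); must satisfy
#'   `0 <= shift < separation`.
#' @param seed Accepted for interface consistency with the other fixture
#'   generators; the geometry is deterministic and the value is unused.
#' @return A [reactant_pair()] (order-0 multipoles, net charge 0).
#' @export
make_proton_shift_pair <- function(separation = 2.5, shift = 0.5,
                                   seed = NULL) {
  separation <- as.numeric(separation); shift <- as.numeric(shift)
  if (!is.finite(separation) || separation <= 0.4)
    stop("separation must be a positive distance well above the contact limit")
  if (!is.finite(shift) || shift < 0 || shift >= separation)
    stop("shift must satisfy 0 <= shift < separation")
  xs <- (separation - shift) / 2     # substrate proton x
  xt <- (separation + shift) / 2     # transition-state proton x
  anchors <- rbind(c(0, 0, 0), c(separation, 0, 0))
  s_xyz <- rbind(c(xs, 0, 0), anchors)
  t_xyz <- rbind(c(xt, 0, 0), anchors)
  if (min(xs, separation - xt) < 0.1)
    stop("invalid geometry: proton within 0.1 Å of an anchor")
  q <- c(1, -0.5, -0.5)
  s_mol <- molecule(c("H", "O", "O"), s_xyz, name = "proton_shift substrate",
                    net_charge = 0)
  t_mol <- molecule(c("H", "O", "O"), t_xyz, name = "proton_shift transition",
                    net_charge = 0)
  reactant_pair(s_mol, multipole_set(q), t_mol, multipole_set(q),
                direction_label = "forward")
}

#' Random neutral multipole cloud
#'
#' Atoms placed uniformly in a 6 Å cube with a 1.2 Å minimum separation
#' (rejection sampling); monopoles N(0, 0.3 e) shifted to exact neutrality;
#' for `order >= 1` small random dipoles (N(0, 0.1) e·bohr per component),
#' for `order = 2` small random symmetric quadrupoles (N(0, 0.1) e·bohr²),
#' detraced. Same seed, same output, bitwise.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param order Multipole truncation order 0, 1 or 2.
#' @param seed Integer seed.
#' @return List with `mol` (a [molecule()], carbon atoms) and `mps` (its
#'   [multipole_set()]).
#' @export
make_random_multipole_cloud <- function(n_atoms, order = 0, seed = 1) {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  order <- as.integer(order)
  withr::with_seed(as.integer(seed), {
    xyz <- matrix(NA_real_, n_atoms, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_atoms) {
      if ((tries <- tries + 1L) > 20000L)
        stop("packing failure: could not place ", n_atoms,
             " atoms at >= 1.2 Å separation in a 6 Å box")
      cand <- stats::runif(3, 0, 6)
      if (placed == 0L ||
          min(sqrt(rowSums(sweep(xyz[seq_len(placed), , drop = FALSE],
                                 2, cand)^2))) >= 1.2) {
        placed <- placed + 1L
        xyz[placed, ] <- cand
      }
    }
    q <- stats::rnorm(n_atoms, 0, 0.3)
    q <- q - mean(q)                       # exact neutrality
    mu <- NULL; theta <- NULL
    if (order >= 1L)
      mu <- matrix(stats::rnorm(3 * n_atoms, 0, 0.1), n_atoms, 3)
    if (order >= 2L) {
      theta <- array(0, dim = c(3, 3, n_atoms))
      for (a in seq_len(n_atoms)) {
        m <- matrix(stats::rnorm(9, 0, 0.1), 3, 3)
        theta[, , a] <- (m + t(m)) / 2
      }
      theta <- detrace_theta(theta)
    }
    list(mol = molecule(rep("C", n_atoms), xyz,
                        name = sprintf("random_cloud n=%d order=%d", n_atoms, order)),
         mps = multipole_set(q, mu = mu, theta = theta, order = order))
  })
}

#' Noisy linear field-vs-barrier dataset
#'
#' Emulates the structure of a substitution study: per site, a catalytic
#' field value `delta_s ~ Uniform(-10, 10)` kcal mol^-1 e^-1 and an observed
#' barrier change `slope * delta_s + intercept + N(0, noise_sd)` kcal mol^-1.
#' Defaults are the reference recovery design: 50 sites, slope 0.15 e,
#' intercept 0.5 kcal mol^-1, noise SD 1.0 kcal mol^-1.
#'
#' @param n_sites Number of sites (>= 2).
#' @param slope True slope, e.
#' @param intercept True intercept, kcal mol^-1.
#' @param noise_sd Gaussian noise SD, kcal mol^-1.
#' @param seed Integer seed.
#' @return Substitution-record data frame (labels `"1"..."n"`).
#' @export
make_linear_dataset <- function(n_sites = 50, slope = 0.15, intercept = 0.5,
                                noise_sd = 1.0, seed = 1) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("n_sites must be >= 2")
  withr::with_seed(as.integer(seed), {
    ds <- stats::runif(n_sites, -10, 10)
    obs <- slope * ds + intercept + stats::rnorm(n_sites, 0, noise_sd)
    substitution_records(site_label = as.character(seq_len(n_sites)),
                         site_index = seq_len(n_sites),
                         delta_s = ds, observed_delta = obs)
  })
}
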