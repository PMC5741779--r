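## Molecule container: ordered atoms (element symbol + Cartesian Å), 1-based
## indices fixed by file order. Deliberately minimal -- no bonds, no residues.

# Bondi (1964) van der Waals radii in Å, with the common later extensions
# (H 1.20 per Bondi; Rowland & Taylor's 1.10 is NOT used). Elements absent
# from this table are not recognized by the readers.
.BONDI_RADII <- c(
  H = 1.20, He = 1.40,
  Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54,
  Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  Ar = 1.88,
  K = 2.75, Ca = 2.31, Ga = 1.87, Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85,
  Kr = 2.02,
  Rb = 3.03, Sr = 2.49, In = 1.93, Sn = 2.17, Sb = 2.06, Te = 2.06, I = 1.98,
  Xe = 2.16
)

#' Bondi van der Waals radii bundled with the package
#'
#' @return Named numeric vector of vdW radii in Å (Bondi 1964 with standard
#'   extensions), indexed by element symbol.
#' @export
vdw_radii <- function() .BONDI_RADII

# Normalize an element symbol ("CL", "cl" -> "Cl"); returns NA_character_ if
# the result is not in the bundled radius table.
normalize_element <- function(el) {
  el <- as.character(el)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
  ifelse(el %in% names(.BONDI_RADII), el, NA_character_)
}

#' Construct a molecule
#'
#' An ordered list of atoms with element symbols and Cartesian coordinates in
#' Å. Atom identity is positional: index i always means the i-th atom in file
#' order, matching the 1-based site numbering used for substitution sites.
#'
#' @param elements Character vector of element symbols (case-insensitive;
#'   must have a van der Waals radius in [vdw_radii()]).
#' @param xyz Numeric n x 3 matrix of coordinates in Å.
#' @param name Free-form name (the XYZ comment line on read/write).
#' @param labels Optional character vector of per-atom site tags.
#' @param net_charge Optional integer net charge in e.
#' @return An object of class `molecule` with fields `name`, `elements`,
#'   `xyz`, `labels`, `net_charge`.
#' @details Invariants enforced: all coordinates finite; no two atoms closer
#'   than 0.1 Å (guards corrupt files); recognized element symbols.
#' @export
molecule <- function(elements, xyz, name = "", labels = NULL,
                     net_charge = NULL) {
  if (length(elements) == 0L) xyz <- matrix(numeric(0), nrow = 0, ncol = 3)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != length(elements))
    stop("xyz must be an n x 3 matrix matching length(elements)")
  storage.mode(xyz) <- "double"
  if (nrow(xyz) && any(!is.finite(xyz)))
    stop("all coordinates must be finite")
  norm <- normalize_element(elements)
  if (anyNA(norm))
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(norm)]), collapse = ", "),
         " (no vdW radius in the bundled table)")
  if (nrow(xyz) >= 2L) {
    dmin <- min(stats::dist(xyz))
    if (dmin < 0.1)
      stop(sprintf("atoms closer than 0.1 Å (min distance %.4f); corrupt geometry?",
                   dmin))
  }
  if (!is.null(labels) && length(labels) != length(norm))
    stop("labels must match the number of atoms")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(
    list(name = as.character(name)[1], elements = norm, xyz = xyz,
         labels = if (is.null(labels)) NULL else as.character(labels),
         net_charge = if (is.null(net_charge)) NULL else as.integer(net_charge)),
    class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol A [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  nrow(mol$xyz)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)", n_atoms(x),
              paste(utils::head(x$elements, 8), collapse = " ")))
  invisible(x)
}
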