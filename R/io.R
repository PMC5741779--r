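## Geometry and result I/O. XYZ is the canonical geometry format (count line,
## comment line, "El x y z" rows in Å); PDB is supported as a minimal
## coordinate reader and as the pseudo-atom output for surface field maps.

#' Read a molecule from a standard XYZ file
#'
#' @param path Path to an XYZ file: atom-count line, comment line, then one
#'   `element x y z` row per atom, coordinates in Å.
#' @return A [molecule()] with atoms in file order (1-based indices); the
#'   comment line becomes the molecule name.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0L)
    stop("line 1 of '", path, "': atom count is not a non-negative integer")
  if (length(lines) < n + 2L)
    stop(sprintf("'%s' declares %d atoms but has only %d atom rows (line 1)",
                 path, n, max(0L, length(lines) - 2L)))
  name <- if (length(lines) >= 2L) lines[2] else ""
  if (n == 0L) return(molecule(character(0), NULL, name = name))
  el <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop(sprintf("line %d of '%s': expected 'element x y z'", ln, path))
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v))
      stop(sprintf("line %d of '%s': unparseable coordinates", ln, path))
    if (is.na(normalize_element(tok[1])))
      stop(sprintf("line %d of '%s': unknown element '%s'", ln, path, tok[1]))
    el[i] <- tok[1]; xyz[i, ] <- v
  }
  molecule(el, xyz, name = name)
}

#' Write a molecule to a standard XYZ file
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @details Coordinates are printed with 8 decimals, so read/write
#'   round-trips are lossless well below 1e-6 Å.
#' @export
write_xyz <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  rows <- if (n) sprintf("%-3s %15.8f %15.8f %15.8f", mol$elements,
                         mol$xyz[, 1], mol$xyz[, 2], mol$xyz[, 3])
          else character(0)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(as.character(n), mol$name, rows), con)
  invisible(NULL)
}

#' Minimal PDB coordinate reader
#'
#' Reads only ATOM/HETATM records: element (columns 77-78, falling back to
#' the atom-name field) and Cartesian coordinates. Intended for geometry
#' ingestion only; occupancy, B-factors and connectivity are ignored.
#'
#' @param path Path to a PDB file.
#' @return A [molecule()] in record order.
#' @export
read_pdb_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no ATOM/HETATM records in '", path, "'")
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  el <- trimws(substr(rec, 77, 78))
  fallback <- gsub("[^A-Za-z].*$", "", trimws(substr(rec, 13, 16)))
  el[!nzchar(el)] <- fallback[!nzchar(el)]
  if (anyNA(c(x, y, z))) stop("unparseable coordinates in '", path, "'")
  molecule(el, cbind(x, y, z), name = basename(path))
}

#' Write catalytic-field values to CSV / PDB / cube outputs
#'
#' Writes, for a set of [compute_catalytic_field()] results:
#' * `<stem>.csv` — columns `site_label,x,y,z,V_S,V_TS,delta_s` (6 decimals);
#' * `<stem>.pdb` — for surface probes, HETATM pseudo-atoms (element X)
#'   carrying delta_s in the B-factor column, clamped to ±999.99 (fixed-width
#'   column) with a warning when clamping occurs;
#' * `<stem>.cube` — optionally, a Gaussian cube file when the values lie on
#'   a declared regular grid (`grid` argument); values in kcal mol^-1 e^-1.
#'
#' @param values Data frame of catalytic-field values (from
#'   [compute_catalytic_field()]): columns `site_label`, `x`, `y`, `z`,
#'   `V_S`, `V_TS`, `delta_s`, `kind`.
#' @param stem Output path stem (extensions are appended).
#' @param formats Character subset of `c("csv", "pdb", "cube")`.
#' @param grid For `"cube"`: list with `origin` (Å, length 3), `n` (integer
#'   length 3) and `step` (Å, length 3); `values` must hold `prod(n)` rows in
#'   x-outer / z-inner order matching that grid.
#' @return Invisibly, the paths written.
#' @export
write_field_outputs <- function(values, stem, formats = c("csv", "pdb"),
                                grid = NULL) {
  if (!is.data.frame(values) || nrow(values) == 0L)
    stop("'values' must be a nonempty data frame of catalytic-field values")
  need <- c("site_label", "x", "y", "z", "V_S", "V_TS", "delta_s")
  if (!all(need %in% names(values)))
    stop("values must have columns ", paste(need, collapse = ", "))
  formats <- match.arg(formats, c("csv", "pdb", "cube"), several.ok = TRUE)
  paths <- character(0)

  if ("csv" %in% formats) {
    p <- paste0(stem, ".csv")
    con <- file(p, "w")
    writeLines("site_label,x,y,z,V_S,V_TS,delta_s", con)
    writeLines(sprintf("%s,%.6f,%.6f,%.6f,%.6f,%.6f,%.6f",
                       values$site_label, values$x, values$y, values$z,
                       values$V_S, values$V_TS, values$delta_s), con)
    close(con)
    paths <- c(paths, p)
  }

  if ("pdb" %in% formats) {
    p <- paste0(stem, ".pdb")
    b <- values$delta_s
    if (any(abs(b) > 999.99)) {
      warning("delta_s magnitudes above 999.99 clamped in PDB B-factor column")
      b <- pmax(pmin(b, 999.99), -999.99)
    }
    idx <- seq_len(nrow(values)) %% 100000L
    rec <- sprintf(
      "HETATM%5d  X   PRB A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           X",
      idx, idx %% 10000L, values$x, values$y, values$z, 1.0, b)
    writeLines(c(rec, "END"), p)
    paths <- c(paths, p)
  }

  if ("cube" %in% formats) {
    if (is.null(grid))
      stop("cube output requires a declared regular grid (see 'grid')")
    n <- as.integer(grid$n)
    if (length(n) != 3L || prod(n) != nrow(values))
      stop("grid dimensions do not match the number of values (mixed grid/non-grid input?)")
    p <- paste0(stem, ".cube")
    ab <- .ANGSTROM_BOHR
    con <- file(p, "w")
    writeLines(c("Static catalytic field delta_s",
                 "Values in kcal mol^-1 e^-1; axes in bohr"), con)
    org <- as.numeric(grid$origin) * ab
    stp <- as.numeric(grid$step) * ab
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", 0L, org[1], org[2], org[3]), con)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", n[1], stp[1], 0, 0), con)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", n[2], 0, stp[2], 0), con)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", n[3], 0, 0, stp[3]), con)
    v <- values$delta_s
    # x-outer / z-inner: rows already in that order; emit 6 per line
    for (start in seq(1, length(v), by = 6)) {
      seg <- v[start:min(start + 5, length(v))]
      writeLines(paste(sprintf("%13.5E", seg), collapse = ""), con)
    }
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}
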