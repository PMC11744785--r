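.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr")

element_Z <- function(symbol) {
  z <- match(toupper(symbol), toupper(.element_symbols))
  if (anyNA(z)) stop("unknown element symbol: ",
                     paste(symbol[is.na(z)], collapse = ", "))
  z
}

#' Construct a molecule
#'
#' A molecule is a set of nuclei (positions stored in Bohr), a net charge,
#' and an optional list of classical point charges for QM/MM embedding.
#' The closed-shell electronic-structure drivers require an even electron
#' count; that is validated there, not here, so open-shell fragments can
#' still be used as integral test substrates.
#'
#' @param symbols character vector of element symbols.
#' @param xyz_bohr numeric n x 3 matrix of positions in Bohr.
#' @param charge integer net charge.
#' @param mm data.frame with columns `q, x, y, z` (charge in elementary
#'   units, positions in Bohr), or `NULL`.
#' @return object of class `molecule`.
#' @export
molecule <- function(symbols, xyz_bohr, charge = 0L, mm = NULL) {
  xyz_bohr <- matrix(as.numeric(xyz_bohr), ncol = 3)
  stopifnot(nrow(xyz_bohr) == length(symbols), all(is.finite(xyz_bohr)))
  Z <- element_Z(symbols)
  if (is.null(mm)) mm <- data.frame(q = numeric(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0))
  structure(list(
    atoms = data.frame(symbol = as.character(symbols), Z = Z,
                       x = xyz_bohr[, 1], y = xyz_bohr[, 2], z = xyz_bohr[, 3],
                       stringsAsFactors = FALSE),
    charge = as.integer(charge),
    mm = mm), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, charge %+d, %d electrons, %d MM charges>\n",
              nrow(x$atoms), x$charge, n_electrons(x), nrow(x$mm)))
  invisible(x)
}

#' Number of electrons of a molecule
#' @param mol a `molecule`.
#' @export
n_electrons <- function(mol) sum(mol$atoms$Z) - mol$charge

#' Nuclear coordinates as an n x 3 matrix (Bohr)
#' @param mol a [molecule()].
#' @export
mol_coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` with
#' coordinates in Angstrom (converted to Bohr on read).
#'
#' @param path file path.
#' @param charge net charge to attach (XYZ carries none).
#' @return a [molecule()].
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  if (length(lines) < n + 2L)
    stop("XYZ parse error: count line promises ", n, " atoms but file has ",
         max(0L, length(lines) - 2L), " coordinate lines")
  sym <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    sym[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) stop("XYZ parse error at line ", ln, ": bad coordinate")
    xyz[i, ] <- v
  }
  tryCatch(element_Z(sym),
           error = function(e) stop("XYZ parse error: ", conditionMessage(e)))
  molecule(sym, xyz * BOHR_PER_ANGSTROM, charge = charge)
}

#' Write a molecule to an XYZ file (Angstrom)
#' @param mol a [molecule()].
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, comment = "written by chirospec") {
  xyz <- mol_coords(mol) / BOHR_PER_ANGSTROM
  lines <- c(sprintf("%d", nrow(xyz)), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f",
                     mol$atoms$symbol, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read MM point charges from whitespace text
#'
#' Four columns: charge (elementary units), x, y, z in Angstrom.
#'
#' @param path file path.
#' @return data.frame `q, x, y, z` with positions in Bohr.
#' @export
read_mm_charges <- function(path) {
  tab <- utils::read.table(path, col.names = c("q", "x", "y", "z"))
  tab[, c("x", "y", "z")] <- tab[, c("x", "y", "z")] * BOHR_PER_ANGSTROM
  tab
}

#' Attach MM point charges to a molecule
#' @param mol a [molecule()].
#' @param mm data.frame `q, x, y, z` (Bohr).
#' @export
set_mm_charges <- function(mol, mm) {
  stopifnot(all(c("q", "x", "y", "z") %in% names(mm)))
  mol$mm <- mm[, c("q", "x", "y", "z")]
  mol
}

#' Nuclear repulsion energy (plus nuclei--MM interaction)
#'
#' Classical Coulomb energy of the fixed charges: sum over nuclear pairs
#' plus the interaction of nuclei with MM point charges. The MM--MM
#' self-energy is a constant of the embedding and is excluded.
#'
#' @param mol a [molecule()].
#' @return energy in Hartree.
#' @export
nuclear_repulsion <- function(mol) {
  R <- mol_coords(mol); Z <- mol$atoms$Z
  e <- 0
  n <- nrow(R)
  if (n > 1) for (a in 1:(n - 1)) for (b in (a + 1):n)
    e <- e + Z[a] * Z[b] / sqrt(sum((R[a, ] - R[b, ])^2))
  if (nrow(mol$mm) > 0) {
    M <- as.matrix(mol$mm[, c("x", "y", "z")])
    for (a in seq_len(n)) {
      d <- sqrt(rowSums((M - matrix(R[a, ], nrow(M), 3, byrow = TRUE))^2))
      e <- e + Z[a] * sum(mol$mm$q / d)
    }
  }
  e
}

# deterministic local RNG scope: evaluates expr with the given seed and
# restores the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
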