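# Gaussian basis handling: Gaussian94 parsing, Cartesian AO indexing,
# primitive expansion tables and normalization.

# Cartesian component exponent triples for angular momentum L, in the fixed
# lexicographic convention: s; x,y,z; xx,xy,xz,yy,yz,zz
cart_components <- function(L) {
  out <- matrix(0L, 0, 3)
  for (lx in L:0) for (ly in (L - lx):0)
    out <- rbind(out, c(lx, ly, L - lx - ly))
  out
}

n_cart <- function(L) ((L + 1L) * (L + 2L)) %/% 2L

odd_fact2 <- function(n) { # (2n-1)!! with n >= 0
  vapply(n, function(k) if (k <= 0) 1 else prod(seq(1, 2 * k - 1, by = 2)),
         numeric(1))
}

# normalization of a primitive Cartesian Gaussian x^l y^m z^n exp(-a r^2)
prim_norm <- function(alpha, lmn) {
  L <- sum(lmn)
  (2 * alpha / pi)^0.75 * (4 * alpha)^(L / 2) /
    sqrt(prod(odd_fact2(lmn)))
}

#' Load a Gaussian94-format basis set
#'
#' Parses the Gaussian94 text format. SP (combined s/p) shells are split
#' into separate S and P shells sharing exponents. Coefficients are stored
#' unnormalized as read; normalization is applied in [build_ao_basis()].
#'
#' Shipped fixtures: `"sto-3g"` and `"def2-svp"` (H, He, C, N, O as
#' transcriptions of the standard published parameter sets).
#'
#' @param name_or_path basis name (case-insensitive) or path to a `.gbs` file.
#' @return named list: element symbol -> list of shells, each a list with
#'   `L`, `exponents`, `coefficients`.
#' @export
load_basis <- function(name_or_path) {
  path <- name_or_path
  if (!file.exists(path)) {
    cand <- system.file("extdata", "basis",
                        paste0(tolower(name_or_path), ".gbs"),
                        package = "chirospec")
    if (!nzchar(cand))
      stop("basis set not found: ", name_or_path)
    path <- cand
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  # split into element blocks separated by ****
  blocks <- list(); cur <- character(0)
  for (ln in lines) {
    if (ln == "****") {
      if (length(cur)) { blocks[[length(blocks) + 1L]] <- cur; cur <- character(0) }
    } else cur <- c(cur, ln)
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
  out <- list()
  Lmap <- c(S = 0L, P = 1L, D = 2L)
  for (blk in blocks) {
    hdr <- strsplit(blk[1], "\\s+")[[1]]
    elem <- hdr[1]
    shells <- list()
    i <- 2L
    while (i <= length(blk)) {
      sh <- strsplit(blk[i], "\\s+")[[1]]
      type <- toupper(sh[1]); nprim <- as.integer(sh[2])
      rows <- blk[(i + 1L):(i + nprim)]
      num <- t(vapply(rows, function(r) {
        as.numeric(gsub("[Dd]([+-])", "e\\1",
                        strsplit(r, "\\s+")[[1]]))
      }, numeric(if (type == "SP") 3L else 2L)))
      dimnames(num) <- NULL
      if (type == "SP") {
        shells <- c(shells,
          list(list(L = 0L, exponents = num[, 1], coefficients = num[, 2]),
               list(L = 1L, exponents = num[, 1], coefficients = num[, 3])))
      } else {
        if (!type %in% names(Lmap))
          stop("unsupported shell type '", type, "' (s, p, d only)")
        shells <- c(shells,
          list(list(L = Lmap[[type]], exponents = num[, 1],
                    coefficients = num[, 2])))
      }
      i <- i + nprim + 1L
    }
    out[[elem]] <- shells
  }
  out
}

#' Build the atomic-orbital basis for a molecule
#'
#' Expands the per-element contracted shells onto the molecular geometry,
#' assigns dense contracted Cartesian AO indices, and constructs the
#' primitive expansion table: a sparse matrix `X` (primitive Cartesian
#' functions x contracted AOs) such that a matrix `M_p` over normalized
#' primitives contracts to the contracted-basis matrix `t(X) %*% M_p %*% X`.
#' Every primitive Cartesian component is individually normalized to unit
#' self-overlap, and each contracted AO is scaled to unit self-overlap.
#'
#' @param mol a [molecule()].
#' @param basis result of [load_basis()] (or a basis name).
#' @return object of class `ao_basis`.
#' @export
build_ao_basis <- function(mol, basis) {
  if (is.character(basis)) basis <- load_basis(basis)
  missing <- setdiff(unique(mol$atoms$symbol), names(basis))
  if (length(missing))
    stop("basis lookup error: no shells for element(s) ",
         paste(missing, collapse = ", "))
  shells <- list()       # contracted shells
  prim <- list()         # primitive shells (one exponent each)
  ao_off <- 0L; pao_off <- 0L
  for (a in seq_len(nrow(mol$atoms))) {
    for (sh in basis[[mol$atoms$symbol[a]]]) {
      sid <- length(shells) + 1L
      shells[[sid]] <- list(id = sid, atom = a, L = sh$L,
                            exponents = sh$exponents,
                            coefficients = sh$coefficients,
                            ao_offset = ao_off, ncomp = n_cart(sh$L))
      for (k in seq_along(sh$exponents)) {
        prim[[length(prim) + 1L]] <- list(
          cshell = sid, atom = a, L = sh$L, alpha = sh$exponents[k],
          coef = sh$coefficients[k], pao_offset = pao_off)
        pao_off <- pao_off + n_cart(sh$L)
      }
      ao_off <- ao_off + n_cart(sh$L)
    }
  }
  n_ao <- ao_off; n_pao <- pao_off
  coords <- mol_coords(mol)
  # expansion table with per-component primitive norms and contracted norms
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (sh in shells) {
    comps <- cart_components(sh$L)
    e <- sh$exponents; c0 <- sh$coefficients
    for (cmp in seq_len(nrow(comps))) {
      lmn <- comps[cmp, ]
      Nk <- vapply(e, prim_norm, numeric(1), lmn = lmn)
      # contracted self-overlap for this component
      g <- outer(e, e, "+")
      s_pair <- (pi / g)^1.5 * prod(odd_fact2(lmn)) / (2 * g)^sum(lmn)
      cc <- c0 * Nk
      selfS <- sum(outer(cc, cc) * s_pair)
      scale <- 1 / sqrt(selfS)
      prim_rows <- which(vapply(prim, function(p) p$cshell, integer(1)) == sh$id)
      for (k in seq_along(e)) {
        ii <- c(ii, prim[[prim_rows[k]]]$pao_offset + cmp)
        jj <- c(jj, sh$ao_offset + cmp)
        xx <- c(xx, cc[k] * scale)
      }
    }
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_pao, n_ao))
  prim_df <- data.frame(
    cshell = vapply(prim, `[[`, integer(1), "cshell"),
    atom = vapply(prim, `[[`, integer(1), "atom"),
    L = vapply(prim, `[[`, integer(1), "L"),
    alpha = vapply(prim, `[[`, numeric(1), "alpha"),
    pao_offset = vapply(prim, `[[`, integer(1), "pao_offset"))
  prim_df$x <- coords[prim_df$atom, 1]
  prim_df$y <- coords[prim_df$atom, 2]
  prim_df$z <- coords[prim_df$atom, 3]
  structure(list(
    molecule = mol, shells = shells, prim = prim_df,
    X = X, n_ao = n_ao, n_pao = n_pao), class = "ao_basis")
}

#' @export
print.ao_basis <- function(x, ...) {
  cat(sprintf(
    "<ao_basis: %d contracted Cartesian AOs, %d primitive shells (%d primitive functions)>\n",
    x$n_ao, nrow(x$prim), x$n_pao))
  invisible(x)
}

# contracted shell table as a data frame (one row per shell)
shell_table <- function(ao) {
  data.frame(
    id = vapply(ao$shells, `[[`, integer(1), "id"),
    atom = vapply(ao$shells, `[[`, integer(1), "atom"),
    L = vapply(ao$shells, `[[`, integer(1), "L"),
    ao_offset = vapply(ao$shells, `[[`, integer(1), "ao_offset"),
    ncomp = vapply(ao$shells, `[[`, integer(1), "ncomp"))
}

# contract a primitive-basis matrix to the contracted basis
contract_matrix <- function(ao, Mp) {
  as.matrix(Matrix::t(ao$X) %*% Mp %*% ao$X)
}

# expand a contracted-basis (density) matrix to the primitive basis
expand_matrix <- function(ao, Mc) {
  as.matrix(ao$X %*% Mc %*% Matrix::t(ao$X))
}
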