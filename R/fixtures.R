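# Synthetic molecular fixtures: spherical water droplets for scaling
# experiments and small chiral molecules for nonzero-CD tests.

# rigid water geometry (TIP3P-style): r(OH) = 0.9572 A, HOH = 104.52 deg,
# returned in Bohr with O at the origin, bisector along +z
.water_template <- function() {
  r <- 0.9572 * BOHR_PER_ANGSTROM
  half <- (104.52 / 2) * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = c(r * sin(half), 0, r * cos(half)),
        H2 = c(-r * sin(half), 0, r * cos(half)))
}

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a spherical water droplet
#'
#' Places `n_molecules` rigid waters with random orientations inside the
#' smallest sphere consistent with liquid density (0.997 g/cm^3), enforcing
#' a minimum O--O distance of 2.5 Angstrom. Deterministic for a fixed seed.
#' If insertion stalls, the sphere is inflated in small steps; a generation
#' error is raised after bounded retries.
#'
#' @param n_molecules number of waters (>= 1).
#' @param seed integer RNG seed.
#' @return a [molecule()]; atom count is `3 * n_molecules`.
#' @export
generate_water_droplet <- function(n_molecules, seed = 1L) {
  stopifnot(n_molecules >= 1)
  vol_per_water <- 18.01528 / (0.997 * codata$N_A) * 1e24  # A^3
  radius <- (3 * n_molecules * vol_per_water / (4 * pi))^(1 / 3)  # A
  dmin <- 2.5  # A, minimum O-O separation
  tmpl <- .water_template()
  with_seed(seed, {
    for (attempt in 1:25) {
      centers <- matrix(NA_real_, n_molecules, 3)
      ok <- TRUE
      for (i in seq_len(n_molecules)) {
        placed <- FALSE
        for (try in 1:400) {
          p <- runif(3, -radius, radius)
          if (sum(p^2) > radius^2) next
          if (i == 1 ||
              min(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                           matrix(p, i - 1, 3, byrow = TRUE))^2)) >= dmin^2) {
            centers[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
      radius <- radius * 1.04
    }
    if (!ok) stop("droplet generation error: could not place ", n_molecules,
                  " waters at the requested density")
    sym <- character(0); xyz <- NULL
    for (i in seq_len(n_molecules)) {
      Rm <- .random_rotation()
      block <- tmpl %*% t(Rm) +
        matrix(centers[i, ] * BOHR_PER_ANGSTROM, 3, 3, byrow = TRUE)
      sym <- c(sym, "O", "H", "H")
      xyz <- rbind(xyz, block)
    }
    mol <- molecule(sym, xyz)
    attr(mol, "droplet_radius_angstrom") <- radius
    mol
  })
}

#' Chiral and achiral test molecules
#'
#' `h2o2_P` / `h2o2_M` are hydrogen peroxide at a +112.5 / -112.5 degree
#' H-O-O-H dihedral; the two are exact coordinate-wise mirror images
#' (reflection through the xz plane), giving an enantiomer pair for
#' sign-flip tests of rotatory strengths. `h2o_planar` is an achiral
#' planar water control.
#'
#' @param name one of `"h2o2_P"`, `"h2o2_M"`, `"h2o_planar"`.
#' @return a [molecule()].
#' @export
generate_chiral_fixture <- function(name) {
  ang <- BOHR_PER_ANGSTROM
  if (name == "h2o_planar") {
    tmpl <- .water_template()  # already planar (y = 0)
    return(molecule(c("O", "H", "H"), tmpl))
  }
  if (!name %in% c("h2o2_P", "h2o2_M"))
    stop("unknown fixture name: ", name)
  sgn <- if (name == "h2o2_P") -1 else 1  # sign such that the measured
  # H1-O1-O2-H2 dihedral of the P fixture is +112.5 degrees
  rOO <- 1.45 * ang; rOH <- 0.97 * ang
  theta <- 100 * pi / 180            # O-O-H bond angle
  phi <- sgn * 112.5 * pi / 180      # H-O-O-H dihedral
  O1 <- c(0, 0, 0); O2 <- c(0, 0, rOO)
  # H on O1 at azimuth 0 about the O1->O2 (+z) axis; H on O2 at azimuth phi
  H1 <- O1 + rOH * c(sin(theta), 0, cos(theta))
  H2 <- O2 + rOH * c(sin(theta) * cos(phi), sin(theta) * sin(phi), -cos(theta))
  molecule(c("O", "O", "H", "H"), rbind(O1, O2, H1, H2))
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 3-vectors (any consistent unit).
#' @return signed dihedral in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
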