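# Primitive ERI evaluation (plan-based production path and the
# McMurchie-Davidson recursive reference) and Schwarz screening factors.

#' Boys function F_m(x)
#'
#' Kernel of Gaussian Coulomb integrals, F_m(x) = integral of
#' t^(2m) exp(-x t^2) over t in (0, 1). Evaluated by a three-regime
#' scheme: closed form near zero, downward recursion from a
#' series-evaluated top order for moderate x, asymptotic plus upward
#' recursion for large x.
#'
#' @param m order (non-negative integer).
#' @param x argument(s), >= 0.
#' @return F_m at each x.
#' @export
boys <- function(m, x) {
  stopifnot(m >= 0, m == as.integer(m))
  if (any(x < 0)) stop("Boys function domain error: x must be >= 0")
  boys_cpp(as.integer(m), as.numeric(x))
}

# shell-pair descriptor helper for the quartet-level API
shell_pair <- function(La, Lb, za, zb, A, B)
  list(La = as.integer(La), Lb = as.integer(Lb), za = za, zb = zb,
       A = as.numeric(A), B = as.numeric(B))

#' Primitive-basis ERI class tensor from an unrolled plan
#'
#' Evaluates all Cartesian component quadruples `[ab|cd]` of one primitive
#' shell quartet (unnormalized primitives) through the straight-line plan
#' interpreter.
#'
#' @param bra_pair,ket_pair lists with `La, Lb, za, zb, A, B` (see
#'   `shell_pair`): angular momenta, exponents, centers (Bohr).
#' @param plan optional plan from [eri_plan()]; looked up by class if
#'   omitted.
#' @return 4-d array `[comp_a, comp_b, comp_c, comp_d]`.
#' @export
primitive_eri <- function(bra_pair, ket_pair, plan = NULL) {
  if (is.null(plan))
    plan <- eri_plan(bra_pair$La, bra_pair$Lb, ket_pair$La, ket_pair$Lb)
  stopifnot(bra_pair$za > 0, bra_pair$zb > 0, ket_pair$za > 0, ket_pair$zb > 0)
  v <- plan_eval_cpp(plan,
                     c(bra_pair$za, bra_pair$zb, ket_pair$za, ket_pair$zb),
                     rbind(bra_pair$A, bra_pair$B, ket_pair$A, ket_pair$B),
                     -1.0)
  array(v, dim = rev(plan$dims))  # stored d-fastest -> dims reversed
}

#' Error-function-attenuated primitive ERI class tensor
#'
#' Same as [primitive_eri()] but for the long-range kernel
#' `erf(omega r12)/r12`, implemented by the standard Boys-argument and
#' prefactor modification. Tends to the full ERI as omega grows and to
#' zero as omega tends to 0+.
#'
#' @inheritParams primitive_eri
#' @param omega attenuation parameter (> 0), in 1/Bohr.
#' @export
attenuated_primitive_eri <- function(bra_pair, ket_pair, omega, plan = NULL) {
  stopifnot(omega > 0)
  if (is.null(plan))
    plan <- eri_plan(bra_pair$La, bra_pair$Lb, ket_pair$La, ket_pair$Lb)
  v <- plan_eval_cpp(plan,
                     c(bra_pair$za, bra_pair$zb, ket_pair$za, ket_pair$zb),
                     rbind(bra_pair$A, bra_pair$B, ket_pair$A, ket_pair$B),
                     omega)
  array(v, dim = rev(plan$dims))
}

#' Recursive reference ERI (McMurchie-Davidson)
#'
#' Independent reference evaluator used to validate the unrolled plans:
#' Hermite-Gaussian expansion with recursively built expansion
#' coefficients and Hermite Coulomb integrals.
#'
#' @inheritParams attenuated_primitive_eri
#' @param omega negative for the full kernel, > 0 for erf attenuation.
#' @export
reference_eri <- function(bra_pair, ket_pair, omega = -1) {
  v <- eri_md_cpp(c(bra_pair$La, bra_pair$Lb, ket_pair$La, ket_pair$Lb),
                  c(bra_pair$za, bra_pair$zb, ket_pair$za, ket_pair$zb),
                  rbind(bra_pair$A, bra_pair$B, ket_pair$A, ket_pair$B),
                  omega)
  array(v, dim = rev(c((bra_pair$La + 1) * (bra_pair$La + 2) / 2,
                       (bra_pair$Lb + 1) * (bra_pair$Lb + 2) / 2,
                       (ket_pair$La + 1) * (ket_pair$La + 2) / 2,
                       (ket_pair$Lb + 1) * (ket_pair$Lb + 2) / 2)))
}

# per-primitive-Cartesian-function normalization vector for an ao_basis
prim_norm_vector <- function(ao) {
  out <- numeric(ao$n_pao)
  for (r in seq_len(nrow(ao$prim))) {
    L <- ao$prim$L[r]
    comps <- cart_components(L)
    for (cmp in seq_len(nrow(comps)))
      out[ao$prim$pao_offset[r] + cmp] <-
        prim_norm(ao$prim$alpha[r], comps[cmp, ])
  }
  out
}

# primitive->contracted expansion weight per primitive Cartesian function
# (each primitive function feeds exactly one contracted AO)
prim_weight_vector <- function(ao) {
  Xs <- Matrix::summary(ao$X)
  out <- numeric(ao$n_pao)
  out[Xs$i] <- Xs$x
  out
}

#' Schwarz screening factors
#'
#' Computes `Q = sqrt([mu nu|mu nu])` for every primitive shell pair
#' (maximized over Cartesian components, normalized primitives) plus the
#' exact contracted-basis Schwarz matrix used by the exchange
#' preselection bound. The Cauchy-Schwarz bound
#' `|[mu nu|la si]| <= Q_munu Q_lasi` is exact, not heuristic.
#'
#' @param ao an `ao_basis`.
#' @return list with `pairs` (data.frame `i, j, Q`, sorted descending by
#'   `Q` with ties broken by shell index) and `Qc` (n_ao x n_ao matrix).
#' @export
schwarz_factors <- function(ao) {
  key <- "schwarz"
  cache <- attr(ao, "cache")
  reg <- eri_plan_registry()
  pr <- schwarz_pairs_cpp(ao$prim, prim_norm_vector(ao), reg)
  pairs <- data.frame(i = pr$i, j = pr$j, Q = pr$Q)
  pairs <- pairs[order(-pairs$Q, pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  st <- shell_table(ao)
  Qc <- contracted_schwarz_cpp(ao$prim, prim_weight_vector(ao),
                               ao$prim$cshell, st$ao_offset, ao$n_ao, reg)
  list(pairs = pairs, Qc = Qc)
}
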