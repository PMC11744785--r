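# Unrolled Obara-Saika evaluation plans for primitive electron repulsion
# integrals.  A plan is a straight-line sequence of fused multiply-add
# operations over a flat workspace: slots 1..30 hold quartet geometry
# scalars, slots 31..31+mmax hold the prefactored Boys values
# pref * F_m(T), and every subsequent slot is one recurrence intermediate.
# Plans are generated once per angular-momentum class by symbolically
# unrolling the vertical and horizontal recurrences, cached for the
# session, and evaluated by a compiled interpreter; no intermediate is
# shared between plans, so each class tensor is computed from scratch.

# fixed geometry slot layout (1-based); must match src/planeval.cpp
.slot <- list(one = 1L, oo2p = 2L, oo2q = 3L, oo2pq = 4L, rop = 5L, roq = 6L,
              PA = 7L, PB = 10L, QC = 13L, QD = 16L, WP = 19L, WQ = 22L,
              AB = 25L, CD = 28L)
.NBASE <- 30L

#' Enumerate ERI kernel angular-momentum classes
#'
#' Distinct integral kernels needed for the Coulomb (`[mu nu|la si]`) and
#' exchange (`[mu la|nu si]`) contractions with basis functions up to
#' angular momentum `l_max`. For Coulomb both the bra and ket pairs are
#' unordered; for exchange the output-index pair is unordered while the
#' summed pair takes all ordered combinations. Up to p functions this
#' gives 9 Coulomb and 12 exchange kernels; up to d functions, 36 and 54.
#'
#' @param l_max maximum angular momentum (0, 1 or 2).
#' @param mode `"coulomb"` or `"exchange"`.
#' @return data.frame with columns `La, Lb, Lc, Ld` (one row per kernel).
#' @export
enumerate_kernel_classes <- function(l_max, mode = c("coulomb", "exchange")) {
  mode <- match.arg(mode)
  if (!l_max %in% 0:2) stop("unsupported l_max: ", l_max)
  Ls <- 0:l_max
  pairs_unordered <- do.call(rbind, lapply(Ls, function(a)
    do.call(rbind, lapply(Ls[Ls >= a], function(b) c(a, b)))))
  pairs_ordered <- as.matrix(expand.grid(Lb = Ls, La = Ls))[, c("La", "Lb")]
  if (mode == "coulomb") {
    out <- expand.grid(bra = seq_len(nrow(pairs_unordered)),
                       ket = seq_len(nrow(pairs_unordered)))
    df <- data.frame(La = pairs_unordered[out$bra, 1],
                     Lb = pairs_unordered[out$bra, 2],
                     Lc = pairs_unordered[out$ket, 1],
                     Ld = pairs_unordered[out$ket, 2])
  } else {
    out <- expand.grid(bra = seq_len(nrow(pairs_unordered)),
                       ket = seq_len(nrow(pairs_ordered)))
    df <- data.frame(La = pairs_unordered[out$bra, 1],
                     Lb = pairs_unordered[out$bra, 2],
                     Lc = pairs_ordered[out$ket, 1],
                     Ld = pairs_ordered[out$ket, 2])
  }
  rownames(df) <- NULL
  df[order(df$La, df$Lb, df$Lc, df$Ld), , drop = FALSE]
}

#' Generate the unrolled evaluation plan for one kernel class
#'
#' Unrolls the Obara-Saika vertical recurrence (building `[e0|f0]^(m)`
#' from the Boys function) and the bra/ket horizontal recurrences into a
#' straight-line operation list with one output slot per Cartesian
#' component quadruple. Plans are cached per session.
#'
#' @param La,Lb,Lc,Ld angular momenta of the four shells (each 0..2).
#' @return plan object (list with `ops`, `out_slots`, `nslots`, `mmax`,
#'   `dims`).
#' @export
eri_plan <- function(La, Lb, Lc, Ld) {
  stopifnot(all(c(La, Lb, Lc, Ld) %in% 0:4))
  key <- paste0("plan_", La, Lb, Lc, Ld)
  if (!is.null(.chirospec_cache[[key]])) return(.chirospec_cache[[key]])

  mmax <- La + Lb + Lc + Ld
  nslots <- .NBASE + mmax + 1L
  memo <- new.env(parent = emptyenv(), size = 4096L)
  ops <- matrix(0L, 1024L, 5L)  # out, intcoef, fac1, fac2, src
  nops <- 0L
  emit <- function(out, coef, f1, f2, src) {
    # force all arguments (src may recurse and emit child rows) before
    # claiming a row for this term
    row <- c(out, coef, f1, f2, src)
    if (nops == nrow(ops)) ops <<- rbind(ops, matrix(0L, nrow(ops), 5L))
    nops <<- nops + 1L
    ops[nops, ] <<- row
  }
  new_slot <- function() { nslots <<- nslots + 1L; nslots }
  ei <- function(i) { v <- c(0L, 0L, 0L); v[i] <- 1L; v }

  vrr <- function(a, c, m) {
    if (all(a == 0L) && all(c == 0L)) return(.NBASE + 1L + m)
    key <- paste(c("V", a, c, m), collapse = ",")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- new_slot()
    if (sum(a) > 0L) {
      i <- which(a > 0L)[1]
      a1 <- a - ei(i)
      emit(out, 1L, .slot$PA + i - 1L, .slot$one, vrr(a1, c, m))
      emit(out, 1L, .slot$WP + i - 1L, .slot$one, vrr(a1, c, m + 1L))
      if (a1[i] > 0L) {
        a2 <- a1 - ei(i)
        emit(out, a1[i], .slot$oo2p, .slot$one, vrr(a2, c, m))
        emit(out, -a1[i], .slot$oo2p, .slot$rop, vrr(a2, c, m + 1L))
      }
      if (c[i] > 0L)
        emit(out, c[i], .slot$oo2pq, .slot$one, vrr(a1, c - ei(i), m + 1L))
    } else {
      i <- which(c > 0L)[1]
      c1 <- c - ei(i)
      emit(out, 1L, .slot$QC + i - 1L, .slot$one, vrr(a, c1, m))
      emit(out, 1L, .slot$WQ + i - 1L, .slot$one, vrr(a, c1, m + 1L))
      if (c1[i] > 0L) {
        c2 <- c1 - ei(i)
        emit(out, c1[i], .slot$oo2q, .slot$one, vrr(a, c2, m))
        emit(out, -c1[i], .slot$oo2q, .slot$roq, vrr(a, c2, m + 1L))
      }
      # a is all zero here, so the bra cross term vanishes
    }
    memo[[key]] <- out
    out
  }

  hrr_bra <- function(a, b, c) {
    if (sum(b) == 0L) return(vrr(a, c, 0L))
    key <- paste(c("B", a, b, c), collapse = ",")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    i <- which(b > 0L)[1]
    b1 <- b - ei(i)
    s1 <- hrr_bra(a + ei(i), b1, c)
    s2 <- hrr_bra(a, b1, c)
    out <- new_slot()
    emit(out, 1L, .slot$one, .slot$one, s1)
    emit(out, 1L, .slot$AB + i - 1L, .slot$one, s2)
    memo[[key]] <- out
    out
  }

  hrr_ket <- function(a, b, c, d) {
    if (sum(d) == 0L) return(hrr_bra(a, b, c))
    key <- paste(c("K", a, b, c, d), collapse = ",")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    i <- which(d > 0L)[1]
    d1 <- d - ei(i)
    s1 <- hrr_ket(a, b, c + ei(i), d1)
    s2 <- hrr_ket(a, b, c, d1)
    out <- new_slot()
    emit(out, 1L, .slot$one, .slot$one, s1)
    emit(out, 1L, .slot$CD + i - 1L, .slot$one, s2)
    memo[[key]] <- out
    out
  }

  ca <- cart_components(La); cb <- cart_components(Lb)
  cc_ <- cart_components(Lc); cd <- cart_components(Ld)
  out_slots <- integer(nrow(ca) * nrow(cb) * nrow(cc_) * nrow(cd))
  k <- 0L
  for (ia in seq_len(nrow(ca))) for (ib in seq_len(nrow(cb)))
    for (ic in seq_len(nrow(cc_))) for (id in seq_len(nrow(cd))) {
      k <- k + 1L
      out_slots[k] <- hrr_ket(as.integer(ca[ia, ]), as.integer(cb[ib, ]),
                              as.integer(cc_[ic, ]), as.integer(cd[id, ]))
    }
  plan <- list(ops = ops[seq_len(nops), , drop = FALSE],
               out_slots = out_slots, nslots = nslots, mmax = mmax,
               dims = c(nrow(ca), nrow(cb), nrow(cc_), nrow(cd)),
               L = c(La, Lb, Lc, Ld))
  .chirospec_cache[[key]] <- plan
  plan
}

# class id used on the C++ side: L in base 5, La most significant
.class_id <- function(La, Lb, Lc, Ld) ((La * 5 + Lb) * 5 + Lc) * 5 + Ld + 1L

# registry of all plans up to d functions, as an external pointer consumed
# by the compiled Coulomb/exchange builders
eri_plan_registry <- function() {
  reg <- .chirospec_cache$plan_registry
  if (!is.null(reg)) return(reg)
  plans <- vector("list", 5^4)
  for (La in 0:2) for (Lb in 0:2) for (Lc in 0:2) for (Ld in 0:2)
    plans[[.class_id(La, Lb, Lc, Ld)]] <- eri_plan(La, Lb, Lc, Ld)
  reg <- plan_registry_cpp(plans)
  .chirospec_cache$plan_registry <- reg
  reg
}

#' Dump a plan as JSON (for inspection)
#' @param plan result of [eri_plan()].
#' @param path output file.
#' @export
plan_to_json <- function(plan, path) {
  jsonlite::write_json(
    list(L = plan$L, dims = plan$dims, mmax = plan$mmax,
         nslots = plan$nslots, n_ops = nrow(plan$ops),
         ops = as.data.frame(plan$ops) |>
           setNames(c("out", "coef", "fac1", "fac2", "src")),
         out_slots = plan$out_slots),
    path, auto_unbox = TRUE)
  invisible(path)
}
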