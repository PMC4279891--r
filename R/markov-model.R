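#' @title Stationary first-order Markov model of a two-monomer copolymer
#'
#' @description
#' A PHBV chain is modelled as a stationary two-state Markov chain over the
#' monomer alphabet \{B, V\} (B = 3-hydroxybutyrate, V = 3-hydroxyvalerate).
#' The chain is parameterized by its two free transition probabilities
#' \eqn{p = P(B \to V)} and \eqn{q = P(V \to B)}; the diagonal entries are
#' \eqn{P(B \to B) = 1 - p} and \eqn{P(V \to V) = 1 - q}. Every other
#' sequence statistic (composition, diad/triad fractions, the D selectivity
#' value, block lengths) is derived from \eqn{(p, q)}.
#'
#' @param p Probability that a V follows a B, in \[0, 1\].
#' @param q Probability that a B follows a V, in \[0, 1\].
#'
#' @return An object of class `transition_matrix`: a list with elements
#'   `p` and `q`.
#'
#' @details `p = q = 0` is rejected: such a chain never leaves its initial
#' state and has no unique stationary composition. Boundary values 0 and 1
#' are otherwise accepted by the constructor; operations that are undefined
#' at a boundary ([d_value()], [mean_block_lengths()]) reject them with a
#' specific error.
#'
#' @examples
#' P <- transition_matrix(0.1, 0.3)
#' stationary_composition(P)
#' d_value(P)
#' @export
transition_matrix <- function(p, q) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(q), length(q) == 1L, is.finite(q))
  if (p < 0 || p > 1 || q < 0 || q > 1)
    stop("transition probabilities must lie in [0, 1]; got p = ", p,
         ", q = ", q)
  if (p == 0 && q == 0)
    stop("degenerate chain: p = q = 0 has no stationary composition")
  structure(list(p = unname(p), q = unname(q)), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("First-order Markov copolymer model\n  P(B->V) = %.6g   P(V->B) = %.6g\n",
              x$p, x$q))
  comp <- stationary_composition(x)
  cat(sprintf("  stationary 3HV fraction x_V = %.6g\n", comp[["x_V"]]))
  if (x$p > 0 && x$q > 0)
    cat(sprintf("  D = %.6g\n", d_value(x)))
  invisible(x)
}

as_transition_matrix <- function(P) {
  if (inherits(P, "transition_matrix")) return(P)
  if (is.numeric(P) && length(P) == 2L) return(transition_matrix(P[[1L]], P[[2L]]))
  stop("expected a transition_matrix or a numeric (p, q) pair")
}

#' Stationary monomer composition of the Markov chain
#'
#' @param P A [transition_matrix()].
#' @return Named numeric vector `c(x_B, x_V)` with
#'   \eqn{x_V = p/(p+q)}, \eqn{x_B = q/(p+q)}.
#' @examples
#' stationary_composition(transition_matrix(0.1, 0.3))  # x_V = 0.25
#' @export
stationary_composition <- function(P) {
  P <- as_transition_matrix(P)
  s <- P$p + P$q
  c(x_B = P$q / s, x_V = P$p / s)
}

#' Model diad (two-monomer sequence) mole fractions
#'
#' Fractions of the four overlapping diads under stationarity:
#' \eqn{F_{ij} = x_i P_{ij}}. They sum to one and satisfy
#' \eqn{F_{BV} = F_{VB}} (detailed balance of a two-state chain).
#'
#' @param P A [transition_matrix()].
#' @return Named numeric vector `c(BB, BV, VB, VV)`.
#' @examples
#' diad_fractions(transition_matrix(0.1, 0.3))
#' @export
diad_fractions <- function(P) {
  P <- as_transition_matrix(P)
  x <- stationary_composition(P)
  c(BB = x[["x_B"]] * (1 - P$p),
    BV = x[["x_B"]] * P$p,
    VB = x[["x_V"]] * P$q,
    VV = x[["x_V"]] * (1 - P$q))
}

#' Model triad (three-monomer sequence) mole fractions
#'
#' \eqn{F_{ijk} = x_i P_{ij} P_{jk}} for all eight triads over \{B, V\}.
#' The eight fractions sum to one and marginalize to the diad fractions
#' from either side.
#'
#' @param P A [transition_matrix()].
#' @return Named numeric vector of length 8 with names `BBB, BBV, ..., VVV`.
#' @export
triad_fractions <- function(P) {
  P <- as_transition_matrix(P)
  x <- stationary_composition(P)
  xs <- c(B = x[["x_B"]], V = x[["x_V"]])
  trans <- matrix(c(1 - P$p, P$p, P$q, 1 - P$q), nrow = 2, byrow = TRUE,
                  dimnames = list(c("B", "V"), c("B", "V")))
  labs <- triad_labels()
  out <- vapply(labs, function(l) {
    ijk <- strsplit(l, "")[[1L]]
    xs[[ijk[1L]]] * trans[ijk[1L], ijk[2L]] * trans[ijk[2L], ijk[3L]]
  }, numeric(1L))
  names(out) <- labs
  out
}

diad_labels <- function() c("BB", "BV", "VB", "VV")

triad_labels <- function() {
  m <- expand.grid(k = c("B", "V"), j = c("B", "V"), i = c("B", "V"),
                   stringsAsFactors = FALSE)
  sort(paste0(m$i, m$j, m$k))
}

#' V-centred and B-centred triad label families
#'
#' The 13C NMR carbonyl region resolves triads centred on one monomer type
#' as a family integrated on its own scale; these helpers list the labels.
#'
#' @return Character vector of four triad labels.
#' @export
v_centred_triads <- function() c("BVB", "BVV", "VVB", "VVV")

#' @rdname v_centred_triads
#' @export
b_centred_triads <- function() c("BBB", "BBV", "VBB", "VBV")

#' The D selectivity statistic of the copolymerization
#'
#' \eqn{D = P_{BB} P_{VV} / (P_{BV} P_{VB}) = (1-p)(1-q)/(pq)}.
#' D equals 1 for a Bernoullian (ideally random) chain, exceeds 1 for a
#' blocky chain, and is below 1 for an alternating-leaning chain. By the
#' diad-ratio identity, \eqn{D = F_{BB} F_{VV} / (F_{BV} F_{VB})}, so D is
#' also computable from diad fractions alone.
#'
#' @param P A [transition_matrix()] with `p > 0` and `q > 0`.
#' @return The scalar D value (>= 0).
#' @examples
#' d_value(bernoullian(0.3))           # exactly 1
#' d_value(transition_matrix(0.1, 0.1))  # 81: strongly blocky
#' @export
d_value <- function(P) {
  P <- as_transition_matrix(P)
  if (P$p == 0 || P$q == 0)
    stop("D is infinite: p or q is zero (homopolymer-like blocks never end)")
  (1 - P$p) * (1 - P$q) / (P$p * P$q)
}

#' Number-average block (run) lengths
#'
#' Mean lengths of uninterrupted B-runs and V-runs. Run lengths are
#' geometric, so \eqn{L_B = 1/p} and \eqn{L_V = 1/q}.
#'
#' @param P A [transition_matrix()] with `p > 0` and `q > 0`.
#' @return Named numeric vector `c(L_B, L_V)`.
#' @export
mean_block_lengths <- function(P) {
  P <- as_transition_matrix(P)
  if (P$p == 0 || P$q == 0)
    stop("infinite block length: p or q is zero")
  c(L_B = 1 / P$p, L_V = 1 / P$q)
}

#' Bernoullian (ideally random) reference model
#'
#' The memoryless chain with the given 3HV fraction: `p = x_V`,
#' `q = 1 - x_V`, so that monomer identity is independent of the previous
#' unit and D is exactly 1.
#'
#' @param x_V 3HV mole fraction, strictly in (0, 1).
#' @return A [transition_matrix()].
#' @export
bernoullian <- function(x_V) {
  stopifnot(is.numeric(x_V), length(x_V) == 1L, is.finite(x_V))
  if (x_V <= 0 || x_V >= 1)
    stop("Bernoullian copolymer requires 0 < x_V < 1; got ", x_V)
  transition_matrix(x_V, 1 - x_V)
}

#' Invert (composition, D) to transition probabilities
#'
#' Recovers the unique `(p, q)` whose stationary 3HV fraction is `x_V` and
#' whose selectivity statistic is `D`. Writing \eqn{a = x_B x_V (D - 1)},
#' the common scale factor \eqn{s} (with \eqn{p = x_V s}, \eqn{q = x_B s})
#' solves the quadratic \eqn{a s^2 + s - 1 = 0}; at \eqn{D = 1} the
#' quadratic degenerates and \eqn{s = 1} (the Bernoullian chain), so the
#' Bernoullian branch is taken whenever `|D - 1|` falls below
#' `branch_tol` for continuity.
#'
#' @param x_V 3HV mole fraction, strictly in (0, 1).
#' @param D Target D value, >= 0.
#' @param branch_tol Half-width of the Bernoullian branch around D = 1.
#' @param feas_tol Tolerance when checking `p, q <= 1`: at the alternating
#'   boundary (D -> 0 with x_V near 1/2) floating-point rounding can push
#'   the larger probability a few ulp above 1; values within `feas_tol`
#'   are clamped.
#' @return A [transition_matrix()]; round-trips through
#'   [stationary_composition()] and [d_value()] to ~1e-10.
#' @examples
#' P <- transition_from_composition_and_d(0.23, 1.15)
#' c(stationary_composition(P)[["x_V"]], d_value(P))
#' @export
transition_from_composition_and_d <- function(x_V, D,
                                              branch_tol = 1e-12,
                                              feas_tol = 1e-9) {
  stopifnot(is.numeric(x_V), length(x_V) == 1L, is.finite(x_V),
            is.numeric(D), length(D) == 1L, is.finite(D))
  if (x_V <= 0 || x_V >= 1)
    stop("composition must satisfy 0 < x_V < 1; got ", x_V)
  if (D < 0) stop("D must be non-negative; got ", D)
  x_B <- 1 - x_V
  a <- x_B * x_V * (D - 1)
  s <- if (abs(D - 1) < branch_tol) 1 else (-1 + sqrt(1 + 4 * a)) / (2 * a)
  p <- x_V * s
  q <- x_B * s
  if (p > 1 + feas_tol || q > 1 + feas_tol)
    stop(sprintf(
      "infeasible (x_V = %g, D = %g): implied p = %g, q = %g exceed 1",
      x_V, D, p, q))
  transition_matrix(min(p, 1), min(q, 1))
}
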