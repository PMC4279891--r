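# Monte-Carlo chain simulation and empirical diad/triad counting.
# The simulator is the brute-force oracle for the closed forms in
# markov-model.R: a long simulated chain must reproduce the model's
# diad/triad fractions to within binomial-scale sampling error.

#' Simulate a monomer chain from the Markov model
#'
#' Draws the first monomer from the stationary composition, then each
#' subsequent monomer from the transition row of the previous one, so the
#' chain is stationary from position 1 (no burn-in needed) and the
#' closed-form diad/triad fractions apply directly.
#'
#' @param P A [transition_matrix()] with `p + q > 0`.
#' @param n Chain length (number of monomer units), >= 2.
#' @param seed Optional integer seed; identical `(P, n, seed)` give an
#'   identical chain. The caller's RNG state is left untouched.
#' @return A `monomer_chain`: a single string over \{B, V\} with
#'   attributes `n` and `seed`.
#' @examples
#' simulate_chain(transition_matrix(0.1, 0.3), n = 20, seed = 1)
#' @export
simulate_chain <- function(P, n, seed = NULL) {
  P <- as_transition_matrix(P)
  stopifnot(is.numeric(n), length(n) == 1L, n == round(n))
  if (n < 2) stop("chain length must be >= 2; got ", n)
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  x_V <- stationary_composition(P)[["x_V"]]
  u <- runif(n)
  state <- logical(n)                 # TRUE = V
  state[1L] <- u[1L] < x_V
  # P(next = V | current) = p if current is B, 1 - q if current is V
  pv <- c(P$p, 1 - P$q)
  for (t in 2L:n) state[t] <- u[t] < pv[state[t - 1L] + 1L]
  monomer_chain(paste(ifelse(state, "V", "B"), collapse = ""), seed = seed)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Construct a monomer chain from a string
#'
#' @param sequence A single string over the alphabet \{B, V\}, length >= 2.
#' @param seed Optional integer seed recorded as provenance (absent for
#'   hand-written chains).
#' @return A `monomer_chain` object.
#' @export
monomer_chain <- function(sequence, seed = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2L)
    stop("a monomer chain needs at least 2 units")
  bad <- setdiff(unique(strsplit(sequence, "")[[1L]]), c("B", "V"))
  if (length(bad))
    stop("monomer alphabet is {B, V}; found: ", paste(bad, collapse = ", "))
  structure(sequence, n = nchar(sequence), seed = seed,
            class = "monomer_chain")
}

#' @export
print.monomer_chain <- function(x, ...) {
  n <- attr(x, "n")
  head <- if (n > 60L) paste0(substr(x, 1L, 60L), "...") else unclass(x)
  cat(sprintf("Monomer chain, n = %d: %s\n", n, head))
  invisible(x)
}

chain_states <- function(chain) {
  if (!inherits(chain, "monomer_chain")) chain <- monomer_chain(chain)
  strsplit(unclass(chain), "")[[1L]]
}

#' Empirical diad fractions of a chain
#'
#' Overlapping diads counted along the open (non-cyclic) chain, i.e. over
#' `n - 1` windows, matching a linear polymer.
#'
#' @param chain A `monomer_chain` or a plain \{B,V\} string, length >= 2.
#' @return Named numeric vector `c(BB, BV, VB, VV)` summing to 1.
#' @examples
#' empirical_diads("BBVV")  # 1/3, 1/3, 0, 1/3
#' @export
empirical_diads <- function(chain) {
  s <- chain_states(chain)
  n <- length(s)
  pairs <- paste0(s[-n], s[-1L])
  counts <- table(factor(pairs, levels = diad_labels()))
  f <- as.vector(counts / (n - 1L))
  names(f) <- diad_labels()
  f
}

#' Empirical triad fractions of a chain
#'
#' Overlapping triads over `n - 2` windows of the open chain.
#'
#' @param chain A `monomer_chain` or a plain \{B,V\} string, length >= 3.
#' @return Named numeric vector of the 8 triad fractions, summing to 1.
#' @export
empirical_triads <- function(chain) {
  s <- chain_states(chain)
  n <- length(s)
  if (n < 3L) stop("triad counting needs a chain of length >= 3")
  trips <- paste0(s[1:(n - 2L)], s[2:(n - 1L)], s[3:n])
  counts <- table(factor(trips, levels = triad_labels()))
  f <- as.vector(counts / (n - 2L))
  names(f) <- triad_labels()
  f
}

#' Empirical D value of a chain
#'
#' Applies the diad-ratio identity
#' \eqn{D = F_{BB} F_{VV} / (F_{BV} F_{VB})} to the empirical diad
#' fractions of the chain.
#'
#' @param chain A `monomer_chain` or \{B,V\} string with all four diads
#'   observed at least once.
#' @return The scalar empirical D.
#' @export
empirical_d <- function(chain) {
  f <- empirical_diads(chain)
  zero <- names(f)[f == 0]
  if (length(zero))
    stop("empirical D undefined: diad(s) never observed: ",
         paste(zero, collapse = ", "))
  f[["BB"]] * f[["VV"]] / (f[["BV"]] * f[["VB"]])
}

#' Empirical mean block lengths of a chain
#'
#' Mean lengths of maximal runs of each monomer type, the empirical
#' counterpart of [mean_block_lengths()].
#'
#' @param chain A `monomer_chain` or \{B,V\} string.
#' @return Named numeric vector `c(L_B, L_V)`; `NA` for a type absent
#'   from the chain.
#' @export
empirical_block_lengths <- function(chain) {
  s <- chain_states(chain)
  r <- rle(s)
  c(L_B = mean(r$lengths[r$values == "B"]),
    L_V = mean(r$lengths[r$values == "V"]))
}

#' Read and write monomer chains as FASTA-like text
#'
#' Chains are stored in FASTA format (`> name` header, sequence lines over
#' \{B, V\}). The reader rejects any character outside the monomer
#' alphabet.
#'
#' @param path File path.
#' @return `read_chains()`: a named list of `monomer_chain` objects.
#' @export
read_chains <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  out <- lapply(seqs, function(s) monomer_chain(paste(s, collapse = "")))
  names(out) <- names(seqs)
  out
}

#' @rdname read_chains
#' @param chains A named list of `monomer_chain` objects (or \{B,V\}
#'   strings).
#' @export
write_chains <- function(chains, path) {
  stopifnot(is.list(chains), length(chains) > 0L, !is.null(names(chains)))
  seqs <- lapply(chains, function(ch) chain_states(ch))
  seqinr::write.fasta(seqs, names = names(chains), file.out = path)
  invisible(path)
}
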