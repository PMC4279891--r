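# Synthetic sample panel: model-consistent, optionally noisy, peak tables
# and chains for a set of (composition, D) sample specifications.

#' Default copolymer sample panel
#'
#' Eleven PHBV copolymer samples spanning 5-80 mol% 3HV: seven produced
#' under conditions yielding random sequence distributions (R5-R80) and
#' four putative block copolymers (B12-B50). Each sample is specified by
#' its 3HV mole fraction and its D value. Sample R5 is flagged: its
#' recorded D (12) is far from 1 although the sample is labelled random,
#' most plausibly a typesetting error in the source table; flagged samples
#' are kept as recorded but should be excluded from benchmark-style
#' round-trip checks.
#'
#' @return A data frame with columns `name`, `x_V` (3HV mole fraction),
#'   `D`, `group` (`"random"`/`"block"`), and `flagged` (logical).
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  data.frame(
    name = c("R5", "R14", "R23", "R53", "R60", "R72", "R80",
             "B12", "B19", "B41", "B50"),
    x_V = c(0.05, 0.14, 0.23, 0.53, 0.60, 0.72, 0.80,
            0.12, 0.19, 0.41, 0.50),
    D = c(12, 1.66, 1.15, 1.92, 2.11, 1.84, 1.23,
          14.81, 10.26, 7.92, 5.35),
    group = c(rep("random", 7L), rep("block", 4L)),
    flagged = c(TRUE, rep(FALSE, 10L)),
    stringsAsFactors = FALSE)
}

#' Generate model-consistent peak tables for one sample
#'
#' Inverts the sample's `(x_V, D)` to a transition matrix, emits the exact
#' model fractions as peak intensities for the requested resonance
#' families, and optionally perturbs each intensity by an independent
#' multiplicative factor `(1 + eps)` with `eps ~ Normal(0, cv^2)`
#' (mimicking integration-area error proportional to peak size), clips at
#' zero and renormalizes within each family. The 1H methyl pair
#' `(I_B, I_V)` is perturbed by the same noise model.
#'
#' @param name Sample identifier.
#' @param x_V 3HV mole fraction in (0, 1).
#' @param D D value, >= 0 and feasible for `x_V`.
#' @param cv Coefficient of variation of the multiplicative intensity
#'   noise; 0 gives exact model fractions.
#' @param seed Optional integer seed; output is reproducible.
#' @param families Resonance families to emit (any of `"diad"`,
#'   `"triad_V"`, `"triad_B"`).
#' @param resolved If `TRUE` (default) the diad family is fully resolved
#'   into four peaks; if `FALSE` the BV and VB resonances are merged into
#'   one peak, as in spectra where they overlap.
#' @return A list with elements `peaks` (a `peak_table`), `methyl`
#'   (named vector `c(I_B, I_V)`), and `P` (the generating
#'   [transition_matrix()]).
#' @examples
#' s <- make_sample_tables("R23", x_V = 0.23, D = 1.15)
#' fit_markov(s$peaks)$D_hat  # recovers 1.15
#' @export
make_sample_tables <- function(name, x_V, D, cv = 0, seed = NULL,
                               families = c("diad", "triad_V"),
                               resolved = TRUE) {
  stopifnot(is.numeric(cv), length(cv) == 1L, cv >= 0)
  families <- match.arg(families, c("diad", "triad_V", "triad_B"),
                        several.ok = TRUE)
  P <- transition_from_composition_and_d(x_V, D)
  x <- stationary_composition(P)
  rows <- list()
  for (fam in families) {
    if (fam == "diad") {
      f <- diad_fractions(P)
      if (resolved) {
        rows[[fam]] <- peak_table(name, "diad", paste0("d_", names(f)),
                                  names(f), as.numeric(f))
      } else {
        rows[[fam]] <- peak_table(
          name, "diad", c("d_BB", "d_BV+VB", "d_VV"),
          c("BB", "BV;VB", "VV"),
          c(f[["BB"]], f[["BV"]] + f[["VB"]], f[["VV"]]))
      }
    } else {
      labs <- if (fam == "triad_V") v_centred_triads() else b_centred_triads()
      centre <- if (fam == "triad_V") x[["x_V"]] else x[["x_B"]]
      f <- triad_fractions(P)[labs] / centre
      rows[[fam]] <- peak_table(name, fam, paste0("t_", labs), labs,
                                as.numeric(f))
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  methyl <- c(I_B = x[["x_B"]], I_V = x[["x_V"]])
  if (cv > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    peaks$intensity <- pmax(
      peaks$intensity * (1 + stats::rnorm(nrow(peaks), 0, cv)), 0)
    key <- interaction(peaks$sample_id, peaks$family, drop = TRUE)
    totals <- tapply(peaks$intensity, key, sum)
    peaks$intensity <- peaks$intensity / as.numeric(totals[key])
    methyl <- pmax(methyl * (1 + stats::rnorm(2L, 0, cv)), 0)
    methyl <- methyl / sum(methyl)
  }
  list(peaks = validate_peak_table(peaks), methyl = methyl, P = P)
}

#' Simulate a monomer chain for one sample specification
#'
#' Inverts `(x_V, D)` and draws a stationary Markov chain of `n` monomers.
#'
#' @inheritParams make_sample_tables
#' @param n Chain length, >= 3.
#' @return A `monomer_chain`.
#' @export
make_sample_chain <- function(x_V, D, n, seed = NULL) {
  if (n < 3) stop("sample chains need n >= 3 (triad counting)")
  simulate_chain(transition_from_composition_and_d(x_V, D), n = n,
                 seed = seed)
}

#' Write a full synthetic panel to disk
#'
#' Generates peak-table CSVs (one per sample), optional FASTA chain files,
#' and a YAML manifest recording each sample's name, composition, D and
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param panel A panel data frame as from [default_panel()].
#' @param cv Intensity noise level passed to [make_sample_tables()].
#' @param seed Base integer seed; sample `i` uses `seed + i`.
#' @param families,resolved Passed to [make_sample_tables()].
#' @param chains If `TRUE`, also write a simulated chain per sample.
#' @param chain_n Chain length when `chains = TRUE`.
#' @return Invisibly, the manifest as a list.
#' @export
write_panel <- function(dir, panel = default_panel(), cv = 0, seed = 1,
                        families = c("diad", "triad_V"), resolved = TRUE,
                        chains = FALSE, chain_n = 10000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, noise_cv = cv,
                   families = as.list(families), resolved = resolved,
                   samples = list())
  for (i in seq_len(nrow(panel))) {
    row <- panel[i, ]
    s_seed <- seed + i
    s <- make_sample_tables(row$name, row$x_V, row$D, cv = cv, seed = s_seed,
                            families = families, resolved = resolved)
    write_peak_csv(s$peaks, file.path(dir, paste0(row$name, "_peaks.csv")))
    writeLines(sprintf("I_B,I_V\n%.12g,%.12g", s$methyl[["I_B"]],
                       s$methyl[["I_V"]]),
               file.path(dir, paste0(row$name, "_methyl.csv")))
    if (chains) {
      ch <- make_sample_chain(row$x_V, row$D, n = chain_n, seed = s_seed)
      write_chains(stats::setNames(list(ch), row$name),
                   file.path(dir, paste0(row$name, "_chain.fasta")))
    }
    manifest$samples[[row$name]] <-
      list(name = row$name, x_V = row$x_V, D = row$D, seed = s_seed,
           flagged = isTRUE(row$flagged))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
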