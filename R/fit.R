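# Nonlinear least-squares estimation of the transition probabilities from
# assigned peak intensities, plus classification and a residual bootstrap.
#
# The objective is the unweighted sum over all supplied peaks of squared
# differences between normalized observed fractions and the model's
# predicted fractions. Optimization runs on logit-transformed (p, q) so
# the box (0,1)^2 is handled smoothly, with a Levenberg-Marquardt solver
# (minpack.lm) and deterministic multistart: a Bernoullian start at a
# moment estimate of x_V plus a 5x5 grid; best RSS wins, ties broken by
# smaller |log D|.

logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

P_BOUNDS <- c(1e-6, 1 - 1e-6)

clamp_prob <- function(x) pmin(pmax(x, P_BOUNDS[1L]), P_BOUNDS[2L])

# Moment estimate of x_V from the normalized table: each sequence label
# contributes its V-content; works for merged assignments and any family.
moment_x_v <- function(table) {
  norm <- normalize_peaks(table)
  est_one <- function(block) {
    vfrac <- vapply(strsplit(block$assignment, ";", fixed = TRUE),
                    function(labs) {
                      labs <- trimws(labs)
                      ch <- strsplit(labs, "")
                      mean(vapply(ch, function(x) mean(x == "V"), numeric(1L)))
                    }, numeric(1L))
    sum(block$intensity * vfrac) / sum(block$intensity)
  }
  blocks <- split(norm, norm$family, drop = TRUE)
  # diads report composition directly; triad families are centred and
  # biased toward their centre monomer, so prefer diads when present
  if ("diad" %in% names(blocks)) return(est_one(blocks[["diad"]]))
  mean(vapply(blocks, est_one, numeric(1L)))
}

# Residual function with the peak table parsed once, outside the
# optimizer loop. Within-family normalization makes the V-centred triad
# fractions depend only on q (and the B-centred only on p): conditional on
# the centre monomer, each neighbour is drawn independently from that
# monomer's transition row.
fit_objective <- function(table, observed) {
  fam <- table$family
  labs <- lapply(strsplit(table$assignment, ";", fixed = TRUE), trimws)
  n <- length(fam)
  function(theta) {
    p <- inv_logit(theta[[1L]])
    q <- inv_logit(theta[[2L]])
    x_B <- q / (p + q)
    x_V <- p / (p + q)
    model <- list(
      diad = c(BB = x_B * (1 - p), BV = x_B * p,
               VB = x_V * q, VV = x_V * (1 - q)),
      triad_V = c(BVB = q * q, BVV = q * (1 - q),
                  VVB = (1 - q) * q, VVV = (1 - q)^2),
      triad_B = c(BBB = (1 - p)^2, BBV = (1 - p) * p,
                  VBB = p * (1 - p), VBV = p * p))
    pred <- vapply(seq_len(n),
                   function(i) sum(model[[fam[i]]][labs[[i]]]),
                   numeric(1L))
    pred - observed
  }
}

#' Fit the first-order Markov model to NMR peak intensities
#'
#' Estimates the transition probabilities `(p, q)` by nonlinear least
#' squares on the normalized peak fractions of one sample, then derives
#' the 3HV composition, the D value, and a sequence-distribution class.
#' On noiseless model-generated tables the generating parameters are
#' recovered to ~1e-6.
#'
#' @param tables A `peak_table` (one sample; may contain several families)
#'   or a list of such tables, which are row-bound.
#' @param mode Which families enter the fit: `"joint"` (all supplied),
#'   `"diads"`, or `"triads"`.
#' @param alt_threshold,block_threshold Classification cut-offs passed to
#'   [classify_distribution()].
#' @param n_boot If > 1, a residual bootstrap of this many replicates is
#'   run for a 95% interval on D (see [bootstrap_d()]).
#' @param seed Seed for the bootstrap only; the fit itself is
#'   deterministic.
#' @return A `fit_result` list: `p_hat`, `q_hat`, `x_V_hat`, `D_hat`,
#'   `rss`, `n_peaks`, `classification`, `converged`, `flags`, and
#'   optionally `ci_D`.
#' @examples
#' P <- transition_matrix(0.1, 0.3)
#' tab <- peak_table("S1", "diad", paste0("d", 1:4), diad_labels(),
#'                   diad_fractions(P))
#' fit_markov(tab)$D_hat  # 21
#' @export
fit_markov <- function(tables, mode = c("joint", "diads", "triads"),
                       alt_threshold = 0.5, block_threshold = 3.0,
                       n_boot = 0, seed = NULL) {
  mode <- match.arg(mode)
  table <- bind_tables(tables)
  sample_id <- unique(table$sample_id)
  if (length(sample_id) != 1L)
    stop("fit_markov fits one sample at a time; got: ",
         paste(sample_id, collapse = ", "))
  keep <- switch(mode,
                 joint  = rep(TRUE, nrow(table)),
                 diads  = table$family == "diad",
                 triads = table$family != "diad")
  if (!any(keep)) stop("no peaks left for mode '", mode, "'")
  table <- validate_peak_table(table[keep, , drop = FALSE])
  norm <- normalize_peaks(table)
  observed <- norm$intensity

  flags <- character(0)
  x_V0 <- moment_x_v(norm)
  if (x_V0 < 0.005 || x_V0 > 0.995) {
    # essentially a homopolymer: the Markov parameters (hence D) are
    # unidentifiable, so do not attempt a fit
    return(structure(list(sample_id = sample_id, p_hat = NA_real_,
                          q_hat = NA_real_, x_V_hat = x_V0, D_hat = NA_real_,
                          rss = NA_real_, n_peaks = nrow(norm),
                          classification = "homopolymer", converged = TRUE,
                          flags = "homopolymer"),
                     class = "fit_result"))
  }

  resid_fn <- fit_objective(norm, observed)
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  starts <- rbind(c(clamp_prob(x_V0), clamp_prob(1 - x_V0)),
                  as.matrix(expand.grid(p = grid, q = grid)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = logit(starts[i, ]), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    pq <- clamp_prob(inv_logit(fit$par))
    rss <- sum(resid_fn(logit(pq))^2)
    cand <- list(pq = pq, rss = rss,
                 abs_log_d = abs(log(d_value(transition_matrix(pq[1L], pq[2L])))),
                 info = fit$info)
    if (is.null(best) || cand$rss < best$rss - 1e-10 ||
        (abs(cand$rss - best$rss) <= 1e-10 && cand$abs_log_d < best$abs_log_d))
      best <- cand
  }
  if (is.null(best)) {
    return(structure(list(sample_id = sample_id, p_hat = NA_real_,
                          q_hat = NA_real_, x_V_hat = x_V0, D_hat = NA_real_,
                          rss = NA_real_, n_peaks = nrow(norm),
                          classification = "unfit", converged = FALSE,
                          flags = "optimizer-failure"),
                     class = "fit_result"))
  }
  P_hat <- transition_matrix(best$pq[1L], best$pq[2L])
  D_hat <- d_value(P_hat)
  res <- list(sample_id = sample_id,
              p_hat = P_hat$p, q_hat = P_hat$q,
              x_V_hat = stationary_composition(P_hat)[["x_V"]],
              D_hat = D_hat,
              rss = best$rss,
              n_peaks = nrow(norm),
              classification = classify_distribution(
                D_hat, alt_threshold = alt_threshold,
                block_threshold = block_threshold),
              converged = best$info %in% 1:4,
              flags = flags)
  class(res) <- "fit_result"
  if (n_boot > 1)
    res$ci_D <- bootstrap_d(table, n_boot = n_boot, seed = seed, mode = mode,
                            alt_threshold = alt_threshold,
                            block_threshold = block_threshold)
  res
}

bind_tables <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  validate_peak_table(df)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Markov fit for sample %s\n", x$sample_id))
  if (is.na(x$D_hat)) {
    cat(sprintf("  classification: %s (x_V estimate %.4f)\n",
                x$classification, x$x_V_hat))
  } else {
    cat(sprintf("  p = %.4f  q = %.4f  x_V = %.4f\n",
                x$p_hat, x$q_hat, x$x_V_hat))
    cat(sprintf("  D = %.3f  (%s)   rss = %.3g over %d peaks\n",
                x$D_hat, x$classification, x$rss, x$n_peaks))
    if (!is.null(x$ci_D))
      cat(sprintf("  bootstrap 95%% CI for D: [%.3f, %.3f]\n",
                  x$ci_D[1L], x$ci_D[2L]))
  }
  invisible(x)
}

#' Classify a sequence distribution by its D value
#'
#' A D value near 1 is consistent with an ideally random (Bernoullian)
#' chain; a D considerably greater than 1 indicates block character; a D
#' well below 1 indicates alternating tendency.
#'
#' @param D D value, >= 0.
#' @param alt_threshold Below this, `"alternating"` (default 0.5).
#' @param block_threshold Above this, `"blocky"` (default 3.0, roughly the
#'   geometric midpoint between the largest D observed among random PHBV
#'   samples and the smallest among putative block samples).
#' @return One of `"random"`, `"blocky"`, `"alternating"`.
#' @examples
#' classify_distribution(1.15)   # random
#' classify_distribution(14.81)  # blocky
#' @export
classify_distribution <- function(D, alt_threshold = 0.5,
                                  block_threshold = 3.0) {
  stopifnot(is.numeric(D), length(D) == 1L, D >= 0)
  if (!(alt_threshold > 0 && alt_threshold < 1 && block_threshold > 1))
    stop("thresholds must satisfy 0 < alt_threshold < 1 < block_threshold")
  if (D > block_threshold) "blocky"
  else if (D < alt_threshold) "alternating"
  else "random"
}

#' Residual bootstrap interval for the fitted D value
#'
#' Refits the model `n_boot` times on pseudo-data regenerated from the
#' base fit and returns the percentile 95% interval of the refitted D
#' values. Because a peak table has few observations relative to the two
#' parameters, a nonparametric resample of the raw residuals badly
#' understates parameter uncertainty (the fit absorbs most of the noise
#' along the model surface), so the bootstrap is parametric: the
#' multiplicative intensity noise level is estimated from the relative
#' residuals with a degrees-of-freedom correction (free observations are
#' family sizes minus one for each family's normalization, minus the two
#' model parameters), and each replicate perturbs the fitted fractions by
#' fresh multiplicative Gaussian noise at that level, clips at zero,
#' renormalizes per family and refits. Noiseless input has zero residuals
#' and yields a zero-width interval at `D_hat`.
#'
#' @param tables Peak table(s) for one sample, as in [fit_markov()].
#' @param n_boot Number of bootstrap replicates, >= 2.
#' @param seed Integer seed; replicates are reproducible.
#' @param mode,alt_threshold,block_threshold Passed through to the refits.
#' @return Numeric vector `c(lower, upper)` (2.5% and 97.5% percentiles),
#'   with attribute `D_boot` holding the replicate D values.
#' @export
bootstrap_d <- function(tables, n_boot = 200, seed = NULL,
                        mode = "joint", alt_threshold = 0.5,
                        block_threshold = 3.0) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  base <- fit_markov(tables, mode = mode, alt_threshold = alt_threshold,
                     block_threshold = block_threshold)
  if (is.na(base$D_hat)) stop("base fit failed; cannot bootstrap")
  table <- bind_tables(tables)
  keep <- switch(mode,
                 joint  = rep(TRUE, nrow(table)),
                 diads  = table$family == "diad",
                 triads = table$family != "diad")
  norm <- normalize_peaks(validate_peak_table(table[keep, , drop = FALSE]))
  fitted <- predict_peak_fractions(
    transition_matrix(base$p_hat, base$q_hat), norm)
  rel_resid <- norm$intensity / fitted - 1
  n_families <- length(unique(norm$family))
  df <- max(1L, (nrow(norm) - n_families) - 2L)
  cv_hat <- sqrt(sum(rel_resid^2) / df)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  fam <- norm$family
  D_boot <- vapply(seq_len(n_boot), function(b) {
    pseudo <- norm
    pert_all <- pmax(fitted * (1 + stats::rnorm(length(fitted), 0, cv_hat)), 0)
    for (f in unique(fam)) {
      idx <- which(fam == f)
      pert <- pert_all[idx]
      if (sum(pert) <= 0) pert <- fitted[idx]
      pseudo$intensity[idx] <- pert / sum(pert)
    }
    fit <- tryCatch(fit_markov(pseudo, mode = mode,
                               alt_threshold = alt_threshold,
                               block_threshold = block_threshold),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit$D_hat)) NA_real_ else fit$D_hat
  }, numeric(1L))
  ci <- stats::quantile(D_boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(ci, D_boot = D_boot)
}
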