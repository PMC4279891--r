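# Independent oracles used across the suite.

# Brute-force least-squares oracle: dense grid search over (p, q) at step
# 1e-3 followed by Nelder-Mead refinement. Model predictions are computed
# from first principles (x_i * P_ij * P_jk with within-family
# renormalization by the family sum), independently of the package's
# optimizer and of its algebraic shortcuts.
oracle_model_pred <- function(p, q, family, labels) {
  x_B <- q / (p + q); x_V <- p / (p + q)
  Pm <- function(i, j) {
    ifelse(i == "B", ifelse(j == "V", p, 1 - p),
           ifelse(j == "B", q, 1 - q))
  }
  x0 <- function(i) ifelse(i == "B", x_B, x_V)
  frac <- function(lab) {
    u <- strsplit(lab, "")[[1L]]
    if (length(u) == 2L) x0(u[1]) * Pm(u[1], u[2])
    else x0(u[1]) * Pm(u[1], u[2]) * Pm(u[2], u[3])
  }
  fam_labels <- switch(family,
                       diad = c("BB", "BV", "VB", "VV"),
                       triad_V = c("BVB", "BVV", "VVB", "VVV"),
                       triad_B = c("BBB", "BBV", "VBB", "VBV"))
  total <- sum(vapply(fam_labels, frac, numeric(1L)))
  sum(vapply(labels, frac, numeric(1L))) / total
}

oracle_rss <- function(p, q, table) {
  norm <- normalize_peaks(table)
  labs <- lapply(strsplit(norm$assignment, ";", fixed = TRUE), trimws)
  pred <- mapply(function(l, f) oracle_model_pred(p, q, f, l),
                 labs, norm$family)
  sum((pred - norm$intensity)^2)
}

oracle_fit <- function(table, step = 1e-3) {
  norm <- normalize_peaks(table)
  labs <- lapply(strsplit(norm$assignment, ";", fixed = TRUE), trimws)
  grid <- seq(step, 1 - step, by = step)
  pg <- rep(grid, times = length(grid))
  qg <- rep(grid, each = length(grid))
  rss <- numeric(length(pg))
  for (i in seq_len(nrow(norm))) {
    pred <- oracle_model_pred_vec(pg, qg, norm$family[i], labs[[i]])
    rss <- rss + (pred - norm$intensity[i])^2
  }
  k <- which.min(rss)
  ref <- stats::optim(c(pg[k], qg[k]),
                      function(th) {
                        if (any(th <= 0) || any(th >= 1)) return(Inf)
                        oracle_rss(th[1], th[2], table)
                      },
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  ref$par
}

# vectorized twin of oracle_model_pred over parallel (p, q) vectors
oracle_model_pred_vec <- function(p, q, family, labels) {
  x_B <- q / (p + q); x_V <- p / (p + q)
  Pm <- function(i, j) {
    if (i == "B") { if (j == "V") p else 1 - p }
    else          { if (j == "B") q else 1 - q }
  }
  x0 <- function(i) if (i == "B") x_B else x_V
  frac <- function(lab) {
    u <- strsplit(lab, "")[[1L]]
    if (length(u) == 2L) x0(u[1]) * Pm(u[1], u[2])
    else x0(u[1]) * Pm(u[1], u[2]) * Pm(u[2], u[3])
  }
  fam_labels <- switch(family,
                       diad = c("BB", "BV", "VB", "VV"),
                       triad_V = c("BVB", "BVV", "VVB", "VVV"),
                       triad_B = c("BBB", "BBV", "VBB", "VBV"))
  total <- Reduce(`+`, lapply(fam_labels, frac))
  Reduce(`+`, lapply(labels, frac)) / total
}

# binomial-scale standard error for an empirical fraction over m windows,
# inflated by a conservative serial-correlation factor of 3
se_fraction <- function(f, m) 3 * sqrt(f * (1 - f) / m)
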