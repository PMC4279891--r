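make_diad_table <- function(P, sample = "S", merged = FALSE) {
  f <- diad_fractions(P)
  if (merged)
    peak_table(sample, "diad", c("d1", "d2", "d3"), c("BB", "BV;VB", "VV"),
               c(f[["BB"]], f[["BV"]] + f[["VB"]], f[["VV"]]))
  else
    peak_table(sample, "diad", paste0("d", 1:4), names(f), as.numeric(f))
}

test_that("peak-table validation is strict about families, labels and overlap", {
  expect_error(peak_table("S", "quad", "p1", "BB", 1), "unknown peak family")
  expect_error(peak_table("S", "diad", c("p1", "p2"), c("BB", "BX"), c(1, 1)),
               "invalid diad assignment")
  expect_error(peak_table("S", "triad_V", c("p1", "p2"), c("BVB", "BBB"), c(1, 1)),
               "invalid triad_V")
  expect_error(peak_table("S", "diad", c("p1", "p2"), c("BB;VV", "VV"), c(1, 1)),
               "overlapping")
  expect_error(peak_table("S", "diad", "p1", "BB", 1), "at least 2 peaks")
  expect_error(peak_table("S", "diad", c("p1", "p2"), c("BB", "VV"), c(0, 0)),
               "positive")
})

test_that("peak CSV round-trips unchanged and rejects malformed input", {
  tab <- make_sample_tables("R23", 0.23, 1.15)$peaks
  tmp <- tempfile(fileext = ".csv")
  write_peak_csv(tab, tmp)
  back <- read_peak_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,family,peak_id,assignment,intensity",
               "S,diad,p1,ZZ,1", "S,diad,p2,BB,1"), bad)
  expect_error(read_peak_csv(bad), "invalid diad")
})

test_that("normalization is idempotent and composition follows the methyl ratio", {
  tab <- peak_table("S", "diad", paste0("d", 1:3), c("BB", "BV;VB", "VV"),
                    c(2, 1, 1))
  norm <- normalize_peaks(tab)
  expect_equal(norm$intensity, c(0.5, 0.25, 0.25))
  expect_equal(normalize_peaks(norm)$intensity, norm$intensity)
  tab0 <- peak_table("S", "diad", paste0("d", 1:3), c("BB", "BV;VB", "VV"),
                     c(3, 0, 1))
  expect_equal(normalize_peaks(tab0)$intensity, c(0.75, 0, 0.25))
  expect_equal(composition_from_methyl(1, 1)[["x_V"]], 0.5)
  expect_equal(composition_from_methyl(77, 23)[["x_V"]], 0.23)
  expect_warning(x <- composition_from_methyl(1, 0), "homopolymer")
  expect_equal(x[["x_V"]], 0)
  expect_error(composition_from_methyl(0, 0), "both zero")
})

test_that("model peak predictions cover merged peaks and centred-family scaling", {
  P <- transition_matrix(0.1, 0.3)
  merged <- make_diad_table(P, merged = TRUE)
  expect_equal(predict_peak_fractions(P, merged), c(0.675, 0.15, 0.175))
  full <- make_diad_table(transition_matrix(0.5, 0.5))
  expect_equal(predict_peak_fractions(transition_matrix(0.5, 0.5), full),
               rep(0.25, 4))
  # fully assigned V-centred family predicts fractions summing to 1
  B <- bernoullian(0.5)
  tv <- peak_table("S", "triad_V", paste0("t", 1:4), v_centred_triads(),
                   rep(1, 4))
  expect_equal(predict_peak_fractions(B, tv), rep(0.25, 4))
})

test_that("fitting noiseless data recovers the generating parameters", {
  P <- transition_matrix(0.1, 0.3)
  tabs <- make_sample_tables("S", 0.25, 21)$peaks  # same (p, q)
  fit <- fit_markov(tabs)
  expect_equal(fit$p_hat, 0.1, tolerance = 1e-6)
  expect_equal(fit$q_hat, 0.3, tolerance = 1e-6)
  expect_equal(fit$D_hat, 21, tolerance = 1e-5)
  expect_equal(fit$x_V_hat, stationary_composition(transition_matrix(fit$p_hat, fit$q_hat))[["x_V"]])
  expect_lt(fit$rss, 1e-12)
  expect_true(fit$converged)
})

test_that("the NLS fit agrees with a dense grid-search oracle", {
  for (pq in list(c(0.1, 0.3), c(0.55, 0.15))) {
    P <- transition_matrix(pq[1], pq[2])
    x_V <- stationary_composition(P)[["x_V"]]
    tab <- make_sample_tables("S", x_V, d_value(P))$peaks
    fit <- fit_markov(tab)
    orc <- oracle_fit(tab, step = 5e-3)
    expect_equal(fit$p_hat, orc[1], tolerance = 1e-4)
    expect_equal(fit$q_hat, orc[2], tolerance = 1e-4)
  }
})

test_that("noiseless parameter recovery to 1e-6 across a (p, q) grid", {
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (q in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      P <- transition_matrix(p, q)
      x_V <- stationary_composition(P)[["x_V"]]
      fit <- fit_markov(make_sample_tables("S", x_V, d_value(P))$peaks)
      expect_equal(fit$p_hat, p, tolerance = 1e-6)
      expect_equal(fit$q_hat, q, tolerance = 1e-6)
    }
  }
})

test_that("merged diad peak plus V-centred triads still identifies (p, q)", {
  P <- transition_matrix(0.0664, 0.4871)
  x_V <- stationary_composition(P)[["x_V"]]
  tab <- make_sample_tables("S", x_V, d_value(P), resolved = FALSE)$peaks
  fit <- fit_markov(tab)
  expect_equal(fit$p_hat, P$p, tolerance = 1e-6)
  expect_equal(fit$q_hat, P$q, tolerance = 1e-6)
})

test_that("the fit is invariant to rescaling intensities within a family", {
  tab <- make_sample_tables("S", 0.23, 1.15)$peaks
  scaled <- tab
  scaled$intensity[scaled$family == "diad"] <-
    scaled$intensity[scaled$family == "diad"] * 137.5
  scaled$intensity[scaled$family == "triad_V"] <-
    scaled$intensity[scaled$family == "triad_V"] * 0.004
  f1 <- fit_markov(tab)
  f2 <- fit_markov(validate_peak_table(scaled))
  expect_equal(f2$p_hat, f1$p_hat, tolerance = 1e-9)
  expect_equal(f2$q_hat, f1$q_hat, tolerance = 1e-9)
  expect_equal(f2$D_hat, f1$D_hat, tolerance = 1e-9)
})

test_that("diads-only fit equals the diad-ratio identity on noiseless data", {
  P <- transition_matrix(0.2242, 0.7506)
  tab <- make_diad_table(P)
  fit <- fit_markov(tab, mode = "diads")
  f <- diad_fractions(P)
  expect_equal(fit$D_hat, f[["BB"]] * f[["VV"]] / (f[["BV"]] * f[["VB"]]),
               tolerance = 1e-6)
})

test_that("classification thresholds split random, blocky and alternating", {
  expect_identical(classify_distribution(1.15), "random")
  expect_identical(classify_distribution(1.0), "random")
  expect_identical(classify_distribution(14.81), "blocky")
  expect_identical(classify_distribution(0.2), "alternating")
  expect_identical(classify_distribution(2.5, block_threshold = 2), "blocky")
  expect_error(classify_distribution(1, alt_threshold = 2), "thresholds")
})

test_that("near-homopolymer tables short-circuit instead of fitting", {
  tab <- peak_table("H", "diad", paste0("d", 1:4), diad_labels(),
                    c(0.999, 0.0005, 0.0005, 0))
  fit <- fit_markov(tab)
  expect_identical(fit$classification, "homopolymer")
  expect_true(is.na(fit$D_hat))
})

test_that("fit quality degrades gracefully under 1% intensity noise", {
  # median relative error of D over the panel at cv = 0.01 stays below 10%
  panel <- default_panel()
  relerr <- vapply(seq_len(nrow(panel)), function(i) {
    t <- make_sample_tables(panel$name[i], panel$x_V[i], panel$D[i],
                            cv = 0.01, seed = 400 + i)
    abs(fit_markov(t$peaks)$D_hat / panel$D[i] - 1)
  }, numeric(1L))
  expect_lt(median(relerr), 0.10)
})

test_that("bootstrap interval collapses on noiseless data and needs n_boot >= 2", {
  tab <- make_sample_tables("R23", 0.23, 1.15)$peaks
  ci <- bootstrap_d(tab, n_boot = 20, seed = 3)
  expect_equal(ci[1], ci[2], tolerance = 1e-6)
  expect_equal(ci[1], 1.15, tolerance = 1e-4)
  expect_error(bootstrap_d(tab, n_boot = 1), ">= 2")
})

test_that("bootstrap intervals usually cover the generating D under 2% noise", {
  hits <- vapply(1:15, function(s) {
    t <- make_sample_tables("R23", 0.23, 1.15, cv = 0.02, seed = s)
    ci <- bootstrap_d(t$peaks, n_boot = 100, seed = s + 5000)
    ci[1] <= 1.15 && 1.15 <= ci[2]
  }, logical(1L))
  expect_gte(sum(hits), 12)
})
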