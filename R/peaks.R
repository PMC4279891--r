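# Assigned NMR peak-intensity tables.
#
# A peak table holds integrated intensities of assigned resonances for one
# or more samples. Each row is one peak; a peak may be a merged resonance
# covering several sequence labels (e.g. the overlapping BV + VB carbonyl
# diad signal), encoded as labels joined by ';' in the `assignment` column.
# Families:
#   diad     - carbonyl diad region, labels BB, BV, VB, VV
#   triad_V  - V-centred triads, labels BVB, BVV, VVB, VVV
#   triad_B  - B-centred triads, labels BBB, BBV, VBB, VBV
# Each centred triad family is integrated on its own NMR scale, so its
# model fractions are normalized within the family before comparison.

peak_families <- function() {
  list(diad    = diad_labels(),
       triad_V = v_centred_triads(),
       triad_B = b_centred_triads())
}

#' Construct a peak-intensity table
#'
#' @param sample_id Sample identifier(s).
#' @param family Resonance family: `"diad"`, `"triad_V"` or `"triad_B"`.
#' @param peak_id Peak identifier(s), unique within a sample/family.
#' @param assignment Sequence label(s) per peak; a merged peak's labels are
#'   joined by `";"` (e.g. `"BV;VB"`).
#' @param intensity Non-negative integrated peak areas (arbitrary units).
#' @return A `peak_table` data frame with those five columns.
#' @examples
#' peak_table("S1", "diad", c("d1", "d2", "d3"),
#'            c("BB", "BV;VB", "VV"), c(6.7, 1.5, 1.8))
#' @export
peak_table <- function(sample_id, family, peak_id, assignment, intensity) {
  df <- data.frame(sample_id = as.character(sample_id),
                   family = as.character(family),
                   peak_id = as.character(peak_id),
                   assignment = as.character(assignment),
                   intensity = as.numeric(intensity),
                   stringsAsFactors = FALSE)
  validate_peak_table(df)
}

#' @rdname peak_table
#' @param df A data frame with the peak-table columns.
#' @export
validate_peak_table <- function(df) {
  required <- c("sample_id", "family", "peak_id", "assignment", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("peak table lacks column(s): ", paste(missing_cols, collapse = ", "))
  fams <- peak_families()
  bad_fam <- setdiff(unique(df$family), names(fams))
  if (length(bad_fam))
    stop("unknown peak family: ", paste(bad_fam, collapse = ", "),
         " (expected ", paste(names(fams), collapse = ", "), ")")
  if (any(!is.finite(df$intensity)) || any(df$intensity < 0))
    stop("peak intensities must be finite and >= 0")
  for (key in split(df, list(df$sample_id, df$family), drop = TRUE)) {
    labs <- unlist(strsplit(key$assignment, ";", fixed = TRUE))
    labs <- trimws(labs)
    allowed <- fams[[key$family[1L]]]
    bad <- setdiff(labs, allowed)
    if (length(bad))
      stop(sprintf("invalid %s assignment label(s) for sample %s: %s",
                   key$family[1L], key$sample_id[1L],
                   paste(bad, collapse = ", ")))
    if (anyDuplicated(labs))
      stop(sprintf(
        "overlapping assignments in sample %s, family %s: label(s) %s",
        key$sample_id[1L], key$family[1L],
        paste(unique(labs[duplicated(labs)]), collapse = ", ")))
    if (nrow(key) < 2L)
      stop(sprintf("sample %s, family %s: need at least 2 peaks",
                   key$sample_id[1L], key$family[1L]))
    if (sum(key$intensity) <= 0)
      stop(sprintf("sample %s, family %s: total intensity must be positive",
                   key$sample_id[1L], key$family[1L]))
  }
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Read or write a peak table as CSV
#'
#' The CSV schema has a required header
#' `sample_id,family,peak_id,assignment,intensity`; merged assignments are
#' `';'`-joined labels. Parsing is strict: an unknown family or sequence
#' label is an error, not a warning.
#'
#' @param path CSV file path.
#' @return `read_peak_csv()`: a validated `peak_table`.
#' @export
read_peak_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       family = "character",
                                       peak_id = "character",
                                       assignment = "character",
                                       intensity = "numeric"))
  tryCatch(validate_peak_table(df),
           error = function(e) stop("in ", path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname read_peak_csv
#' @param table A `peak_table`.
#' @export
write_peak_csv <- function(table, path) {
  table <- validate_peak_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize peak intensities to fractions
#'
#' Divides each intensity by its sample/family total, turning raw
#' integrated areas into relative fractions; idempotent.
#'
#' @param table A `peak_table`.
#' @return The table with intensities summing to 1 within each
#'   sample/family block.
#' @export
normalize_peaks <- function(table) {
  table <- validate_peak_table(as.data.frame(table))
  key <- interaction(table$sample_id, table$family, drop = TRUE)
  totals <- tapply(table$intensity, key, sum)
  table$intensity <- table$intensity / as.numeric(totals[key])
  validate_peak_table(table)
}

#' 3HV composition from 1H methyl resonance intensities
#'
#' The 3HV mole fraction is the relative intensity of the 3HV methyl
#' resonance: \eqn{x_V = I_V / (I_B + I_V)}.
#'
#' @param I_B,I_V Non-negative intensities of the 3HB and 3HV methyl
#'   resonances (arbitrary units), not both zero.
#' @return Named numeric vector `c(x_B, x_V)`. A boundary value (0 or 1)
#'   is returned with a homopolymer warning: it is not a valid copolymer
#'   composition.
#' @examples
#' composition_from_methyl(77, 23)  # x_V = 0.23
#' @export
composition_from_methyl <- function(I_B, I_V) {
  stopifnot(is.numeric(I_B), is.numeric(I_V), I_B >= 0, I_V >= 0)
  if (I_B + I_V <= 0) stop("methyl intensities are both zero")
  x_V <- I_V / (I_B + I_V)
  if (x_V == 0 || x_V == 1)
    warning("methyl intensities indicate a homopolymer (x_V = ", x_V, ")")
  c(x_B = 1 - x_V, x_V = x_V)
}

#' Model-predicted peak fractions for a peak table
#'
#' For each peak, sums the model mole fractions of its assigned sequences
#' under the first-order Markov model. Diad predictions come straight from
#' [diad_fractions()]; triad predictions are renormalized within the
#' centred family (dividing the V-centred fractions by \eqn{x_V}, the
#' B-centred by \eqn{x_B}) because each centred multiplet family is
#' integrated on its own scale, so a fully assigned family predicts
#' fractions summing to 1.
#'
#' @param P A [transition_matrix()].
#' @param table A `peak_table`.
#' @return Numeric vector of predicted fractions, one per row of `table`.
#' @export
predict_peak_fractions <- function(P, table) {
  P <- as_transition_matrix(P)
  table <- validate_peak_table(as.data.frame(table))
  x <- stationary_composition(P)
  model <- list(diad = diad_fractions(P),
                triad_V = triad_fractions(P)[v_centred_triads()] / x[["x_V"]],
                triad_B = triad_fractions(P)[b_centred_triads()] / x[["x_B"]])
  vapply(seq_len(nrow(table)), function(i) {
    labs <- trimws(strsplit(table$assignment[i], ";", fixed = TRUE)[[1L]])
    sum(model[[table$family[i]]][labs])
  }, numeric(1L))
}
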