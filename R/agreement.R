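# Inter-rater agreement: percent agreement, Cohen's kappa and the
# prevalence-adjusted bias-adjusted kappa (PABAK), with the qualitative
# interpretation bands used in clinical reliability reporting.

#' Build a confusion table from two raters' nominal ratings
#'
#' Pairs where either rating falls outside `categories` (e.g.
#' `cannot_be_determined`) are excluded pairwise, mirroring
#' available-case denominators.
#'
#' @param a,b equal-length vectors of nominal ratings (rater A rows,
#'   rater B columns).
#' @param categories category set defining the table (default yes/no).
#' @return `k x k` integer matrix of class `confusion_table`.
#' @export
confusion_table <- function(a, b, categories = c("yes", "no")) {
  if (length(a) != length(b)) {
    sca_error("rating vectors must have equal length", "swallowCA_bad_parameter")
  }
  keep <- a %in% categories & b %in% categories
  a <- factor(a[keep], levels = categories)
  b <- factor(b[keep], levels = categories)
  m <- as.matrix(table(a, b))
  class(m) <- c("confusion_table", class(m))
  m
}

check_table <- function(t) {
  t <- unclass(as.matrix(t))
  if (nrow(t) != ncol(t)) sca_error("confusion table must be square", "swallowCA_bad_parameter")
  if (any(t < 0) || any(t != floor(t))) {
    sca_error("confusion table needs nonnegative integer counts", "swallowCA_bad_parameter")
  }
  if (sum(t) < 1) sca_error("confusion table is empty (n = 0)", "swallowCA_empty_table")
  t
}

#' Percent (observed) agreement
#' @param t square confusion matrix (rater A rows, rater B columns).
#' @return proportion of agreeing pairs, `trace(t) / n`.
#' @export
percent_agreement <- function(t) {
  t <- check_table(t)
  sum(diag(t)) / sum(t)
}

#' Cohen's kappa
#'
#' `kappa = (po - pe) / (1 - pe)` with chance agreement
#' `pe = sum_i row_i * col_i / n^2`. When both raters are constant on the
#' same category (`pe = 1`), kappa is undefined and `NA` is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param t square confusion matrix.
#' @return kappa in `[-1, 1]`, or flagged `NA` in the degenerate case.
#' @export
cohens_kappa <- function(t) {
  t <- check_table(t)
  n <- sum(t)
  po <- sum(diag(t)) / n
  pe <- sum(rowSums(t) * colSums(t)) / n^2
  if (pe >= 1 - 1e-12) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Prevalence-adjusted bias-adjusted kappa (PABAK)
#'
#' `(k * po - 1) / (k - 1)` for `k` categories; for the usual 2x2 case
#' this is `2 * po - 1`. Unlike Cohen's kappa, PABAK is immune to skewed
#' marginal prevalence and rater bias.
#'
#' @param t square confusion matrix with `k >= 2` categories.
#' @return PABAK coefficient.
#' @export
pabak <- function(t) {
  t <- check_table(t)
  k <- nrow(t)
  if (k < 2) sca_error("PABAK requires at least 2 categories", "swallowCA_bad_parameter")
  po <- sum(diag(t)) / sum(t)
  (k * po - 1) / (k - 1)
}

#' Qualitative interpretation band of an agreement coefficient
#'
#' Bands: excellent `[0.80, 1.00]`, substantial `[0.61, 0.80)`, moderate
#' `[0.41, 0.61)`, fair `[0.21, 0.41)`, slight_to_poor below 0.21. The
#' conventional printed band list overlaps at 0.80 and skips
#' (0.20, 0.21); this partition resolves both by assigning 0.80 upward
#' and extending slight_to_poor to 0.21.
#'
#' @param coefficient agreement coefficient in `[-1, 1]`.
#' @return one of `"excellent"`, `"substantial"`, `"moderate"`, `"fair"`,
#'   `"slight_to_poor"` (vectorised).
#' @export
interpret_agreement <- function(coefficient) {
  if (any(!is.na(coefficient) & (coefficient < -1 | coefficient > 1))) {
    sca_error("agreement coefficients must lie in [-1, 1]", "swallowCA_bad_parameter")
  }
  cut_points <- c(-Inf, 0.21, 0.41, 0.61, 0.80, Inf)
  bands <- c("slight_to_poor", "fair", "moderate", "substantial", "excellent")
  as.character(bands[findInterval(coefficient, cut_points, left.open = FALSE)])
}

#' Per-parameter two-rater agreement report
#'
#' From a long two-rater ratings table, builds a yes/no confusion table
#' per (phase, parameter) — `cannot_be_determined` pairs excluded — and
#' reports percent agreement, Cohen's kappa, PABAK and the interpretation
#' band.
#'
#' @param ratings long ratings `data.frame`
#'   (`neonate_id,rater_id,phase,parameter,value`), exactly two raters.
#' @param band_on which coefficient the band interprets (default kappa).
#' @return `data.frame` with `phase, parameter, n_pairs,
#'   percent_agreement, kappa, pabak, band`.
#' @export
rater_agreement <- function(ratings, band_on = c("kappa", "pabak")) {
  band_on <- match.arg(band_on)
  raters <- sort(unique(ratings$rater_id))
  if (length(raters) != 2L) {
    sca_error(sprintf("expected exactly 2 raters, found %d", length(raters)),
              "swallowCA_bad_table")
  }
  inv <- unique(ratings[c("phase", "parameter")])
  rows <- lapply(seq_len(nrow(inv)), function(i) {
    sub <- ratings[ratings$phase == inv$phase[i] & ratings$parameter == inv$parameter[i], ]
    a <- sub[sub$rater_id == raters[1], ]
    b <- sub[sub$rater_id == raters[2], ]
    b <- b[match(a$neonate_id, b$neonate_id), ]
    t <- confusion_table(a$value, b$value)
    n <- sum(t)
    if (n == 0) {
      return(data.frame(
        phase = inv$phase[i], parameter = inv$parameter[i], n_pairs = 0L,
        percent_agreement = NA_real_, kappa = NA_real_, pabak = NA_real_,
        band = NA_character_, stringsAsFactors = FALSE
      ))
    }
    k <- cohens_kappa(t)
    pb <- pabak(t)
    coef <- if (band_on == "kappa") k else pb
    data.frame(
      phase = inv$phase[i], parameter = inv$parameter[i], n_pairs = n,
      percent_agreement = percent_agreement(t),
      kappa = as.numeric(k), pabak = pb,
      band = if (is.na(coef)) NA_character_ else interpret_agreement(as.numeric(coef)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
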