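# Agreement statistics between reference (cuff) and estimated pressures:
# coefficient of determination, Bland-Altman bias and limits of agreement,
# and error-band accuracy tables.

#' Coefficient of determination against the reference
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' reference mean. Undefined (returned as `NA`) when the reference has zero
#' variance.
#'
#' @param reference,estimate equal-length numeric vectors (mmHg), length >= 2.
#' @return scalar R-squared, or `NA` for a zero-variance reference.
#' @export
r_squared <- function(reference, estimate) {
  stopifnot(length(reference) == length(estimate), length(reference) >= 2)
  ss_tot <- sum((reference - mean(reference))^2)
  if (ss_tot == 0) {
    warning("zero reference variance: R-squared undefined")
    return(NA_real_)
  }
  1 - sum((estimate - reference)^2) / ss_tot
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are `estimate - reference`; bias is their mean and the limits
#' of agreement are `bias +/- 1.96 * SD` with the sample (n-1) standard
#' deviation. Pair means are returned for plotting.
#'
#' @param reference,estimate equal-length numeric vectors (mmHg), length >= 2.
#' @return list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `differences`, `means`, `n`.
#' @export
bland_altman <- function(reference, estimate) {
  stopifnot(length(reference) == length(estimate), length(reference) >= 2)
  d <- estimate - reference
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, differences = d,
                 means = (reference + estimate) / 2, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f mmHg, limits of agreement [%.2f, %.2f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of pair (mmHg)",
                              ylab = "estimate - reference (mmHg)", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = c("red", "blue", "red"))
  invisible(x)
}

#' Error-band accuracy
#'
#' Fraction of estimates whose absolute error is strictly below each
#' threshold (the bands are printed as "<5 mmHg" etc., so a tie at the
#' threshold falls outside the band).
#'
#' @param differences numeric vector of `estimate - reference` errors (mmHg).
#' @param thresholds positive increasing thresholds, default `c(5, 10, 15)`.
#' @return named numeric vector of fractions in [0, 1], one per threshold.
#' @export
band_accuracy <- function(differences, thresholds = c(5, 10, 15)) {
  if (!length(differences)) stop("empty differences")
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be positive and strictly increasing")
  vapply(stats::setNames(thresholds, paste0("within_", thresholds)),
         function(th) mean(abs(differences) < th), 0)
}

#' Histogram summary of a reference-pressure corpus
#'
#' Counts at 1 mmHg bins plus the empirical minimum and maximum, for both
#' pressure columns of a reference table.
#'
#' @param references data.frame with `sbp_mmHg` and `dbp_mmHg` columns.
#' @return list with per-target `counts` (named by left bin edge), `min`,
#'   `max` and `n`.
#' @export
dataset_summary <- function(references) {
  stopifnot(nrow(references) >= 1)
  one <- function(v) {
    bins <- floor(v)
    list(counts = table(factor(bins, levels = seq(min(bins), max(bins)))),
         min = min(v), max = max(v), n = length(v))
  }
  list(sbp = one(references$sbp_mmHg), dbp = one(references$dbp_mmHg))
}

#' Build the agreement report for all algorithms and targets
#'
#' Assembles per-(algorithm, target) R-squared, Bland-Altman bias and limits
#' of agreement, and error-band fractions into one report shaped like the
#' standard accuracy tables (algorithms as rows, error bands as columns).
#' Algorithms with missing predictions produce rows of `NA` (explicit gaps).
#'
#' @param predictions nested list: `predictions[[target]][[algorithm]]` is a
#'   numeric vector of test-fold estimates, targets `"sbp"` and `"dbp"`.
#' @param references list with numeric `sbp` and `dbp` reference vectors for
#'   the same test fold.
#' @param thresholds error bands in mmHg, default `c(5, 10, 15)`.
#' @return object of class `bp_agreement`: a data.frame with columns
#'   `target, algorithm, n_test, r2, bias, loa_low, loa_high` and one
#'   `within_*` column per band.
#' @export
build_report <- function(predictions, references, thresholds = c(5, 10, 15)) {
  targets <- names(predictions)
  if (!length(targets)) stop("no predictions supplied")
  rows <- list()
  for (tg in targets) {
    ref <- references[[tg]]
    if (is.null(ref) || !length(ref)) stop("missing references for ", tg)
    for (alg in names(predictions[[tg]])) {
      est <- predictions[[tg]][[alg]]
      row <- data.frame(target = tg, algorithm = alg, n_test = length(ref),
                        r2 = NA_real_, bias = NA_real_,
                        loa_low = NA_real_, loa_high = NA_real_,
                        stringsAsFactors = FALSE)
      bands <- stats::setNames(rep(NA_real_, length(thresholds)),
                               paste0("within_", thresholds))
      if (!is.null(est) && length(est) == length(ref)) {
        ba <- bland_altman(ref, est)
        row$r2 <- suppressWarnings(r_squared(ref, est))
        row$bias <- ba$bias; row$loa_low <- ba$loa_low; row$loa_high <- ba$loa_high
        bands <- band_accuracy(ba$differences, thresholds)
      }
      rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(as.list(bands)))
    }
  }
  rep <- do.call(rbind, rows)
  attr(rep, "thresholds") <- thresholds
  class(rep) <- c("bp_agreement", "data.frame")
  rep
}

#' @export
print.bp_agreement <- function(x, ...) {
  thresholds <- attr(x, "thresholds")
  alg_label <- c(rfr = "Random Forest Regression (RFR)",
                 gbr = "Gradient Boosting Regression (GBR)",
                 abr = "Adaptive Boosting Regression (ABR)")
  for (tg in unique(x$target)) {
    sub <- x[x$target == tg, , drop = FALSE]
    cat(sprintf("%s estimation accuracy (n = %d):\n", toupper(tg), sub$n_test[1]))
    bandcols <- paste0("within_", thresholds)
    cat(sprintf("%-36s %6s %s\n", "", "R2",
                paste(sprintf("%9s", paste0("<", thresholds, " mmHg")), collapse = " ")))
    for (i in seq_len(nrow(sub))) {
      lbl <- alg_label[sub$algorithm[i]]
      if (is.na(lbl)) lbl <- sub$algorithm[i]
      cat(sprintf("%-36s %6s %s\n", lbl,
                  ifelse(is.na(sub$r2[i]), "NA", sprintf("%.3f", sub$r2[i])),
                  paste(sprintf("%8.1f%%", 100 * unlist(sub[i, bandcols])), collapse = " ")))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
plot.bp_agreement <- function(x, predictions, references, ...) {
  targets <- unique(x$target)
  old <- graphics::par(mfrow = c(length(targets), 2))
  on.exit(graphics::par(old))
  for (tg in targets) {
    ref <- references[[tg]]
    alg <- x$algorithm[x$target == tg][1]
    est <- predictions[[tg]][[alg]]
    graphics::plot(ref, est, xlab = sprintf("reference %s (mmHg)", toupper(tg)),
                   ylab = "estimate (mmHg)", main = alg)
    graphics::abline(0, 1, col = "blue")
    plot(bland_altman(ref, est), main = sprintf("%s Bland-Altman", toupper(tg)))
  }
  invisible(x)
}
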