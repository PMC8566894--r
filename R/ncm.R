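# Sloan neutral community model: occurrence frequency vs. regional mean
# relative abundance, parameterized by the immigration probability m.

#' Neutral-model expected occurrence frequency
#'
#' Under the Sloan stationary beta approximation, a taxon with metacommunity
#' relative abundance `p` is detected (local relative abundance above the
#' detection limit `d`) with probability
#' `1 - I_d(Nm p, Nm (1 - p))`, `I` being the regularized incomplete beta
#' function. `Nm` is the product of community size and immigration
#' probability.
#'
#' @param p metacommunity mean relative abundance(s), in (0, 1).
#' @param Nm immigration parameter (> 0).
#' @param d detection limit as a relative abundance (> 0).
#' @return expected occurrence frequency in `[0, 1]` (vectorized over `p`).
#' @examples
#' ncm_expected_frequency(0.5, Nm = 2, d = 0.5) # beta(1,1) is uniform: 0.5
#' @export
ncm_expected_frequency <- function(p, Nm, d) {
  if (Nm <= 0) stop("Nm must be > 0")
  if (d <= 0 || d >= 1) stop("d must be in (0, 1)")
  stopifnot(all(p > 0 & p < 1))
  1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
}

#' Fit the Sloan neutral community model
#'
#' Estimates `Nm` by nonlinear least squares on the occurrence-frequency
#' curve: each taxon contributes its regional mean relative abundance `p_i`
#' (mean over samples of within-sample relative abundance) and its observed
#' occurrence frequency (fraction of samples where it is present); `Nm`
#' minimizes the sum of squared frequency residuals over a bounded search
#' `(0, 10 * N_mean]`. `m = Nm / N_mean` with `N_mean` the mean sample total.
#' `R^2 = 1 - SSE/SST` about the mean observed frequency and can be negative
#' for a poor fit.
#'
#' @param m samples x taxa count matrix.
#' @param d detection limit, or `"auto"` (one read: `1 / N_mean`).
#' @param level prediction-band level for the taxon partition (default 0.95).
#' @return object of class `ncm_fit`: list with `Nm`, `m`, `N_mean`, `d`,
#'   `r_squared`, `n_samples`, `degenerate` flag, and `taxa` — a data.frame
#'   with `taxon_id`, `p`, `freq`, `predicted`, `ci_lo`, `ci_hi`,
#'   `partition`.
#' @export
fit_ncm <- function(m, d = "auto", level = 0.95) {
  check_community(m, integer_counts = FALSE)
  n <- nrow(m)
  if (n < 20) warning("fewer than 20 samples; NCM fit will be unstable")
  N_mean <- mean(rowSums(m))
  if (identical(d, "auto")) d <- 1 / N_mean
  rel <- m / rowSums(m)
  p <- colMeans(rel)
  freq <- colMeans(m > 0)
  keep <- p > 0 & p < 1 # taxa absent everywhere (or filling every read) carry no signal
  fit_ncm_curve(p[keep], freq[keep], n_samples = n, N_mean = N_mean, d = d,
                level = level, taxon_ids = colnames(m)[keep])
}

#' @rdname fit_ncm
#'
#' @description `fit_ncm_curve()` is the curve-level fitter behind
#'   [fit_ncm()]: it takes the per-taxon `(p, freq)` pairs directly, which is
#'   also the natural entry point for occupancy data generated from the
#'   frequency curve itself.
#'
#' @param p per-taxon metacommunity mean relative abundances, in (0, 1).
#' @param freq per-taxon observed occurrence frequencies, in `[0, 1]`.
#' @param n_samples number of samples behind `freq` (sets the prediction
#'   band width).
#' @param N_mean mean community size (converts `Nm` to `m`).
#' @param taxon_ids optional taxon labels.
#' @export
fit_ncm_curve <- function(p, freq, n_samples, N_mean, d = 1 / N_mean,
                          level = 0.95, taxon_ids = NULL) {
  stopifnot(length(p) == length(freq), all(freq >= 0 & freq <= 1))
  sst <- sum((freq - mean(freq))^2)
  degenerate <- sst == 0
  if (degenerate)
    warning("all observed frequencies identical; R^2 undefined (degenerate fit)")

  sse_of <- function(logNm)
    sum((freq - ncm_expected_frequency(p, exp(logNm), d))^2)
  opt <- stats::optimize(sse_of, interval = log(c(1e-3, 10 * N_mean)))
  Nm <- exp(opt$minimum)
  predicted <- ncm_expected_frequency(p, Nm, d)
  r2 <- if (degenerate) NA_real_ else 1 - opt$objective / sst

  fit <- structure(list(
    Nm = Nm, m = Nm / N_mean, N_mean = N_mean, d = d,
    r_squared = r2, n_samples = n_samples, degenerate = degenerate,
    taxa = data.frame(taxon_id = taxon_ids %||% paste0("taxon_", seq_along(p)),
                      p = unname(p), freq = unname(freq),
                      predicted = unname(predicted),
                      stringsAsFactors = FALSE)),
    class = "ncm_fit")
  partition_taxa(fit, level = level)
}

#' Partition taxa against the neutral prediction band
#'
#' Labels each taxon `above`, `within` or `below` the prediction band around
#' the fitted frequency curve. The default band is the exact binomial
#' prediction interval at the predicted frequency with `n` = number of
#' samples — the quantity being banded is a future observed frequency, so a
#' prediction interval (not a confidence interval for the proportion) is
#' what calibrates: it covers the observed frequency of a truly neutral
#' taxon at the nominal level. A Wilson score band is available via
#' `method = "wilson"` (it under-covers observations by a few percent at
#' moderate frequencies).
#'
#' @param fit an `ncm_fit`.
#' @param level band level (default 0.95).
#' @param method `"exact"` (binomial prediction quantiles, default) or
#'   `"wilson"`.
#' @return the `ncm_fit` with `taxa$ci_lo`, `taxa$ci_hi`, `taxa$partition`
#'   filled in.
#' @export
partition_taxa <- function(fit, level = 0.95, method = c("exact", "wilson")) {
  stopifnot(inherits(fit, "ncm_fit"))
  method <- match.arg(method)
  n <- fit$n_samples
  ci <- if (method == "wilson") {
    wilson_interval(fit$taxa$predicted, n, level)
  } else {
    a <- (1 - level) / 2
    list(lo = stats::qbinom(a, n, fit$taxa$predicted) / n,
         hi = stats::qbinom(1 - a, n, fit$taxa$predicted) / n)
  }
  fit$taxa$ci_lo <- ci$lo
  fit$taxa$ci_hi <- ci$hi
  fit$taxa$partition <- ifelse(fit$taxa$freq > ci$hi, "above",
                        ifelse(fit$taxa$freq < ci$lo, "below", "within"))
  fit$level <- level
  fit
}

# Wilson score interval for a binomial proportion (vectorized over phat).
wilson_interval <- function(phat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(lo = pmax(0, centre - half), hi = pmin(1, centre + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM fit: Nm = %.1f, m = %.3f (N_mean = %.0f, d = %.2g)\n",
              x$Nm, x$m, x$N_mean, x$d))
  cat(sprintf("R^2 = %s over %d taxa, %d samples\n",
              if (is.na(x$r_squared)) "NA (degenerate)" else sprintf("%.3f", x$r_squared),
              nrow(x$taxa), x$n_samples))
  cat("partition:", paste(names(table(x$taxa$partition)),
                          table(x$taxa$partition), collapse = ", "), "\n")
  invisible(x)
}
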