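# Peak detection in divergence distributions and molecular-clock dating.
#
# Whole-genome duplications appear as modes in the distribution of paralog
# divergences. Modes are estimated by a univariate Gaussian mixture
# (unequal variances) fitted on log-transformed Ks (raw scale for 4dTv), with
# the number of components chosen by BIC; a kernel-density fallback is
# available for small samples.

#' Detect peaks in a divergence distribution
#'
#' Fits Gaussian mixtures with 1..`max_components` components and selects the
#' component count by BIC. Ks values are fitted on the log scale (a standard
#' transformation for rate distributions; zero, saturated and above-cap values
#' are removed first) and reported back-transformed, so `mean` is the peak
#' location on the natural scale. 4dTv values are fitted on the raw scale.
#' Peaks are reported in ascending mean order and, following the usual
#' naming of recent/intermediate/ancient duplication modes, the top-3-weight
#' components are labelled alpha, beta, gamma by ascending mean.
#'
#' @param values numeric vector of per-pair ks or 4dTv values.
#' @param statistic `"ks"` or `"fourdtv"`.
#' @param max_components maximum number of mixture components.
#' @param cap values above this are excluded before fitting; default 5 for ks
#'   (the Jukes-Cantor correction explodes near saturation) and 0.5 for raw
#'   4dTv (the transversion proportion asymptotes at 1/2 under K80, so larger
#'   values are sampling noise from spurious or saturated pairs).
#' @param method `"gmm"` (default) or `"kde"` (Gaussian kernel, Silverman
#'   bandwidth, local maxima).
#' @param min_values minimum sample size for the mixture fit.
#' @param seed RNG seed for mixture initialisation.
#' @return data.frame of class `peak_estimates` with columns `statistic`,
#'   `mean`, `weight`, `sigma`, `label`.
#' @export
detect_peaks <- function(values, statistic = c("ks", "fourdtv"),
                         max_components = 4L, cap = NULL,
                         method = c("gmm", "kde"), min_values = 30L,
                         seed = 1729L) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (is.null(cap)) cap <- if (statistic == "ks") 5 else 0.5
  v <- values[is.finite(values) & values <= cap]
  log_scale <- statistic == "ks"
  if (log_scale) v <- v[v > 0]
  if (length(v) < min_values && method == "gmm") {
    stop("need at least ", min_values, " finite values for the mixture fit (",
         length(v), " supplied); consider method = \"kde\"")
  }
  if (stats::sd(v) == 0) {
    warning("constant input: single zero-width component")
    return(peak_frame(statistic, mean = v[1], weight = 1, sigma = 0))
  }
  x <- if (log_scale) log(v) else v
  if (method == "gmm") {
    set.seed(seed)
    fit <- Mclust(x, G = seq_len(max_components), modelNames = "V",
                  verbose = FALSE)
    if (is.null(fit)) stop("mixture fit failed")
    mu <- as.numeric(fit$parameters$mean)
    w <- as.numeric(fit$parameters$pro)
    sg <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sg) == 1L) sg <- rep(sg, length(mu))
  } else {
    d <- stats::density(x, bw = "nrd0")
    i <- which(diff(sign(diff(d$y))) == -2) + 1L
    if (length(i) == 0) i <- which.max(d$y)
    mu <- d$x[i]
    # weight: share of observations nearest each mode
    nearest <- apply(abs(outer(x, mu, "-")), 1, which.min)
    w <- tabulate(nearest, nbins = length(mu)) / length(x)
    sg <- rep(d$bw, length(mu))
  }
  o <- order(mu)
  mu <- mu[o]; w <- w[o]; sg <- sg[o]
  if (log_scale) {
    sg <- exp(mu) * sg   # delta-method spread on the natural scale
    mu <- exp(mu)
  }
  peak_frame(statistic, mu, w, sg)
}

peak_frame <- function(statistic, mean, weight, sigma) {
  out <- data.frame(statistic = statistic, mean = mean,
                    weight = weight / sum(weight), sigma = sigma,
                    label = NA_character_, stringsAsFactors = FALSE)
  top <- utils::head(order(out$weight, decreasing = TRUE), 3L)
  top <- top[order(out$mean[top])]
  out$label[top] <- c("alpha", "beta", "gamma")[seq_along(top)]
  class(out) <- c("peak_estimates", "data.frame")
  out
}

#' Date divergence peaks with a molecular clock
#'
#' Converts a synonymous-divergence peak location into an absolute age with
#' T = Ks / (2 * rate), where `rate` is the synonymous substitution rate per
#' site per year (1.5e-8 for dicots). The factor 2 accounts for the two
#' lineages accumulating substitutions independently since the duplication.
#'
#' @param peaks a `peak_estimates` table with `statistic == "ks"`, or a
#'   numeric vector of ks peak locations.
#' @param rate synonymous substitutions per site per year; must be > 0.
#' @return the input with a `time_mya` column appended (or a numeric vector of
#'   ages in million years for numeric input).
#' @export
date_peak <- function(peaks, rate = 1.5e-8) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number")
  }
  if (is.numeric(peaks)) {
    return(peaks / (2 * rate) / 1e6)
  }
  if (!all(peaks$statistic == "ks")) {
    stop("dating applies to ks peaks only")
  }
  peaks$rate <- rate
  peaks$time_mya <- peaks$mean / (2 * rate) / 1e6
  peaks
}
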