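#' Intensity autocorrelation curve
#'
#' The central exchange object between the forward model, the multi-tau
#' correlator, the fitter and the noise model: a lag grid with g2 values and
#' optionally a coherence factor and per-lag standard deviations.
#'
#' @param tau Strictly increasing lag times, s.
#' @param g2 Intensity autocorrelation values, same length as `tau`.
#' @param beta Coherence factor in (0, 1], or `NA` when unknown (e.g. for
#'   measured curves before fitting).
#' @param sigma Optional per-lag standard deviation of g2.
#'
#' @return An object of class `correlation_curve` (also a data.frame with
#'   columns `tau`, `g2` and optionally `sigma`).
#' @examples
#' correlation_curve(tau = c(1e-6, 1e-5), g2 = c(1.49, 1.35), beta = 0.5)
#' @export
correlation_curve <- function(tau, g2, beta = NA_real_, sigma = NULL) {
  tau <- as.numeric(tau); g2 <- as.numeric(g2)
  if (length(tau) != length(g2))
    stop("`tau` and `g2` must have the same length")
  if (length(tau) == 0L) stop("empty curve")
  if (any(tau < 0)) stop("lag times must be >= 0")
  if (any(diff(tau) <= 0)) stop("`tau` must be strictly increasing")
  if (!is.na(beta) && (beta <= 0 || beta > 1))
    stop("`beta` must lie in (0, 1]")
  df <- data.frame(tau = tau, g2 = g2)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(tau))
      stop("`sigma` must match the lag grid length")
    if (any(sigma < 0)) stop("`sigma` must be >= 0")
    df$sigma <- sigma
  }
  structure(df, beta = beta, class = c("correlation_curve", "data.frame"))
}

#' @export
print.correlation_curve <- function(x, ...) {
  b <- attr(x, "beta")
  cat(sprintf("<correlation_curve> %d lags, tau %.3g .. %.3g s%s%s\n",
              nrow(x), min(x$tau), max(x$tau),
              if (is.na(b)) "" else sprintf(", beta = %.3g", b),
              if ("sigma" %in% names(x)) ", with per-lag sigma" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more lags\n", nrow(x) - 6L))
  invisible(x)
}

#' Coherence factor stored on a correlation curve
#'
#' @param curve A [correlation_curve()].
#' @return The coherence factor `beta`, possibly `NA`.
#' @export
curve_beta <- function(curve) {
  stopifnot(inherits(curve, "correlation_curve"))
  attr(curve, "beta")
}

#' Write a correlation curve as delimited text
#'
#' Plain comma-separated text with header `tau_s,g2` and an optional third
#' `sigma` column; reread losslessly by [read_correlation_curve()].
#'
#' @param curve A [correlation_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(tau_s = curve$tau, g2 = curve$g2)
  if ("sigma" %in% names(curve)) df$sigma <- curve$sigma
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correlation curve from delimited text
#'
#' @param path File with header columns `tau_s,g2[,sigma]`.
#' @param beta Optional coherence factor to attach.
#' @return A [correlation_curve()].
#' @export
read_correlation_curve <- function(path, beta = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("tau_s", "g2")
  if (!all(need %in% names(df)))
    stop("curve file must have header columns tau_s,g2[,sigma]: ", path)
  correlation_curve(df$tau_s, df$g2, beta = beta,
                    sigma = if ("sigma" %in% names(df)) df$sigma else NULL)
}
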