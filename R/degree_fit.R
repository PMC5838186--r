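# Degree-distribution power-law fit. Scale-free networks have degree counts
# N(k) ~ a * k^b with b < 0; the fit is ordinary least squares of
# log10 N(k) on log10 k, the convention of network-topology tools (not a
# maximum-likelihood exponent estimate).

#' Degree histogram
#'
#' @param graph an interaction graph.
#' @return data frame with ascending degree `k` and count `count` (zero-count
#'   degrees omitted); counts sum to the node count.
#' @export
degree_histogram <- function(graph) {
  d <- igraph::degree(graph)
  if (length(d) == 0) {
    return(data.frame(k = integer(), count = integer()))
  }
  tab <- table(d)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Fit a power law to a degree histogram
#'
#' Fits `N(k) = a * k^b` by least squares of `log10 N(k)` on `log10 k`, using
#' only points with `k >= 1` and `N(k) >= 1` (degree 0 has no logarithm).
#' Reports the regression `r_squared_log` and, on the original scale, the
#' Pearson correlation between observed and fitted counts. Degenerate
#' zero-variance inputs yield `r_squared_log = 0` (and `correlation = 0`)
#' with a warning rather than an error.
#'
#' @param hist a [degree_histogram()] data frame (columns `k`, `count`).
#' @return an object of class `power_law_fit`: list with `a`, `b`,
#'   `correlation`, `r_squared_log`, `n_points`.
#' @export
fit_power_law <- function(hist) {
  stopifnot(is.data.frame(hist), all(c("k", "count") %in% names(hist)))
  use <- hist$k >= 1 & hist$count >= 1
  k <- hist$k[use]
  nk <- hist$count[use]
  if (length(k) < 2) {
    stop("power-law fit needs at least 2 points with k >= 1 and count >= 1")
  }
  x <- log10(k)
  y <- log10(nk)
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2])
  if (is.na(b)) b <- 0 # identical k values cannot happen in a histogram
  a <- 10^unname(stats::coef(fit)[1])
  if (stats::var(y) <= 0) {
    warning("zero variance in log-counts; r_squared_log reported as 0")
    r2 <- 0
  } else {
    r2 <- summary(fit)$r.squared
  }
  fitted_nk <- a * k^b
  if (stats::sd(nk) <= 0 || stats::sd(fitted_nk) <= 0) {
    if (stats::var(y) > 0) warning("degenerate fit; correlation reported as 0")
    correlation <- 0
  } else {
    correlation <- stats::cor(nk, fitted_nk)
  }
  structure(list(a = a, b = b, correlation = correlation,
                 r_squared_log = r2, n_points = length(k)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: N(k) = %.4g * k^%.4g  (correlation %.3f, R2 on log values %.3f, %d points)\n",
    x$a, x$b, x$correlation, x$r_squared_log, x$n_points))
  invisible(x)
}

#' Degree distribution with fitted counts
#'
#' @param hist a [degree_histogram()] data frame.
#' @param fit a [fit_power_law()] result.
#' @return data frame with `k`, `count` and the fitted `a * k^b` (NA at
#'   `k = 0`).
#' @export
degree_fit_table <- function(hist, fit) {
  fitted <- ifelse(hist$k >= 1, fit$a * hist$k^fit$b, NA_real_)
  data.frame(k = hist$k, count = hist$count, fitted = fitted)
}
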