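#' Potential scale reduction factor (R-hat)
#'
#' Gelman-Rubin convergence diagnostic with the Brooks-Gelman sampling-
#' variability correction, computed from two or more chains of equal
#' post-burn-in length. Values below 1.1 are the conventional convergence
#' criterion. For a fitted model, returns the stored per-parameter values.
#'
#' @param x a numeric matrix (iterations x chains) or an `occuband_fit`.
#' @param ... unused.
#' @return Scalar (matrix input) or named vector (fit input).
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @rdname rhat
#' @export
rhat.default <- function(x, ...) {
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2) stop("R-hat needs at least 2 chains")
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B_n <- stats::var(means)                 # = B/n
  if (W == 0) return(1)
  varplus <- (n - 1) / n * W + B_n
  r2 <- (m + 1) / m * varplus / W - (n - 1) / (m * n)
  sqrt(max(r2, 0))
}

#' @rdname rhat
#' @export
rhat.occuband_fit <- function(x, ...) x$rhat

#' Posterior summaries: median and 95% credible interval
#'
#' Equal-tailed quantile summaries (0.025, 0.5, 0.975) per parameter from
#' pooled post-burn-in draws.
#'
#' @param draws numeric vector or matrix (iterations x parameters).
#' @return `data.frame` with `parameter`, `median`, `lower`, `upper`.
#' @examples
#' posterior_summary(matrix(1:100, 100, 1, dimnames = list(NULL, "x")))
#' @export
posterior_summary <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) == 0) stop("no draws to summarize")
  q <- apply(draws, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  nm <- colnames(draws)
  if (is.null(nm)) nm <- paste0("par", seq_len(ncol(draws)))
  data.frame(parameter = nm, median = q[2, ], lower = q[1, ], upper = q[3, ],
             row.names = NULL)
}

#' Squared-loss Bayesian p-value (posterior predictive check)
#'
#' For every retained draw the sampler records the squared-loss discrepancy
#' `T(y, theta) = sum_cells (y - E[y | theta, latent])^2` for the observed
#' data and for a replicate data set simulated from the same draw; the
#' Bayesian p-value is the fraction of draws in which the replicate
#' discrepancy exceeds the observed one. Values near 0 or 1 indicate lack of
#' fit; ties (possible because the discrepancies are sums over finitely many
#' binary cells) are split at random. Only cells that entered the likelihood
#' (surveyed sessions; banding years after first capture) are included.
#'
#' @param fit an `occuband_fit`.
#' @param layer `"pooled"` (sum over both data types, for the joint model),
#'   `"point"` or `"band"`.
#' @return p-value in `[0, 1]`.
#' @export
bayes_pvalue <- function(fit, layer = c("pooled", "point", "band")) {
  layer <- match.arg(layer)
  d <- fit$disc
  to <- switch(layer,
               pooled = d[, "T_obs_point"] + d[, "T_obs_band"],
               point = d[, "T_obs_point"],
               band = d[, "T_obs_band"])
  tr <- switch(layer,
               pooled = d[, "T_rep_point"] + d[, "T_rep_band"],
               point = d[, "T_rep_point"],
               band = d[, "T_rep_band"])
  ties <- tr == to
  mean(tr > to | (ties & runif(length(to)) < 0.5))
}
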