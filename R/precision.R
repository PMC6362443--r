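#' Relative credible-interval precision gain of the joint model
#'
#' For every site-year quantity - apparent survival `phi_jt`, abundance
#' `N_jt` and recruitment `G_jt` - computes the length of the 95% credible
#' interval under a single-data fit and under the joint fit, and the relative
#' difference `(single - joint) / joint`: positive values mean the joint
#' model is more precise, and the magnitude is the fractional precision
#' gained by adding the second data type.
#'
#' Survival is compared for any pair of fits (every model predicts `phi` at
#' every site from the shared regression); `N` and `G` require both fits to
#' carry the abundance component (point vs joint). Cells whose joint
#' credible interval has zero length are undefined and dropped with a
#' warning.
#'
#' @param single an `occuband_fit` from a single-data model.
#' @param joint an `occuband_fit` from the joint model on the same data.
#' @return Object of class `ob_precision`: `cells` (per-cell data frame) and
#'   `aggregate` (mean and SD of the relative difference per parameter).
#' @examples
#' \donttest{
#' tr <- sim_occuband(study_design(25, 5, 3, 3, seed = 1), seed = 1)
#' ctl <- mcmc_control(2, 2000, 1000)
#' fp <- fit_occuband(tr$detections, NULL, tr$covariates, "point",
#'                    control = ctl, seed = 1)
#' fj <- fit_occuband(tr$detections, tr$bandings, tr$covariates, "joint",
#'                    control = ctl, seed = 1)
#' relative_bci(fp, fj)
#' }
#' @export
relative_bci <- function(single, joint) {
  stopifnot(inherits(single, "occuband_fit"), inherits(joint, "occuband_fit"))
  if (joint$model != "joint")
    stop("second argument must be a joint-model fit")
  if (!identical(single$design$n_sites, joint$design$n_sites) ||
      !identical(single$design$n_years, joint$design$n_years))
    stop("fits are not on matching designs")
  J <- joint$design$n_sites; T <- joint$design$n_years

  bci_len <- function(draws) {
    q <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    q[2, ] - q[1, ]
  }
  cell_df <- function(par, len_s, len_j, years) {
    data.frame(parameter = par,
               site = rep(seq_len(J), times = length(years)),
               year = rep(years, each = J),
               len_single = len_s, len_joint = len_j,
               reldiff = ifelse(len_j > 0, (len_s - len_j) / len_j, NA_real_))
  }

  cells <- cell_df("phi", bci_len(single$phi), bci_len(joint$phi), 2:T)
  if (!is.null(single$N) && !is.null(joint$N)) {
    cells <- rbind(cells,
                   cell_df("N", bci_len(single$N), bci_len(joint$N), 1:T),
                   cell_df("G", bci_len(single$G), bci_len(joint$G), 2:T))
  }
  ndrop <- sum(is.na(cells$reldiff))
  if (ndrop > 0)
    warning(ndrop, " cell(s) with zero-length joint BCI dropped")

  agg <- do.call(rbind, lapply(split(cells, cells$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               mean = mean(d$reldiff, na.rm = TRUE),
               sd = sd(d$reldiff, na.rm = TRUE),
               n_cells = sum(!is.na(d$reldiff)))
  }))
  rownames(agg) <- NULL
  structure(list(cells = cells, aggregate = agg,
                 single_model = single$model),
            class = "ob_precision")
}

#' @export
print.ob_precision <- function(x, digits = 3, ...) {
  cat("Relative BCI-length difference, ", x$single_model,
      " model vs joint model [(single - joint)/joint]:\n", sep = "")
  y <- x$aggregate
  y$mean <- round(y$mean, digits); y$sd <- round(y$sd, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Violin-style plot of per-site precision gains
#'
#' Mirrored kernel-density outlines of the per-cell relative BCI-length
#' differences, one violin per parameter, with the mean marked.
#'
#' @param x an `ob_precision`.
#' @param ... unused.
#' @return Invisibly, `x`.
#' @export
plot.ob_precision <- function(x, ...) {
  sp <- split(x$cells$reldiff, x$cells$parameter)
  sp <- lapply(sp, function(v) v[is.finite(v)])
  sp <- sp[vapply(sp, length, integer(1)) > 1]
  np <- length(sp)
  plot.default(NULL, xlim = c(0.5, np + 0.5),
               ylim = range(unlist(sp)), xaxt = "n",
               xlab = "", ylab = "relative BCI-length difference")
  axis(1, at = seq_len(np), labels = names(sp))
  for (i in seq_len(np)) {
    d <- density(sp[[i]])
    w <- 0.35 * d$y / max(d$y)
    polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
            col = adjustcolor("steelblue", 0.5), border = "grey30")
    lines(c(i - 0.25, i + 0.25), rep(mean(sp[[i]]), 2), lwd = 2)
  }
  abline(h = 0, lty = 3)
  invisible(x)
}
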