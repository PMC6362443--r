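#' @export
print.occuband_fit <- function(x, ...) {
  cat("occuband fit:", x$model, "model\n")
  cat("  ", x$design$n_sites, " sites x ", x$design$n_years, " years",
      if (!is.null(x$bandings)) paste0("; ", length(x$bandings$f),
                                       " banded individuals"), "\n", sep = "")
  cat("  ", x$control$n_chains, " chains x ", x$control$n_iter,
      " iterations (burn-in ", x$control$burn_in, ", thin ",
      x$control$thin, "); ", nrow(x$beta), " retained draws\n", sep = "")
  mr <- max(x$rhat)
  if (is.na(mr)) cat("  R-hat unavailable (single chain)\n")
  else cat(sprintf("  max R-hat = %.3f%s\n", mr,
                   if (mr < 1.1) "" else "  [convergence not reached]"))
  invisible(x)
}

#' Posterior summary table of a fitted model
#'
#' Per-parameter posterior medians, equal-tailed 95% credible intervals and
#' R-hat for the effective coefficients (indicator times raw value when
#' selection is on), plus indicator posterior means when indicator variable
#' selection was used.
#'
#' @param object an `occuband_fit`.
#' @param ... unused.
#' @return `data.frame` (invisibly for print).
#' @export
summary.occuband_fit <- function(object, ...) {
  out <- object$summary
  if (!is.null(object$vmeans)) {
    out$support <- NA_real_
    sel <- names(object$vmeans)
    for (nm in sel) {
      rows <- if (nm %in% c("a4", "d2"))
        grep(paste0("^", nm, "\\["), out$parameter)
      else which(out$parameter == nm)
      out$support[rows] <- object$vmeans[[nm]]
    }
  }
  class(out) <- c("summary.occuband_fit", "data.frame")
  out
}

#' @export
print.summary.occuband_fit <- function(x, digits = 3, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.occuband_fit <- function(object, ...) {
  setNames(object$summary$median, object$summary$parameter)
}

#' Traceplots and survival-estimate plots for a fitted model
#'
#' `type = "trace"` overlays the chains for a few key parameters (the block
#' intercepts by default); `type = "phi"` plots posterior median apparent
#' survival with 95% credible bands over years, averaged across sites.
#'
#' @param x an `occuband_fit`.
#' @param type `"trace"` or `"phi"`.
#' @param pars parameters for the traceplot.
#' @param ... passed to the underlying plot calls.
#' @return Invisibly, `x`.
#' @export
plot.occuband_fit <- function(x, type = c("trace", "phi"),
                              pars = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (is.null(pars)) {
      cand <- c("a0", "b0", "c0", "d0", "e0")
      pars <- cand[cand %in% x$summary$parameter]
    }
    op <- par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
    on.exit(par(op))
    for (pp in pars) {
      m <- vapply(x$beta_chains, function(b) b[, pp],
                  numeric(nrow(x$beta_chains[[1]])))
      matplot(m, type = "l", lty = 1, ylab = pp, xlab = "", ...)
    }
  } else {
    J <- x$design$n_sites; T <- x$design$n_years
    qs <- apply(x$phi, 2, quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE)
    med <- colMeans(matrix(qs[2, ], J, T - 1))
    lo <- colMeans(matrix(qs[1, ], J, T - 1))
    hi <- colMeans(matrix(qs[3, ], J, T - 1))
    yrs <- 2:T
    plot.default(yrs, med, type = "b", ylim = range(lo, hi), xlab = "year",
                 ylab = "apparent survival (site mean)", ...)
    lines(yrs, lo, lty = 2); lines(yrs, hi, lty = 2)
  }
  invisible(x)
}

#' Posterior predictive replicate data sets
#'
#' Draws replicate detection/non-detection (and banding, for models that
#' include it) data sets from randomly selected posterior draws, conditioning
#' on the drawn latent abundances and alive states - the same predictive
#' distribution the goodness-of-fit discrepancy uses.
#'
#' @param object an `occuband_fit`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of length `nsim`; each element has `$detections` and/or
#'   `$bandings` binary arrays shaped like the observed data.
#' @export
simulate.occuband_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  J <- des$n_sites; K <- des$n_sessions; T <- des$n_years
  rows <- sample.int(nrow(object$beta), nsim, replace = TRUE)
  nbox <- integer(J); nbox[des$nbox_sites] <- 1L
  out <- vector("list", nsim)
  for (r in seq_along(rows)) {
    i <- rows[r]
    rep_i <- list()
    if (!is.null(object$N)) {
      b <- object$beta[i, ]
      d2 <- b[grep("^d2\\[", names(b))]
      Nmat <- matrix(object$N[i, ], J, T)
      y <- array(NA_integer_, c(J, K, T))
      for (t in seq_len(T)) for (k in seq_len(K)) {
        on <- which(des$sampled[, k, t] & !is.na(object$detections$y[, k, t]))
        if (!length(on)) next
        p <- plogis(b["d0"] + b["d1"] * nbox[on] + d2[des$observer[on, k, t]])
        y[on, k, t] <- rbinom(length(on), 1L, 1 - (1 - p)^Nmat[on, t])
      }
      rep_i$detections <- y
    }
    if (!is.null(object$z) && length(object$bandings$f) > 0) {
      b <- object$beta[i, ]
      I <- length(object$bandings$f)
      zmat <- matrix(object$z[i, ], I, T)
      pB <- plogis(b["e0"] + b["e1"] * object$bandings$sex)
      yb <- matrix(NA_integer_, I, T)
      for (ii in seq_len(I)) {
        fi <- object$bandings$f[ii]
        yb[ii, fi] <- 1L
        if (fi < T) {
          tt <- (fi + 1):T
          yb[ii, tt] <- rbinom(length(tt), 1L, zmat[ii, tt] * pB[ii])
        }
      }
      rep_i$bandings <- yb
    }
    out[[r]] <- rep_i
  }
  out
}

#' Pearson residuals of the detection layer
#'
#' Residuals `(y - p_hat) / sqrt(p_hat (1 - p_hat))` per surveyed
#' site-session-year, where `p_hat` is the posterior mean of the effective
#' detection probability `1 - (1 - p_jkt)^N_jt`.
#'
#' @param object an `occuband_fit` with a detection component.
#' @param ... unused.
#' @return Array (site x session x year), `NA` at unsurveyed cells.
#' @export
residuals.occuband_fit <- function(object, ...) {
  if (is.null(object$N))
    stop("residuals are defined for the detection layer (point/joint models)")
  des <- object$design
  J <- des$n_sites; K <- des$n_sessions; T <- des$n_years
  nbox <- integer(J); nbox[des$nbox_sites] <- 1L
  rows <- unique(round(seq(1, nrow(object$beta),
                           length.out = min(nrow(object$beta), 500))))
  ndr <- length(rows)
  peff <- array(0, c(J, K, T))
  d2cols <- grep("^d2\\[", colnames(object$beta))
  for (i in rows) {
    b <- object$beta[i, ]
    Nmat <- matrix(object$N[i, ], J, T)
    for (t in seq_len(T)) for (k in seq_len(K)) {
      p <- plogis(b["d0"] + b["d1"] * nbox +
                    object$beta[i, d2cols][des$observer[, k, t]])
      peff[, k, t] <- peff[, k, t] + (1 - (1 - p)^Nmat[, t]) / ndr
    }
  }
  res <- (object$detections$y - peff) / sqrt(peff * (1 - peff))
  res[is.na(object$detections$y)] <- NA
  res
}
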