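#' Define a monitoring study design
#'
#' Lays out a point-count study: sites (point-count stations) grouped into
#' transects, repeat visits (sessions) within years, a subset of sites that
#' carry nest boxes (where banding happens), and an observer assigned to every
#' surveyed site-session-year. The default arguments reproduce the scale of
#' the motivating field study: 149 stations on 15 transects surveyed 3 times
#' per year for 8 years, nest boxes at roughly half the stations, and a pool
#' of 9 observers.
#'
#' Sites are assigned to transects in contiguous blocks of near-equal size
#' (stations lie along transect lines). Nest-box sites are drawn without
#' replacement; observers are assigned uniformly at random per
#' site-session-year. `sampled` starts all-`TRUE`; set entries to `FALSE` to
#' emulate unequal effort (e.g. years in which a transect was visited once).
#'
#' @param n_sites number of point-count stations.
#' @param n_transects number of transects; must not exceed `n_sites`.
#' @param n_sessions visits per year (secondary periods).
#' @param n_years study years (primary periods).
#' @param nbox_fraction fraction of sites receiving nest boxes, in (0, 1].
#' @param n_observers size of the observer pool.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `ob_design`: a list with counts, the
#'   site-to-transect map `transect`, `nbox_sites`, the observer array
#'   `observer` (site x session x year) and the logical `sampled` mask.
#' @examples
#' d <- study_design(n_sites = 20, n_transects = 4, n_years = 3, seed = 1)
#' table(d$transect)
#' @export
study_design <- function(n_sites = 149, n_transects = 15, n_sessions = 3,
                         n_years = 8, nbox_fraction = 72 / 149,
                         n_observers = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- c(n_sites = n_sites, n_transects = n_transects,
              n_sessions = n_sessions, n_years = n_years,
              n_observers = n_observers)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("all design counts must be positive integers")
  if (n_transects > n_sites)
    stop("invalid design: more transects (", n_transects,
         ") than sites (", n_sites, ")")
  if (nbox_fraction <= 0 || nbox_fraction > 1)
    stop("nbox_fraction must be in (0, 1]")

  # contiguous near-equal blocks of stations along each transect line
  transect <- sort(rep_len(seq_len(n_transects), n_sites))
  n_nbox <- max(1L, round(nbox_fraction * n_sites))
  nbox_sites <- sort(sample.int(n_sites, n_nbox))
  observer <- array(sample.int(n_observers, n_sites * n_sessions * n_years,
                               replace = TRUE),
                    dim = c(n_sites, n_sessions, n_years))
  sampled <- array(TRUE, dim = c(n_sites, n_sessions, n_years))

  structure(list(n_sites = as.integer(n_sites),
                 n_transects = as.integer(n_transects),
                 n_sessions = as.integer(n_sessions),
                 n_years = as.integer(n_years),
                 n_observers = as.integer(n_observers),
                 transect = as.integer(transect),
                 nbox_sites = as.integer(nbox_sites),
                 observer = observer,
                 sampled = sampled),
            class = "ob_design")
}

#' @export
print.ob_design <- function(x, ...) {
  cat("Study design:", x$n_sites, "sites on", x$n_transects, "transects,",
      x$n_sessions, "sessions x", x$n_years, "years\n")
  cat("  nest boxes at", length(x$nbox_sites), "sites;",
      x$n_observers, "observers;",
      sum(!x$sampled), "unsurveyed site-session-years\n")
  invisible(x)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "ob_design"))
  if (length(design$transect) != design$n_sites)
    stop("transect map length does not match n_sites")
  if (!all(design$nbox_sites %in% seq_len(design$n_sites)))
    stop("nbox_sites must be a subset of sites")
  # at least one surveyed session per site-year
  per_sy <- apply(design$sampled, c(1, 3), any)
  if (!all(per_sy))
    stop("sampled mask leaves some site-years entirely unsurveyed")
  invisible(design)
}

#' Generate site and site-year covariates for a design
#'
#' Produces the covariates the demographic regressions use: standardized burn
#' severity (`dnbr`, site-level), a nest-box indicator (`nbox`, from the
#' design), a burned indicator, time since fire (`tfire`), and standardized
#' snag and live-tree basal area (`snag`, `live`, site x year). Burn severity
#' and snag basal area are drawn higher at burned sites so that the covariate
#' correlation structure resembles a post-wildfire landscape; `dnbr`, `snag`
#' and `live` are standardized to mean zero and unit variance.
#'
#' Time since fire is coded as `burned_j * (t + tfire_start - 1)`, a site-year
#' covariate that is zero at unburned sites: the verbal "indicator for burned
#' x time since fire" definition. With `tfire_site_specific = FALSE` it is the
#' pure yearly index `t + tfire_start - 1` at every site, the form the model
#' equations print (the two coincide when all sites burned).
#'
#' @param design an `ob_design`.
#' @param burned_fraction fraction of sites inside a fire perimeter; the
#'   default matches the motivating study (109 of 149 stations burned).
#' @param tfire_site_specific logical, see Details.
#' @param tfire_start value of the time-since-fire index in study year 1
#'   (the study began one year post-fire).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `ob_covariates`: list with `dnbr`, `nbox`,
#'   `burned` (length `n_sites`), `tfire`, `snag`, `live`
#'   (`n_sites` x `n_years` matrices) and the `design`.
#' @examples
#' d <- study_design(n_sites = 30, n_transects = 3, n_years = 4, seed = 1)
#' cv <- sim_covariates(d, seed = 2)
#' round(c(mean(cv$dnbr), var(cv$dnbr)), 3)
#' @export
sim_covariates <- function(design, burned_fraction = 109 / 149,
                           tfire_site_specific = TRUE, tfire_start = 1,
                           seed = NULL) {
  validate_design(design)
  if (!is.null(seed)) set.seed(seed)
  J <- design$n_sites
  T <- design$n_years

  burned <- integer(J)
  burned[sample.int(J, round(burned_fraction * J))] <- 1L
  dnbr_raw <- ifelse(burned == 1, rnorm(J, 1.5, 0.8), rnorm(J, 0, 0.3))
  dnbr <- as.numeric(scale(dnbr_raw))

  nbox <- integer(J)
  nbox[design$nbox_sites] <- 1L

  yr <- matrix(rep(seq_len(T) + tfire_start - 1, each = J), J, T)
  tfire <- if (tfire_site_specific) yr * burned else yr

  # snags accumulate where fire killed trees; live basal area the reverse
  snag_raw <- 0.9 * burned + matrix(rnorm(J * T, 0, 0.5), J, T) +
    rnorm(J, 0, 0.4)
  live_raw <- -0.7 * burned + matrix(rnorm(J * T, 0, 0.5), J, T) +
    rnorm(J, 0, 0.4)
  snag <- matrix(as.numeric(scale(as.vector(snag_raw))), J, T)
  live <- matrix(as.numeric(scale(as.vector(live_raw))), J, T)

  structure(list(dnbr = dnbr, nbox = nbox, burned = burned,
                 tfire = tfire, snag = snag, live = live, design = design),
            class = "ob_covariates")
}

#' @export
print.ob_covariates <- function(x, ...) {
  cat("Covariates for", x$design$n_sites, "sites x", x$design$n_years,
      "years (", sum(x$burned), "burned sites )\n")
  invisible(x)
}
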