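#' Read and write the long-form data files
#'
#' Detection data travel as long-form CSV with columns
#' `site, transect, session, year, observer, y`; unsurveyed
#' site-session-years are simply absent. Banding data use columns
#' `individual, site, sex, year, y, first_capture` with one row per
#' individual-year from first capture onward. Covariates use columns
#' `site, transect, year, nbox, burned, dnbr, tfire, snag, live`. All
#' indices are 1-based in the files. Writers and readers round-trip exactly;
#' readers validate loudly (duplicate keys, non-binary `y`, detections
#' before the declared first capture are errors).
#'
#' @param x the object to write.
#' @param path file path.
#' @name occuband_io
NULL

#' @rdname occuband_io
#' @export
write_detections <- function(x, path) {
  stopifnot(inherits(x, "ob_detections"))
  des <- x$design
  idx <- which(!is.na(x$y), arr.ind = TRUE)
  df <- data.frame(site = idx[, 1], transect = des$transect[idx[, 1]],
                   session = idx[, 2], year = idx[, 3],
                   observer = des$observer[idx], y = x$y[idx])
  df <- df[order(df$site, df$year, df$session), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname occuband_io
#' @param design optional `ob_design` giving the full dimensions (otherwise
#'   inferred from the maxima present in the file).
#' @export
read_detections <- function(path, design = NULL) {
  df <- read.csv(path)
  required <- c("site", "transect", "session", "year", "observer", "y")
  if (!all(required %in% names(df)))
    stop("detection file must have columns ", paste(required, collapse = ", "))
  if (anyDuplicated(df[c("site", "session", "year")]))
    stop("duplicate (site, session, year) rows in detection file")
  if (!all(df$y %in% c(0, 1)))
    stop("detection y values must be 0 or 1")
  if (is.null(design)) {
    design <- study_design(n_sites = max(df$site),
                           n_transects = max(df$transect),
                           n_sessions = max(df$session),
                           n_years = max(df$year),
                           n_observers = max(df$observer),
                           nbox_fraction = 1)
    tr <- integer(design$n_sites)
    tr[df$site] <- df$transect
    design$transect <- tr
    design$sampled[] <- FALSE
    design$nbox_sites <- integer(0)
  }
  y <- array(NA_integer_,
             c(design$n_sites, design$n_sessions, design$n_years))
  cells <- cbind(df$site, df$session, df$year)
  y[cells] <- as.integer(df$y)
  design$observer[cells] <- as.integer(df$observer)
  design$sampled[cells] <- TRUE
  structure(list(y = y, design = design), class = "ob_detections")
}

#' @rdname occuband_io
#' @export
write_bandings <- function(x, path) {
  stopifnot(inherits(x, "ob_bandings"))
  I <- length(x$f)
  rows <- do.call(rbind, lapply(seq_len(I), function(i) {
    yrs <- x$f[i]:x$n_years
    data.frame(individual = i, site = x$site[i], sex = x$sex[i],
               year = yrs, y = x$y[i, yrs], first_capture = x$f[i])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname occuband_io
#' @param n_years number of study years (otherwise the file maximum).
#' @export
read_bandings <- function(path, n_years = NULL) {
  df <- read.csv(path)
  required <- c("individual", "site", "sex", "year", "y")
  if (!all(required %in% names(df)))
    stop("banding file must have columns ", paste(required, collapse = ", "))
  if (!all(df$y %in% c(0, 1))) stop("banding y values must be 0 or 1")
  if (is.null(n_years)) n_years <- max(df$year)
  ids <- sort(unique(df$individual))
  I <- length(ids)
  y <- matrix(NA_integer_, I, n_years)
  f <- site <- sex <- integer(I)
  for (i in seq_len(I)) {
    d <- df[df$individual == ids[i], ]
    fi <- if ("first_capture" %in% names(df)) d$first_capture[1]
          else min(d$year[d$y == 1])
    if (any(d$y == 1 & d$year < fi))
      stop("individual ", ids[i], " detected before declared first capture")
    if (!any(d$y == 1 & d$year == fi))
      stop("individual ", ids[i], " has no detection at first capture year")
    f[i] <- fi
    site[i] <- d$site[1]
    sex[i] <- d$sex[1]
    y[i, d$year] <- as.integer(d$y)
  }
  structure(list(y = y, f = f, site = site, sex = sex, z = NULL,
                 n_years = n_years, design = NULL),
            class = "ob_bandings")
}

#' @rdname occuband_io
#' @export
write_covariates <- function(x, path) {
  stopifnot(inherits(x, "ob_covariates"))
  des <- x$design
  J <- des$n_sites; T <- des$n_years
  df <- data.frame(site = rep(seq_len(J), T),
                   transect = rep(des$transect, T),
                   year = rep(seq_len(T), each = J),
                   nbox = rep(x$nbox, T), burned = rep(x$burned, T),
                   dnbr = rep(x$dnbr, T),
                   tfire = as.vector(x$tfire), snag = as.vector(x$snag),
                   live = as.vector(x$live))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname occuband_io
#' @export
read_covariates <- function(path, design = NULL) {
  df <- read.csv(path)
  required <- c("site", "transect", "year", "nbox", "burned", "dnbr",
                "tfire", "snag", "live")
  if (!all(required %in% names(df)))
    stop("covariate file must have columns ", paste(required, collapse = ", "))
  J <- max(df$site); T <- max(df$year)
  if (nrow(df) != J * T) stop("covariate file must have one row per site-year")
  df <- df[order(df$year, df$site), ]
  if (is.null(design)) {
    design <- study_design(n_sites = J, n_transects = max(df$transect),
                           n_years = T, nbox_fraction = 1)
    design$transect <- df$transect[seq_len(J)]
    design$nbox_sites <- which(df$nbox[seq_len(J)] == 1)
  }
  structure(list(dnbr = df$dnbr[seq_len(J)],
                 nbox = as.integer(df$nbox[seq_len(J)]),
                 burned = as.integer(df$burned[seq_len(J)]),
                 tfire = matrix(df$tfire, J, T),
                 snag = matrix(df$snag, J, T),
                 live = matrix(df$live, J, T),
                 design = design),
            class = "ob_covariates")
}

#' Scenario files: one YAML document describing a whole experiment
#'
#' A scenario bundles the design, covariate-generation settings, generating
#' parameter values, the marking rule, MCMC settings, prior switches and the
#' seed. `read_scenario()` validates the schema (unknown keys are rejected)
#' and fills defaults; `write_scenario()` is its inverse.
#'
#' @param path YAML file path.
#' @param scenario a scenario list as returned by `read_scenario()`.
#' @return `read_scenario()`: a validated scenario list of class
#'   `ob_scenario`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_scenario(raw)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname read_scenario
#' @param x a plain list with scenario fields.
#' @export
validate_scenario <- function(x) {
  known <- c("design", "covariates", "params", "marking_rule", "mcmc",
             "priors", "costs", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "))
  check_block <- function(block, allowed) {
    extra <- setdiff(names(x[[block]]), allowed)
    if (length(extra))
      stop("unknown keys in scenario block '", block, "': ",
           paste(extra, collapse = ", "))
  }
  check_block("design", names(formals(study_design)))
  check_block("covariates", setdiff(names(formals(sim_covariates)),
                                    c("design", "seed")))
  check_block("params", names(formals(occuband_params)))
  check_block("mcmc", names(formals(mcmc_control)))
  check_block("priors", names(formals(occuband_priors)))
  check_block("costs", c("point", "band", "joint"))
  if (is.null(x$seed)) stop("scenario must set a seed")
  x$marking_rule <- if (is.null(x$marking_rule)) 0.3 else x$marking_rule
  structure(x, class = "ob_scenario")
}
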