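#' Exponential photoinhibition photosynthesis-irradiance model
#'
#' The rapid-light-curve model
#' rETR(PAR) = rETRs * (1 - exp(-alpha * PAR / rETRs)) * exp(-beta * PAR / rETRs),
#' where `alpha` is the light-limited initial slope, `beta` >= 0 the slope
#' beyond the onset of photoinhibition, and `rETRs` the maximum potential
#' rETR in the absence of photoinhibition. With `beta = 0` the curve is the
#' classic saturating exponential.
#'
#' @param par photon irradiance(s), µmol photons m^-2 s^-1, >= 0.
#' @param alpha initial slope (> 0).
#' @param beta photoinhibition slope (>= 0).
#' @param retr_s scale parameter (> 0, a.u.).
#' @return rETR value(s), 0 at `par = 0`.
#' @export
model_retr <- function(par, alpha, beta, retr_s) {
  check_rlc_params(alpha, beta, retr_s)
  if (any(par < 0)) stop("negative PAR")
  retr_s * (1 - exp(-alpha * par / retr_s)) * exp(-beta * par / retr_s)
}

check_rlc_params <- function(alpha, beta, retr_s) {
  if (!(alpha > 0)) stop("alpha must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  if (!(retr_s > 0)) stop("retr_s must be > 0")
  invisible(NULL)
}

#' Closed-form curve maximum of the photoinhibition model
#'
#' rETRmax = rETRs * (alpha/(alpha+beta)) * (beta/(alpha+beta))^(beta/alpha),
#' with the 0^0 limit at `beta = 0` taken as 1 (so rETRmax = rETRs, the
#' continuity limit of the uninhibited curve).
#'
#' @inheritParams model_retr
#' @return The maximum of the rETR curve over irradiance.
#' @export
retr_max <- function(alpha, beta, retr_s) {
  check_rlc_params(alpha, beta, retr_s)
  if (beta == 0) return(retr_s)
  retr_s * (alpha / (alpha + beta)) * (beta / (alpha + beta))^(beta / alpha)
}

#' Light saturation coefficient
#'
#' Ek = rETRmax / alpha, the irradiance at the onset of saturation (where
#' the initial slope meets the curve maximum).
#'
#' @inheritParams model_retr
#' @return Ek in µmol photons m^-2 s^-1.
#' @export
rlc_ek <- function(alpha, beta, retr_s) {
  check_rlc_params(alpha, beta, retr_s)
  retr_max(alpha, beta, retr_s) / alpha
}

#' Fit the photoinhibition model to rapid-light-curve data
#'
#' Nonlinear least squares by the Levenberg-Marquardt algorithm
#' ([minpack.lm::nlsLM()]) with box constraints alpha > 0, beta >= 0,
#' rETRs > 0. Starting values (unless supplied): alpha0 from the
#' through-origin least-squares slope of the 3 lowest-irradiance points,
#' rETRs0 = 1.2 x the largest observed rETR, beta0 = 0.01 alpha0.
#' Non-convergence is reported through the `converged` flag, never as an
#' exception; all-zero data return the degenerate lower-bound fit with a
#' warning.
#'
#' @param data an `rlc_data` object or data frame with columns `par`,
#'   `retr` (>= 4 points, at least one with `par > 0`).
#' @param init optional named list/vector with starting `alpha`, `beta`,
#'   `retr_s`.
#' @return Object of class `rlc_fit`: list with `alpha`, `beta`, `retr_s`,
#'   `retr_max`, `ek`, `rss`, `converged`, `iterations`, `data`.
#' @export
fit_rlc <- function(data, init = NULL) {
  if (!is.data.frame(data) || !all(c("par", "retr") %in% names(data)))
    stop("`data` must have columns par and retr")
  data <- data[stats::complete.cases(data[, c("par", "retr")]), ]
  if (nrow(data) < 4L) stop("need at least 4 RLC points")
  if (!any(data$par > 0)) stop("need at least one point with PAR > 0")

  if (all(data$retr == 0)) {
    warning("all rETR values are 0; returning degenerate lower-bound fit")
    eps <- 1e-8
    return(new_rlc_fit(eps, 0, eps, rss = 0, converged = FALSE,
                       iterations = 0L, data = data))
  }
  if (is.null(init)) {
    low <- data[data$par > 0, ][order(data$par[data$par > 0]), ][
      seq_len(min(3L, sum(data$par > 0))), ]
    alpha0 <- sum(low$par * low$retr) / sum(low$par^2)
    if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- 1e-3
    # beta and retr_s are strongly correlated near beta = 0, so a single
    # start can stall in the flat valley; try an inhibited, an
    # uninhibited and a high-scale start and keep the best fit
    top <- max(data$retr)
    starts <- list(
      list(alpha = alpha0, beta = 0.01 * alpha0, retr_s = 1.2 * top),
      list(alpha = alpha0, beta = 0, retr_s = 1.02 * top),
      list(alpha = alpha0, beta = 0.05 * alpha0, retr_s = 2 * top))
  } else {
    starts <- list(as.list(init)[c("alpha", "beta", "retr_s")])
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500,
                                     ftol = 1e-12, ptol = 1e-12)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        retr ~ model_retr(par, alpha, beta, retr_s),
        data = data,
        start = st[c("alpha", "retr_s", "beta")],
        lower = c(alpha = 1e-12, retr_s = 1e-12, beta = 0),
        control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(cf = stats::coef(fit)[c("alpha", "beta", "retr_s")],
                   rss = rss, conv = fit$convInfo)
  }
  # the full model is ill-conditioned near beta = 0 (beta and retr_s are
  # nearly collinear there); always offer the exact uninhibited submodel
  red <- tryCatch(
    minpack.lm::nlsLM(
      retr ~ retr_s * (1 - exp(-alpha * par / retr_s)),
      data = data,
      start = starts[[1]][c("alpha", "retr_s")],
      lower = c(alpha = 1e-12, retr_s = 1e-12),
      control = ctrl),
    error = function(e) NULL)
  if (!is.null(red)) {
    rss <- sum(stats::resid(red)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(red)
      best <- list(cf = c(alpha = cf[["alpha"]], beta = 0,
                          retr_s = cf[["retr_s"]]),
                   rss = rss, conv = red$convInfo)
    }
  }
  if (is.null(best)) {
    st <- starts[[1]]
    return(new_rlc_fit(st$alpha, st$beta, st$retr_s,
                       rss = sum((data$retr -
                                    model_retr(data$par, st$alpha,
                                               st$beta, st$retr_s))^2),
                       converged = FALSE, iterations = 0L, data = data))
  }
  cf <- best$cf
  new_rlc_fit(cf[["alpha"]], cf[["beta"]], cf[["retr_s"]],
              rss = best$rss,
              converged = isTRUE(best$conv$isConv),
              iterations = best$conv$finIter, data = data)
}

new_rlc_fit <- function(alpha, beta, retr_s, rss, converged, iterations,
                        data) {
  rmax <- retr_max(max(alpha, 1e-12), max(beta, 0), max(retr_s, 1e-12))
  structure(list(alpha = alpha, beta = beta, retr_s = retr_s,
                 retr_max = rmax, ek = rmax / alpha, rss = rss,
                 converged = converged, iterations = iterations,
                 data = data),
            class = "rlc_fit")
}

#' @export
print.rlc_fit <- function(x, ...) {
  cat(sprintf(paste0("rlc_fit: alpha = %.4g, beta = %.4g, rETRs = %.4g | ",
                     "rETRmax = %.4g, Ek = %.4g | rss = %.3g, %s\n"),
              x$alpha, x$beta, x$retr_s, x$retr_max, x$ek, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.rlc_fit <- function(object, ...)
  c(alpha = object$alpha, beta = object$beta, retr_s = object$retr_s,
    retr_max = object$retr_max, ek = object$ek)

#' Fit rapid light curves for every chamber of a specimen
#'
#' Convenience wrapper: [build_rlc()] + [fit_rlc()] per chamber mask.
#'
#' @param seq `fluor_sequence`.
#' @param map `chamber_map`.
#' @return Named list of `rlc_fit` objects, youngest chamber first.
#' @export
fit_rlc_per_chamber <- function(seq, map) {
  ages <- seq_len(n_chambers(map)) - 1L
  out <- lapply(ages, function(a)
    fit_rlc(build_rlc(seq, chamber_mask(map, a), roi = chamber_name(a))))
  names(out) <- chamber_name(ages)
  out
}
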