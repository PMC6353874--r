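#' Risk set for an age window
#'
#' Returns the participants at risk in the half-open window [t, t + dt):
#' those not yet diagnosed at age t whose diagnosis status is observable
#' over the whole window.  All interval comparisons use half-open
#' conventions, so integer-rounded ages land in exactly one window:
#' membership requires (delta = 0, or delta = 1 with t <= td) and
#' t + dt < t2.  The enrollment-restricted variant additionally requires
#' t1 < t; it conditions on being enrolled before the window, which matters
#' when the event (death) precludes later enrollment, and is a subset of
#' the standard risk set for every window.
#'
#' @param records survival data.frame with columns \code{t1}, \code{t2},
#'   \code{td}, \code{delta} (as returned by \code{\link{healthspan}}).
#' @param t window start age (years).
#' @param dt window width in years (> 0).
#' @param mode \code{"standard"} or \code{"enrollment_restricted"}.
#' @return logical vector marking risk-set membership.
#' @export
risk_set <- function(records, t, dt,
                     mode = c("standard", "enrollment_restricted")) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("window width dt must be positive")
  d <- records$delta
  td <- records$td
  healthy_at_t <- (d == 0L) | (d == 1L & t <= td)
  healthy_at_t[is.na(healthy_at_t)] <- d[is.na(healthy_at_t)] == 0L
  inset <- healthy_at_t & (t + dt < records$t2)
  if (mode == "enrollment_restricted") inset <- inset & (records$t1 < t)
  inset
}

#' Age-specific incidence rate in one window
#'
#' N_h is the size of the risk set, N_d the number of its members diagnosed
#' in [t, t + dt), and the rate m = N_d / (dt * N_h) per year.  An empty
#' risk set yields NA (undefined), never zero.
#'
#' @inheritParams risk_set
#' @return list with \code{n_h}, \code{n_d}, \code{rate}.
#' @export
incidence_rate <- function(records, t, dt,
                           mode = c("standard", "enrollment_restricted")) {
  mode <- match.arg(mode)
  inset <- risk_set(records, t, dt, mode)
  n_h <- sum(inset)
  td <- records$td
  hit <- inset & records$delta == 1L & !is.na(td) & t <= td & td < t + dt
  n_d <- sum(hit)
  if (n_h == 0L) {
    warning("empty risk set at t = ", t, "; rate undefined")
    return(list(n_h = 0L, n_d = 0L, rate = NA_real_))
  }
  list(n_h = n_h, n_d = n_d, rate = n_d / (dt * n_h))
}

#' Age-specific incidence curve
#'
#' Evaluates the windowed incidence rate over an age grid, with 95%
#' confidence intervals.  The default interval is exact Poisson on the
#' event count N_d with exposure N_h * dt (standard for rare-event
#' incidence); a normal approximation is available.
#'
#' @inheritParams risk_set
#' @param ages strictly increasing window start ages.
#' @param ci_method \code{"poisson"} (exact, default) or \code{"normal"}.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with columns \code{age}, \code{n_h}, \code{n_d},
#'   \code{rate}, \code{ci_low}, \code{ci_high}, \code{log_ok} (TRUE when
#'   rate and bounds are strictly positive, i.e. safe on a log scale).
#' @export
incidence_curve <- function(records, ages, dt = 1,
                            mode = c("standard", "enrollment_restricted"),
                            ci_method = c("poisson", "normal"),
                            conf_level = 0.95) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  if (any(diff(ages) <= 0)) stop("age grid must be strictly increasing")
  out <- lapply(ages, function(t) {
    r <- suppressWarnings(incidence_rate(records, t, dt, mode))
    if (is.na(r$rate)) {
      ci <- c(NA_real_, NA_real_)
    } else if (ci_method == "poisson") {
      exposure <- r$n_h * dt
      ci <- stats::poisson.test(r$n_d, conf.level = conf_level)$conf.int /
        exposure
    } else {
      se <- sqrt(r$n_d) / (r$n_h * dt)
      zq <- stats::qnorm(1 - (1 - conf_level) / 2)
      ci <- r$rate + c(-1, 1) * zq * se
    }
    data.frame(age = t, n_h = r$n_h, n_d = r$n_d, rate = r$rate,
               ci_low = ci[1], ci_high = ci[2])
  })
  out <- do.call(rbind, out)
  out$log_ok <- !is.na(out$rate) & out$rate > 0 & out$ci_low > 0
  out
}

#' Gompertz slope of an incidence curve
#'
#' Weighted least-squares fit of log(rate) against age over windows with at
#' least \code{min_events} events (weights = event counts).  Under a
#' Gompertz hazard h0 * exp(gamma * t), the slope estimates gamma and the
#' intercept log(h0); the implied risk doubling time is log(2) / slope.
#'
#' @param curve output of \code{\link{incidence_curve}}.
#' @param min_events minimum N_d for a window to enter the fit.
#' @return list with \code{slope} (per year), \code{intercept} (log rate at
#'   age 0), \code{doubling_time} (years), \code{n_windows}.
#' @export
incidence_slope <- function(curve, min_events = 5) {
  use <- !is.na(curve$rate) & curve$rate > 0 & curve$n_d >= min_events
  if (sum(use) < 2) stop("need at least two usable windows")
  fit <- stats::lm(log(rate) ~ age, data = curve[use, ],
                   weights = curve$n_d[use])
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       doubling_time = log(2) / slope, n_windows = sum(use))
}
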