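#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-stratum effect estimates with weights w_i = 1 / se_i^2:
#' beta = sum(w_i beta_i) / sum(w_i), se = 1 / sqrt(sum(w_i)).
#'
#' @param beta per-stratum effect estimates.
#' @param se per-stratum standard errors (> 0).
#' @return list with \code{beta}, \code{se}, \code{z}, \code{p}.
#' @export
fixed_effect_meta <- function(beta, se) {
  if (length(beta) == 0) stop("no strata to combine")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return alpha / m.
#' @export
bonferroni <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Chi-square threshold for a tail probability
#'
#' The upper quantile k of the central chi-square with 1 df such that
#' P(chi2_1 > k) = alpha; e.g. alpha = 0.05 / 12 gives k of about 8.2.
#'
#' @param alpha tail probability in (0, 1).
#' @return the threshold k.
#' @export
chi2_threshold <- function(alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qchisq(alpha, df = 1, lower.tail = FALSE)
}

#' Replication design
#'
#' @param n_disc discovery sample size.
#' @param n_rep replication sample size.
#' @param lambda_ldsc LD-score regression intercept used to deflate
#'   discovery statistics (>= 1 expected; a warning is issued otherwise).
#' @param alpha replication significance level (default 0.05 / 12).
#' @return object of class \code{"replication_design"}.
#' @export
replication_design <- function(n_disc, n_rep, lambda_ldsc = 1,
                               alpha = 0.05 / 12) {
  stopifnot(n_disc >= 1, n_rep >= 1, alpha > 0, alpha < 1)
  if (lambda_ldsc < 1)
    warning("lambda_ldsc < 1 is unusual for an LD-score intercept")
  structure(list(n_disc = n_disc, n_rep = n_rep,
                 lambda_ldsc = lambda_ldsc, alpha = alpha),
            class = "replication_design")
}

#' Replication power of a discovery signal
#'
#' The replication test statistic is modelled as non-central chi-square
#' with 1 df and non-centrality NCP = (T2_disc - 1) * N_rep / N_disc, where
#' T2_disc = (beta_disc / se_disc)^2 / lambda_ldsc is the discovery
#' statistic deflated by the LD-score intercept.  NCP is floored at zero
#' (the formula can go negative for weak signals, which would be
#' undefined).  Power is the probability of exceeding the chi-square
#' threshold at the design's alpha.
#'
#' @param beta_disc discovery effect estimate(s).
#' @param se_disc discovery standard error(s) (> 0).
#' @param design a \code{\link{replication_design}}.
#' @return data.frame with columns \code{t2_disc}, \code{ncp}, \code{k},
#'   \code{power}.
#' @export
replication_power <- function(beta_disc, se_disc, design) {
  stopifnot(inherits(design, "replication_design"))
  if (any(se_disc <= 0)) stop("se_disc must be positive")
  t2 <- (beta_disc / se_disc)^2 / design$lambda_ldsc
  ncp <- pmax(0, (t2 - 1) * design$n_rep / design$n_disc)
  k <- chi2_threshold(design$alpha)
  power <- stats::pchisq(k, df = 1, ncp = ncp, lower.tail = FALSE)
  data.frame(t2_disc = t2, ncp = ncp, k = k, power = power)
}
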