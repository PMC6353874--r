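#' Residual weights for the perturbative score test
#'
#' From a fitted null model, each participant gets the weight
#' rho_n = e^{beta x_n} (e^{Gamma min(td_n, t2_n)} - 1) /
#'         sum_m e^{beta x_m} (e^{Gamma min(td_m, t2_m)} - 1),
#' normalized to sum to one, and the martingale-type residual
#' delta_n - N_d rho_n.  At the maximum-likelihood fit, N_d rho_n equals
#' the participant's fitted cumulative hazard (baseline score identity),
#' so the residuals sum to zero exactly.
#'
#' @param fit a converged \code{\link{coxgomp_fit}}.
#' @param records the survival records the model was fitted to.
#' @param X the design matrix used in the fit (or NULL).
#' @return object of class \code{"residual_weights"}: list with \code{rho},
#'   \code{n_d}, \code{resid}.
#' @export
residual_weights <- function(fit, records, X = NULL) {
  stopifnot(inherits(fit, "coxgomp_fit"))
  n_d <- sum(records$delta)
  if (n_d == 0) stop("all-censored cohort: no events, weights undefined")
  eta <- if (is.null(X)) 0 else drop(as.matrix(X) %*% fit$params$beta)
  w <- exp(eta) * expm1(fit$params$gamma * obs_time(records))
  rho <- w / sum(w)
  structure(list(rho = rho, n_d = n_d,
                 resid = records$delta - n_d * rho),
            class = "residual_weights")
}

#' Per-variant perturbative score statistic
#'
#' Closed-form first-order effect estimate for a dosage s around the fitted
#' null model:
#'   beta_s  = sum_n s_n (delta_n - N_d rho_n) / (N_d V_rho(s)),
#'   sigma_s^2 = 1 / (N_d V_rho(s)),
#' where V_rho(s) is the rho-weighted central variance
#' sum_n rho_n (s_n - sum_m rho_m s_m)^2.  Since the residuals sum to zero,
#' the statistic is invariant to adding a constant to s.  A variant that is
#' monomorphic under the weights (zero weighted variance) fails QC and
#' returns NA.
#'
#' @param s dosage vector (missing values mean-imputed).
#' @param w a \code{\link{residual_weights}}.
#' @return list with \code{beta} (log hazard ratio per effect allele),
#'   \code{se}, \code{z}, \code{p}, \code{qc_pass}.
#' @export
snp_stat <- function(s, w) {
  stopifnot(inherits(w, "residual_weights"))
  if (length(s) != length(w$rho)) stop("dosage vector not aligned to weights")
  if (anyNA(s)) s[is.na(s)] <- mean(s, na.rm = TRUE)
  mu <- sum(w$rho * s)
  v <- sum(w$rho * (s - mu)^2)
  if (v <= 0)
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                qc_pass = FALSE))
  beta <- sum(s * w$resid) / (w$n_d * v)
  se <- 1 / sqrt(w$n_d * v)
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       qc_pass = TRUE)
}

#' Variant quality control
#'
#' Pass requires an expected effective minor allele count (twice the minor
#' allele frequency times sample size times imputation info) strictly above
#' \code{emac_min}, and imputation info strictly above \code{info_min}.
#'
#' @param eaf effect-allele frequency in [0, 1].
#' @param info imputation info score in (0, 1].
#' @param n sample size.
#' @param emac_min effective minor-allele-count threshold (default 200).
#' @param info_min info threshold (default 0.7).
#' @return logical (vectorized).
#' @export
variant_qc <- function(eaf, info, n, emac_min = 200, info_min = 0.7) {
  maf <- pmin(eaf, 1 - eaf)
  (2 * maf * n * info > emac_min) & (info > info_min)
}

#' Genome-wide variant screen
#'
#' Applies \code{\link{variant_qc}} and \code{\link{snp_stat}} to every
#' variant of a dosage panel, in input order.  Missing dosages are
#' mean-imputed per variant.
#'
#' @param panel a \code{\link{dosage_panel}} aligned to the weights.
#' @param w a \code{\link{residual_weights}}.
#' @param emac_min,info_min QC thresholds, see \code{\link{variant_qc}}.
#' @return summary-statistics data.frame with columns \code{snp},
#'   \code{chr}, \code{pos}, \code{ea}, \code{ra}, \code{eaf}, \code{info},
#'   \code{n}, \code{beta}, \code{se}, \code{z}, \code{p}, \code{qc}.
#' @export
run_gwas <- function(panel, w, emac_min = 200, info_min = 0.7) {
  stopifnot(inherits(panel, "dosage_panel"), inherits(w, "residual_weights"))
  if (ncol(panel$dosages) != length(w$rho))
    stop("panel has ", ncol(panel$dosages), " participants but weights have ",
         length(w$rho))
  n <- length(w$rho)
  vm <- panel$variants
  qc_meta <- variant_qc(vm$eaf, vm$info, n, emac_min, info_min)
  res <- lapply(seq_len(nrow(vm)), function(j) {
    if (!qc_meta[j])
      return(data.frame(beta = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, qc = FALSE))
    st <- snp_stat(panel$dosages[j, ], w)
    data.frame(beta = st$beta, se = st$se, z = st$z, p = st$p,
               qc = st$qc_pass)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    snp = vm$id, chr = vm$chr, pos = vm$pos, ea = vm$ea, ra = vm$ra,
    eaf = vm$eaf, info = vm$info, n = n,
    beta = res$beta, se = res$se, z = res$z, p = res$p, qc = res$qc,
    stringsAsFactors = FALSE
  )
  n_fail <- sum(!out$qc)
  if (n_fail > 0)
    message(n_fail, " variant(s) failed QC ",
            "(eMAC <= ", emac_min, ", info <= ", info_min,
            ", or monomorphic)")
  out
}

#' Genomic-control inflation factor (median estimator)
#'
#' lambda = median(chi-square statistics) / median of the central
#' chi-square with 1 df (0.4549...).
#'
#' @param x either chi-square statistics (\code{what = "chi2"}) or
#'   two-sided p-values (\code{what = "p"}, converted via the chi-square
#'   quantile).
#' @param what interpretation of \code{x}.
#' @return the scalar lambda.
#' @export
genomic_control_lambda <- function(x, what = c("chi2", "p")) {
  what <- match.arg(what)
  x <- x[!is.na(x)]
  if (length(x) < 1) stop("need at least one statistic")
  chi2 <- if (what == "p") stats::qchisq(x, df = 1, lower.tail = FALSE) else x
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Genomic-control adjustment of summary statistics
#'
#' Divides the chi-square statistics by lambda and recomputes p-values;
#' effect sizes keep their point estimates while standard errors inflate by
#' sqrt(lambda), so z = beta / se stays consistent with the adjusted
#' chi-square.  Ranking of p-values is preserved.  Lambda below 1 triggers
#' a warning and no deflation by default.
#'
#' @param stats_df summary statistics from \code{\link{run_gwas}}.
#' @param lambda inflation factor (>= 1 expected).
#' @param allow_deflation apply lambda < 1 anyway (default FALSE).
#' @return the adjusted summary-statistics data.frame.
#' @export
adjust_gc <- function(stats_df, lambda, allow_deflation = FALSE) {
  if (lambda < 1) {
    warning("lambda < 1; no deflation applied",
            if (allow_deflation) " is overridden" else "")
    if (!allow_deflation) return(stats_df)
  }
  out <- stats_df
  out$se <- stats_df$se * sqrt(lambda)
  out$z <- stats_df$beta / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out
}
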