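#' Simulation specification for a synthetic cohort
#'
#' Bundles and validates everything needed to generate a cohort whose event
#' ages follow Gompertz proportional hazards, together with multi-source
#' diagnosis records and Hardy-Weinberg genotype dosages.  The defaults
#' emulate a mid-life biobank design: enrollment ages uniform on [40, 70)
#' years and 8 years of administrative follow-up.
#'
#' @param n_participants number of participants (>= 1).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param conditions data.frame with columns \code{name}, \code{h0}
#'   (baseline hazard per year, > 0) and \code{gamma} (Gompertz shape per
#'   year, > 0), one row per condition.
#' @param covariate_effects named numeric vector of log-hazard effects per
#'   covariate unit (a covariate named \code{"sex"} is drawn Bernoulli(0.5)
#'   coded 0/1; any other covariate is standard normal).
#' @param variant_spec data.frame with columns \code{maf} (in (0, 0.5]),
#'   \code{beta} (per-allele log-hazard effect) and \code{info} (imputation
#'   info target in (0, 1]); may have zero rows.
#' @param enrollment_range numeric length-2: enrollment ages are uniform on
#'   \code{[enrollment_range[1], enrollment_range[2])} years.
#' @param followup_years administrative follow-up duration in years (>= 0).
#' @param interview_only_prob probability that a non-registry diagnosis is
#'   recorded only in the verbal-interview source.
#' @param death_condition name of the condition whose records go to the
#'   death registry (\code{NULL} if none).
#' @param round_ages emit integer-rounded record ages (registry data often
#'   carries rounded ages; the incidence estimator must tolerate them).
#'
#' @return an object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(n_participants,
                            seed = 1L,
                            conditions,
                            covariate_effects = c(sex = 0.26),
                            variant_spec = NULL,
                            enrollment_range = c(40, 70),
                            followup_years = 8,
                            interview_only_prob = 0.1,
                            death_condition = NULL,
                            round_ages = FALSE) {
  stopifnot(n_participants >= 1, is.data.frame(conditions))
  if (!all(c("name", "h0", "gamma") %in% names(conditions)))
    stop("conditions needs columns name, h0, gamma")
  if (any(conditions$h0 <= 0) || any(conditions$gamma <= 0))
    stop("all baseline hazards h0 and shapes gamma must be strictly positive")
  if (is.null(variant_spec))
    variant_spec <- data.frame(maf = numeric(), beta = numeric(), info = numeric())
  if (nrow(variant_spec) > 0) {
    if (any(variant_spec$maf <= 0 | variant_spec$maf > 0.5))
      stop("variant MAFs must lie in (0, 0.5]")
    if (any(variant_spec$info <= 0 | variant_spec$info > 1))
      stop("imputation info targets must lie in (0, 1]")
  }
  if (interview_only_prob < 0 || interview_only_prob > 1)
    stop("interview_only_prob must be a probability")
  if (followup_years < 0) stop("followup_years must be non-negative")
  if (!is.null(death_condition) && !death_condition %in% conditions$name)
    stop("death_condition must name a condition")
  structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    conditions = conditions,
    covariate_effects = covariate_effects,
    variant_spec = variant_spec,
    enrollment_range = enrollment_range,
    followup_years = followup_years,
    interview_only_prob = interview_only_prob,
    death_condition = death_condition,
    round_ages = round_ages
  ), class = "simulation_spec")
}

#' Draw Gompertz proportional-hazards event ages
#'
#' Exact inverse-CDF sampler for the hazard h(t) = h0 * exp(gamma * t + eta):
#' with E standard exponential, the event age is
#' t = log(1 + gamma * E / (h0 * exp(eta))) / gamma, so that the survival
#' function is S(t) = exp(-(h0 e^eta / gamma) (e^{gamma t} - 1)).
#'
#' @param n number of draws.
#' @param h0 baseline hazard per year (> 0).
#' @param gamma Gompertz shape per year (> 0).
#' @param eta linear predictor (log-hazard shift), scalar or length n.
#' @param E optional standard-exponential deviates (for deterministic use);
#'   drawn internally when missing.
#' @return event ages in years.
#' @export
draw_event_age <- function(n, h0, gamma, eta = 0, E = NULL) {
  if (h0 <= 0 || gamma <= 0) stop("h0 and gamma must be strictly positive")
  if (is.null(E)) E <- stats::rexp(n)
  log1p(gamma * E / (h0 * exp(eta))) / gamma
}

#' Simulate a Hardy-Weinberg dosage panel
#'
#' Hard genotype calls are binomial(2, MAF).  When the imputation-info
#' target is below 1, each dosage is a convex mix of the hard call and the
#' population mean 2*MAF with weight sqrt(info), so that the variance ratio
#' var(dosage) / (2 MAF (1 - MAF)) -- the standard info statistic --
#' approximates the target.
#'
#' @param variant_spec data.frame with columns \code{maf}, \code{beta},
#'   \code{info} (see \code{\link{simulation_spec}}).
#' @param n_participants cohort size.
#' @return a \code{dosage_panel}: list with \code{variants} (data.frame of
#'   id, chr, pos, ea, ra, eaf, info) and \code{dosages} (variants x
#'   participants matrix, entries in [0, 2]).
#' @export
simulate_genotypes <- function(variant_spec, n_participants) {
  m <- nrow(variant_spec)
  dos <- matrix(0, nrow = m, ncol = n_participants)
  eaf <- info_real <- numeric(m)
  for (j in seq_len(m)) {
    maf <- variant_spec$maf[j]
    if (maf <= 0 || maf > 0.5) stop("MAF must lie in (0, 0.5]")
    g <- stats::rbinom(n_participants, 2L, maf)
    a <- sqrt(variant_spec$info[j])
    d <- a * g + (1 - a) * 2 * maf
    dos[j, ] <- d
    eaf[j] <- mean(d) / 2
    info_real[j] <- stats::var(d) / (2 * maf * (1 - maf))
  }
  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(m)),
    chr = rep(1L, m),
    pos = seq_len(m) * 1000L,
    ea = rep("A", m), ra = rep("G", m),
    eaf = eaf, info = info_real,
    stringsAsFactors = FALSE
  )
  dosage_panel(variants, dos)
}

#' Construct a dosage panel
#'
#' @param variants data.frame with columns id, chr, pos, ea, ra, eaf, info.
#' @param dosages numeric matrix, one row per variant, one column per
#'   participant; entries in [0, 2] or NA for missing.
#' @param participants optional participant ids (column names).
#' @return object of class \code{"dosage_panel"}.
#' @export
dosage_panel <- function(variants, dosages, participants = NULL) {
  stopifnot(nrow(variants) == nrow(dosages))
  if (length(dosages) > 0 && any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  if (!is.null(participants)) colnames(dosages) <- participants
  structure(list(variants = variants, dosages = dosages),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("dosage_panel:", nrow(x$variants), "variants x",
      ncol(x$dosages), "participants\n")
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Each participant receives an enrollment age t1, an administrative
#' follow-up end t2 = t1 + followup_years, covariates, genotype dosages, and
#' one independent latent Gompertz event age per condition (proportional
#' hazards: the linear predictor sums the covariate and per-allele variant
#' effects).  Conditions with latent age below t2 are emitted as diagnosis
#' records; pre-enrollment events (age < t1) are kept, emulating clinical
#' history available at recruitment.  Non-registry records land in the
#' interview source alone with probability \code{interview_only_prob},
#' otherwise in the hospital source.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list with \code{diagnoses} (participant_id, source, code, age),
#'   \code{covariates} (participant_id + covariate columns),
#'   \code{followup} (participant_id, t1, t2), \code{panel} (a
#'   \code{dosage_panel}), \code{condition_map} (the code map used for the
#'   records), and \code{true_params} (echo of the generating values).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  ids <- sprintf("P%06d", seq_len(n))

  covs <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  eta_cov <- numeric(n)
  for (nm in names(spec$covariate_effects)) {
    x <- if (identical(nm, "sex")) stats::rbinom(n, 1L, 0.5) else stats::rnorm(n)
    covs[[nm]] <- x
    eta_cov <- eta_cov + spec$covariate_effects[[nm]] * x
  }

  panel <- simulate_genotypes(spec$variant_spec, n)
  eta_gen <- if (nrow(spec$variant_spec) > 0)
    drop(crossprod(panel$dosages, spec$variant_spec$beta)) else numeric(n)
  eta <- eta_cov + eta_gen

  t1 <- stats::runif(n, spec$enrollment_range[1], spec$enrollment_range[2])
  t2 <- t1 + spec$followup_years

  cond <- spec$conditions
  map <- synthetic_condition_map(cond$name, spec$death_condition)

  recs <- vector("list", nrow(cond))
  for (k in seq_len(nrow(cond))) {
    age <- draw_event_age(n, cond$h0[k], cond$gamma[k], eta)
    hit <- which(age < t2)
    if (length(hit) == 0) { recs[[k]] <- NULL; next }
    is_death <- !is.null(spec$death_condition) &&
      cond$name[k] == spec$death_condition
    if (is_death) {
      src <- rep("death_registry", length(hit))
      code <- rep(paste0("DTH_", toupper(cond$name[k])), length(hit))
    } else {
      interview_only <- stats::runif(length(hit)) < spec$interview_only_prob
      src <- ifelse(interview_only, "interview", "hospital")
      code <- ifelse(interview_only,
                     paste0("SR_", toupper(cond$name[k])),
                     paste0("ICD_", toupper(cond$name[k])))
    }
    a <- age[hit]
    if (spec$round_ages) a <- round(a)
    recs[[k]] <- data.frame(
      participant_id = ids[hit], source = src, code = code, age = a,
      stringsAsFactors = FALSE
    )
  }
  diagnoses <- do.call(rbind, recs)
  if (is.null(diagnoses))
    diagnoses <- data.frame(participant_id = character(), source = character(),
                            code = character(), age = numeric(),
                            stringsAsFactors = FALSE)
  diagnoses <- diagnoses[order(diagnoses$participant_id, diagnoses$age), ,
                         drop = FALSE]
  rownames(diagnoses) <- NULL
  colnames(panel$dosages) <- ids

  list(
    diagnoses = diagnoses,
    covariates = covs,
    followup = data.frame(participant_id = ids, t1 = t1, t2 = t2,
                          stringsAsFactors = FALSE),
    panel = panel,
    condition_map = map,
    true_params = list(
      seed = spec$seed, conditions = cond,
      covariate_effects = spec$covariate_effects,
      variant_spec = spec$variant_spec,
      eta = eta
    )
  )
}

# One synthetic code per condition and source; death goes only to the
# death registry, everything else to hospital (ICD-style) + interview codes.
synthetic_condition_map <- function(cond_names, death_condition = NULL) {
  rows <- lapply(cond_names, function(nm) {
    if (!is.null(death_condition) && nm == death_condition) {
      data.frame(condition = nm, source = "death_registry",
                 code = paste0("DTH_", toupper(nm)), stringsAsFactors = FALSE)
    } else {
      data.frame(condition = nm,
                 source = c("hospital", "interview"),
                 code = c(paste0("ICD_", toupper(nm)),
                          paste0("SR_", toupper(nm))),
                 stringsAsFactors = FALSE)
    }
  })
  condition_map(do.call(rbind, rows))
}
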