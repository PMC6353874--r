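#' Condition-code map
#'
#' Maps condition names to diagnosis codes per source.  Hospital (ICD-10
#' style) and registry codes are authoritative; interview (self-reported)
#' codes are a fallback used only when a participant has no hospital or
#' registry record for that condition.
#'
#' @param map data.frame with columns \code{condition}, \code{source}
#'   (one of hospital, interview, cancer_registry, death_registry) and
#'   \code{code}.
#' @return object of class \code{"condition_map"}.
#' @export
condition_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("condition", "source", "code") %in% names(map)))
  bad <- setdiff(unique(map$source), DIAGNOSIS_SOURCES)
  if (length(bad)) stop("unknown sources: ", paste(bad, collapse = ", "))
  if (anyDuplicated(map[c("condition", "source", "code")]))
    map <- unique(map)
  # within a condition a code may not be claimed by two sources
  for (cn in unique(map$condition)) {
    sub <- map[map$condition == cn, ]
    if (anyDuplicated(sub$code))
      stop("code sets must be disjoint across sources within condition ", cn)
  }
  structure(map, class = c("condition_map", "data.frame"))
}

DIAGNOSIS_SOURCES <- c("hospital", "interview", "cancer_registry",
                       "death_registry")

# Sources whose records take priority over the interview fallback.
PRIMARY_SOURCES <- c("hospital", "cancer_registry", "death_registry")

#' First-onset ages per participant and condition
#'
#' Resolves multi-source diagnosis records against a condition-code map.
#' For each participant/condition pair the onset age is the minimum over
#' hospital (and registry) records; self-reported interview records are
#' used only when no hospital/registry record exists for that pair.
#' Unmapped codes are skipped and counted (attribute \code{n_unmapped}).
#'
#' @param records data.frame with columns \code{participant_id},
#'   \code{source}, \code{code}, \code{age}.
#' @param map a \code{\link{condition_map}}.
#' @param match \code{"exact"} or \code{"prefix"}: prefix matching treats a
#'   map code as an ICD-10 block prefix (record code "C50" matches map
#'   entry "C5").
#' @return data.frame (\code{onset_table}) with columns
#'   \code{participant_id}, \code{condition}, \code{onset_age},
#'   \code{onset_source}; attribute \code{n_unmapped} counts skipped
#'   records.
#' @export
condition_onsets <- function(records, map, match = c("exact", "prefix")) {
  match <- match.arg(match)
  stopifnot(is.data.frame(records),
            all(c("participant_id", "source", "code", "age") %in%
                  names(records)))
  if (nrow(records) > 0 && any(records$age < 0))
    stop("negative ages in diagnosis records")
  bad_src <- !records$source %in% DIAGNOSIS_SOURCES
  n_bad_src <- sum(bad_src)
  records <- records[!bad_src, , drop = FALSE]

  if (match == "exact") {
    key <- paste(records$source, records$code, sep = "\r")
    mkey <- paste(map$source, map$code, sep = "\r")
    idx <- base::match(key, mkey)
  } else {
    idx <- rep(NA_integer_, nrow(records))
    for (s in unique(map$source)) {
      msel <- which(map$source == s)
      rsel <- which(records$source == s & is.na(idx))
      if (!length(rsel)) next
      for (mi in msel[order(-nchar(map$code[msel]))]) {
        hit <- startsWith(records$code[rsel], map$code[mi])
        idx[rsel[hit]] <- mi
        rsel <- rsel[!hit]
        if (!length(rsel)) break
      }
    }
  }
  unmapped <- is.na(idx)
  n_unmapped <- sum(unmapped) + n_bad_src
  if (n_unmapped > 0)
    message(n_unmapped, " diagnosis record(s) skipped (unmapped code or source)")
  rec <- records[!unmapped, , drop = FALSE]
  cond <- map$condition[idx[!unmapped]]

  if (nrow(rec) == 0) {
    out <- data.frame(participant_id = character(), condition = character(),
                      onset_age = numeric(), onset_source = character(),
                      stringsAsFactors = FALSE)
  } else {
    dt <- data.table::data.table(
      participant_id = rec$participant_id, condition = cond,
      age = rec$age, primary = rec$source %in% PRIMARY_SOURCES,
      source = rec$source
    )
    # hospital/registry minimum wins; interview minimum only as fallback
    res <- dt[, {
      if (any(primary)) {
        i <- which(primary)[which.min(age[primary])]
      } else {
        i <- which.min(age)
      }
      list(onset_age = age[i], onset_source = source[i])
    }, by = c("participant_id", "condition")]
    out <- as.data.frame(res)
  }
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("onset_table", "data.frame")
  out
}

#' Healthspan survival phenotype
#'
#' The healthspan event is the first onset among the selected conditions:
#' td = min onset age, delta = 1 iff td exists and td <= t2.  With
#' \code{death_mode = "censor"} death is removed from the event set and a
#' death age occurring before every other onset truncates the follow-up end
#' t2 instead (the sensitivity analysis treating death as censoring).
#'
#' @param onsets an onset table from \code{\link{condition_onsets}}.
#' @param followup data.frame with columns \code{participant_id},
#'   \code{t1}, \code{t2}.
#' @param conditions condition subset to use, in tie-break priority order;
#'   defaults to all conditions present.
#' @param death_mode \code{"event"} (death ends healthspan) or
#'   \code{"censor"}.
#' @param death_condition name of the death condition.
#' @return data.frame of survival records: \code{participant_id},
#'   \code{t1}, \code{t2}, \code{td} (NA when censored), \code{delta},
#'   \code{terminating_condition}.
#' @export
healthspan <- function(onsets, followup, conditions = NULL,
                       death_mode = c("event", "censor"),
                       death_condition = "death") {
  death_mode <- match.arg(death_mode)
  stopifnot(all(c("participant_id", "t1", "t2") %in% names(followup)))
  if (is.null(conditions)) conditions <- unique(onsets$condition)

  on <- onsets[onsets$condition %in% conditions, , drop = FALSE]
  death_on <- on[on$condition == death_condition, , drop = FALSE]
  if (death_mode == "censor")
    on <- on[on$condition != death_condition, , drop = FALSE]

  t2 <- followup$t2
  names(t2) <- followup$participant_id
  if (death_mode == "censor" && nrow(death_on) > 0) {
    # death can only truncate follow-up, never extend it
    trunc <- pmin(t2[death_on$participant_id], death_on$onset_age)
    t2[death_on$participant_id] <- trunc
  }

  # deterministic tie-break: order of `conditions` is the priority
  prio <- base::match(on$condition, conditions)
  ord <- order(on$participant_id, on$onset_age, prio)
  on <- on[ord, , drop = FALSE]
  first <- on[!duplicated(on$participant_id), , drop = FALSE]

  td <- first$onset_age[base::match(followup$participant_id,
                                    first$participant_id)]
  term <- first$condition[base::match(followup$participant_id,
                                      first$participant_id)]
  t2v <- unname(t2[followup$participant_id])
  delta <- as.integer(!is.na(td) & td <= t2v)
  td[delta == 0L] <- NA_real_
  term[delta == 0L] <- NA_character_
  if (any(delta == 1L & td > t2v, na.rm = TRUE))
    stop("internal consistency error: event age exceeds follow-up end")
  data.frame(
    participant_id = followup$participant_id,
    t1 = followup$t1, t2 = t2v, td = td, delta = delta,
    terminating_condition = term, stringsAsFactors = FALSE
  )
}

#' Event tallies with percentage shares
#'
#' Counts events per condition and expresses each count as a percentage of
#' the column total, rounded to one decimal -- the layout of the standard
#' events-by-source summary table.
#'
#' @param x either a named numeric vector of per-condition counts, an
#'   onset table (each onset counts as one event for its condition), or a
#'   healthspan survival data.frame (each event counts towards its
#'   terminating condition).
#' @param by_source when \code{x} is an onset table, also split counts by
#'   contributing source.
#' @return data.frame with columns \code{condition}, \code{events},
#'   \code{share} (percent, one decimal); with \code{by_source}, an extra
#'   \code{source} column and shares within each source column.
#' @export
tally <- function(x, by_source = FALSE) {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
    out <- data.frame(condition = names(counts),
                      events = as.numeric(counts),
                      stringsAsFactors = FALSE)
    out$share <- round(100 * out$events / sum(out$events), 1)
    return(out)
  }
  stopifnot(is.data.frame(x), nrow(x) > 0)
  if ("terminating_condition" %in% names(x)) {
    ev <- x[x$delta == 1L, , drop = FALSE]
    counts <- table(ev$terminating_condition)
    return(tally(stats::setNames(as.numeric(counts), names(counts))))
  }
  stopifnot("condition" %in% names(x))
  if (!by_source) {
    counts <- table(x$condition)
    return(tally(stats::setNames(as.numeric(counts), names(counts))))
  }
  parts <- lapply(split(x, x$onset_source), function(sub) {
    t <- tally(stats::setNames(as.numeric(table(sub$condition)),
                               names(table(sub$condition))))
    t$source <- sub$onset_source[1]
    t
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[c("source", "condition", "events", "share")]
}
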