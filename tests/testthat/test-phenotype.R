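# Phenotype builder: source-priority onset resolution, healthspan
# assembly, and event tallies.

simple_map <- function() {
  condition_map(data.frame(
    condition = c("cancer", "cancer", "diabetes", "diabetes", "mi", "mi",
                  "death"),
    source = c("hospital", "interview", "hospital", "interview",
               "hospital", "interview", "death_registry"),
    code = c("C50", "SR_CANCER", "E11", "SR_DIAB", "I21", "SR_MI",
             "DTH"),
    stringsAsFactors = FALSE
  ))
}

test_that("interview records are a fallback, not a competitor", {
  rec <- data.frame(
    participant_id = c("A", "A", "B", "B"),
    source = c("hospital", "interview", "hospital", "interview"),
    code = c("C50", "SR_DIAB", "I21", "SR_MI"),
    age = c(55, 50, 60, 58), stringsAsFactors = FALSE
  )
  on <- condition_onsets(rec, simple_map())
  get <- function(id, cond) on[on$participant_id == id &
                                 on$condition == cond, ]
  # no hospital diabetes record for A: interview age is used
  expect_equal(get("A", "cancer")$onset_age, 55)
  expect_equal(get("A", "diabetes")$onset_age, 50)
  expect_equal(get("A", "diabetes")$onset_source, "interview")
  # B has both hospital and interview MI: hospital wins even though later
  expect_equal(get("B", "mi")$onset_age, 60)
  expect_equal(get("B", "mi")$onset_source, "hospital")
})

test_that("unmapped codes are skipped and counted, empty input is empty", {
  rec <- data.frame(participant_id = "A", source = "hospital",
                    code = "Z99", age = 40, stringsAsFactors = FALSE)
  expect_message(on <- condition_onsets(rec, simple_map()), "skipped")
  expect_equal(nrow(on), 0)
  expect_equal(attr(on, "n_unmapped"), 1)
  on0 <- condition_onsets(rec[0, ], simple_map())
  expect_equal(nrow(on0), 0)
  expect_error(condition_onsets(
    data.frame(participant_id = "A", source = "hospital", code = "C50",
               age = -1), simple_map()), "negative")
})

test_that("prefix matching resolves ICD-10 block codes", {
  rec <- data.frame(participant_id = "A", source = "hospital",
                    code = "C509", age = 51, stringsAsFactors = FALSE)
  on_exact <- suppressMessages(condition_onsets(rec, simple_map(),
                                                match = "exact"))
  on_pref <- condition_onsets(rec, simple_map(), match = "prefix")
  expect_equal(nrow(on_exact), 0)
  expect_equal(on_pref$condition, "cancer")
  expect_equal(on_pref$onset_age, 51)
})

test_that("healthspan takes the first onset among selected conditions", {
  on <- data.frame(participant_id = c("A", "A", "B"),
                   condition = c("cancer", "diabetes", "cancer"),
                   onset_age = c(55, 50, 72),
                   onset_source = "hospital", stringsAsFactors = FALSE)
  fu <- data.frame(participant_id = c("A", "B", "C"),
                   t1 = c(45, 45, 45), t2 = c(70, 70, 70),
                   stringsAsFactors = FALSE)
  hs <- healthspan(on, fu)
  expect_equal(hs$td[hs$participant_id == "A"], 50)
  expect_equal(hs$terminating_condition[hs$participant_id == "A"],
               "diabetes")
  # B's onset is beyond follow-up: censored; C has no onsets at all
  expect_equal(hs$delta[hs$participant_id == "B"], 0L)
  expect_true(is.na(hs$td[hs$participant_id == "B"]))
  expect_equal(hs$delta[hs$participant_id == "C"], 0L)
  expect_equal(hs$t2[hs$participant_id == "C"], 70)
})

test_that("death as censoring truncates follow-up instead of ending span", {
  on <- data.frame(participant_id = c("A", "A"),
                   condition = c("death", "cancer"),
                   onset_age = c(60, 65), onset_source = "death_registry",
                   stringsAsFactors = FALSE)
  fu <- data.frame(participant_id = "A", t1 = 45, t2 = 70,
                   stringsAsFactors = FALSE)
  cens <- healthspan(on, fu, death_mode = "censor")
  expect_equal(cens$delta, 0L)
  expect_equal(cens$t2, 60)
  ev <- healthspan(on, fu, death_mode = "event")
  expect_equal(ev$delta, 1L)
  expect_equal(ev$td, 60)
  expect_equal(ev$terminating_condition, "death")
})

test_that("death modes agree whenever death is not the first onset", {
  set.seed(8)
  spec <- simulation_spec(
    n_participants = 1500, seed = 8,
    conditions = data.frame(name = c("cancer", "death"),
                            h0 = c(1e-4, 4e-5), gamma = c(0.098, 0.09)),
    covariate_effects = c(sex = 0.2),
    followup_years = 8, death_condition = "death")
  coh <- simulate_cohort(spec)
  on <- condition_onsets(coh$diagnoses, coh$condition_map)
  ev <- healthspan(on, coh$followup, death_mode = "event")
  cen <- healthspan(on, coh$followup, death_mode = "censor")
  death_first <- ev$delta == 1L &
    !is.na(ev$terminating_condition) & ev$terminating_condition == "death"
  same <- !death_first
  expect_true(any(death_first))  # the comparison must be non-vacuous
  expect_identical(ev$delta[same], cen$delta[same])
  expect_equal(ev$td[same], cen$td[same])
})

test_that("adding a record never increases any healthspan event age", {
  on <- data.frame(participant_id = c("A", "B"),
                   condition = c("cancer", "cancer"),
                   onset_age = c(55, 60), onset_source = "hospital",
                   stringsAsFactors = FALSE)
  fu <- data.frame(participant_id = c("A", "B"), t1 = 45, t2 = 70,
                   stringsAsFactors = FALSE)
  base <- healthspan(on, fu)
  extra <- rbind(on, data.frame(participant_id = "A",
                                condition = "diabetes", onset_age = 48,
                                onset_source = "interview"))
  more <- healthspan(extra, fu)
  expect_true(all(more$td <= base$td, na.rm = TRUE))
})

test_that("tie at the minimal onset resolves by condition priority order", {
  on <- data.frame(participant_id = c("A", "A"),
                   condition = c("diabetes", "cancer"),
                   onset_age = c(50, 50), onset_source = "hospital",
                   stringsAsFactors = FALSE)
  fu <- data.frame(participant_id = "A", t1 = 45, t2 = 70,
                   stringsAsFactors = FALSE)
  hs <- healthspan(on, fu, conditions = c("cancer", "diabetes"))
  expect_equal(hs$terminating_condition, "cancer")
  hs2 <- healthspan(on, fu, conditions = c("diabetes", "cancer"))
  expect_equal(hs2$terminating_condition, "diabetes")
})

test_that("tally shares are one-decimal percentages summing to 100", {
  counts <- c(cancer = 74172, diabetes = 26026, mi = 24751, stroke = 6902,
              copd = 5881, dementia = 2706, death = 2399, chf = 1883)
  t <- tally(counts)
  expect_equal(t$share[t$condition == "cancer"], 51.3)
  expect_equal(t$share[t$condition == "diabetes"], 18.0)
  expect_equal(t$share[t$condition == "death"], 1.7)
  expect_lt(abs(sum(t$share) - 100), 0.1 * length(counts))
  expect_equal(tally(c(only = 42))$share, 100.0)
})

test_that("tally works on onset tables and survival records", {
  on <- data.frame(participant_id = c("A", "A", "B"),
                   condition = c("cancer", "diabetes", "cancer"),
                   onset_age = c(55, 50, 60),
                   onset_source = c("hospital", "interview", "hospital"),
                   stringsAsFactors = FALSE)
  t <- tally(on)
  expect_equal(t$events[t$condition == "cancer"], 2)
  ts <- tally(on, by_source = TRUE)
  expect_true(all(c("source", "share") %in% names(ts)))
  fu <- data.frame(participant_id = c("A", "B"), t1 = 45, t2 = 70,
                   stringsAsFactors = FALSE)
  th <- tally(healthspan(on, fu))
  expect_equal(th$events[th$condition == "diabetes"], 1)
})
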