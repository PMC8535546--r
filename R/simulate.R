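# Synthetic cohort generator. Each user follows one of four behavioural
# archetypes mirroring the groups a K-means clustering of real app users
# resolves: steady exercisers (about one session every two days throughout),
# decliners (moderate first month, then tapering to almost nothing),
# rampers (slow start, rising second and third months) and inactives (very
# low activity in all three months). Active-day workout seconds are
# log-normal (positive, right-skewed: cohort dispersion far exceeds the
# mean, and active-day mass falls mostly below 1800 s), with a log-normal
# per-user level multiplier. Adherence - any activity in the fourth month -
# is sampled with archetype-dependent propensity so that behaviour in
# months 1-3 carries signal about month 4, and the realised adherent count
# is exactly round(fraction * n).

#' Behavioural archetype specification
#'
#' @param name archetype name.
#' @param p_active daily activity probabilities for months 1, 2, 3.
#' @param p_month4 daily activity probability in month 4 for adherent
#'   users (non-adherent users have an all-zero month 4 by definition).
#' @param dur_meanlog,dur_sdlog log-normal parameters of active-day workout
#'   seconds (median `exp(dur_meanlog)`).
#' @param propensity relative weight with which users of this archetype are
#'   drawn into the adherent class.
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(name, p_active, p_month4,
                           dur_meanlog = log(600), dur_sdlog = 0.7,
                           propensity = 0.5) {
  stopifnot(length(p_active) == 3L, all(p_active >= 0), all(p_active <= 1),
            p_month4 >= 0, p_month4 <= 1, dur_sdlog >= 0)
  structure(list(name = name, p_active = p_active, p_month4 = p_month4,
                 dur_meanlog = dur_meanlog, dur_sdlog = dur_sdlog,
                 propensity = propensity),
            class = "archetype_spec")
}

#' Default archetypes
#'
#' @return Named list of four [archetype_spec()]s: `steady`, `declining`,
#'   `ramping`, `inactive`.
#' @export
default_archetypes <- function() {
  list(
    steady    = archetype_spec("steady", c(0.50, 0.50, 0.50), 0.50,
                               propensity = 0.95),
    declining = archetype_spec("declining", c(0.50, 0.15, 0.01), 0.08,
                               propensity = 0.08),
    ramping   = archetype_spec("ramping", c(0.10, 0.30, 0.50), 0.50,
                               propensity = 0.85),
    inactive  = archetype_spec("inactive", c(0.02, 0.01, 0.01), 0.05,
                               propensity = 0.02)
  )
}

#' Cohort generator configuration
#'
#' @param n_users cohort size.
#' @param weights archetype mixture weights (summing to 1).
#' @param adherent_fraction fraction of adherent users; the realised count
#'   is `round(adherent_fraction * n_users)`. Default 112/246, the split
#'   observed in the study cohort the generator emulates.
#' @param archetypes named list of [archetype_spec()]s.
#' @param user_sdlog sd (log scale) of the per-user duration level
#'   multiplier.
#' @param seed RNG seed: identical seeds give identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_users = 200L,
                          weights = c(steady = 0.32, declining = 0.33,
                                      ramping = 0.13, inactive = 0.22),
                          adherent_fraction = 112 / 246,
                          archetypes = default_archetypes(),
                          user_sdlog = 0.25, seed = 1L) {
  stopifnot(n_users >= 0, abs(sum(weights) - 1) < 1e-8,
            adherent_fraction >= 0, adherent_fraction <= 1,
            all(names(weights) %in% names(archetypes)))
  structure(list(n_users = as.integer(n_users), weights = weights,
                 adherent_fraction = adherent_fraction,
                 archetypes = archetypes, user_sdlog = user_sdlog,
                 seed = seed),
            class = "cohort_config")
}

#' Simulate one user's 120-day series
#'
#' Days in months 1-3 are active with the archetype's per-month
#' probability; active-day seconds are log-normal. Adherent users stay
#' active in month 4 with probability `p_month4` per day (at least one
#' active day enforced); non-adherent users have an all-zero month 4, so
#' the generated label is recoverable by [true_label()] by construction.
#'
#' @param arch an [archetype_spec()].
#' @param adherent logical.
#' @param user_id identifier for the generated series.
#' @param level per-user duration level multiplier.
#' @return `list(series = <daily_series>, label, archetype)`.
#' @export
simulate_user <- function(arch, adherent, user_id = "u", level = 1) {
  values <- numeric(120)
  meanlog <- arch$dur_meanlog + log(level)
  for (m in 1:3) {
    days <- (30L * (m - 1L) + 1L):(30L * m)
    act <- runif(30) < arch$p_active[m]
    values[days[act]] <- rlnorm(sum(act), meanlog, arch$dur_sdlog)
  }
  if (adherent) {
    act <- runif(30) < arch$p_month4
    if (!any(act)) act[sample.int(30, 1L)] <- TRUE
    values[90L + which(act)] <- rlnorm(sum(act), meanlog, arch$dur_sdlog)
  }
  list(series = daily_series(user_id, values),
       label = if (adherent) "adherent" else "non_adherent",
       archetype = arch$name)
}

#' Simulate a cohort
#'
#' @param config a [cohort_config()].
#' @return An `adherefit_cohort`: list of per-user
#'   `list(series, label, archetype)` entries. Reproducible given the
#'   config seed.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_users = 10, seed = 7))
#' table(cohort_labels(coh))
simulate_cohort <- function(config = cohort_config()) {
  n <- config$n_users
  out <- vector("list", n)
  if (n == 0L) return(structure(out, class = "adherefit_cohort"))
  with_seed(config$seed, {
    arch_names <- sample(names(config$weights), n, replace = TRUE,
                         prob = config$weights)
    prop <- vapply(arch_names,
                   function(a) config$archetypes[[a]]$propensity, numeric(1))
    n_adh <- round(config$adherent_fraction * n)
    adherent <- rep(FALSE, n)
    if (n_adh > 0)
      adherent[sample.int(n, min(n_adh, n), prob = prop)] <- TRUE
    levels <- rlnorm(n, 0, config$user_sdlog)
    ids <- sprintf("u%03d", seq_len(n))
    for (i in seq_len(n))
      out[[i]] <- simulate_user(config$archetypes[[arch_names[i]]],
                                adherent[i], ids[i], levels[i])
  })
  structure(out, class = "adherefit_cohort")
}

#' Cohort accessors
#'
#' @param cohort an `adherefit_cohort`.
#' @return `cohort_series`: list of `daily_series`; `cohort_labels` /
#'   `cohort_archetypes`: character vectors.
#' @export
cohort_series <- function(cohort) lapply(cohort, `[[`, "series")

#' @rdname cohort_series
#' @export
cohort_labels <- function(cohort)
  vapply(cohort, `[[`, character(1), "label")

#' @rdname cohort_series
#' @export
cohort_archetypes <- function(cohort)
  vapply(cohort, `[[`, character(1), "archetype")

#' @export
print.adherefit_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x), "users;",
      sum(cohort_labels(x) == "adherent"), "adherent\n")
  if (length(x))
    print(table(archetype = cohort_archetypes(x)))
  invisible(x)
}

#' Export a cohort as session logs
#'
#' Emits one finished session per active day in the sessions CSV dialect
#' (`user_id,start_time,duration_s,finished`), so the full pipeline can be
#' driven from files. Note that re-importing anchors each user at their
#' first session date, so users whose first active day is not day 1 come
#' back left-shifted.
#'
#' @param cohort an `adherefit_cohort`.
#' @param start_date calendar date of day 1.
#' @return `data.frame` of session records.
#' @export
cohort_to_sessions <- function(cohort, start_date = as.Date("2021-01-01")) {
  rows <- lapply(cohort, function(u) {
    act <- which(u$series$values > 0)
    if (!length(act)) return(NULL)
    data.frame(
      user_id = u$series$user_id,
      start_time = paste0(format(start_date + act - 1L), "T12:00:00"),
      duration_s = u$series$values[act],
      finished = "true",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Ground-truth table of a cohort
#'
#' @param cohort an `adherefit_cohort`.
#' @return `data.frame(user_id, label, archetype)`.
#' @export
cohort_truth <- function(cohort) {
  data.frame(
    user_id = vapply(cohort, function(u) as.character(u$series$user_id),
                     character(1)),
    label = cohort_labels(cohort),
    archetype = cohort_archetypes(cohort),
    stringsAsFactors = FALSE
  )
}
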