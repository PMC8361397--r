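#' Condition levels of the conflict task
#'
#' Factor levels used throughout the package for the three conflict
#' conditions of the modified Attention Network Task: all four arrowheads
#' congruent, one deviant arrowhead at the end of the row (incongruent-EASY),
#' or in the middle (incongruent-HARD).
#' @export
ant_conditions <- c("congruent", "incongruent_easy", "incongruent_hard")

#' Cue-to-target delays of the task schedule (seconds)
#'
#' The twelve approximately exponentially spaced delays between cue offset
#' and target onset; each value occurs exactly three times per 36-trial run,
#' in random order.
#' @export
ant_cue_target_delays <- c(0.700, 0.770, 0.850, 0.960, 1.080, 1.240, 1.430,
                           1.660, 1.940, 2.300, 2.700, 3.200)

#' Target-to-next-cue delays of the task schedule (seconds)
#'
#' The twelve delays between target onset and the onset of the next trial's
#' cue; each value occurs exactly three times per 36-trial run.
#' @export
ant_target_cue_delays <- c(4.300, 4.500, 4.750, 5.000, 5.350, 5.700, 6.100,
                           6.400, 6.800, 7.200, 7.700, 8.300)

#' Trial-schedule configuration
#'
#' Describes the per-run event structure of the task: a 200 ms cue, a
#' variable cue-target delay, a target displayed until response or for at
#' most the 3 s response window, and a variable target-to-next-cue delay.
#' With the default delay lists a 36-trial run spans 280 s of events and fits
#' a 156-volume acquisition at TR 1.92 s.
#'
#' @param n_runs Runs per subject. The task protocol uses 5 or 6 (and the
#'   inclusion filters enforce that range); smaller values are allowed for
#'   reduced-size simulation studies.
#' @param trials_per_run Trials per run; the delay lists assume 36.
#' @param cue_duration Cue presentation time in seconds.
#' @param response_window Maximum response time in seconds; slower trials are
#'   recorded as missed.
#' @param cue_target_delays,target_cue_delays Delay value lists; each value
#'   is used exactly `trials_per_run / length(delays)` times per run.
#' @param condition_split Named integer vector of trials per condition per
#'   run; must sum to `trials_per_run`.
#' @param start_offset Onset of the first cue relative to run start
#'   (seconds).
#'
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(n_runs = 6,
                            trials_per_run = 36,
                            cue_duration = 0.200,
                            response_window = 3.0,
                            cue_target_delays = ant_cue_target_delays,
                            target_cue_delays = ant_target_cue_delays,
                            condition_split = c(congruent = 12,
                                                incongruent_easy = 12,
                                                incongruent_hard = 12),
                            start_offset = 2.0) {
  if (n_runs < 1 || n_runs > 6) {
    stop("`n_runs` must be between 1 and 6.", call. = FALSE)
  }
  if (sum(condition_split) != trials_per_run) {
    stop("`condition_split` must sum to `trials_per_run`.", call. = FALSE)
  }
  if (!setequal(names(condition_split), ant_conditions)) {
    stop("`condition_split` must be named by the three task conditions.",
         call. = FALSE)
  }
  for (d in list(cue_target_delays, target_cue_delays)) {
    if (trials_per_run %% length(d) != 0) {
      stop("Delay list length must divide `trials_per_run`.", call. = FALSE)
    }
  }
  structure(
    list(n_runs = n_runs, trials_per_run = trials_per_run,
         cue_duration = cue_duration, response_window = response_window,
         cue_target_delays = cue_target_delays,
         target_cue_delays = target_cue_delays,
         condition_split = condition_split[ant_conditions],
         start_offset = start_offset),
    class = "schedule_config"
  )
}

#' Generate a randomized trial schedule
#'
#' Builds the per-run event table: conditions randomly interleaved according
#' to the configured split, and each delay value used exactly its quota of
#' times per run in random order. Onsets chain as cue onset + cue duration +
#' cue-target delay = target onset; the next cue follows the target-cue
#' delay after target onset.
#'
#' @param config A [schedule_config()].
#' @param seed Integer seed; identical seeds give identical schedules.
#'
#' @return A tibble with columns `run`, `trial_index`, `condition`,
#'   `cue_onset`, `target_onset`, `cue_target_delay`, `target_cue_delay`
#'   (times in seconds from run start).
#' @examples
#' sched <- generate_trial_schedule(schedule_config(), seed = 1)
#' nrow(sched)  # 6 runs x 36 trials = 216
#' @export
generate_trial_schedule <- function(config = schedule_config(), seed = NULL) {
  stopifnot(inherits(config, "schedule_config"))
  build <- function() {
    purrr::map_dfr(seq_len(config$n_runs), function(r) {
      m <- config$trials_per_run
      conds <- sample(rep(names(config$condition_split),
                          config$condition_split))
      ctd <- sample(rep(config$cue_target_delays,
                        m / length(config$cue_target_delays)))
      tcd <- sample(rep(config$target_cue_delays,
                        m / length(config$target_cue_delays)))
      cue_onset <- numeric(m)
      target_onset <- numeric(m)
      t <- config$start_offset
      for (k in seq_len(m)) {
        cue_onset[k] <- t
        target_onset[k] <- t + config$cue_duration + ctd[k]
        t <- target_onset[k] + tcd[k]
      }
      tibble::tibble(
        run = r, trial_index = seq_len(m),
        condition = factor(conds, levels = ant_conditions),
        cue_onset = cue_onset, target_onset = target_onset,
        cue_target_delay = ctd, target_cue_delay = tcd
      )
    })
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
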