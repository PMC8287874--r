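#' Staircase protocol
#'
#' Trial structure of one adaptive staircase: 4 practice trials followed by
#' 60 test trials (64 total), starting from 80% SNR for the signal-in-noise
#' task or 120 arcsec for the feature task. The test value of the first
#' test trial is determined by the threshold obtained in the practice
#' trials (the posterior is carried over from practice).
#'
#' @param task `"snr"` or `"feature"`.
#' @param stimulus_condition `"upright"`, `"inverted"`, or `"random"`.
#' @param n_practice number of practice trials.
#' @param n_test number of test trials.
#' @param initial_value first test value, linear units; defaults to 0.8
#'   (SNR) or 120 (arcsec) by task.
#' @param response_window_ms response window; trials that time out are
#'   scored incorrect.
#' @return A list of class `staircase_protocol`.
#' @export
staircase_protocol <- function(task = c("snr", "feature"),
                               stimulus_condition = c("upright", "inverted", "random"),
                               n_practice = 4L, n_test = 60L,
                               initial_value = NULL,
                               response_window_ms = 3000) {
  task <- match.arg(task)
  stimulus_condition <- match.arg(stimulus_condition)
  if (is.null(initial_value))
    initial_value <- if (task == "snr") 0.8 else 120
  structure(
    list(task = task, stimulus_condition = stimulus_condition,
         n_practice = as.integer(n_practice), n_test = as.integer(n_test),
         initial_value = initial_value,
         response_window_ms = response_window_ms),
    class = "staircase_protocol"
  )
}

#' Run one adaptive staircase against a simulated observer
#'
#' Runs the full 4 + 60 trial protocol: on every trial the staircase
#' recommends an intensity (the first practice trial uses the protocol's
#' initial value), the observer responds, and the posterior is updated.
#' The posterior accumulated over the practice trials seeds the first test
#' recommendation.
#'
#' @param observer a [psychometric_observer()].
#' @param protocol a [staircase_protocol()].
#' @param seed integer seed for the observer's responses.
#' @param ... passed to [quest_create()] (prior and psychometric-family
#'   settings).
#' @return A list of class `staircase_run`: `estimate` (one-row tibble from
#'   [quest_estimate()]), `state` (final `quest_state`), and `history`
#'   (64-row tibble: `trial`, `phase`, `intensity`, `outcome`).
#' @examples
#' obs <- psychometric_observer(threshold_alpha = 0.4)
#' run <- run_staircase(obs, staircase_protocol("snr"), seed = 1)
#' run$estimate$value
#' @export
run_staircase <- function(observer, protocol = staircase_protocol(),
                          seed = NULL, ...) {
  stopifnot(inherits(observer, "psychometric_observer"),
            inherits(protocol, "staircase_protocol"))
  local_seed(seed, {
    state <- quest_create(protocol$initial_value, task = protocol$task, ...)
    for (i in seq_len(protocol$n_practice)) {
      intensity <- if (i == 1) protocol$initial_value else quest_recommend(state)
      outcome <- observer_respond(observer, intensity, state$criterion)
      state <- quest_update(state, intensity, outcome, phase = "practice")
    }
    for (i in seq_len(protocol$n_test)) {
      intensity <- quest_recommend(state)
      outcome <- observer_respond(observer, intensity, state$criterion)
      state <- quest_update(state, intensity, outcome, phase = "test")
    }
    structure(
      list(estimate = quest_estimate(state), state = state,
           history = state$history, protocol = protocol),
      class = "staircase_run"
    )
  })
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "<staircase_run> %s/%s: %d trials, threshold = %.4g (95%% CI %.4g-%.4g)\n",
    x$protocol$task, x$protocol$stimulus_condition, nrow(x$history),
    x$estimate$value, x$estimate$ci95_low, x$estimate$ci95_high
  ))
  invisible(x)
}

#' @export
tidy.staircase_run <- function(x, ...) x$history

#' @export
glance.staircase_run <- function(x, ...) x$estimate

#' Run a full psychophysical session for one subject
#'
#' Runs the six test runs of one task — three stimulus conditions (upright
#' face, inverted face, random surface) crossed with two stimulus
#' identities — in random order. Each run interleaves two staircases (one
#' per stimulus gender) in strict alternation, 64 trials each. The
#' per-condition threshold is the mean of the estimates from that
#' condition's staircases.
#'
#' @param observers named list of [psychometric_observer()]s, one per
#'   condition (`upright`, `inverted`, `random`).
#' @param task `"snr"` or `"feature"`.
#' @param seed integer seed.
#' @param subject subject label carried into the output tables.
#' @param ... passed to [run_staircase()].
#' @return A list of class `session_result`: `staircases` (tibble: subject,
#'   condition, identity, run, staircase, threshold, converged),
#'   `thresholds` (tibble: subject, condition, threshold — staircase
#'   means), `runs` (the underlying `staircase_run` objects), and
#'   `schedule` (the interleaved trial order per run).
#' @export
run_session <- function(observers, task = c("snr", "feature"), seed = NULL,
                        subject = "s01", ...) {
  task <- match.arg(task)
  conditions <- c("upright", "inverted", "random")
  if (!all(conditions %in% names(observers)))
    abort("`observers` must be a named list with upright, inverted, random.")
  local_seed(seed, {
    runs_plan <- tidyr::expand_grid(condition = conditions,
                                    identity = c("id1", "id2"))
    runs_plan <- runs_plan[sample(nrow(runs_plan)), ]
    runs_plan$run <- seq_len(nrow(runs_plan))

    all_runs <- list()
    schedule <- list()
    rows <- list()
    for (k in seq_len(nrow(runs_plan))) {
      cond <- runs_plan$condition[k]
      pair <- purrr::map(c("male", "female"), function(g) {
        run_staircase(
          observers[[cond]],
          staircase_protocol(task, stimulus_condition = cond),
          seed = NULL, ...
        )
      })
      names(pair) <- c("male", "female")
      n_tr <- nrow(pair$male$history)
      # strict alternation of the two staircases within the run
      schedule[[k]] <- tibble(
        run = runs_plan$run[k],
        trial_in_run = seq_len(2L * n_tr),
        staircase = rep(c("male", "female"), times = n_tr)
      )
      rows[[k]] <- purrr::imap(pair, function(r, g) tibble(
        subject = subject, condition = cond,
        identity = runs_plan$identity[k], run = runs_plan$run[k],
        staircase = g, threshold = r$estimate$value,
        converged = r$estimate$converged
      )) |> purrr::list_rbind()
      all_runs[[k]] <- pair
    }
    staircases <- purrr::list_rbind(rows)
    thresholds <- staircases |>
      dplyr::group_by(.data$subject, .data$condition) |>
      dplyr::summarise(threshold = mean(.data$threshold), .groups = "drop")
    structure(
      list(staircases = staircases, thresholds = thresholds,
           runs = all_runs, schedule = purrr::list_rbind(schedule),
           task = task),
      class = "session_result"
    )
  })
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s task, %d staircases\n",
              x$task, nrow(x$staircases)))
  print(x$thresholds)
  invisible(x)
}

#' @export
tidy.session_result <- function(x, ...) x$staircases

#' @export
glance.session_result <- function(x, ...) x$thresholds

#' Convert staircase history into an fMRI stimulus-sampling range
#'
#' Implements the in-bore rule that tailors stimulus test values for the
#' scanner: take the mean of the test values presented on the last 30 test
#' trials and return a range of +/- 1 SD around it. If the staircase fails
#' the reliability checks (no asymptotic convergence, or a credible
#' interval reaching the floor of the posterior grid — see
#' [quest_reliable()]), the function falls back to a fixed 80% SNR.
#'
#' @param run a `staircase_run` (or a `quest_state`) with at least 30 test
#'   trials.
#' @return One-row tibble: `low`, `high`, `fallback` (logical). Under
#'   fallback `low = high = 0.8`.
#' @export
derive_fmri_sampling_range <- function(run) {
  state <- if (inherits(run, "staircase_run")) run$state else run
  stopifnot(inherits(state, "quest_state"))
  test <- dplyr::filter(state$history, .data$phase == "test")
  if (nrow(test) < 30)
    abort("need at least 30 test trials to derive a sampling range.")
  if (!quest_reliable(state))
    return(tibble(low = 0.8, high = 0.8, fallback = TRUE))
  last30 <- utils::tail(test$intensity, 30)
  m <- mean(last30)
  s <- stats::sd(last30)
  tibble(low = m - s, high = m + s, fallback = FALSE)
}

#' Sample a trial SNR from an fMRI sampling range
#'
#' Uniform draw within the subject- and condition-specific range, clipped
#' to the physical SNR range `[0, 1]`. A fallback range yields the constant
#' 0.8.
#'
#' @param range one-row tibble from [derive_fmri_sampling_range()] (or any
#'   list with `low`/`high`).
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of SNR values in `[0, 1]`.
#' @export
sample_trial_snr <- function(range, n = 1, seed = NULL) {
  local_seed(seed, {
    x <- stats::runif(n, range$low, range$high)
    pmin(pmax(x, 0), 1)
  })
}
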