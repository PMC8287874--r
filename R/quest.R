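#' Weibull psychometric function anchored at the staircase criterion
#'
#' Probability of a correct response at log10 intensity `x` for a threshold
#' `threshold` (also in log10 units):
#' \deqn{\psi(x) = \gamma + (1-\gamma-\lambda)\,
#'   (1 - \exp(-10^{\beta (x - T + \epsilon)}))}
#' where \eqn{\epsilon} is chosen so that \eqn{\psi(T)} equals the staircase
#' criterion (82% correct by default). With this anchoring the threshold
#' parameter *is* the intensity at criterion, so posterior summaries of the
#' threshold read directly as criterion-level intensities.
#'
#' @param x log10 intensity (log10 SNR for the signal-in-noise task; log10
#'   arcsec for the feature task).
#' @param threshold log10 threshold (intensity at criterion).
#' @param beta Weibull slope.
#' @param gamma lower asymptote (0.5 for 2-AFC).
#' @param lambda lapse rate (upper asymptote is `1 - lambda`).
#' @param criterion target proportion correct the threshold is anchored to.
#' @return Probability of a correct response, same length as `x`.
#' @export
weibull_psych <- function(x, threshold, beta = 3.5, gamma = 0.5,
                          lambda = 0.01, criterion = 0.82) {
  eps <- criterion_offset(beta, gamma, lambda, criterion)
  gamma + (1 - gamma - lambda) * (1 - exp(-10^(beta * (x - threshold + eps))))
}

# log10 shift that places the criterion point at the threshold parameter.
criterion_offset <- function(beta, gamma, lambda, criterion) {
  pstar <- (criterion - gamma) / (1 - gamma - lambda)
  if (pstar <= 0 || pstar >= 1)
    abort("criterion must lie strictly between gamma and 1 - lambda.")
  log10(-log(1 - pstar)) / beta
}

#' Simulated psychophysical observer
#'
#' An observer whose responses follow a Weibull psychometric function, with
#' an optional probability of not responding at all within the response
#' window (timeouts are scored as incorrect by the staircase).
#'
#' @param threshold_alpha intensity at criterion, in *linear* units (SNR in
#'   `[0, 1]` for the signal-in-noise task; arcsec for the feature task).
#' @param slope_beta Weibull slope.
#' @param guess_gamma lower asymptote; 0.5 for a 2-alternative task.
#' @param lapse_lambda lapse rate, in `[0, 0.1]`.
#' @param nonresponse_rate probability a trial times out with no response.
#' @return An object of class `psychometric_observer`.
#' @examples
#' obs <- psychometric_observer(threshold_alpha = 0.4)
#' @export
psychometric_observer <- function(threshold_alpha, slope_beta = 3.5,
                                  guess_gamma = 0.5, lapse_lambda = 0.01,
                                  nonresponse_rate = 0) {
  if (guess_gamma < 0 || guess_gamma >= 1) abort("`guess_gamma` must be in [0, 1).")
  if (lapse_lambda < 0 || lapse_lambda > 0.1) abort("`lapse_lambda` must be in [0, 0.1].")
  if (slope_beta <= 0) abort("`slope_beta` must be positive.")
  if (threshold_alpha <= 0) abort("`threshold_alpha` must be positive (linear units).")
  assert_scalar_prob(nonresponse_rate, "nonresponse_rate")
  structure(
    list(threshold_alpha = threshold_alpha, slope_beta = slope_beta,
         guess_gamma = guess_gamma, lapse_lambda = lapse_lambda,
         nonresponse_rate = nonresponse_rate),
    class = "psychometric_observer"
  )
}

#' Simulate observer responses at given intensities
#'
#' @param observer a [psychometric_observer()].
#' @param intensity linear intensity (vectorized).
#' @param criterion criterion the observer's threshold is anchored to.
#' @return Character vector of outcomes: `"correct"`, `"incorrect"`, or
#'   `"timeout"`.
#' @export
observer_respond <- function(observer, intensity, criterion = 0.82) {
  stopifnot(inherits(observer, "psychometric_observer"))
  p <- weibull_psych(log10(intensity), log10(observer$threshold_alpha),
                     observer$slope_beta, observer$guess_gamma,
                     observer$lapse_lambda, criterion)
  out <- ifelse(stats::runif(length(p)) < p, "correct", "incorrect")
  if (observer$nonresponse_rate > 0) {
    to <- stats::runif(length(p)) < observer$nonresponse_rate
    out[to] <- "timeout"
  }
  out
}

#' Initialize a QUEST adaptive staircase
#'
#' Sets up the Bayesian posterior over candidate log10 thresholds: a
#' Gaussian prior centered at the initial test value with SD
#' `prior_sd` log units, discretized on `grid_n` points spanning +/- 3
#' prior SDs.
#'
#' @param initial_value first test value, linear units (e.g. 0.8 for 80%
#'   SNR; 120 for 120 arcsec).
#' @param task `"snr"` (physical range `[0, 1]` SNR) or `"feature"`
#'   (physical range `[0, 150]` arcsec); determines recommendation
#'   clipping.
#' @param beta,gamma,lambda Weibull parameters assumed by the staircase.
#' @param criterion proportion correct tracked (0.82).
#' @param prior_sd prior SD in log10 units.
#' @param grid_n number of posterior support points.
#' @return An object of class `quest_state`: list with `grid`, `posterior`,
#'   `psi_params`, `criterion`, `task`, and a `history` tibble.
#' @export
quest_create <- function(initial_value, task = c("snr", "feature"),
                         beta = 3.5, gamma = 0.5, lambda = 0.01,
                         criterion = 0.82, prior_sd = 2, grid_n = 201) {
  task <- match.arg(task)
  if (criterion <= gamma || criterion >= 1 - lambda)
    abort("`criterion` must lie in (gamma, 1 - lambda).")
  mu <- log10(initial_value)
  grid <- seq(mu - 3 * prior_sd, mu + 3 * prior_sd, length.out = grid_n)
  prior <- stats::dnorm(grid, mu, prior_sd)
  structure(
    list(
      grid = grid,
      posterior = prior / sum(prior),
      psi_params = c(beta = beta, gamma = gamma, lambda = lambda),
      criterion = criterion,
      task = task,
      initial_value = initial_value,
      history = tibble(
        trial = integer(), phase = character(),
        intensity = numeric(), outcome = character()
      )
    ),
    class = "quest_state"
  )
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf(
    "<quest_state> %s task, %d trials, threshold estimate %.4g (linear)\n",
    x$task, nrow(x$history), 10^sum(x$grid * x$posterior)
  ))
  invisible(x)
}

#' Bayesian update of a QUEST staircase after one trial
#'
#' Multiplies the posterior by the likelihood of the observed outcome under
#' each candidate threshold and renormalizes. Timeouts are scored as
#' incorrect responses. The trial is appended to the staircase history.
#'
#' @param state a [quest_create()] state.
#' @param intensity linear intensity presented.
#' @param outcome `"correct"`, `"incorrect"`, or `"timeout"`.
#' @param phase `"practice"` or `"test"`.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, intensity, outcome,
                         phase = c("test", "practice")) {
  stopifnot(inherits(state, "quest_state"))
  phase <- match.arg(phase)
  if (!is.finite(intensity) || intensity <= 0)
    abort("`intensity` must be finite and positive.")
  outcome <- match.arg(outcome, c("correct", "incorrect", "timeout"))
  p <- weibull_psych(log10(intensity), state$grid,
                     state$psi_params[["beta"]], state$psi_params[["gamma"]],
                     state$psi_params[["lambda"]], state$criterion)
  lik <- if (outcome == "correct") p else 1 - p
  post <- state$posterior * lik
  z <- sum(post)
  if (!is.finite(z) || z <= 0)
    abort("QUEST posterior underflow: all posterior mass lost.")
  state$posterior <- post / z
  state$history <- dplyr::bind_rows(state$history, tibble(
    trial = nrow(state$history) + 1L, phase = phase,
    intensity = intensity, outcome = outcome
  ))
  state
}

#' Next test intensity recommended by a QUEST staircase
#'
#' Returns the intensity at which the current posterior-mean threshold
#' yields criterion performance (with the criterion-anchored psychometric
#' function this is the posterior-mean threshold itself), converted to
#' linear units and clipped to the physical range of the task
#' (`[0, 1]` SNR; `[0, 150]` arcsec).
#'
#' @param state a `quest_state`.
#' @return Linear intensity for the next trial.
#' @export
quest_recommend <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  t_hat <- sum(state$grid * state$posterior)
  upper <- if (state$task == "snr") 1 else 150
  min(10^t_hat, upper)
}

#' Posterior threshold summary for a staircase
#'
#' @param state a `quest_state`.
#' @param grid_floor_quantile posterior quantile pair used for the 95%
#'   credible interval.
#' @return One-row tibble: `value` (linear intensity at criterion,
#'   posterior mean on the log scale back-transformed), `value_log10`,
#'   `ci95_low`, `ci95_high` (linear), and `converged` (the reliability
#'   check of [quest_reliable()]).
#' @export
quest_estimate <- function(state, grid_floor_quantile = c(0.025, 0.975)) {
  stopifnot(inherits(state, "quest_state"))
  t_hat <- sum(state$grid * state$posterior)
  cdf <- cumsum(state$posterior)
  ci <- state$grid[c(
    which(cdf >= grid_floor_quantile[1])[1],
    which(cdf >= grid_floor_quantile[2])[1]
  )]
  tibble(
    value = 10^t_hat, value_log10 = t_hat,
    ci95_low = 10^ci[1], ci95_high = 10^ci[2],
    converged = quest_reliable(state)
  )
}

#' Reliability check for a completed staircase
#'
#' A staircase is considered reliable when (a) the last 30 test values have
#' asymptoted — the absolute slope of an ordinary least-squares line through
#' them is below `max_slope` intensity units per trial — and (b) the 95%
#' credible interval has lifted off the floor of the posterior grid (its
#' lower bound exceeds the grid minimum).
#'
#' @param state a `quest_state` with at least 30 test trials (otherwise
#'   `FALSE`).
#' @param max_slope convergence tolerance, linear intensity units/trial.
#' @return Logical scalar.
#' @export
quest_reliable <- function(state, max_slope = 0.005) {
  test <- dplyr::filter(state$history, .data$phase == "test")
  if (nrow(test) < 30) return(FALSE)
  last30 <- utils::tail(test$intensity, 30)
  slope <- stats::cov(seq_along(last30), last30) / stats::var(seq_along(last30))
  cdf <- cumsum(state$posterior)
  ci_low <- state$grid[which(cdf >= 0.025)[1]]
  abs(slope) < max_slope && ci_low > state$grid[1]
}

#' @describeIn quest_create tidy view of the trial history.
#' @param x a `quest_state`.
#' @param ... unused.
#' @export
tidy.quest_state <- function(x, ...) x$history

#' @describeIn quest_create one-row posterior summary (see
#'   [quest_estimate()]).
#' @export
glance.quest_state <- function(x, ...) quest_estimate(x)
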