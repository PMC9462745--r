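#' Task parameters for the noisy two-alternative forced-choice task
#'
#' The task presents a scalar signal \eqn{s(t)}, sampled every `dt` seconds
#' from a Gaussian with per-episode mean \eqn{\mu} and standard deviation
#' \eqn{\sigma/\sqrt{dt}} (white-noise convention: `sigma` carries units
#' \eqn{s^{-1/2}}, so the information content per unit time is independent of
#' the step size). The agent must report the sign of \eqn{\mu} within `t_max`
#' seconds; \eqn{\mu} itself is redrawn each episode from
#' \eqn{N(0, \sigma_\mu^2)}. `sigma_I` is the standard deviation of the
#' intrinsic read-out noise added to every integrator at every step.
#'
#' @param dt Time step (s). Default 0.01.
#' @param t_max Maximum episode duration (s); rounded to an integer multiple
#'   of `dt` with a warning if needed. Default 2.
#' @param sigma Signal noise scale (units \eqn{s^{-1/2}}). Default 0.18.
#' @param sigma_mu Standard deviation of the per-episode mean. Default 0.25.
#' @param sigma_I Intrinsic read-out noise standard deviation. Default 0.02.
#' @return An object of class `task_params`.
#' @examples
#' tp <- task_params()
#' tp$n_steps  # 200
#' @export
task_params <- function(dt = 0.01, t_max = 2, sigma = 0.18,
                        sigma_mu = 0.25, sigma_I = 0.02) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(t_max), length(t_max) == 1, t_max >= dt,
            is.numeric(sigma), sigma > 0,
            is.numeric(sigma_mu), sigma_mu >= 0,
            is.numeric(sigma_I), sigma_I >= 0)
  n_steps <- t_max / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    warning("t_max is not an integer multiple of dt; rounding to ",
            round(n_steps) * dt, " s")
  }
  n_steps <- max(1L, as.integer(round(n_steps)))
  structure(list(dt = dt, t_max = n_steps * dt, sigma = sigma,
                 sigma_mu = sigma_mu, sigma_I = sigma_I,
                 n_steps = n_steps),
            class = "task_params")
}

#' @export
print.task_params <- function(x, ...) {
  cat("Task: dt =", x$dt, "s, t_max =", x$t_max, "s (", x$n_steps,
      "steps ), sigma =", x$sigma, "s^-1/2, sigma_mu =", x$sigma_mu,
      ", sigma_I =", x$sigma_I, "\n")
  invisible(x)
}

## proportionality constant of the coherence <-> mu mapping
.COH_K <- 0.216

#' Convert stimulus coherence to signal-mean magnitude
#'
#' Maps the percentage of coherently moving dots to the magnitude of the
#' signal mean, \eqn{|\mu| = 0.216\, c / \sqrt{100 - c}}. The form follows
#' from a stimulus model in which a fraction \eqn{c} of dots moves coherently
#' (contributing to the mean) while the remaining \eqn{1 - c} move at random
#' (contributing to the variance).
#'
#' @param coherence Coherence percentage, in `[0, 100)`. Vectorised.
#' @return Signal-mean magnitude(s).
#' @examples
#' coherence_to_mu(51.2)  # ~1.583
#' @export
coherence_to_mu <- function(coherence) {
  if (any(!is.finite(coherence)) || any(coherence < 0) || any(coherence >= 100))
    stop("coherence must lie in [0, 100)")
  .COH_K * coherence / sqrt(100 - coherence)
}

#' Convert a signal-mean magnitude back to coherence
#'
#' Closed-form inverse of [coherence_to_mu()] on `[0, 100)`: the positive
#' root of \eqn{k^2 c^2 + \mu^2 c - 100 \mu^2 = 0} with \eqn{k = 0.216}.
#'
#' @param mu_magnitude Non-negative signal-mean magnitude(s).
#' @return Coherence percentage(s).
#' @export
mu_to_coherence <- function(mu_magnitude) {
  if (any(!is.finite(mu_magnitude)) || any(mu_magnitude < 0))
    stop("mu_magnitude must be finite and non-negative")
  m2 <- mu_magnitude^2
  k2 <- .COH_K^2
  (-m2 + sqrt(m2^2 + 400 * k2 * m2)) / (2 * k2)
}

#' Draw per-episode signal means
#'
#' @param n Number of draws.
#' @param sigma_mu Standard deviation of the zero-mean Gaussian over \eqn{\mu}.
#' @return Numeric vector of length `n`.
#' @export
sample_mu <- function(n, sigma_mu) {
  stopifnot(sigma_mu >= 0)
  stats::rnorm(n, 0, sigma_mu)
}

#' Generate one episode of the task
#'
#' Draws `round(t_max/dt)` i.i.d. samples from
#' \eqn{N(\mu, (\sigma/\sqrt{dt})^2)}.
#'
#' @param params A [task_params()] object.
#' @param mu True signal mean for this episode.
#' @param coherence_label Optional coherence tag (percent) recorded with the
#'   episode; must satisfy `|mu| == coherence_to_mu(coherence_label)`.
#' @return An object of class `episode` with fields `mu`, `samples`,
#'   `coherence_label`.
#' @export
generate_episode <- function(params, mu, coherence_label = NULL) {
  stopifnot(inherits(params, "task_params"))
  if (!is.null(coherence_label)) {
    stopifnot(abs(abs(mu) - coherence_to_mu(coherence_label)) < 1e-9)
  }
  samples <- stats::rnorm(params$n_steps, mean = mu,
                          sd = params$sigma / sqrt(params$dt))
  structure(list(mu = mu, samples = samples,
                 coherence_label = coherence_label),
            class = "episode")
}

#' Score the outcome of an episode
#'
#' Reward 1 iff the chosen side matches the sign of \eqn{\mu}; a timeout (or
#' any action at \eqn{\mu = 0}) earns nothing. `correct` is `NA` when
#' \eqn{\mu = 0} or on timeout: no correct side exists.
#'
#' @param action One of `"left"`, `"right"`, `"timeout"` (or the integer
#'   coding -1, 1, 0 used in logs).
#' @param mu True signal mean.
#' @return List with `reward` (0/1) and `correct` (logical or `NA`).
#' @export
score_outcome <- function(action, mu) {
  action <- decode_action(action)
  if (action == "timeout" || mu == 0) {
    return(list(reward = 0L,
                correct = if (mu == 0) NA else NA))
  }
  hit <- (action == "right" && mu > 0) || (action == "left" && mu < 0)
  list(reward = as.integer(hit), correct = hit)
}

## integer action coding used throughout logs: left = -1, wait/timeout = 0,
## right = +1
decode_action <- function(action) {
  if (is.numeric(action)) {
    action <- c(`-1` = "left", `0` = "timeout", `1` = "right")[
      as.character(as.integer(action))]
    if (is.na(action)) stop("unknown integer action code")
    return(unname(action))
  }
  action <- match.arg(action, c("left", "right", "timeout", "wait"))
  if (action == "wait") "timeout" else action
}

encode_action <- function(action) {
  switch(decode_action(action), left = -1L, timeout = 0L, right = 1L)
}
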