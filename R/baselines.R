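#' Single-timescale Ornstein-Uhlenbeck threshold model
#'
#' The classical comparison model: one leaky integrator of the signal with
#' time constant `tau`, read out with intrinsic noise `sigma_I_eff`, that
#' answers 'right' ('left') the first time the noisy value reaches
#' \eqn{+\Theta} (\eqn{-\Theta}), and times out otherwise.
#'
#' @param tau Integration time constant (s).
#' @param theta Decision threshold \eqn{\Theta > 0} (0 decides at the first
#'   step).
#' @param sigma_I_eff Read-out noise standard deviation, typically rescaled
#'   by [alpha_rescale()] for a fair comparison with the multi-timescale
#'   agent.
#' @return An object of class `threshold_model`.
#' @export
threshold_model <- function(tau, theta, sigma_I_eff = 0.02) {
  stopifnot(tau > 0, theta >= 0, sigma_I_eff >= 0)
  structure(list(tau = tau, theta = theta, sigma_I_eff = sigma_I_eff),
            class = "threshold_model")
}

#' Run the OU threshold model on a batch of episodes
#'
#' @param model A [threshold_model()].
#' @param task A [task_params()] object.
#' @param mus Per-episode signal means (or give `n_episodes` /
#'   `coherence` as in [run_episodes()]).
#' @param n_episodes,coherence See [run_episodes()].
#' @param record_traces Record the per-step noisy integrator value (the
#'   model's decision variable, playing the role \eqn{\Delta\Sigma_{right}}
#'   has in the agent).
#' @return Same structure as [run_episodes()].
#' @export
ou_decide <- function(model, task, mus = NULL, n_episodes = NULL,
                      coherence = NULL, record_traces = FALSE) {
  stopifnot(inherits(model, "threshold_model"),
            inherits(task, "task_params"))
  if (is.null(mus)) {
    if (!is.null(coherence)) {
      m <- coherence_to_mu(coherence)
      mus <- m * sample(c(-1, 1), n_episodes, replace = TRUE)
    } else {
      mus <- sample_mu(n_episodes, task$sigma_mu)
    }
  }
  res <- cpp_ou_decide(model$tau, task$dt, task$n_steps,
                       task$sigma / sqrt(task$dt), model$sigma_I_eff,
                       model$theta, mus, record_traces)
  out <- data.frame(episode_id = seq_along(mus), mu = mus,
                    coherence = mu_to_coherence(abs(mus)),
                    action = res$action,
                    decision_time = res$step * task$dt,
                    reward = res$reward,
                    correct = ifelse(res$action == 0 | mus == 0, NA,
                                     res$reward == 1))
  ret <- list(outcomes = out)
  if (record_traces) {
    # present traces like the agent's: a one-column dsr matrix (the OU
    # decision variable) so the aligned-curve machinery applies unchanged
    ret$traces <- lapply(res$traces, function(v) {
      m <- matrix(v, ncol = 3, nrow = length(v))
      colnames(m) <- c("dsr", "ds_s", "ds_c")
      m[, "ds_c"] <- model$theta
      m
    })
  }
  ret
}

#' Grid-search optimisation of the OU decision threshold
#'
#' Maximises the fraction of correct (rewarded) episodes over a dense grid
#' of candidate thresholds, using common random numbers across candidates so
#' the comparison is noise-matched. Ties break toward the smaller threshold.
#'
#' @param tau Integration time constant (s).
#' @param task A [task_params()] object.
#' @param thresholds Candidate grid; default 60 points spanning
#'   `[0, 3 * sigma_mu]`.
#' @param n_episodes Episodes for the search. Default 4000.
#' @param sigma_I_eff Read-out noise for the single integrator.
#' @return A [threshold_model()] at the optimum, with attributes `curve`
#'   (data frame `theta`, `accuracy`) and `accuracy`.
#' @export
optimize_threshold <- function(tau, task,
                               thresholds = seq(0, 3 * task$sigma_mu,
                                                length.out = 60),
                               n_episodes = 4000, sigma_I_eff = 0.02) {
  stopifnot(length(thresholds) >= 2, all(thresholds >= 0))
  thresholds <- sort(thresholds)
  mus <- sample_mu(n_episodes, task$sigma_mu)
  res <- cpp_ou_grid(tau, task$dt, task$n_steps,
                     task$sigma / sqrt(task$dt), sigma_I_eff, mus,
                     thresholds)
  acc <- res$correct / res$n
  best <- which.max(acc) # which.max takes the first maximum: smaller theta
  model <- threshold_model(tau, thresholds[best], sigma_I_eff)
  attr(model, "curve") <- data.frame(theta = thresholds, accuracy = acc,
                                     decided = res$decided / res$n)
  attr(model, "accuracy") <- acc[best]
  model
}

#' Noise rescaling factor for single-integrator comparisons
#'
#' The multi-timescale agent averages away read-out noise across its
#' \eqn{n_\tau} independently-noisy integrators. For a fair comparison, the
#' noise on a single integrator is rescaled by
#' \eqn{\alpha_I = \max_\tau|\theta^*_\tau| / \sqrt{\sum_\tau
#' \theta^{*2}_\tau}}, computed from the trained 'right' signal weights:
#' \eqn{\alpha_I = 1} when a single weight is non-zero, and
#' \eqn{1/\sqrt{n_\tau}} when all weights are equal (the effective noise of
#' an equal-weight average of \eqn{n_\tau} independent read-outs).
#'
#' @param theta_star Trained 'right'-action signal weights (or any non-zero
#'   weight vector).
#' @return Scalar \eqn{\alpha_I \in [1/\sqrt{n_\tau}, 1]}.
#' @export
alpha_rescale <- function(theta_star) {
  if (all(theta_star == 0)) stop("alpha_rescale needs a non-zero weight")
  max(abs(theta_star)) / sqrt(sum(theta_star^2))
}

#' Accuracy of the optimal fixed-time observer
#'
#' The ideal decider forced to answer at time `t` from the sign of the
#' summed signal is correct with probability
#' \eqn{1/2 + \arctan(\sigma_\mu \sqrt{t} / \sigma)/\pi} when \eqn{\mu \sim
#' N(0, \sigma_\mu^2)} (the identity \eqn{E[\Phi(a|Z|)] = 1/2 +
#' \arctan(a)/\pi} applied to the Gaussian sign test).
#'
#' @param t Observation time(s) (s).
#' @param sigma_mu Standard deviation of the signal-mean distribution.
#' @param sigma Signal noise scale (units \eqn{s^{-1/2}}).
#' @return Fraction correct in `[0.5, 1)`. Vectorised over `t`.
#' @export
fixed_t_accuracy <- function(t, sigma_mu = 0.25, sigma = 0.18) {
  stopifnot(all(t >= 0))
  0.5 + atan(sigma_mu * sqrt(t) / sigma) / pi
}

#' Experimental psychometric reference curve
#'
#' Fraction correct as a function of coherence, with parameters fitted to
#' classical primate random-dots data:
#' \eqn{1 - 0.5\,\exp[-(c/7.97)^{1.62}]}.
#'
#' @param coherence Coherence percentage(s), non-negative.
#' @return Fraction correct. Vectorised.
#' @export
psychometric_reference <- function(coherence) {
  stopifnot(all(coherence >= 0))
  1 - 0.5 * exp(-(coherence / 7.97)^1.62)
}

#' Coefficient of variation of pure drift-diffusion response times
#'
#' For the leak-free drift-diffusion model with absorbing thresholds, the
#' response-time CV as a function of coherence \eqn{c} (percent) is
#' \eqn{((100 - c)/c^2)^{1/4}} -- the inverse-Gaussian CV under the
#' coherence-to-drift mapping of [coherence_to_mu()].
#'
#' @param coherence Coherence percentage(s) in `(0, 100]`.
#' @return CV. Vectorised.
#' @export
ddm_cv <- function(coherence) {
  if (any(coherence <= 0) || any(coherence > 100))
    stop("ddm_cv requires coherence in (0, 100] (diverges at 0)")
  ((100 - coherence) / coherence^2)^0.25
}

#' First-passage simulation of the pure drift-diffusion model
#'
#' Leak-free accumulation \eqn{x \mathrel{+}= s_t\,dt} with \eqn{s_t \sim
#' N(\mu, (\sigma/\sqrt{dt})^2)} (the task's white-noise convention) and
#' absorbing boundaries at \eqn{\pm\Theta}. At \eqn{\Theta = \sigma^2 /
#' 0.216} the analytic CV of the winning-boundary passage times equals
#' [ddm_cv()] at the corresponding coherence.
#'
#' @param mu Drift.
#' @param theta Absorbing boundary.
#' @param sigma Noise scale (units \eqn{s^{-1/2}}).
#' @param dt Simulation step (s); small steps reduce discretisation bias.
#' @param n Number of passages.
#' @param t_cap Give up after this time (s); such runs return `NA`.
#' @return Data frame `fpt` (s), `side` (-1/+1, 0 when capped).
#' @export
simulate_ddm_fpt <- function(mu, theta, sigma = 0.18, dt = 5e-4, n = 10000,
                             t_cap = 20) {
  res <- cpp_ddm_fpt(mu, sigma / sqrt(dt), theta, dt,
                     as.integer(ceiling(t_cap / dt)), n)
  data.frame(fpt = res$steps * dt, side = res$side)
}
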