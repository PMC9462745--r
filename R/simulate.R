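#' Run a batch of episodes under a frozen policy
#'
#' Simulates episodes of the task with the given actor, sampling one action
#' per step from the softmax policy. Decision-variable traces
#' (\eqn{\Delta\Sigma_{right}}, \eqn{\Delta\Sigma^s}, \eqn{\Delta\Sigma^c}
#' per step) can be recorded for the decision-aligned analyses.
#'
#' @param params An [agent_params()] actor.
#' @param task A [task_params()] object.
#' @param mus Vector of per-episode signal means. Alternatively give
#'   `n_episodes` to draw them from \eqn{N(0, \sigma_\mu^2)}.
#' @param n_episodes Number of episodes when `mus` is missing.
#' @param coherence Optional single coherence (percent); episodes then use
#'   \eqn{\mu = \pm} [coherence_to_mu()]`(coherence)` with random sign.
#' @param record_traces Record per-step decision variables.
#' @return List with `outcomes` (a data frame: `episode_id`, `mu`,
#'   `coherence`, `action` (-1 left, 0 timeout, +1 right), `decision_time`
#'   (s), `reward`, `correct`) and, if requested, `traces` (one matrix per
#'   episode with columns `dsr`, `ds_s`, `ds_c`).
#' @export
run_episodes <- function(params, task, mus = NULL, n_episodes = NULL,
                         coherence = NULL, record_traces = FALSE) {
  stopifnot(inherits(params, "agent_params"), inherits(task, "task_params"))
  if (is.null(mus)) {
    if (!is.null(coherence)) {
      stopifnot(!is.null(n_episodes))
      m <- coherence_to_mu(coherence)
      mus <- m * sample(c(-1, 1), n_episodes, replace = TRUE)
    } else {
      stopifnot(!is.null(n_episodes))
      mus <- sample_mu(n_episodes, task$sigma_mu)
    }
  }
  res <- cpp_run_batch(params$grid$taus, task$dt, task$n_steps,
                       task$sigma / sqrt(task$dt), task$sigma_I,
                       params$theta_s, params$theta_c, params$b,
                       mus, record_traces)
  out <- data.frame(episode_id = seq_along(mus), mu = mus,
                    coherence = mu_to_coherence(abs(mus)),
                    action = res$action,
                    decision_time = res$step * task$dt,
                    reward = res$reward,
                    correct = ifelse(res$action == 0 | mus == 0, NA,
                                     res$reward == 1))
  ret <- list(outcomes = out)
  if (record_traces) ret$traces <- res$traces
  ret
}
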