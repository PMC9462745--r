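#' Critic parameters
#'
#' The critic estimates the expected return \eqn{V(t)} of the current episode
#' as a linear read-out of the same integrator banks the actor sees:
#' \eqn{V = \sum_\tau w^s_\tau |y^s_\tau| + \sum_\tau w^c_\tau y^c_\tau +
#' b_v}. The absolute value on the signal bank respects the left/right
#' symmetry of the expected reward.
#'
#' @param grid A [make_grid()] object.
#' @param w_s,w_c Weight vectors on the signal-magnitude and clock
#'   integrators. Default zero.
#' @param b_v Bias. Default 0.
#' @return An object of class `critic_params`.
#' @export
critic_params <- function(grid, w_s = numeric(grid$n_tau),
                          w_c = numeric(grid$n_tau), b_v = 0) {
  stopifnot(inherits(grid, "timescale_grid"),
            length(w_s) == grid$n_tau, length(w_c) == grid$n_tau)
  structure(list(grid = grid, w_s = w_s, w_c = w_c, b_v = b_v),
            class = "critic_params")
}

#' Critic value for one read-out
#'
#' @param readout List with `y_signal`, `y_clock`.
#' @param critic A [critic_params()] object.
#' @return Scalar expected-return estimate.
#' @export
critic_value <- function(readout, critic) {
  stopifnot(inherits(critic, "critic_params"))
  sum(critic$w_s * abs(readout$y_signal)) +
    sum(critic$w_c * readout$y_clock) + critic$b_v
}

#' Temporal-difference error for one transition
#'
#' @param prev_V Value estimate at the current step.
#' @param next_V Value estimate at the next step (ignored on terminal
#'   transitions).
#' @param reward Reward received on the transition (0 or 1).
#' @param terminal_flag `TRUE` if the transition ends the episode.
#' @param gamma Discount factor.
#' @return The TD error \eqn{\delta}.
#' @export
td_step <- function(prev_V, next_V, reward, terminal_flag, gamma) {
  reward + gamma * next_V * (1 - as.numeric(terminal_flag)) - prev_V
}

#' Gradient of the log-policy with respect to the actor parameters
#'
#' For the softmax policy, \eqn{\partial \log p(a) / \partial \Sigma_b =
#' 1\{a = b\} - p_b}; the chain rule then distributes the read-out features
#' over the weights (the `wait` row sees \eqn{|y^s_\tau|}).
#'
#' @param readout List with `y_signal`, `y_clock`.
#' @param params An [agent_params()] actor.
#' @param action The action taken (`"left"`, `"wait"`, `"right"`).
#' @return List with `theta_s`, `theta_c` (3 x n_tau) and `b` (length 3)
#'   gradients, mirroring the shape of [agent_params()].
#' @export
grad_log_policy <- function(readout, params, action) {
  action <- match.arg(action, ACTIONS)
  p <- softmax_policy(action_sums(readout, params))
  coef <- as.numeric(ACTIONS == action) - p
  feats <- rbind(left = readout$y_signal,
                 wait = abs(readout$y_signal),
                 right = readout$y_signal)
  list(theta_s = coef * feats,
       theta_c = coef %o% readout$y_clock,
       b = coef)
}

#' Gradient of the critic value with respect to the critic parameters
#'
#' @inheritParams critic_value
#' @return List with `w_s`, `w_c`, `b_v` gradients.
#' @export
grad_critic <- function(readout, critic) {
  list(w_s = abs(readout$y_signal), w_c = readout$y_clock, b_v = 1)
}

#' Eligibility-trace accumulation and parameter update
#'
#' One step of the TD(\eqn{\lambda}) update on a flat parameter vector:
#' the trace decays by \eqn{\gamma\lambda} and absorbs the current gradient,
#' then the parameters move by `lr * delta * trace`. With `lambda = 0` this
#' reduces to the one-step actor-critic update.
#'
#' @param params Flat numeric parameter vector.
#' @param traces Flat trace vector (zero at episode start).
#' @param grad Current gradient (same length).
#' @param delta TD error.
#' @param lr Learning rate.
#' @param lambda Trace decay in `[0, 1]`.
#' @param gamma Discount factor.
#' @return List with updated `params` and `traces`.
#' @export
accumulate_and_apply <- function(params, traces, grad, delta, lr, lambda,
                                 gamma) {
  stopifnot(length(params) == length(traces),
            length(params) == length(grad))
  if (any(!is.finite(grad)))
    stop("non-finite gradient in eligibility-trace update")
  traces <- gamma * lambda * traces + grad
  list(params = params + lr * delta * traces, traces = traces)
}

#' Training configuration for the actor-critic procedure
#'
#' Defaults are chosen so that training on the default task reaches the
#' accuracy floor within roughly 1e5 episodes. The halting rule evaluates
#' signal neutrality on frozen held-out batches at every checkpoint and
#' returns the snapshot at its running maximum over checkpoints whose
#' overall accuracy is at least `accuracy_floor`; training stops once that
#' maximum has not improved for `peak_detection_window` consecutive
#' checkpoints (or at `n_episodes_max`).
#'
#' @param lr_actor,lr_critic Learning rates.
#' @param lambda_actor,lambda_critic Eligibility-trace decay in `[0, 1]`.
#' @param gamma Discount factor in `(0, 1]` (episodic task, undiscounted by
#'   default).
#' @param b_wait_init Initial `wait` bias; a high value makes the untrained
#'   agent wait a random finite time before a random choice.
#' @param n_episodes_max Hard stop.
#' @param checkpoint_every Episodes between diagnostic checkpoints.
#' @param eval_episodes Held-out episodes per evaluation batch (one batch of
#'   random-\eqn{\mu} episodes for accuracy, plus one per fixed coherence).
#' @param accuracy_floor Minimum overall accuracy for a checkpoint to count
#'   as a candidate signal-neutrality peak.
#' @param peak_detection_window Checkpoints without a new peak before
#'   halting.
#' @param divergence_guard Abort if any |parameter| exceeds this bound.
#' @param delta_clip Clip the TD error to this magnitude before applying
#'   updates. Rewards lie in `[0, 1]`, so well-behaved TD errors never
#'   exceed 1 plus the value-estimate error; the clip bounds the gain of
#'   the value-update feedback loop (which can otherwise run away during
#'   the long, high-variance episodes early in training) without moving
#'   its fixed points.
#' @param batched Accumulate the TD(lambda) updates over an episode and
#'   apply them once at its end, instead of applying each update online
#'   within the episode. Default `FALSE` (online).
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr_actor = 1.2e-2, lr_critic = 7e-2,
                            lambda_actor = 0.8, lambda_critic = 0,
                            gamma = 1, b_wait_init = 4,
                            n_episodes_max = 150000,
                            checkpoint_every = 2000, eval_episodes = 2000,
                            accuracy_floor = 0.81,
                            peak_detection_window = 10,
                            divergence_guard = 1000, delta_clip = 1,
                            batched = FALSE) {
  stopifnot(lr_actor > 0, lr_critic > 0,
            lambda_actor >= 0, lambda_actor <= 1,
            lambda_critic >= 0, lambda_critic <= 1,
            gamma > 0, gamma <= 1,
            n_episodes_max >= checkpoint_every)
  structure(list(lr_actor = lr_actor, lr_critic = lr_critic,
                 lambda_actor = lambda_actor, lambda_critic = lambda_critic,
                 gamma = gamma, b_wait_init = b_wait_init,
                 n_episodes_max = as.integer(n_episodes_max),
                 checkpoint_every = as.integer(checkpoint_every),
                 eval_episodes = as.integer(eval_episodes),
                 accuracy_floor = accuracy_floor,
                 peak_detection_window = as.integer(peak_detection_window),
                 divergence_guard = divergence_guard,
                 delta_clip = delta_clip,
                 batched = isTRUE(batched)),
            class = "training_config")
}

EVAL_COHERENCES <- c(0, 3.2, 6.4, 12.8, 25.6, 51.2)

## Held-out evaluation of a frozen actor: overall accuracy on random-mu
## episodes plus the six-coherence battery (traces for signal neutrality,
## response times for the scalar property). RNG state is saved and restored
## so that training noise is unaffected and every checkpoint sees the same
## held-out sequences.
evaluate_checkpoint <- function(params, task, eval_seed, n_eval,
                                coherences = EVAL_COHERENCES,
                                curve_window = 0.6, curve_min_count = 100) {
  rng_state <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (!is.null(rng_state))
      assign(".Random.seed", rng_state, envir = .GlobalEnv)
  })
  set.seed(eval_seed)
  overall <- run_episodes(params, task, n_episodes = n_eval)$outcomes
  # accuracy in the psychometric sense: fraction of correct *choices*
  # (timeouts are not choices; they are tracked separately)
  accuracy <- mean(overall$correct[overall$action != 0L], na.rm = TRUE)
  reward_rate <- mean(overall$reward)
  late_fraction <- mean(overall$action == 0)

  batches <- lapply(coherences, function(co)
    run_episodes(params, task, n_episodes = n_eval, coherence = co,
                 record_traces = TRUE))
  names(batches) <- as.character(coherences)

  curves <- suppressWarnings(
    build_aligned_curves(batches, coherences, dt = task$dt,
                         window = curve_window,
                         min_count = curve_min_count))
  sn <- tryCatch(signal_neutrality(curves), error = function(e) NA_real_)
  rts <- lapply(batches, function(b) {
    o <- b$outcomes
    o$decision_time[o$action != 0]
  })
  sp <- tryCatch(scalar_property(rts), error = function(e) NA_real_)
  per_coh <- lapply(batches, function(b) performance_curves(b$outcomes))
  list(accuracy = accuracy, reward_rate = reward_rate,
       late_fraction = late_fraction,
       mean_rt = mean(overall$decision_time[overall$action != 0]),
       signal_neutrality = sn, scalar_property = sp,
       per_coherence = do.call(rbind, per_coh),
       cv_by_coherence = vapply(rts, function(x)
         if (length(x) >= 2) cv(x) else NA_real_, numeric(1)))
}

#' Train the agent by online actor-critic TD(lambda)
#'
#' Runs episodes with \eqn{\mu \sim N(0, \sigma_\mu^2)}, applying per-step
#' online updates with eligibility traces, and evaluates frozen held-out
#' diagnostics every `checkpoint_every` episodes. Training halts at the
#' signal-neutrality peak (conditioned on the accuracy floor; see
#' [training_config()]) or at `n_episodes_max`, and the returned actor is
#' the snapshot at the detected peak (the final snapshot if no checkpoint
#' ever met the floor).
#'
#' @param task A [task_params()] object.
#' @param grid A [make_grid()] object.
#' @param config A [training_config()] object.
#' @param init Optional starting [agent_params()] (e.g. from
#'   [restrict_to_single_tau()] or a previous fit); its grid overrides
#'   `grid`.
#' @param init_critic Optional starting [critic_params()] (to continue a
#'   previous fit).
#' @param clock Set `FALSE` to train the clock-less comparison model (clock
#'   weights frozen at zero).
#' @param eval_seed Seed for the frozen held-out evaluation batches
#'   (derived from the current RNG if missing).
#' @param verbose Print a line per checkpoint.
#' @return An object of class `mta_fit`: `params` and `critic` at the peak,
#'   `final_params`, `final_critic`, `trace` (one row per checkpoint),
#'   `halting_episode` (episode index of the peak snapshot), `snapshots`.
#' @export
train <- function(task, grid, config = training_config(), init = NULL,
                  init_critic = NULL, clock = TRUE, eval_seed = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(task, "task_params"),
            inherits(config, "training_config"))
  if (is.null(init)) {
    stopifnot(inherits(grid, "timescale_grid"))
    init <- agent_params(grid, b = c(0, config$b_wait_init, 0))
  } else {
    grid <- init$grid
  }
  if (is.null(eval_seed))
    eval_seed <- sample.int(.Machine$integer.max, 1)
  params <- init
  critic <- if (is.null(init_critic)) critic_params(grid) else init_critic
  n_tau <- grid$n_tau
  sd_sample <- task$sigma / sqrt(task$dt)

  trace_rows <- list()
  snapshots <- list()
  best_sn <- -Inf
  best_idx <- NA_integer_
  since_best <- 0L
  n_ckpt <- config$n_episodes_max %/% config$checkpoint_every

  for (ck in seq_len(n_ckpt)) {
    res <- cpp_train_chunk(grid$taus, task$dt, task$n_steps, sd_sample,
                           task$sigma_I, task$sigma_mu,
                           params$theta_s, params$theta_c, params$b,
                           critic$w_s, critic$w_c, critic$b_v,
                           config$checkpoint_every,
                           config$lr_actor, config$lr_critic,
                           config$lambda_actor, config$lambda_critic,
                           config$gamma, config$divergence_guard, clock,
                           config$batched, config$delta_clip)
    params$theta_s <- res$theta_s
    params$theta_c <- res$theta_c
    params$b <- stats::setNames(res$b, ACTIONS)
    critic$w_s <- res$w_s
    critic$w_c <- res$w_c
    critic$b_v <- res$b_v

    ev <- evaluate_checkpoint(params, task, eval_seed, config$eval_episodes)
    episode_index <- ck * config$checkpoint_every
    trace_rows[[ck]] <- data.frame(
      episode_index = episode_index,
      accuracy = ev$accuracy,
      reward_rate = ev$reward_rate,
      late_fraction = ev$late_fraction,
      mean_rt = ev$mean_rt,
      signal_neutrality = ev$signal_neutrality,
      scalar_property = ev$scalar_property,
      train_reward = mean(res$reward),
      train_late = mean(res$action == 0L),
      train_rt = mean(res$step[res$action != 0L]) * task$dt,
      t(stats::setNames(ev$per_coherence$accuracy,
                        paste0("acc_", EVAL_COHERENCES))),
      t(stats::setNames(ev$per_coherence$mean_rt,
                        paste0("rt_", EVAL_COHERENCES))))
    snapshots[[ck]] <- list(params = params, critic = critic)
    if (verbose)
      message(sprintf(
        "episode %d: acc %.3f, late %.3f, SN %.3g, SP %.3g",
        episode_index, ev$accuracy, ev$late_fraction,
        ev$signal_neutrality, ev$scalar_property))

    if (is.finite(ev$signal_neutrality) &&
        ev$accuracy >= config$accuracy_floor &&
        ev$signal_neutrality > best_sn) {
      best_sn <- ev$signal_neutrality
      best_idx <- ck
      since_best <- 0L
    } else if (!is.na(best_idx)) {
      since_best <- since_best + 1L
      if (since_best >= config$peak_detection_window) break
    }
  }

  trace <- do.call(rbind, trace_rows)
  peak <- if (is.na(best_idx)) length(snapshots) else best_idx
  structure(list(params = snapshots[[peak]]$params,
                 critic = snapshots[[peak]]$critic,
                 final_params = params, final_critic = critic,
                 trace = trace,
                 halting_episode = peak * config$checkpoint_every,
                 peak_found = !is.na(best_idx),
                 snapshots = snapshots,
                 task = task, config = config, eval_seed = eval_seed),
            class = "mta_fit")
}

#' @export
print.mta_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat("Actor-critic fit:", nrow(x$trace), "checkpoints,",
      "halting episode", x$halting_episode,
      if (x$peak_found) "(signal-neutrality peak)" else "(no peak found)",
      "\n  held-out accuracy at halt:",
      round(x$trace$accuracy[x$halting_episode %/%
                               x$config$checkpoint_every], 3), "\n")
  invisible(x)
}
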