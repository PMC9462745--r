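# Shared small objects and a cache for expensive trained artifacts.
# Everything is built in code at test time; trainings are created once per
# session and reused by the tests that need them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

default_task <- function() task_params()
default_grid <- function() make_grid()

# a hand-set, non-degenerate actor used by metric and log tests
hand_agent <- function(grid = default_grid()) {
  p <- agent_params(grid, b = c(0, 2, 0))
  p$theta_s["right", ] <- seq(1.5, 0.3, length.out = grid$n_tau)
  p$theta_s["left", ] <- -p$theta_s["right", ]
  p$theta_s["wait", ] <- -0.5
  p$theta_c["wait", ] <- 0.3
  p
}

random_readout <- function(n_tau) {
  list(y_signal = stats::rnorm(n_tau), y_clock = stats::runif(n_tau))
}

# the reference training runs shared by the acceptance tests: five
# independent default-configuration trainings of the full agent
full_fits <- function() cached("full_fits", function() {
  lapply(1:5, function(i) {
    set.seed(100 + i)
    train(default_task(), default_grid(), eval_seed = 9000 + i)
  })
})

# Comparative models trained on the same task, five seeds each. They need
# not reach the full agent's accuracy floor, so halting uses
# accuracy_floor = 0 and the comparison takes each model's best-accuracy
# checkpoint (its signal-neutrality peak can occur while the policy is
# still random, which would make the comparison vacuous).
best_snapshot <- function(fit) {
  fit$snapshots[[which.max(fit$trace$accuracy)]]$params
}

# The single-tau agent's integrator read-outs at tau = 2 s are an order of
# magnitude smaller than the fast multi-tau features, so it trains at
# correspondingly larger rates.
single_tau_fits <- function(tau = 2) cached("single_tau_fits", function() {
  cfg <- training_config(lr_actor = 0.03, lr_critic = 0.15,
                         n_episodes_max = 120000, checkpoint_every = 6000,
                         eval_episodes = 1000, accuracy_floor = 0,
                         peak_detection_window = 20)
  lapply(1:5, function(i) {
    set.seed(300 + i)
    init <- agent_params(make_grid(1, tau, tau), b = c(0, 4, 0))
    train(default_task(), NULL, cfg, init = init, eval_seed = 9300 + i)
  })
})

noclock_fits <- function() cached("noclock_fits", function() {
  cfg <- training_config(n_episodes_max = 48000, checkpoint_every = 4000,
                         eval_episodes = 1000, accuracy_floor = 0,
                         peak_detection_window = 6)
  lapply(1:5, function(i) {
    set.seed(500 + i)
    train(default_task(), default_grid(), cfg, clock = FALSE,
          eval_seed = 9500 + i)
  })
})
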