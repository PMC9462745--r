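test_that("action sums follow the weighted-sum definitions", {
  g <- make_grid(1, 1, 1)
  # single tau, theta_s[right] = 2, y = 0.5, b[right] = -0.3 -> sigma 0.7
  p <- agent_params(g, b = c(0, 0, -0.3))
  p$theta_s["right", ] <- 2
  s <- action_sums(list(y_signal = 0.5, y_clock = 0.2), p)
  expect_equal(unname(s$sigma[["right"]]), 0.7)
  # null parameters give all-zero sums
  p0 <- agent_params(make_grid())
  r <- random_readout(10)
  s0 <- action_sums(r, p0)
  expect_equal(unname(s0$sigma), c(0, 0, 0))
  expect_error(action_sums(list(y_signal = 1:3, y_clock = 1:3), p0),
               "grid")
})

test_that("the wait pathway sees |y|: mirrored signals swap left/right and leave wait unchanged", {
  set.seed(5)
  g <- make_grid()
  p <- agent_params(g, b = c(0.4, 1.1, 0.4))
  p$theta_s["right", ] <- rnorm(10)
  p$theta_s["left", ] <- -p$theta_s["right", ]
  p$theta_s["wait", ] <- rnorm(10)
  p$theta_c[] <- rep(rnorm(10), each = 3)  # equal clock weights
  r <- random_readout(10)
  r_neg <- list(y_signal = -r$y_signal, y_clock = r$y_clock)
  s <- action_sums(r, p)
  sm <- action_sums(r_neg, p)
  expect_equal(sm$sigma[["left"]], s$sigma[["right"]], tolerance = 1e-12)
  expect_equal(sm$sigma[["right"]], s$sigma[["left"]], tolerance = 1e-12)
  expect_equal(sm$sigma[["wait"]], s$sigma[["wait"]], tolerance = 1e-12)
  # hence the policy mirrors exactly
  expect_equal(unname(softmax_policy(sm)[c("right", "wait", "left")]),
               unname(softmax_policy(s)[c("left", "wait", "right")]),
               tolerance = 1e-12)
})

test_that("softmax policy normalises, shifts invariantly, and matches hand values", {
  expect_equal(unname(softmax_policy(c(0, 0, 0))), rep(1 / 3, 3))
  # sigma[right] = 1, others 0 -> e/(2+e)
  p <- softmax_policy(c(0, 0, 1))
  expect_equal(unname(p[["right"]]), exp(1) / (2 + exp(1)), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    s <- rnorm(3, sd = 5)
    expect_equal(sum(softmax_policy(s)), 1, tolerance = 1e-12)
    expect_equal(softmax_policy(s + 17.3), softmax_policy(s),
                 tolerance = 1e-12)
  }
  # overflow safety
  expect_equal(unname(softmax_policy(c(1e4, 0, 0))[["left"]]), 1)
  expect_error(softmax_policy(c(NaN, 0, 0)), "non-finite")
})

test_that("act samples according to the policy", {
  expect_true(all(replicate(20, act(c(0, 1, 0))) == "wait"))
  set.seed(7)
  draws <- replicate(1e4, act(c(0.2, 0.5, 0.3)))
  f <- table(factor(draws, c("left", "wait", "right"))) / 1e4
  expect_lt(max(abs(f - c(0.2, 0.5, 0.3))), 3 * sqrt(0.5 * 0.5 / 1e4))
  set.seed(11); a1 <- replicate(10, act(c(0.3, 0.3, 0.4)))
  set.seed(11); a2 <- replicate(10, act(c(0.3, 0.3, 0.4)))
  expect_identical(a1, a2)
})

test_that("single-timescale restriction has nine parameters and embeds the full agent", {
  full <- hand_agent()
  r1 <- restrict_to_single_tau(full, 2)
  expect_equal(r1$grid$n_tau, 1L)
  expect_length(c(r1$theta_s, r1$theta_c, r1$b), 9)
  # a full agent with weight only at one tau equals the restricted agent
  g <- default_grid()
  tau_idx <- 7
  p <- agent_params(g, b = c(0.1, 0.9, -0.2))
  p$theta_s[, tau_idx] <- c(-1, 0.5, 1)
  p$theta_c[, tau_idx] <- c(0.2, -0.3, 0.2)
  r <- restrict_to_single_tau(p, g$taus[tau_idx])
  r$theta_s[, 1] <- p$theta_s[, tau_idx]
  r$theta_c[, 1] <- p$theta_c[, tau_idx]
  ro_full <- list(y_signal = numeric(10), y_clock = numeric(10))
  ro_full$y_signal[tau_idx] <- 0.33
  ro_full$y_clock[tau_idx] <- 0.71
  ro_1 <- list(y_signal = 0.33, y_clock = 0.71)
  expect_equal(softmax_policy(action_sums(ro_1, r)),
               softmax_policy(action_sums(ro_full, p)), tolerance = 1e-12)
})

test_that("strip_clock zeroes the time pathway only", {
  p <- hand_agent()
  p$theta_c["right", ] <- 0.1
  sc <- strip_clock(p)
  r <- random_readout(10)
  s <- action_sums(r, sc)
  expect_equal(unname(s$sigma_c), unname(p$b))
  expect_equal(s$ds_c, unname(p$b[["wait"]] - p$b[["right"]]))
  expect_equal(s$ds_s, action_sums(r, p)$ds_s)
  # the deterministic clock curve of a stripped agent is flat
  dsc <- dsc_curve(sc, default_task())
  expect_equal(dsc$ds_c, rep(p$b[["wait"]] - p$b[["right"]], 200))
})

test_that("decision-variable decomposition dsr = ds_s - ds_c holds per step", {
  set.seed(8)
  p <- hand_agent()
  for (i in 1:50) {
    s <- action_sums(random_readout(10), p)
    expect_equal(s$dsr, s$ds_s - s$ds_c, tolerance = 1e-12)
    expect_equal(s$dsr, unname(s$sigma[["right"]] - s$sigma[["wait"]]),
                 tolerance = 1e-12)
    expect_equal(s$ds_c, unname(s$sigma_c[["wait"]] - s$sigma_c[["right"]]),
                 tolerance = 1e-12)
  }
  # and in the compiled episode runner's recorded traces
  b <- run_episodes(p, default_task(), n_episodes = 20,
                    record_traces = TRUE)
  for (tr in b$traces)
    expect_equal(unname(tr[, "dsr"]),
                 unname(tr[, "ds_s"] - tr[, "ds_c"]), tolerance = 1e-12)
})

test_that("compiled episode runner agrees with the R-level policy pipeline", {
  # sigma_I = 0 and a fixed seed: replay the same signal stream in R and
  # check the recorded decision variables step by step
  task <- task_params(sigma_I = 0)
  p <- hand_agent()
  set.seed(9)
  b <- run_episodes(p, task, mus = 0.3, record_traces = TRUE)
  set.seed(9)
  mu <- 0.3
  st <- bank_init(p$grid)
  tr <- b$traces[[1]]
  for (k in seq_len(nrow(tr))) {
    s_t <- rnorm(1, mu, task$sigma / sqrt(task$dt))
    st <- step_bank(st, s_t, task$dt)
    sums <- action_sums(observe(st, 0), p)
    expect_equal(unname(tr[k, "dsr"]), sums$dsr, tolerance = 1e-10)
    runif(1) # the action draw consumed by the compiled runner
  }
})
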