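# build a synthetic batch whose traces and outcomes are fully controlled:
# each episode decides 'right' at a given step with a prescribed dsr trace
synthetic_batch <- function(n_episodes, decide_step, trace_fun,
                            mu = 0.5) {
  traces <- lapply(seq_len(n_episodes), function(i) {
    k <- decide_step(i)
    m <- cbind(dsr = trace_fun(i, seq_len(k)), ds_s = 0, ds_c = 0)
    m
  })
  outcomes <- data.frame(episode_id = seq_len(n_episodes), mu = mu,
                         coherence = mu_to_coherence(abs(mu)),
                         action = 1L,
                         decision_time = vapply(seq_len(n_episodes),
                                                decide_step, 1) * 0.01,
                         reward = as.integer(mu > 0),
                         correct = mu > 0)
  list(outcomes = outcomes, traces = traces)
}

test_that("aligned curves average traces and enforce the minimum-count rule", {
  # identical traces: the curve equals the trace on its interval
  b <- synthetic_batch(120, function(i) 80, function(i, k) sin(k / 10))
  cs <- build_aligned_curves(list(b), coherences = 51.2, dt = 0.01,
                             min_count = 100)
  expect_equal(cs$coherences, 51.2)
  expect_equal(cs$curves[[1]]$mean, rev(sin((1:80) / 10))[1:61])
  expect_equal(cs$curves[[1]]$lag_s, (0:60) * 0.01)
  # 99 episodes at min_count 100: curve omitted with a warning
  b99 <- synthetic_batch(99, function(i) 80, function(i, k) k)
  expect_warning(c99 <- build_aligned_curves(list(b99), 51.2, 0.01,
                                             min_count = 100), "omitted")
  expect_length(c99$curves, 0)
  # counts shrink the interval: episodes deciding at step 30 only support
  # lags 0..29; with half the episodes at step 80 the curve stops where
  # counts drop below min_count
  bmix <- synthetic_batch(200, function(i) if (i <= 150) 30 else 80,
                          function(i, k) k)
  cm <- build_aligned_curves(list(bmix), 51.2, 0.01, min_count = 100)
  expect_equal(nrow(cm$curves[[1]]), 30)
  # at 0% coherence 'right'-choice episodes qualify despite reward 0
  b0 <- synthetic_batch(120, function(i) 50, function(i, k) k, mu = 0)
  c0 <- build_aligned_curves(list(b0), 0, 0.01, min_count = 100)
  expect_length(c0$curves, 1)
})

test_that("signal neutrality is capped for perfect collapse, 1 for extremes, and affine-invariant", {
  b1 <- synthetic_batch(150, function(i) 80, function(i, k) k / 40)
  b2 <- synthetic_batch(150, function(i) 80, function(i, k) k / 40)
  cs <- build_aligned_curves(list(b1, b2), c(25.6, 51.2), 0.01)
  expect_equal(signal_neutrality(cs), 1e6)  # identical curves
  # two constant curves at the global extremes: mean max distance 1
  blo <- synthetic_batch(150, function(i) 80, function(i, k) 0 * k)
  bhi <- synthetic_batch(150, function(i) 80, function(i, k) 0 * k + 1)
  cs2 <- build_aligned_curves(list(blo, bhi), c(25.6, 51.2), 0.01)
  expect_equal(signal_neutrality(cs2), 1)
  # affine transforms of all curves leave the measure unchanged
  set.seed(22)
  mk <- function(a, b0) synthetic_batch(150, function(i) 80,
                                        function(i, k) a * sin(k / 9) + b0)
  cs3 <- build_aligned_curves(list(mk(1, 0), mk(0.5, 0.2)), c(25.6, 51.2),
                              0.01)
  cs4 <- build_aligned_curves(list(mk(3, -1), mk(1.5, -0.4)),
                              c(25.6, 51.2), 0.01)
  expect_equal(signal_neutrality(cs4), signal_neutrality(cs3),
               tolerance = 1e-9)
  expect_error(signal_neutrality(build_aligned_curves(list(b1), 51.2,
                                                      0.01)), "two")
})

test_that("cv matches distributional identities", {
  set.seed(23)
  expect_equal(cv(rexp(2e5)), 1, tolerance = 0.02)
  expect_equal(cv(rgamma(2e5, shape = 4)), 0.5, tolerance = 0.02)
  expect_equal(cv(rep(3.3, 10)), 0)
  expect_error(cv(1), "two")
  expect_error(cv(c(-5, 1)), "positive")
  # scale invariance
  x <- rgamma(1000, 3)
  expect_equal(cv(17 * x), cv(x), tolerance = 1e-12)
})

test_that("scalar property is the inverse CV range with a cap", {
  # CVs 0.4 and 0.6 -> 1 / 0.2
  set.seed(24)
  rts <- list(a = rgamma(4e4, shape = 1 / 0.4^2, scale = 1),
              b = rgamma(4e4, shape = 1 / 0.6^2, scale = 2))
  cvs <- c(cv(rts$a), cv(rts$b))
  expect_equal(scalar_property(rts), 1 / (max(cvs) - min(cvs)),
               tolerance = 1e-9)
  expect_equal(scalar_property(rts), 5, tolerance = 0.5)
  x <- rgamma(1000, 3)
  expect_equal(scalar_property(list(x, x, 2 * x)), 1e6)
  expect_error(scalar_property(list(x)), "two")
  # common rescaling of all response times leaves the measure unchanged
  expect_equal(scalar_property(lapply(rts, `*`, 3.7)),
               scalar_property(rts), tolerance = 1e-9)
})

test_that("gamma fits recover parameters and rescale to unit mean", {
  set.seed(25)
  for (shape in c(1.5, 3, 8)) {
    x <- rgamma(1e4, shape = shape, scale = 0.2)
    f <- gamma_fit(x)
    expect_equal(f$shape, shape, tolerance = 0.05)
    expect_equal(f$cv, 1 / sqrt(f$shape), tolerance = 1e-9)
    # unit-mean rescaled density integrates to mean 1
    m1 <- stats::integrate(function(u) u * f$unit_density(u), 0, Inf)$value
    expect_equal(m1, 1, tolerance = 1e-6)
  }
  expect_error(gamma_fit(rgamma(10, 2)), "50")
  expect_error(gamma_fit(c(rep(1, 60), -1)), "positive")
})

test_that("performance curves report chance for a random-action policy", {
  task <- default_task()
  set.seed(26)
  rand <- agent_params(default_grid(), b = c(0, 2, 0))  # signal-blind
  out <- do.call(rbind, lapply(c(3.2, 12.8, 51.2), function(co)
    run_episodes(rand, task, n_episodes = 2000, coherence = co)$outcomes))
  perf <- performance_curves(out)
  expect_equal(nrow(perf), 3)
  expect_true(all(abs(perf$accuracy - 0.5) < 3 * perf$acc_se))
})

test_that("boundary strip pairs the decision envelope with the clock curve", {
  task <- default_task()
  p <- hand_agent()
  set.seed(27)
  batches <- lapply(c(12.8, 25.6, 51.2), function(co)
    run_episodes(p, task, n_episodes = 800, coherence = co,
                 record_traces = TRUE))
  bs <- boundary_strip(batches, p, task)
  expect_s3_class(bs, "boundary_strip")
  expect_equal(nrow(bs$strip), task$n_steps)
  expect_equal(bs$dsc$ds_c, dsc_curve(p, task)$ds_c)
  ok <- !is.na(bs$strip$lo)
  expect_gt(sum(ok), 5)                      # some bins are populated
  expect_true(all(bs$strip$n[ok] >= 20))     # only well-filled bins report
  expect_true(all(bs$strip$lo[ok] <= bs$strip$hi[ok]))
  # bins flagged (NA), not interpolated, where decisions are scarce
  expect_true(anyNA(bs$strip$lo))
})
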