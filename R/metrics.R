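#' Decision-aligned average decision-variable curves
#'
#' For each coherence, averages the per-step \eqn{\Delta\Sigma_{right}}
#' traces of qualifying episodes (correct 'right' decisions; at 0% coherence,
#' where no correct side exists, episodes whose choice was 'right') over a
#' window of lags before the decision. A curve's interval of validity is
#' shrunk where fewer than `min_count` episodes contribute; coherences with
#' no qualifying episodes are omitted with a warning.
#'
#' @param batches Named list, one element per coherence, each as returned by
#'   [run_episodes()] with `record_traces = TRUE` (fields `outcomes`,
#'   `traces`).
#' @param coherences Coherence percentages, parallel to `batches`.
#' @param dt Time step (s).
#' @param window Alignment window before the decision (s). Default 0.6.
#' @param min_count Minimum episodes per retained lag. Default 100.
#' @param column Trace column to average. Default `"dsr"`.
#' @return An object of class `aligned_curves`: a list with `coherences`
#'   and `curves` (per coherence, a data frame `lag_s`, `mean`, `n`; lag 0
#'   is the decision step).
#' @export
build_aligned_curves <- function(batches, coherences, dt, window = 0.6,
                                 min_count = 100, column = "dsr") {
  stopifnot(length(batches) == length(coherences))
  n_lag <- as.integer(round(window / dt)) + 1L
  curves <- list()
  kept <- c()
  for (i in seq_along(batches)) {
    o <- batches[[i]]$outcomes
    tr <- batches[[i]]$traces
    qual <- if (coherences[i] == 0) {
      which(o$action == 1L)
    } else {
      which(o$action == 1L & o$reward == 1L)
    }
    if (length(qual) == 0) {
      warning("no qualifying episodes at coherence ", coherences[i],
              "%; curve omitted")
      next
    }
    steps <- o$decision_time[qual] / dt
    sums <- numeric(n_lag)
    counts <- integer(n_lag)
    for (q in seq_along(qual)) {
      m <- tr[[qual[q]]]
      k <- as.integer(round(steps[q]))
      jmax <- min(n_lag - 1L, k - 1L)
      v <- m[k - (0:jmax), column]
      sums[1:(jmax + 1L)] <- sums[1:(jmax + 1L)] + v
      counts[1:(jmax + 1L)] <- counts[1:(jmax + 1L)] + 1L
    }
    ok <- counts >= min_count
    keep <- if (!ok[1]) 0L else (which(c(!ok, TRUE))[1] - 1L)
    if (keep == 0L) {
      warning("fewer than ", min_count, " episodes at every lag for ",
              "coherence ", coherences[i], "%; curve omitted")
      next
    }
    curves[[length(curves) + 1L]] <-
      data.frame(lag_s = (seq_len(keep) - 1L) * dt,
                 mean = sums[seq_len(keep)] / counts[seq_len(keep)],
                 n = counts[seq_len(keep)])
    kept <- c(kept, coherences[i])
  }
  structure(list(coherences = kept, curves = curves),
            class = "aligned_curves")
}

#' Signal-neutrality measure
#'
#' Jointly min-max rescales all decision-aligned curves to `[0, 1]` (global
#' minimum of the curve minima to 0, global maximum of the maxima to 1),
#' computes at each lag the maximum pairwise distance among the curves
#' defined there (lags where fewer than two curves are defined are skipped),
#' averages over lags, and returns the inverse. A perfect collapse (mean
#' distance below `1e-9`) returns the `cap` so the measure stays finite.
#'
#' @param curves An [build_aligned_curves()] object.
#' @param cap Value returned for a perfect collapse. Default `1e6`.
#' @return Scalar signal-neutrality measure (larger = better collapse).
#' @export
signal_neutrality <- function(curves, cap = 1e6) {
  stopifnot(inherits(curves, "aligned_curves"))
  cl <- curves$curves
  if (length(cl) < 2)
    stop("signal neutrality needs at least two aligned curves")
  all_vals <- unlist(lapply(cl, `[[`, "mean"))
  lo <- min(all_vals)
  hi <- max(all_vals)
  if (hi - lo < 1e-12) return(cap)
  resc <- lapply(cl, function(d) (d$mean - lo) / (hi - lo))
  n_lags <- max(vapply(resc, length, integer(1)))
  dists <- rep(NA_real_, n_lags)
  for (j in seq_len(n_lags)) {
    vals <- unlist(lapply(resc, function(v) if (length(v) >= j) v[j]))
    if (length(vals) >= 2) dists[j] <- max(vals) - min(vals)
  }
  m <- mean(dists, na.rm = TRUE)
  if (!is.finite(m)) stop("no lag has two or more defined curves")
  if (m < 1e-9) cap else 1 / m
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the sample mean.
#'
#' @param x Numeric vector of at least two response times with positive mean.
#' @return Scalar CV.
#' @export
cv <- function(x) {
  if (length(x) < 2) stop("cv needs at least two values")
  m <- mean(x)
  if (m <= 0) stop("cv needs a positive mean")
  stats::sd(x) / m
}

#' Scalar-property measure
#'
#' The inverse of the range (max minus min) of the response-time
#' coefficients of variation across coherences: large when the CV is nearly
#' constant, i.e. when the shape of the response-time distribution is
#' invariant to difficulty (Weber's law).
#'
#' @param rts_by_coherence List of response-time vectors, one per coherence.
#' @param cap Value returned when the CV range is below `1e-9`.
#' @return Scalar measure (larger = more scalar).
#' @export
scalar_property <- function(rts_by_coherence, cap = 1e6) {
  cvs <- vapply(rts_by_coherence, function(x)
    if (length(x) >= 2 && mean(x) > 0) cv(x) else NA_real_, numeric(1))
  cvs <- cvs[is.finite(cvs)]
  if (length(cvs) < 2)
    stop("scalar property needs valid CVs for at least two coherences")
  rng <- max(cvs) - min(cvs)
  if (rng < 1e-9) cap else 1 / rng
}

#' Maximum-likelihood Gamma fit of response times
#'
#' Fits a Gamma distribution by maximum likelihood and returns, alongside
#' shape and scale, the unit-mean rescaling used to compare distribution
#' shapes across difficulties: dividing the times by the fitted mean
#' (shape x scale) leaves a Gamma with the same shape and mean one, whose
#' density is available as `unit_density`.
#'
#' @param rts At least 50 positive response times.
#' @return List with `shape`, `scale`, `mean`, `cv` (\eqn{1/\sqrt{shape}})
#'   and `unit_density` (a function of the rescaled time).
#' @export
gamma_fit <- function(rts) {
  if (length(rts) < 50) stop("gamma_fit needs at least 50 response times")
  if (any(rts <= 0)) stop("gamma_fit needs strictly positive times")
  m <- mean(rts)
  v <- stats::var(rts)
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- suppressWarnings(
    MASS::fitdistr(rts, "gamma", start = start, lower = c(1e-8, 1e-8)))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  list(shape = shape, scale = 1 / rate, mean = shape / rate,
       cv = 1 / sqrt(shape),
       unit_density = function(u) stats::dgamma(u, shape = shape,
                                                rate = shape))
}

#' Psychometric and chronometric summaries per coherence
#'
#' @param outcomes An outcomes data frame from [run_episodes()] (possibly
#'   row-bound across coherences).
#' @return Data frame with one row per coherence: `coherence`, `n`,
#'   `n_decided`, `accuracy` (fraction correct among decided episodes; `NA`
#'   at 0% coherence), `acc_se` (binomial), `mean_rt` (s, decided episodes),
#'   `rt_se`, `late_fraction`.
#' @export
performance_curves <- function(outcomes) {
  co <- signif(outcomes$coherence, 6)
  res <- lapply(split(outcomes, co), function(d) {
    dec <- d[d$action != 0L, ]
    corr <- dec$correct[!is.na(dec$correct)]
    acc <- if (length(corr) > 0) mean(corr) else NA_real_
    data.frame(coherence = d$coherence[1], n = nrow(d),
               n_decided = nrow(dec), accuracy = acc,
               acc_se = if (length(corr) > 1)
                 sqrt(acc * (1 - acc) / length(corr)) else NA_real_,
               mean_rt = mean(dec$decision_time),
               rt_se = stats::sd(dec$decision_time) /
                 sqrt(max(1, nrow(dec))),
               late_fraction = mean(d$action == 0L))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$coherence), ]
  rownames(out) <- NULL
  out
}

#' Deterministic clock-pathway decision variable
#'
#' \eqn{\Delta\Sigma^c(t) = \Sigma^c_{wait}(t) - \Sigma^c_{right}(t)}
#' computed on the noise-free clock trajectories
#' \eqn{x^c_\tau(t) = 1 - e^{-t/\tau}}. This is the time-dependent soft
#' threshold ("collapsing boundary") implemented by the clock weights.
#'
#' @param params An [agent_params()] actor.
#' @param task A [task_params()] object (grid of times).
#' @return Data frame `t` (s), `ds_c`.
#' @export
dsc_curve <- function(params, task) {
  t <- seq_len(task$n_steps) * task$dt
  xc <- vapply(params$grid$taus, function(tau) 1 - exp(-t / tau),
               numeric(length(t)))
  if (params$grid$n_tau == 1) xc <- matrix(xc, ncol = 1)
  ds_c <- as.numeric(xc %*% (params$theta_c["wait", ] -
                               params$theta_c["right", ])) +
    params$b[["wait"]] - params$b[["right"]]
  data.frame(t = t, ds_c = ds_c)
}

#' Collapsing-boundary strip
#'
#' Pairs the deterministic clock threshold \eqn{\Delta\Sigma^c(t)} with the
#' central band of the signal-pathway decision variable
#' \eqn{\Delta\Sigma^s} observed at decision time: per time bin (one bin per
#' step), the central `quantile` interval of \eqn{\Delta\Sigma^s} among
#' correct 'right' decisions. Bins with fewer than `min_per_bin` decisions
#' are flagged (`NA` envelope), not interpolated.
#'
#' @param batches As in [build_aligned_curves()].
#' @param params The actor that produced the batches.
#' @param task A [task_params()] object.
#' @param quantile Central mass of the strip. Default 0.80.
#' @param min_per_bin Minimum decisions per reported bin. Default 20.
#' @return An object of class `boundary_strip`: list with `strip` (data
#'   frame `t`, `n`, `lo`, `hi`, `mid`) and `dsc` (from [dsc_curve()]).
#' @export
boundary_strip <- function(batches, params, task, quantile = 0.80,
                           min_per_bin = 20) {
  ds_at_dec <- list()
  for (b in batches) {
    o <- b$outcomes
    qual <- which(o$action == 1L & (o$reward == 1L | o$mu == 0))
    if (length(qual) == 0) next
    k <- as.integer(round(o$decision_time[qual] / task$dt))
    v <- vapply(seq_along(qual),
                function(i) b$traces[[qual[i]]][k[i], "ds_s"], numeric(1))
    ds_at_dec[[length(ds_at_dec) + 1L]] <- data.frame(step = k, ds_s = v)
  }
  dd <- do.call(rbind, ds_at_dec)
  lo_q <- (1 - quantile) / 2
  strip <- data.frame(t = seq_len(task$n_steps) * task$dt,
                      n = 0L, lo = NA_real_, hi = NA_real_,
                      mid = NA_real_)
  if (!is.null(dd)) {
    tab <- split(dd$ds_s, dd$step)
    for (s in names(tab)) {
      i <- as.integer(s)
      strip$n[i] <- length(tab[[s]])
      if (strip$n[i] >= min_per_bin) {
        qs <- stats::quantile(tab[[s]], c(lo_q, 0.5, 1 - lo_q),
                              names = FALSE)
        strip$lo[i] <- qs[1]
        strip$mid[i] <- qs[2]
        strip$hi[i] <- qs[3]
      }
    }
  }
  structure(list(strip = strip, dsc = dsc_curve(params, task)),
            class = "boundary_strip")
}

#' Full held-out evaluation battery for a frozen actor
#'
#' Runs one random-\eqn{\mu} batch plus one batch per fixed coherence and
#' computes every operational measure: overall accuracy, psychometric and
#' chronometric curves, signal neutrality, response-time CVs and the scalar
#' property, and the collapsing-boundary strip.
#'
#' @param params An [agent_params()] actor.
#' @param task A [task_params()] object.
#' @param n_episodes Episodes per batch. Default 2000.
#' @param coherences Fixed-coherence battery. Default
#'   `c(0, 3.2, 6.4, 12.8, 25.6, 51.2)`.
#' @param keep_batches Return the raw batches too.
#' @return List with `accuracy`, `late_fraction`, `performance` (per
#'   coherence), `signal_neutrality`, `cv_by_coherence`, `scalar_property`,
#'   `boundary`, and optionally `batches`.
#' @export
evaluate_agent <- function(params, task, n_episodes = 2000,
                           coherences = EVAL_COHERENCES,
                           keep_batches = FALSE) {
  overall <- run_episodes(params, task, n_episodes = n_episodes)$outcomes
  batches <- lapply(coherences, function(co)
    run_episodes(params, task, n_episodes = n_episodes, coherence = co,
                 record_traces = TRUE))
  names(batches) <- as.character(coherences)
  curves <- build_aligned_curves(batches, coherences, dt = task$dt)
  rts <- lapply(batches, function(b)
    b$outcomes$decision_time[b$outcomes$action != 0L])
  perf <- performance_curves(
    do.call(rbind, lapply(batches, `[[`, "outcomes")))
  out <- list(accuracy = mean(overall$correct[overall$action != 0L],
                              na.rm = TRUE),
              reward_rate = mean(overall$reward),
              late_fraction = mean(overall$action == 0L),
              performance = perf,
              signal_neutrality = tryCatch(signal_neutrality(curves),
                                           error = function(e) NA_real_),
              cv_by_coherence = vapply(rts, function(x)
                if (length(x) >= 2) cv(x) else NA_real_, numeric(1)),
              scalar_property = tryCatch(scalar_property(rts),
                                         error = function(e) NA_real_),
              boundary = boundary_strip(batches, params, task),
              aligned_curves = curves)
  if (keep_batches) out$batches <- batches
  out
}
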