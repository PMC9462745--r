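ACTIONS <- c("left", "wait", "right")

#' Actor parameters
#'
#' The actor is defined by six weight vectors over the timescale grid --
#' three on the signal bank and three on the clock bank, one per action in
#' `{left, wait, right}` -- plus one bias per action. The `wait` weights act
#' on the *absolute value* of the signal read-outs, so that a signal and its
#' mirror image defer a decision equally.
#'
#' @param grid A [make_grid()] object.
#' @param theta_s,theta_c 3 x n_tau matrices (rows `left`, `wait`, `right`)
#'   of signal and clock weights. Default all zero.
#' @param b Length-3 bias vector (`left`, `wait`, `right`). Default zero.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(grid,
                         theta_s = matrix(0, 3, grid$n_tau),
                         theta_c = matrix(0, 3, grid$n_tau),
                         b = c(0, 0, 0)) {
  stopifnot(inherits(grid, "timescale_grid"),
            is.matrix(theta_s), all(dim(theta_s) == c(3, grid$n_tau)),
            is.matrix(theta_c), all(dim(theta_c) == c(3, grid$n_tau)),
            length(b) == 3)
  dimnames(theta_s) <- dimnames(theta_c) <- list(ACTIONS, NULL)
  names(b) <- ACTIONS
  structure(list(grid = grid, theta_s = theta_s, theta_c = theta_c, b = b),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Actor over", x$grid$n_tau, "timescale(s); biases:",
      paste(sprintf("%s=%.3g", ACTIONS, x$b), collapse = ", "), "\n")
  invisible(x)
}

#' The six weighted sums and the decision-variable decompositions
#'
#' Computes, from one noisy read-out, the signal part
#' \eqn{\Sigma^s_a} and clock part \eqn{\Sigma^c_a} (the latter carrying the
#' bias) for each action, their totals \eqn{\Sigma_a}, and the decision
#' variables: \eqn{\Delta\Sigma_{right} = \Sigma_{right} - \Sigma_{wait}}
#' (the propensity to answer 'right'), its 'left' counterpart, the
#' signal-only part \eqn{\Delta\Sigma^s = \Sigma^s_{right} - \Sigma^s_{wait}}
#' and the time-only part \eqn{\Delta\Sigma^c = \Sigma^c_{wait} -
#' \Sigma^c_{right}}, so that \eqn{\Delta\Sigma_{right} = \Delta\Sigma^s -
#' \Delta\Sigma^c}. The 'right' clock sums are used in \eqn{\Delta\Sigma^c};
#' set `dsc_left = TRUE` to read the (numerically near-identical) 'left'
#' variant as a diagnostic.
#'
#' @param readout A list with `y_signal`, `y_clock` (from [observe()]).
#' @param params An [agent_params()] object.
#' @param dsc_left If `TRUE`, additionally return `ds_c_left`.
#' @return List with `sigma_s`, `sigma_c`, `sigma` (named length-3 vectors),
#'   `dsr`, `dsl`, `ds_s`, `ds_c`.
#' @export
action_sums <- function(readout, params, dsc_left = FALSE) {
  stopifnot(inherits(params, "agent_params"))
  ys <- readout$y_signal
  yc <- readout$y_clock
  if (length(ys) != params$grid$n_tau || length(yc) != params$grid$n_tau)
    stop("readout length does not match the agent's timescale grid")
  sigma_s <- c(left = sum(params$theta_s["left", ] * ys),
               wait = sum(params$theta_s["wait", ] * abs(ys)),
               right = sum(params$theta_s["right", ] * ys))
  sigma_c <- c(left = sum(params$theta_c["left", ] * yc) + params$b[["left"]],
               wait = sum(params$theta_c["wait", ] * yc) + params$b[["wait"]],
               right = sum(params$theta_c["right", ] * yc) + params$b[["right"]])
  sigma <- sigma_s + sigma_c
  out <- list(sigma_s = sigma_s, sigma_c = sigma_c, sigma = sigma,
              dsr = sigma[["right"]] - sigma[["wait"]],
              dsl = sigma[["left"]] - sigma[["wait"]],
              ds_s = sigma_s[["right"]] - sigma_s[["wait"]],
              ds_c = sigma_c[["wait"]] - sigma_c[["right"]])
  if (dsc_left)
    out$ds_c_left <- sigma_c[["wait"]] - sigma_c[["left"]]
  out
}

#' Softmax policy over {left, wait, right}
#'
#' @param sums Either the list returned by [action_sums()] or a length-3
#'   numeric vector of action sums.
#' @return Named probability triple summing to 1.
#' @export
softmax_policy <- function(sums) {
  s <- if (is.list(sums)) sums$sigma else sums
  stopifnot(length(s) == 3)
  if (any(!is.finite(s)))
    stop("non-finite action sums passed to softmax_policy: ",
         paste(signif(s, 4), collapse = ", "))
  e <- exp(s - max(s))
  p <- e / sum(e)
  names(p) <- ACTIONS
  p
}

#' Sample an action from a policy
#'
#' @param policy Probability triple over `{left, wait, right}`.
#' @return One of `"left"`, `"wait"`, `"right"`.
#' @export
act <- function(policy) {
  stopifnot(length(policy) == 3, all(policy >= 0),
            abs(sum(policy) - 1) < 1e-8)
  sample(ACTIONS, 1, prob = policy)
}

#' Restrict an agent to a single timescale
#'
#' Builds the nine-parameter comparison agent: one signal weight, one clock
#' weight per action, plus the three biases, all at timescale `tau`.
#'
#' @param params_template An [agent_params()] object whose biases are kept.
#' @param tau The single time constant (s).
#' @return An `agent_params` over a one-timescale grid.
#' @export
restrict_to_single_tau <- function(params_template, tau) {
  stopifnot(tau > 0)
  grid1 <- make_grid(1, tau, tau)
  agent_params(grid1, b = params_template$b)
}

#' Remove the internal clock from an agent
#'
#' Zeroes every clock weight (biases are retained), yielding the comparison
#' model with multiple signal timescales but no perception of elapsed time:
#' its \eqn{\Delta\Sigma^c} is the constant \eqn{b_{wait} - b_{right}}.
#'
#' @param params An [agent_params()] object.
#' @return The same agent with `theta_c` identically zero.
#' @export
strip_clock <- function(params) {
  params$theta_c[] <- 0
  params
}
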