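#' One activation update of a cognitive map
#'
#' The canonical fuzzy-cognitive-map inference step with logistic squashing.
#' For each unclamped factor i the next activation is
#' `plogis(steepness * (self_memory * (2 * a_i - 1) + sum_j sign_ji * (w_ji / 10) * a_j))`,
#' i.e. incoming influences are rescaled to \[0, 1\], signed, summed
#' together with an optional recentred memory of the node's own state, and
#' squashed back into (0, 1). Clamped factors are copied unchanged. A node
#' receiving no input settles at `plogis(0) = 0.5`, read as "no
#' information".
#'
#' @param state named numeric vector of activations in \[0, 1\], one per
#'   factor id of the model.
#' @param model an [fcm_model()].
#' @param clamp named numeric vector of factors held fixed at the given
#'   activation in \[0, 1\] (an intervention).
#' @param steepness positive steepness of the logistic squashing function
#'   (default 1). As steepness tends to 0 all unclamped activations tend
#'   to 0.5.
#' @param self_memory coefficient in \[0, 1\] on the node's own recentred
#'   activation `2 * a_i - 1` (default 0: no memory).
#' @param display_only use only display-threshold edges (default FALSE:
#'   dynamics run on the full retained edge set).
#' @return Named activation vector after one update.
#' @export
#' @examples
#' m <- fcm_model(data.frame(id = c("a", "b")),
#'                data.frame(source = "a", target = "b", weight = 10))
#' fcm_step(c(a = 1, b = 0.5), m, clamp = c(a = 1))  # b -> plogis(1)
fcm_step <- function(state, model, clamp = NULL, steepness = 1,
                     self_memory = 0, display_only = FALSE) {
  ids <- model$nodes$id
  state <- state[ids]
  if (anyNA(state)) stop("`state` must name every factor of the model")
  if (any(state < 0 | state > 1)) stop("activations must lie in [0, 1]")
  if (steepness <= 0) stop("`steepness` must be positive")
  if (self_memory < 0 || self_memory > 1) stop("`self_memory` must lie in [0, 1]")
  clamp <- check_clamp(clamp, ids)

  W <- coef(model, display_only = display_only) / 10   # signed, in [-1, 1]
  input <- as.numeric(state %*% W) + self_memory * (2 * state - 1)
  nxt <- plogis(steepness * input)
  names(nxt) <- ids
  nxt[names(clamp)] <- clamp
  nxt
}

check_clamp <- function(clamp, ids) {
  if (is.null(clamp) || length(clamp) == 0L) return(numeric())
  if (is.null(names(clamp)) || any(!nzchar(names(clamp)))) {
    stop("`clamp` must be a named vector of factor activations")
  }
  unknown <- setdiff(names(clamp), ids)
  if (length(unknown)) {
    stop("clamped factor(s) not in the model: ", paste(unknown, collapse = ", "))
  }
  if (any(clamp < 0 | clamp > 1)) stop("clamped activations must lie in [0, 1]")
  clamp
}

#' Run a what-if scenario to steady state
#'
#' Iterates [fcm_step()] from an initial state (default: 0.5 everywhere,
#' clamps applied) until the maximum absolute change falls below `tol`
#' (`converged`), a previously visited state recurs (`limit_cycle`,
#' detected on states rounded to 12 decimals), or `max_iter` updates have
#' been taken.
#'
#' @inheritParams fcm_step
#' @param init optional named initial activation vector; defaults to 0.5
#'   for unclamped factors.
#' @param max_iter maximum number of updates (default 200).
#' @param tol convergence tolerance on the max-norm change (default 1e-6).
#' @return An `fcm_trajectory`: list with `states` (matrix, one row per
#'   visited state including the initial one), `status`
#'   (`converged` / `limit_cycle` / `max_iter`) and `steady` (the final
#'   state).
#' @export
run_scenario <- function(model, clamp = NULL, steepness = 1,
                         self_memory = 0, init = NULL, max_iter = 200,
                         tol = 1e-6, display_only = FALSE) {
  stopifnot(inherits(model, "fcm"))
  if (tol <= 0) stop("`tol` must be positive")
  ids <- model$nodes$id
  clamp <- check_clamp(clamp, ids)
  state <- setNames(rep(0.5, length(ids)), ids)
  if (!is.null(init)) {
    init <- init[intersect(names(init), ids)]
    state[names(init)] <- init
  }
  state[names(clamp)] <- clamp

  states <- matrix(state, nrow = 1, dimnames = list(NULL, ids))
  seen <- new.env(parent = emptyenv())
  assign(state_key(state), 1L, envir = seen)
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    nxt <- fcm_step(state, model, clamp = clamp, steepness = steepness,
                    self_memory = self_memory, display_only = display_only)
    states <- rbind(states, nxt)
    if (max(abs(nxt - state)) < tol) {
      status <- "converged"
      state <- nxt
      break
    }
    k <- state_key(nxt)
    if (!is.null(seen[[k]])) {
      status <- "limit_cycle"
      state <- nxt
      break
    }
    assign(k, it + 1L, envir = seen)
    state <- nxt
  }
  rownames(states) <- NULL
  structure(list(states = states, status = status, steady = state,
                 clamp = clamp, steepness = steepness,
                 self_memory = self_memory),
            class = "fcm_trajectory")
}

state_key <- function(state) paste(sprintf("%.12f", state), collapse = ",")

#' @export
print.fcm_trajectory <- function(x, ...) {
  cat("Scenario trajectory: ", nrow(x$states) - 1L, " update(s), status ",
      x$status, "\n", sep = "")
  if (length(x$clamp)) {
    cat("Clamped:", paste(sprintf("%s=%g", names(x$clamp), x$clamp),
                          collapse = ", "), "\n")
  }
  cat("Final state:\n")
  print(round(x$steady, 4))
  invisible(x)
}

#' Steady-state activations under an intervention
#'
#' Convenience wrapper around [run_scenario()]: returns only the final
#' activation vector. Warns if the scenario did not converge.
#'
#' @param object an `fcm` model.
#' @param clamp named vector of clamped activations (the intervention).
#' @param ... passed to [run_scenario()].
#' @export
predict.fcm <- function(object, clamp = NULL, ...) {
  tr <- run_scenario(object, clamp = clamp, ...)
  if (tr$status != "converged") {
    warning("scenario did not converge (status: ", tr$status, ")")
  }
  tr$steady
}

#' Compare two scenarios on the same model
#'
#' Runs a baseline and an intervention scenario and reports the factor-wise
#' steady-state differences plus an impact-weighted composite,
#' `sum(impact_i * delta_i)` over factors with an impact score — a summary
#' of how much the intervention moves the factors that matter for the
#' modeled outcome.
#'
#' @param model an `fcm` model.
#' @param baseline,intervention lists of arguments to [run_scenario()]
#'   (e.g. `list(clamp = c(policy = 0.9))`).
#' @return Data frame with columns `factor`, `baseline`, `intervention`,
#'   `delta`; the composite is attached as attribute `composite` and shown
#'   by printing.
#' @export
compare_scenarios <- function(model, baseline = list(), intervention = list()) {
  runs <- list(baseline = baseline, intervention = intervention)
  steady <- lapply(names(runs), function(nm) {
    tr <- do.call(run_scenario, c(list(model), runs[[nm]]))
    if (tr$status != "converged") {
      stop("scenario `", nm, "` did not converge (status: ", tr$status, ")")
    }
    tr$steady
  })
  out <- data.frame(factor = model$nodes$id,
                    baseline = as.numeric(steady[[1]]),
                    intervention = as.numeric(steady[[2]]),
                    stringsAsFactors = FALSE)
  out$delta <- out$intervention - out$baseline
  imp <- model$nodes$impact
  attr(out, "composite") <- sum(imp * out$delta, na.rm = TRUE)
  class(out) <- c("fcm_scenario_comparison", "data.frame")
  out
}

#' @export
print.fcm_scenario_comparison <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$baseline <- round(y$baseline, digits)
  y$intervention <- round(y$intervention, digits)
  y$delta <- round(y$delta, digits)
  print(y, row.names = FALSE)
  cat(sprintf("Impact-weighted composite delta: %.*f\n", digits,
              attr(x, "composite")))
  invisible(x)
}
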