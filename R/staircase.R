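#' Configure a transformed up-down staircase
#'
#' An n-down-1-up (or n-up-1-down) adaptive rule: after `n_consecutive`
#' consecutive correct responses the level steps in the "harder" direction,
#' and after any incorrect response it steps the other way. Such a rule
#' converges at the level where the probability of `n_consecutive` correct
#' responses is 1/2, i.e. at percent-correct `0.5^(1/n)` (see
#' [convergence_probability()]).
#'
#' All staircases are additive on their working axis (dB for contrast,
#' log2 arc seconds for disparity, where a multiplicative factor of sqrt(2)
#' is an additive step of 0.5).
#'
#' @param n_consecutive Consecutive correct responses required to step
#'   toward "harder".
#' @param step Additive step size on the working axis (> 0).
#' @param initial_level Starting level.
#' @param correct_direction `-1` if correct responses move the level down
#'   (detection and stereo staircases, where lower = harder), `+1` if they
#'   move it up (the masking staircase, where a higher mask is harder).
#' @param max_reversals Terminate when this many reversals are recorded.
#' @param max_trials Terminate after this many trials.
#' @param min_level,max_level Physical clamps (e.g. contrast cannot exceed
#'   0 dB; disparity cannot fall below 1 arc sec = 0 log2 units). Clamped
#'   trials still count.
#' @return A `staircase_config` object.
#' @export
staircase_config <- function(n_consecutive, step, initial_level,
                             correct_direction = -1,
                             max_reversals = 9, max_trials = 120,
                             min_level = -Inf, max_level = Inf) {
  if (n_consecutive < 1 || step <= 0 || max_reversals < 1 || max_trials < 1) {
    rlang::abort("Invalid staircase configuration.")
  }
  if (!correct_direction %in% c(-1, 1)) {
    rlang::abort("`correct_direction` must be -1 or +1.")
  }
  structure(
    list(n_consecutive = as.integer(n_consecutive), step = step,
         initial_level = initial_level,
         correct_direction = correct_direction,
         max_reversals = as.integer(max_reversals),
         max_trials = as.integer(max_trials),
         min_level = min_level, max_level = max_level),
    class = "staircase_config"
  )
}

#' Initialise staircase state
#'
#' @param config A [staircase_config()].
#' @return A `staircase_state` object holding the current level, the
#'   consecutive-correct counter, the last step direction, the reversal
#'   count, and the trial history.
#' @export
staircase_new <- function(config) {
  structure(
    list(level = config$initial_level,
         n_correct = 0L,
         last_direction = 0,
         reversals = 0L,
         n_trials = 0L,
         levels = numeric(config$max_trials),
         outcomes = logical(config$max_trials),
         terminated = FALSE),
    class = "staircase_state"
  )
}

#' Advance a staircase by one trial
#'
#' Records the trial at the current level, applies the transformed up-down
#' rule, and updates termination. A reversal is recorded whenever the step
#' direction changes relative to the previous step; the consecutive-correct
#' counter resets on every level change and on every incorrect response.
#'
#' @param state A `staircase_state`.
#' @param config The matching [staircase_config()].
#' @param correct Logical: was the response correct?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, config, correct) {
  if (state$terminated) {
    rlang::abort("Cannot update a terminated staircase.")
  }
  i <- state$n_trials + 1L
  state$levels[i] <- state$level
  state$outcomes[i] <- correct
  state$n_trials <- i

  direction <- 0
  if (correct) {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct >= config$n_consecutive) {
      direction <- config$correct_direction # toward harder
      state$n_correct <- 0L
    }
  } else {
    direction <- -config$correct_direction # toward easier
    state$n_correct <- 0L
  }
  if (direction != 0) {
    if (state$last_direction != 0 && direction != state$last_direction) {
      state$reversals <- state$reversals + 1L
    }
    state$last_direction <- direction
    state$level <- min(max(state$level + direction * config$step,
                           config$min_level), config$max_level)
  }
  state$terminated <- state$reversals >= config$max_reversals ||
    state$n_trials >= config$max_trials
  state
}

#' Has a staircase terminated?
#'
#' True once the staircase has reached its reversal bound or trial cap,
#' whichever comes first.
#'
#' @inheritParams staircase_update
#' @return Logical flag.
#' @export
is_terminated <- function(state, config) {
  state$reversals >= config$max_reversals ||
    state$n_trials >= config$max_trials
}

#' Asymptotic percent correct targeted by an n-down-1-up rule
#'
#' The transformed up-down rule equilibrates where stepping down (after n
#' consecutive corrects) and stepping up are equally likely, i.e. where
#' `p^n = 1/2`. A 3-down-1-up rule therefore converges at 79% correct and a
#' 2-down-1-up rule at 71%.
#'
#' @param n_consecutive Number of consecutive correct responses required.
#' @return The targeted probability correct, `0.5^(1/n)`.
#' @export
#' @examples
#' convergence_probability(3) # 0.7937
#' convergence_probability(2) # 0.7071
convergence_probability <- function(n_consecutive) {
  if (any(n_consecutive < 1)) rlang::abort("`n_consecutive` must be >= 1.")
  0.5^(1 / n_consecutive)
}

staircase_trials <- function(state, staircase_id = "s1") {
  n <- state$n_trials
  # plain data.frame: this sits on the simulation hot path
  data.frame(
    staircase_id = rep(staircase_id, n),
    trial_index = seq_len(n),
    level = state$levels[seq_len(n)],
    outcome = as.integer(state$outcomes[seq_len(n)])
  )
}

#' Run a staircase against a response callback
#'
#' Repeatedly presents the current level to `respond` (a function mapping a
#' level to a logical outcome, e.g. a simulated observer) until the
#' staircase terminates. With a seeded random number generator the run is
#' exactly reproducible.
#'
#' @param config A [staircase_config()].
#' @param respond `function(level) -> logical`.
#' @param staircase_id Label attached to emitted trials.
#' @return An object of class `staircase_run`: list with `trials` (tibble:
#'   `staircase_id`, `trial_index`, `level`, `outcome`), the final `state`,
#'   and the `config`.
#' @export
run_staircase <- function(config, respond, staircase_id = "s1") {
  state <- staircase_new(config)
  while (!state$terminated) {
    state <- staircase_update(state, config, isTRUE(respond(state$level)))
  }
  structure(
    list(trials = tibble::as_tibble(staircase_trials(state, staircase_id)),
         state = state, config = config),
    class = "staircase_run"
  )
}

#' Run randomly interleaved staircases
#'
#' Each trial is drawn from a uniformly random non-terminated member of the
#' set (e.g. the pair of per-eye staircases), until all members have
#' terminated. The merged schedule preserves each member's internal trial
#' order.
#'
#' @param configs Named list of [staircase_config()] objects.
#' @param responders Named list (same names) of `function(level) -> logical`.
#' @return List with `trials` (data frame in presentation order, with
#'   `staircase_id` naming the member and `presentation` the merged order)
#'   and `states` (named list of final states).
#' @export
run_interleaved <- function(configs, responders) {
  ids <- names(configs)
  if (is.null(ids) || !identical(sort(ids), sort(names(responders)))) {
    rlang::abort("`configs` and `responders` must share the same names.")
  }
  states <- lapply(configs, staircase_new)
  sched_id <- character(0)
  active <- ids[!vapply(states, `[[`, logical(1), "terminated")]
  while (length(active) > 0) {
    pick <- if (length(active) == 1) active else sample(active, 1)
    st <- states[[pick]]
    st <- staircase_update(st, configs[[pick]],
                           isTRUE(responders[[pick]](st$level)))
    states[[pick]] <- st
    sched_id <- c(sched_id, pick)
    active <- ids[!vapply(states, `[[`, logical(1), "terminated")]
  }
  per <- lapply(ids, function(id) staircase_trials(states[[id]], id))
  trials <- do.call(rbind, per)
  # reorder into presentation order
  key <- paste(trials$staircase_id, trials$trial_index)
  seen <- stats::ave(seq_along(sched_id), sched_id, FUN = seq_along)
  order_key <- paste(sched_id, seen)
  trials <- trials[match(order_key, key), ]
  trials$presentation <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  list(trials = trials, states = states)
}

#' Mean of the last reversal levels
#'
#' A classical staircase summary: the mean level at the final `n_last`
#' reversals, used as a quick convergence check against the psychometric
#' fit.
#'
#' @param run A `staircase_run`.
#' @param n_last Number of final reversals to average.
#' @return Mean reversal level (NA if no reversals occurred).
#' @export
reversal_mean <- function(run, n_last = 6) {
  tr <- run$trials
  lv <- tr$level
  oc <- as.logical(tr$outcome)
  # reconstruct step directions to locate reversal trials
  cfg <- run$config
  dirs <- numeric(0)
  at <- integer(0)
  ncor <- 0L
  last <- 0
  for (i in seq_along(lv)) {
    d <- 0
    if (oc[i]) {
      ncor <- ncor + 1L
      if (ncor >= cfg$n_consecutive) {
        d <- cfg$correct_direction
        ncor <- 0L
      }
    } else {
      d <- -cfg$correct_direction
      ncor <- 0L
    }
    if (d != 0) {
      if (last != 0 && d != last) {
        dirs <- c(dirs, d)
        at <- c(at, i)
      }
      last <- d
    }
  }
  if (length(at) == 0) return(NA_real_)
  take <- utils::tail(at, n_last)
  mean(lv[take])
}
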