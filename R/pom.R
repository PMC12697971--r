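#' Sum-of-sines intensity model parameters
#'
#' The intensity trace whose per-cycle extrema supply the controller's
#' patience schedule:
#' \eqn{I(t) = I_0 + \sum_i A_i \sin(2\pi f_i t + \phi_i)}.
#' Defaults are three superposed waves with amplitudes (2.743, 1.372, 0.914),
#' frequencies (0.1, 0.2, 0.4) and zero phases; only the deviations
#' \eqn{|I - I_0|} matter downstream, so the mean level `i0` is an arbitrary
#' positive constant.
#'
#' @param i0 mean intensity (default 10).
#' @param amplitudes,frequencies,phases equal-length vectors; frequencies > 0.
#' @return An `"rlif_params"` list.
#' @export
rlif_params <- function(i0 = 10, amplitudes = c(2.743, 1.372, 0.914),
                        frequencies = c(0.1, 0.2, 0.4), phases = c(0, 0, 0)) {
  stopifnot(length(amplitudes) >= 1,
            length(amplitudes) == length(frequencies),
            length(amplitudes) == length(phases),
            all(frequencies > 0))
  structure(list(i0 = i0, amplitudes = amplitudes, frequencies = frequencies,
                 phases = phases), class = "rlif_params")
}

#' Evaluate the intensity model
#'
#' @param params an [rlif_params()].
#' @param t time (vectorized).
#' @return \eqn{I_0 + \sum_i A_i \sin(2\pi f_i t + \phi_i)}.
#' @export
rlif_intensity <- function(params, t) {
  vapply(t, function(tt)
    params$i0 + sum(params$amplitudes *
                      sin(2 * pi * params$frequencies * tt + params$phases)),
    numeric(1))
}

# Fundamental period of the superposition: 1 / gcd of the frequencies,
# computed on a rational approximation.
rlif_period <- function(params) {
  fr <- round(params$frequencies * 1e6)
  g <- Reduce(function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }, fr)
  1e6 / g
}

#' Patience schedule from the intensity extrema
#'
#' Locates the local extrema of the intensity over one fundamental period on a
#' dense grid, maps their absolute deviations \eqn{|I - I_0|} affinely onto
#' integer patience values in `[patience_min, patience_max]`, sorts ascending
#' and deduplicates. These thresholds are the stagnation budgets the
#' controller walks between: small thresholds end a wrapper episode quickly,
#' large ones let it search longer.
#'
#' @param params an [rlif_params()].
#' @param grid_points grid resolution (>= 1000).
#' @param patience_min,patience_max integer bounds of the mapping (defaults 3
#'   and 12).
#' @return An `"extrema_schedule"`: list with `thresholds` (ascending unique
#'   positive integers), `cursor` (index of the active threshold, starts at 1)
#'   and `extrema` (the raw deviations found).
#' @export
extrema_schedule <- function(params, grid_points = 4096, patience_min = 3,
                             patience_max = 12) {
  if (grid_points < 1000) stop("grid_points must be >= 1000", call. = FALSE)
  period <- rlif_period(params)
  tt <- seq(0, period, length.out = grid_points)
  I <- rlif_intensity(params, tt)
  dI <- diff(I)
  # local extrema: sign change of the discrete derivative
  s <- sign(dI)
  idx <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1L
  dev <- abs(I[idx] - params$i0)
  if (length(dev) == 0) dev <- max(abs(I - params$i0))
  rng <- range(dev)
  scaled <- if (rng[1] == rng[2]) rep((patience_min + patience_max) / 2, length(dev))
            else patience_min + (dev - rng[1]) / (rng[2] - rng[1]) *
                   (patience_max - patience_min)
  thresholds <- sort(unique(as.integer(round(scaled))))
  structure(list(thresholds = thresholds, cursor = 1L, extrema = dev),
            class = "extrema_schedule")
}

#' Average improvement rate of a fitness history
#'
#' \eqn{AIR = \frac{1}{N-1}\sum_{i=1}^{N-1} (f_{i+1} - f_i)/f_i}: the mean
#' relative fitness gain between consecutive wrapper iterations. Positive
#' while the search improves, drifting to zero (or below) at saturation.
#'
#' @param fitness_history numeric vector of per-iteration best fitness values,
#'   length >= 2, all strictly positive.
#' @return The average improvement rate.
#' @export
air <- function(fitness_history) {
  n <- length(fitness_history)
  if (n < 2) stop("need at least 2 fitness values", call. = FALSE)
  if (any(fitness_history == 0))
    stop("fitness values must be non-zero", call. = FALSE)
  f <- fitness_history
  mean((f[-1] - f[-n]) / f[-n])
}

#' Initialize controller state
#'
#' @param schedule an [extrema_schedule()].
#' @param ec_up consecutive AIR increases required to raise the active
#'   threshold (default 3).
#' @param ec_down consecutive non-positive AIR values required to lower it
#'   (default 2).
#' @return A `"pom_state"` list.
#' @export
pom_state <- function(schedule, ec_up = 3, ec_down = 2) {
  structure(list(fitness_history = numeric(0), air_history = numeric(0),
                 cad = 0L, schedule = schedule, restarts = 0L,
                 ec_up = as.integer(ec_up), ec_down = as.integer(ec_down),
                 up_streak = 0L, down_streak = 0L),
            class = "pom_state")
}

#' One controller step
#'
#' Appends the iteration's best fitness and recomputes the average improvement
#' rate over the history since the last restart. A drop in AIR relative to the
#' previous value increments the stagnation counter CAD. Extremum control then
#' adjusts the active patience threshold: `ec_up` consecutive AIR increases
#' advance the cursor to a larger threshold (the search is going better than
#' expected, let it run); `ec_down` consecutive non-positive AIR values move
#' it to a smaller one (end the episode sooner). When CAD exceeds the active
#' threshold the controller orders a restart — the filter is re-run and the
#' population re-initialized — and CAD resets to zero with a fresh history.
#'
#' @param state a [pom_state()].
#' @param new_best_fitness the iteration's best fitness value (> 0).
#' @return `list(state = <updated>, action = "continue"|"restart")`.
#' @export
pom_step <- function(state, new_best_fitness) {
  state$fitness_history <- c(state$fitness_history, new_best_fitness)
  if (length(state$fitness_history) >= 2) {
    cur_air <- air(state$fitness_history)
    prev_air <- if (length(state$air_history)) state$air_history[length(state$air_history)] else NA_real_
    state$air_history <- c(state$air_history, cur_air)
    dropped <- (!is.na(prev_air) && cur_air < prev_air) || cur_air <= 0
    if (dropped) {
      state$cad <- state$cad + 1L
      state$up_streak <- 0L
    } else if (!is.na(prev_air) && cur_air > prev_air) {
      state$up_streak <- state$up_streak + 1L
    }
    if (cur_air <= 0) state$down_streak <- state$down_streak + 1L
    else state$down_streak <- 0L
    nthr <- length(state$schedule$thresholds)
    if (state$up_streak >= state$ec_up) {
      state$schedule$cursor <- min(state$schedule$cursor + 1L, nthr)
      state$up_streak <- 0L
    }
    if (state$down_streak >= state$ec_down) {
      state$schedule$cursor <- max(state$schedule$cursor - 1L, 1L)
      state$down_streak <- 0L
    }
  }
  threshold <- state$schedule$thresholds[state$schedule$cursor]
  if (state$cad > threshold) {
    state$cad <- 0L
    state$restarts <- state$restarts + 1L
    state$fitness_history <- numeric(0)
    state$air_history <- numeric(0)
    state$up_streak <- 0L
    state$down_streak <- 0L
    return(list(state = state, action = "restart"))
  }
  list(state = state, action = "continue")
}
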