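#' Logistic chaos stream
#'
#' State of the logistic map \eqn{x_{n+1} = Seed \cdot x_n (1 - x_n)}, the
#' pseudo-random driver used for population initialization and dung-beetle
#' step factors. With `seed_param` in (3, 4) (default 3.9) the map is chaotic
#' and iterates never leave (0, 1) when started inside it.
#'
#' @param state current value in (0, 1) (the degenerate fixed points 0 and 1
#'   are rejected).
#' @param seed_param the chaotic seed parameter, in (3, 4).
#' @return A `"chaos_stream"` list.
#' @export
chaos_stream <- function(state, seed_param = 3.9) {
  if (!is.numeric(state) || state <= 0 || state >= 1)
    stop("chaos state must lie strictly in (0, 1)", call. = FALSE)
  if (seed_param <= 3 || seed_param >= 4)
    stop("seed_param must lie in (3, 4)", call. = FALSE)
  structure(list(state = state, seed_param = seed_param), class = "chaos_stream")
}

#' Advance a logistic chaos stream
#'
#' Returns the next `count` iterates of the map, advancing the stream.
#'
#' @param stream a [chaos_stream()].
#' @param count number of iterates.
#' @return `list(values = <numeric(count)>, stream = <advanced stream>)`.
#' @export
logistic_sequence <- function(stream, count) {
  stopifnot(inherits(stream, "chaos_stream"), count >= 1)
  v <- numeric(count)
  x <- stream$state; s <- stream$seed_param
  for (i in seq_len(count)) {
    x <- s * x * (1 - x)
    v[i] <- x
  }
  list(values = v, stream = chaos_stream(x, s))
}

# Fan a master RNG stream out into n independent chaos streams.
spawn_chaos_streams <- function(n, seed_param = 3.9) {
  lapply(stats::runif(n, 0.05, 0.95), chaos_stream, seed_param = seed_param)
}

#' Search-space box
#'
#' @param dim number of dimensions (candidate features).
#' @param lower,upper box bounds, `lower < upper` (equal bounds are allowed as
#'   the degenerate point box).
#' @return A `"search_space"` list.
#' @export
search_space <- function(dim, lower = -1, upper = 1) {
  stopifnot(dim >= 1, lower <= upper)
  structure(list(dim = as.integer(dim), lower = lower, upper = upper),
            class = "search_space")
}

#' Chaotic population initialization
#'
#' Maps each agent's own logistic sequence affinely into the search box:
#' \eqn{P_{ij} = l + (u - l)\,\delta_{ij}}. Independent per-agent streams keep
#' the initial population diverse.
#'
#' @param space a [search_space()].
#' @param n_agents number of agents.
#' @param streams list of `n_agents` [chaos_stream()] objects.
#' @return `list(positions = <n_agents x dim matrix>, streams = <advanced>)`.
#' @export
chaotic_init <- function(space, n_agents, streams) {
  stopifnot(length(streams) == n_agents)
  P <- matrix(0, n_agents, space$dim)
  for (i in seq_len(n_agents)) {
    sq <- logistic_sequence(streams[[i]], space$dim)
    P[i, ] <- space$lower + (space$upper - space$lower) * sq$values
    streams[[i]] <- sq$stream
  }
  list(positions = P, streams = streams)
}

#' Median-threshold binarization of a continuous position
#'
#' The median of the position's own components (mean of the middle two for
#' even length) is the selection threshold: component `j` maps to 1 iff it
#' exceeds the median. Because roughly half the components exceed their own
#' median, the mask is never empty and never full on tie-free input. Ties at
#' the maximum (so that nothing strictly exceeds the median) fall back to
#' selecting the maximal components; a constant vector selects the
#' `ceiling(J/2)` lowest-index features.
#'
#' @param position numeric vector, length >= 2.
#' @return Logical mask of the same length with at least one `TRUE`.
#' @export
binarize_median <- function(position) {
  J <- length(position)
  if (J < 2) stop("position must have length >= 2", call. = FALSE)
  if (max(position) == min(position)) {
    mask <- logical(J)
    mask[seq_len(ceiling(J / 2))] <- TRUE
    return(mask)
  }
  mu <- stats::median(position)
  mask <- position > mu
  if (!any(mask)) mask <- position == max(position)
  mask
}

#' Grey-wolf coefficient vectors
#'
#' The convergence factor \eqn{a = 2(1 - t/T)} decays linearly from 2 to 0;
#' each leader's coefficient vectors are \eqn{A = 2 a r_1 - a} (components in
#' \eqn{[-a, a]}) and \eqn{C = 2 r_2} (components in \eqn{[0, 2]}), with fresh
#' uniform draws per dimension.
#'
#' @param t,T current and maximum iteration.
#' @param dim dimensionality.
#' @return List with `a` and, per leader, `A1..A3`, `C1..C3`.
#' @export
gwo_coefficients <- function(t, T, dim) {
  a <- 2 * (1 - t / T)
  mk_A <- function() 2 * a * stats::runif(dim) - a
  mk_C <- function() 2 * stats::runif(dim)
  list(a = a, A1 = mk_A(), A2 = mk_A(), A3 = mk_A(),
       C1 = mk_C(), C2 = mk_C(), C3 = mk_C())
}

# Leader-guided candidate for one wolf: X_k = X_lead - A * |C * X_lead - X|
gwo_candidate <- function(x_lead, x, A, C) x_lead - A * abs(C * x_lead - x)

#' One grey-wolf position update over the pack
#'
#' Every non-leader wolf moves to the mean of the three leader-guided
#' candidates (distances taken to the alpha, beta and delta positions with
#' fresh `A`/`C` coefficient vectors per wolf), clipped to the search box;
#' masks and fitness are then recomputed and the leaders re-ranked.
#'
#' @param pack a wolf pack as produced by [init_pack()].
#' @param t,T current and maximum iteration (drive the convergence factor).
#' @param fit_fun memoised fitness function over global feature indices.
#' @param candidates integer vector mapping box dimensions to feature columns.
#' @return The updated pack.
#' @export
gwo_step <- function(pack, t, T, fit_fun, candidates) {
  sp <- pack$space
  lead <- pack$leaders
  Xa <- pack$positions[lead[1L], ]
  Xb <- pack$positions[lead[2L], ]
  Xd <- pack$positions[lead[3L], ]
  for (i in setdiff(seq_len(nrow(pack$positions)), lead)) {
    co <- gwo_coefficients(t, T, sp$dim)
    x <- pack$positions[i, ]
    x1 <- gwo_candidate(Xa, x, co$A1, co$C1)
    x2 <- gwo_candidate(Xb, x, co$A2, co$C2)
    x3 <- gwo_candidate(Xd, x, co$A3, co$C3)
    newx <- pmin(pmax((x1 + x2 + x3) / 3, sp$lower), sp$upper)
    pack$positions[i, ] <- newx
    pack$masks[i, ] <- binarize_median(newx)
    pack$fitness[[i]] <- fit_fun(candidates[pack$masks[i, ]])
  }
  rank_leaders(pack)
}

rank_leaders <- function(pack) {
  n <- length(pack$fitness)
  ord <- seq_len(n)
  # insertion-style sort indices by compare_fitness (n is small)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (compare_fitness(pack$fitness[[ord[j]]], pack$fitness[[ord[i]]]) > 0L) {
      tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
    }
  }
  pack$leaders <- ord[seq_len(min(3L, n))]
  pack
}

#' Initialize and evaluate a wolf pack
#'
#' Chaotic initialization over the box, median binarization of every row, and
#' fitness evaluation; leaders (alpha, beta, delta) are the three best masks
#' under [compare_fitness()].
#'
#' @param space a [search_space()].
#' @param n_wolves population size.
#' @param streams per-agent [chaos_stream()] list.
#' @param fit_fun memoised fitness function.
#' @param candidates feature columns corresponding to the box dimensions.
#' @return `list(pack = , streams = )`; the pack holds `positions`, `masks`,
#'   `fitness`, `leaders`, `space`.
#' @export
init_pack <- function(space, n_wolves, streams, fit_fun, candidates) {
  ci <- chaotic_init(space, n_wolves, streams)
  masks <- t(apply(ci$positions, 1L, binarize_median))
  if (space$dim == 1L) masks <- matrix(masks, ncol = 1L)
  fitness <- lapply(seq_len(n_wolves), function(i) fit_fun(candidates[masks[i, ]]))
  pack <- structure(list(positions = ci$positions, masks = masks,
                         fitness = fitness, leaders = integer(0), space = space),
                    class = "wolf_pack")
  list(pack = rank_leaders(pack), streams = ci$streams)
}

#' Chaotic forager position update
#'
#' One componentwise dung-beetle move towards the best-so-far position:
#' \eqn{x' = x + \delta\,\mathrm{sign}(x_{best} - x)\,\log(1 + |x_{best} - x|)}
#' with the natural logarithm; `sign(0) = 0` and `delta = 0` both leave the
#' position unchanged.
#'
#' @param x current position (vector).
#' @param x_best best-so-far position.
#' @param delta chaotic step factor (scalar).
#' @return The updated position.
#' @export
cdba_update <- function(x, x_best, delta) {
  d <- x_best - x
  x + delta * sign(d) * log(1 + abs(d))
}

#' Chaotic dung-beetle refinement around a leader
#'
#' A small beetle swarm starts at the leader position, each component nudged
#' by one chaotic draw, and for `n_steps` applies the chaotic forager update
#' [cdba_update()], where \eqn{\delta} is the beetle's own chaotic
#' step factor and \eqn{x_{best}} the best-so-far position (initialized to the
#' leader). The logarithmic step shrinks with distance to the best, giving a
#' precise local approach; `sign(0) = 0`, so a beetle exactly at the best does
#' not move. Returns the best position/fitness found — the input leader if
#' nothing improves.
#'
#' @param leader_position numeric position vector.
#' @param leader_fitness its `"fitness_result"`.
#' @param swarm_size number of beetles (0 disables refinement).
#' @param n_steps update steps per beetle.
#' @param streams list of `swarm_size` [chaos_stream()] objects.
#' @param fit_fun memoised fitness function.
#' @param candidates feature columns corresponding to the dimensions.
#' @param space a [search_space()] for clipping.
#' @return `list(position = , fitness = , streams = )`.
#' @export
cdba_refine <- function(leader_position, leader_fitness, swarm_size, n_steps,
                        streams, fit_fun, candidates, space) {
  best_x <- leader_position
  best_f <- leader_fitness
  if (swarm_size < 1)
    return(list(position = best_x, fitness = best_f, streams = streams))
  J <- length(leader_position)
  pos <- matrix(0, swarm_size, J)
  for (b in seq_len(swarm_size)) {
    sq <- logistic_sequence(streams[[b]], J)
    streams[[b]] <- sq$stream
    # initial scatter: one chaotic draw per component, +/- a tenth of the box
    pos[b, ] <- pmin(pmax(leader_position +
      (sq$values - 0.5) * (space$upper - space$lower) / 5, space$lower), space$upper)
  }
  for (step in seq_len(n_steps)) {
    for (b in seq_len(swarm_size)) {
      sq <- logistic_sequence(streams[[b]], 1L)
      streams[[b]] <- sq$stream
      delta <- sq$values[1L]
      newx <- cdba_update(pos[b, ], best_x, delta)
      newx <- pmin(pmax(newx, space$lower), space$upper)
      pos[b, ] <- newx
      f <- fit_fun(candidates[binarize_median(newx)])
      if (fitness_better(f, best_f)) {
        best_f <- f
        best_x <- newx
      }
    }
  }
  list(position = best_x, fitness = best_f, streams = streams)
}

#' One iteration of the hybrid grey-wolf / chaotic dung-beetle wrapper
#'
#' Runs [cdba_refine()] once around each of the alpha, beta and delta wolves,
#' pools the refined results with the current leaders, re-sorts by
#' [compare_fitness()] to reassign the leaders (elitist: the best fitness
#' never degrades), then applies [gwo_step()] to the rest of the pack. With
#' `beetle_swarm = 0` this reduces to a pure binary grey-wolf iteration.
#'
#' @param pack a wolf pack.
#' @param t,T current and maximum (global) iteration.
#' @param fit_fun memoised fitness function.
#' @param candidates feature columns for the box dimensions.
#' @param beetle_swarm,beetle_steps dung-beetle sub-swarm size and steps.
#' @param beetle_streams list of `beetle_swarm` [chaos_stream()] objects
#'   (shared across the three leader refinements, advancing through them).
#' @return `list(pack = , beetle_streams = )`.
#' @export
hgw_cdbw_iterate <- function(pack, t, T, fit_fun, candidates,
                             beetle_swarm = 10, beetle_steps = 5,
                             beetle_streams = list()) {
  for (li in pack$leaders) {
    ref <- cdba_refine(pack$positions[li, ], pack$fitness[[li]],
                       beetle_swarm, beetle_steps, beetle_streams,
                       fit_fun, candidates, pack$space)
    beetle_streams <- ref$streams
    if (fitness_better(ref$fitness, pack$fitness[[li]])) {
      pack$positions[li, ] <- ref$position
      pack$masks[li, ] <- binarize_median(ref$position)
      pack$fitness[[li]] <- ref$fitness
    }
  }
  pack <- rank_leaders(pack)
  pack <- gwo_step(pack, t, T, fit_fun, candidates)
  list(pack = pack, beetle_streams = beetle_streams)
}
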