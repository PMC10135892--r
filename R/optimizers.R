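#' Optimizer configuration
#'
#' Shared settings for the eight population-based binary feature-subset
#' searches. All algorithms run 50 iterations with a population of 10 by
#' default; algorithm-specific parameters default to the standard values
#' of the original publications and can be overridden through `params`.
#'
#' Algorithm-specific defaults:
#' * `MPA` (marine predators): `fads_effect = 0.2`, `constant_P = 0.5`,
#'   `levy_exponent = 1.5`
#' * `ASOA` (atom search): `depth_weight = 50`, `multiplier_weight = 0.2`
#' * `HHOA` (Harris hawks): `levy_exponent = 1.5`
#' * `BOA` (butterfly): `modular_modality = 0.01`,
#'   `switch_probability = 0.8`, `power_exponent = 0.1`
#' * `WOA` (whale): `spiral_constant = 1`
#' * `GWOA` (grey wolf): no extra parameters
#' * `BA` (bat): `f_max = 2`, `f_min = 0`, `rate_constant = 0.9`
#'   (loudness decay and pulse-rate growth), `loudness_max = 2`,
#'   `pulse_rate_max = 1`
#' * `FA` (firefly): `absorption = 1`, `attractiveness_base = 1`,
#'   `light_amplitude = 1`, `alpha_control = 0.97`, `alpha0 = 1`
#'
#' @param algorithm one of `"MPA"`, `"ASOA"`, `"HHOA"`, `"BOA"`, `"WOA"`,
#'   `"GWOA"`, `"BA"`, `"FA"`.
#' @param iterations number of iterations (default 50).
#' @param pop_size population size (default 10).
#' @param seed integer seed; every stochastic draw of a run flows from it,
#'   so runs are bit-reproducible.
#' @param params named list of overrides for the algorithm-specific
#'   parameters listed above.
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm, iterations = 50L, pop_size = 10L,
                             seed = 1L, params = list()) {
  algorithm <- match.arg(algorithm, wbm_algorithms())
  defaults <- switch(algorithm,
    MPA  = list(fads_effect = 0.2, constant_P = 0.5, levy_exponent = 1.5),
    ASOA = list(depth_weight = 50, multiplier_weight = 0.2),
    HHOA = list(levy_exponent = 1.5),
    BOA  = list(modular_modality = 0.01, switch_probability = 0.8,
                power_exponent = 0.1),
    WOA  = list(spiral_constant = 1),
    GWOA = list(),
    BA   = list(f_max = 2, f_min = 0, rate_constant = 0.9,
                loudness_max = 2, pulse_rate_max = 1),
    FA   = list(absorption = 1, attractiveness_base = 1, light_amplitude = 1,
                alpha_control = 0.97, alpha0 = 1))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for ", algorithm, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(params)] <- params
  if (any(unlist(defaults) < 0))
    stop("algorithm parameters must be >= 0", call. = FALSE)
  structure(list(algorithm = algorithm, iterations = as.integer(iterations),
                 pop_size = as.integer(pop_size), seed = as.integer(seed),
                 params = defaults),
            class = "optimizer_config")
}

#' Names of the available metaheuristics
#' @return Character vector of the eight algorithm identifiers.
#' @export
wbm_algorithms <- function() {
  c("MPA", "ASOA", "HHOA", "BOA", "WOA", "GWOA", "BA", "FA")
}

#' Threshold binarization of a continuous agent position
#'
#' Agents live in the continuous unit cube; a feature is included iff the
#' S-shaped transfer of its coordinate exceeds one half, which for the
#' standard sigmoid transfer reduces to a strict `position > 0.5`
#' threshold. Deterministic and independent of dimensionality.
#'
#' @param position numeric vector with finite components.
#' @return A [subset_mask()]-shaped object (possibly all-zero).
#' @export
binarize_position <- function(position) {
  stopifnot(all(is.finite(position)))
  subset_mask_fast(as.integer(position > 0.5))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Mantegna Levy-flight steps with stability exponent beta
levy_steps <- function(n, beta = 1.5) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(n, sd = sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

#' Atom masses from a vector of costs
#'
#' In the atom-search update each agent's inertia is derived from its cost
#' by exponential ranking, normalized so the masses form a proper
#' distribution (they sum to one each iteration); better atoms are
#' heavier.
#'
#' @param fit numeric vector of costs (lower is better).
#' @return Numeric vector of masses summing to 1.
#' @export
aso_masses <- function(fit) {
  best <- min(fit); worst <- max(fit)
  m <- exp(-(fit - best) / (worst - best + 1e-12))
  m / sum(m)
}

# --- run state -------------------------------------------------------------
# state: pos (pop x D), vel (pop x D), fit (numeric cost per agent),
# nsel (features per agent), gbest_pos/gbest_I (continuous guidance best),
# plus per-algorithm slots (leaders, loudness, pulse, fa_alpha)

new_state <- function(pos, cfg) {
  list(pos = pos, vel = matrix(0, nrow(pos), ncol(pos)),
       fit = rep(Inf, nrow(pos)), nsel = rep(ncol(pos), nrow(pos)),
       gbest_pos = pos[1, ], gbest_I = Inf, gbest_nsel = ncol(pos),
       pop = nrow(pos), D = ncol(pos))
}

# evaluate agent rows of state$pos through the evaluator, updating the
# per-agent costs and the continuous guidance best
state_eval <- function(state, ev, rows = seq_len(state$pop)) {
  for (i in rows) {
    fv <- ev(binarize_position(state$pos[i, ]))
    state$fit[i] <- fv$I
    state$nsel[i] <- fv$n_selected
    if (fv$I < state$gbest_I ||
        (fv$I == state$gbest_I && fv$n_selected < state$gbest_nsel)) {
      state$gbest_I <- fv$I
      state$gbest_nsel <- fv$n_selected
      state$gbest_pos <- state$pos[i, ]
    }
  }
  state
}

#' Initialize and evaluate a population
#'
#' Positions are drawn uniformly on the unit cube from the seeded
#' generator active in the calling context; every agent is evaluated once
#' and the global best recorded.
#'
#' @param D dimensionality (number of candidate features), >= 1.
#' @param cfg an [optimizer_config()].
#' @param evaluator function mask -> `fitness_value` (see
#'   [cached_evaluator()]).
#' @return Population state (list) used by [run_optimizer()].
#' @export
init_population <- function(D, cfg, evaluator) {
  if (D < 1L) stop("D must be >= 1", call. = FALSE)
  pos <- matrix(stats::runif(cfg$pop_size * D), cfg$pop_size, D)
  state_eval(new_state(pos, cfg), evaluator)
}

#' Run one binary metaheuristic feature search
#'
#' Seeds the generator from `cfg$seed`, initializes the population, then
#' executes `cfg$iterations` steps of the configured algorithm. Every
#' candidate position is thresholded with [binarize_position()] before
#' evaluation. The returned solution is the best mask ever evaluated
#' anywhere in the run (elitist bookkeeping independent of the algorithm's
#' own memory); ties are broken toward fewer selected features, then
#' toward the earlier-evaluated mask.
#'
#' @param cfg an [optimizer_config()].
#' @param evaluator function mask -> `fitness_value`; must be total
#'   (all-zero masks must return a worst-case cost, as
#'   [cached_evaluator()] does).
#' @param D number of candidate features.
#' @return List with `best_mask` ([subset_mask()]), `best_fitness`
#'   (`fitness_value`), and `history` (list with non-increasing
#'   `best_fitness_per_iteration`, `evaluations_used`, `best_mask`).
#' @export
run_optimizer <- function(cfg, evaluator, D) {
  stopifnot(inherits(cfg, "optimizer_config"))
  step_fn <- switch(cfg$algorithm,
    MPA = mpa_step, ASOA = asoa_step, HHOA = hhoa_step, BOA = boa_step,
    WOA = woa_step, GWOA = gwoa_step, BA = ba_step, FA = fa_step,
    stop("unknown algorithm: ", cfg$algorithm, call. = FALSE))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  # elitist tracker over every evaluated mask, independent of step internals
  tracker <- new.env(parent = emptyenv())
  tracker$best <- NULL
  tracker$bits <- NULL
  tracker$n <- 0L
  ev <- function(mask) {
    fv <- evaluator(mask)
    tracker$n <- tracker$n + 1L
    if (fitness_better(fv, tracker$best)) {
      tracker$best <- fv
      tracker$bits <- if (inherits(mask, "subset_mask")) mask$bits else as.integer(mask)
    }
    fv
  }

  state <- init_population(D, cfg, ev)
  history <- numeric(cfg$iterations)
  for (t in seq_len(cfg$iterations)) {
    state <- step_fn(state, cfg, ev, t, cfg$iterations)
    history[t] <- tracker$best$I
  }
  list(best_mask = subset_mask_fast(tracker$bits),
       best_fitness = tracker$best,
       history = list(best_fitness_per_iteration = history,
                      evaluations_used = tracker$n,
                      best_mask = subset_mask_fast(tracker$bits)))
}

# --- marine predators ------------------------------------------------------
# Three phases split at thirds of the run: Brownian exploration, mixed
# Brownian/Levy, Levy exploitation; per-agent memory keeps the better of the
# old and moved position; a fish-aggregating-devices perturbation follows,
# also evaluated and memory-filtered (so this step costs 2*pop evaluations).

#' One iteration of an optimizer's update rule
#'
#' The eight `*_step()` functions each advance a population state by one
#' iteration of the corresponding canonical update (marine predators, atom
#' search, Harris hawks, butterfly, whale, grey wolf, bat, firefly),
#' parameterized by [optimizer_config()]. They are exposed for testing and
#' instrumentation; normal use goes through [run_optimizer()]. Positions
#' are clamped to the unit cube after every move.
#'
#' @param state population state from [init_population()].
#' @param cfg an [optimizer_config()] for the matching algorithm.
#' @param ev evaluator function mask -> `fitness_value`.
#' @param t current iteration (1-based).
#' @param Tmax total number of iterations.
#' @return The updated population state.
#' @name optimizer_steps
NULL

#' @rdname optimizer_steps
#' @export
mpa_step <- function(state, cfg, ev, t, Tmax) {
  p <- cfg$params; pop <- state$pop; D <- state$D
  P <- p$constant_P
  CF <- (1 - t / Tmax)^(2 * t / Tmax)
  elite <- state$gbest_pos
  old_pos <- state$pos; old_fit <- state$fit; old_nsel <- state$nsel
  for (i in seq_len(pop)) {
    x <- state$pos[i, ]
    if (t <= Tmax / 3) {                       # Brownian exploration
      RB <- stats::rnorm(D)
      x <- x + P * stats::runif(D) * (RB * (elite - RB * x))
    } else if (t <= 2 * Tmax / 3) {            # mixed phase
      if (i <= pop / 2) {
        RL <- levy_steps(D, p$levy_exponent)
        x <- x + P * stats::runif(D) * (RL * (elite - RL * x))
      } else {
        RB <- stats::rnorm(D)
        x <- elite + P * CF * (RB * (RB * elite - x))
      }
    } else {                                   # Levy exploitation
      RL <- levy_steps(D, p$levy_exponent)
      x <- elite + P * CF * (RL * (RL * elite - x))
    }
    state$pos[i, ] <- clamp01(x)
  }
  state <- state_eval(state, ev)
  state <- mpa_memory(state, old_pos, old_fit, old_nsel)

  # fish-aggregating-devices effect
  old_pos <- state$pos; old_fit <- state$fit; old_nsel <- state$nsel
  FADs <- p$fads_effect
  r <- stats::runif(1)
  if (r < FADs) {
    U <- matrix(stats::runif(pop * D) < FADs, pop, D)
    state$pos <- clamp01(state$pos +
      CF * matrix(stats::runif(pop * D), pop, D) * U)
  } else {
    r1 <- sample.int(pop, pop, replace = TRUE)
    r2 <- sample.int(pop, pop, replace = TRUE)
    state$pos <- clamp01(state$pos +
      (FADs * (1 - r) + r) * (state$pos[r1, , drop = FALSE] -
                              state$pos[r2, , drop = FALSE]))
  }
  state <- state_eval(state, ev)
  mpa_memory(state, old_pos, old_fit, old_nsel)
}

# per-agent elitist memory: revert agents that got worse
mpa_memory <- function(state, old_pos, old_fit, old_nsel) {
  worse <- state$fit > old_fit |
    (state$fit == old_fit & state$nsel > old_nsel)
  if (any(worse)) {
    state$pos[worse, ] <- old_pos[worse, , drop = FALSE]
    state$fit[worse] <- old_fit[worse]
    state$nsel[worse] <- old_nsel[worse]
  }
  state
}

# --- atom search -----------------------------------------------------------
# Lennard-Jones-style interaction among the K best atoms plus a constraint
# force toward the best; exponentially ranked masses; velocity update.

#' @rdname optimizer_steps
#' @export
asoa_step <- function(state, cfg, ev, t, Tmax) {
  p <- cfg$params; pop <- state$pop; D <- state$D
  M <- aso_masses(state$fit)
  K <- max(2L, min(pop, ceiling(pop - (pop - 2) * sqrt(t / Tmax))))
  kbest <- order(state$fit)[seq_len(min(K, pop))]
  eta <- p$depth_weight * (1 - (t - 1) / Tmax)^3 * exp(-5 * t / Tmax)
  lambda <- p$multiplier_weight * exp(-20 * t / Tmax)
  g <- 0.1 * sin(pi / 2 * t / Tmax)
  h_min <- 1.1 + g; h_max <- 1.24
  kmean <- colMeans(state$pos[kbest, , drop = FALSE])
  new_pos <- state$pos; new_vel <- state$vel
  for (i in seq_len(pop)) {
    x <- state$pos[i, ]
    sigma <- sqrt(sum((x - kmean)^2)) + 1e-12
    Fi <- numeric(D)
    for (j in kbest) {
      if (j == i) next
      d <- state$pos[j, ] - x
      r <- sqrt(sum(d^2))
      h <- min(max(r / sigma, h_min), h_max)
      # LJ-style force: repulsion below the equilibrium distance,
      # attraction above it
      Fi <- Fi + stats::runif(1) * eta * (h^(-7) - 2 * h^(-13)) * d / (r + 1e-12)
    }
    Gi <- lambda * (state$gbest_pos - x)
    a <- (Fi + Gi) / M[i]
    v <- stats::runif(D) * state$vel[i, ] + a
    v <- pmin(pmax(v, -0.5), 0.5)  # keep atom moves on the cube's scale
    new_vel[i, ] <- v
    new_pos[i, ] <- clamp01(x + v)
  }
  state$pos <- new_pos; state$vel <- new_vel
  state_eval(state, ev)
}

# --- Harris hawks ----------------------------------------------------------
# Escape energy decays over the run; exploration when |E| >= 1, otherwise
# one of four besiege variants, the rapid-dive ones using Levy flights and
# greedy acceptance (up to 2*pop extra evaluations per iteration).

#' @rdname optimizer_steps
#' @export
hhoa_step <- function(state, cfg, ev, t, Tmax) {
  p <- cfg$params; pop <- state$pop; D <- state$D
  xmean <- colMeans(state$pos)
  best <- state$gbest_pos
  for (i in seq_len(pop)) {
    x <- state$pos[i, ]
    E0 <- 2 * stats::runif(1) - 1
    E <- 2 * E0 * (1 - t / Tmax)
    J <- 2 * (1 - stats::runif(1))
    if (abs(E) >= 1) {                         # exploration
      if (stats::runif(1) >= 0.5) {
        xr <- state$pos[sample.int(pop, 1), ]
        xnew <- xr - stats::runif(1) * abs(xr - 2 * stats::runif(1) * x)
      } else {
        xnew <- (best - xmean) - stats::runif(1) * stats::runif(D)
      }
      state$pos[i, ] <- clamp01(xnew)
      state <- state_eval(state, ev, i)
    } else {
      r <- stats::runif(1)
      if (r >= 0.5 && abs(E) >= 0.5) {         # soft besiege
        xnew <- (best - x) - E * abs(J * best - x)
        state$pos[i, ] <- clamp01(xnew)
        state <- state_eval(state, ev, i)
      } else if (r >= 0.5) {                   # hard besiege (E=0 -> best)
        xnew <- best - E * abs(best - x)
        state$pos[i, ] <- clamp01(xnew)
        state <- state_eval(state, ev, i)
      } else {                                 # rapid dives
        base <- if (abs(E) >= 0.5) x else xmean
        Y <- clamp01(best - E * abs(J * best - base))
        fY <- ev(binarize_position(Y))
        if (fY$I < state$fit[i]) {
          state$pos[i, ] <- Y
          state$fit[i] <- fY$I; state$nsel[i] <- fY$n_selected
        } else {
          Z <- clamp01(Y + stats::runif(D) * levy_steps(D, p$levy_exponent))
          fZ <- ev(binarize_position(Z))
          if (fZ$I < state$fit[i]) {
            state$pos[i, ] <- Z
            state$fit[i] <- fZ$I; state$nsel[i] <- fZ$n_selected
          }
        }
        if (state$fit[i] < state$gbest_I) {
          state$gbest_I <- state$fit[i]; state$gbest_nsel <- state$nsel[i]
          state$gbest_pos <- state$pos[i, ]
        }
      }
    }
    best <- state$gbest_pos
  }
  state
}

# --- butterfly -------------------------------------------------------------
# Fragrance c * |cost|^a drives either a global move toward the best (with
# the switch probability) or a local move between two random butterflies.

#' @rdname optimizer_steps
#' @export
boa_step <- function(state, cfg, ev, t, Tmax) {
  p <- cfg$params; pop <- state$pop
  # sensory modality starts at the configured value and grows each
  # iteration as in the original formulation
  if (is.null(state$boa_c)) state$boa_c <- p$modular_modality
  state$boa_c <- state$boa_c + 0.5 / (state$boa_c * Tmax)
  fragrance <- state$boa_c * abs(state$fit)^p$power_exponent
  for (i in seq_len(pop)) {
    x <- state$pos[i, ]
    r <- stats::runif(state$D)
    if (stats::runif(1) < p$switch_probability) {
      xnew <- x + (r^2 * state$gbest_pos - x) * fragrance[i]
    } else {
      jk <- sample.int(pop, 2, replace = TRUE)
      xnew <- x + (r^2 * state$pos[jk[1], ] - state$pos[jk[2], ]) * fragrance[i]
    }
    state$pos[i, ] <- clamp01(xnew)
  }
  state_eval(state, ev)
}

# --- whale -----------------------------------------------------------------
# Coefficient a decays 2 -> 0; encircling the best (|A| < 1), exploring
# toward a random whale (|A| >= 1), or a logarithmic spiral, branch chosen
# with probability one half.

#' @rdname optimizer_steps
#' @export
woa_step <- function(state, cfg, ev, t, Tmax) {
  p <- cfg$params; pop <- state$pop; D <- state$D
  a <- 2 - 2 * t / Tmax
  for (i in seq_len(pop)) {
    x <- state$pos[i, ]
    A <- 2 * a * stats::runif(D) - a
    C <- 2 * stats::runif(D)
    if (stats::runif(1) < 0.5) {
      if (max(abs(A)) < 1) {
        Dv <- abs(C * state$gbest_pos - x)
        xnew <- state$gbest_pos - A * Dv
      } else {
        xr <- state$pos[sample.int(pop, 1), ]
        Dv <- abs(C * xr - x)
        xnew <- xr - A * Dv
      }
    } else {
      l <- stats::runif(1, -1, 1)
      Dp <- abs(state$gbest_pos - x)
      xnew <- Dp * exp(p$spiral_constant * l) * cos(2 * pi * l) + state$gbest_pos
    }
    state$pos[i, ] <- clamp01(xnew)
  }
  state_eval(state, ev)
}

# --- grey wolf -------------------------------------------------------------
# Each agent moves to the mean of three leader-guided points; the leaders
# (alpha, beta, delta) are the three best solutions seen so far.

#' @rdname optimizer_steps
#' @export
gwoa_step <- function(state, cfg, ev, t, Tmax) {
  pop <- state$pop; D <- state$D
  if (is.null(state$leaders)) state <- gwo_update_leaders(state)
  a <- 2 - 2 * t / Tmax
  L <- state$leaders
  for (i in seq_len(pop)) {
    x <- state$pos[i, ]
    xnew <- numeric(D)
    for (l in 1:3) {
      A <- 2 * a * stats::runif(D) - a
      C <- 2 * stats::runif(D)
      Dl <- abs(C * L$pos[l, ] - x)
      xnew <- xnew + (L$pos[l, ] - A * Dl) / 3
    }
    state$pos[i, ] <- clamp01(xnew)
  }
  state <- state_eval(state, ev)
  gwo_update_leaders(state)
}

# keep the three lowest-cost agents ever seen as leaders (padded by
# repetition of the best when the population is smaller than three)
gwo_update_leaders <- function(state) {
  cand_pos <- state$pos
  cand_fit <- state$fit
  if (!is.null(state$leaders)) {
    cand_pos <- rbind(cand_pos, state$leaders$pos)
    cand_fit <- c(cand_fit, state$leaders$fit)
  }
  ord <- order(cand_fit)[seq_len(min(3L, length(cand_fit)))]
  pos <- cand_pos[ord, , drop = FALSE]
  fit <- cand_fit[ord]
  while (nrow(pos) < 3L) {
    pos <- rbind(pos, pos[1, ])
    fit <- c(fit, fit[1])
  }
  state$leaders <- list(pos = pos, fit = fit)
  state
}

# --- bat -------------------------------------------------------------------
# Frequency-tuned velocities toward the best; occasional local walk around
# the best scaled by the mean loudness; greedy acceptance gated by the
# agent's loudness, which then decays (2 * 0.9^k after k acceptances) while
# its pulse rate grows.

#' @rdname optimizer_steps
#' @export
ba_step <- function(state, cfg, ev, t, Tmax) {
  p <- cfg$params; pop <- state$pop; D <- state$D
  if (is.null(state$loudness)) {
    state$loudness <- rep(p$loudness_max, pop)
    state$pulse <- rep(0, pop)
  }
  Amean <- mean(state$loudness)
  for (i in seq_len(pop)) {
    freq <- p$f_min + (p$f_max - p$f_min) * stats::runif(1)
    v <- state$vel[i, ] + (state$pos[i, ] - state$gbest_pos) * freq
    v <- pmin(pmax(v, -1), 1)  # keep frequency moves on the cube's scale
    xnew <- clamp01(state$pos[i, ] + v)
    if (stats::runif(1) > state$pulse[i])
      xnew <- clamp01(state$gbest_pos + stats::runif(D, -0.5, 0.5) * Amean)
    fv <- ev(binarize_position(xnew))
    state$vel[i, ] <- v
    if (stats::runif(1) < state$loudness[i] && fv$I <= state$fit[i]) {
      state$pos[i, ] <- xnew
      state$fit[i] <- fv$I; state$nsel[i] <- fv$n_selected
      state$loudness[i] <- state$loudness[i] * p$rate_constant
      state$pulse[i] <- p$pulse_rate_max * (1 - p$rate_constant^t)
    }
    if (fv$I < state$gbest_I) {
      state$gbest_I <- fv$I; state$gbest_nsel <- fv$n_selected
      state$gbest_pos <- xnew
    }
  }
  state
}

# --- firefly ---------------------------------------------------------------
# Dimmer fireflies move toward brighter ones with attractiveness
# beta0 * exp(-gamma r^2); all get a random perturbation whose scale is
# multiplied by the control constant (0.97) each iteration.

#' @rdname optimizer_steps
#' @export
fa_step <- function(state, cfg, ev, t, Tmax) {
  p <- cfg$params; pop <- state$pop; D <- state$D
  beta0 <- p$attractiveness_base * p$light_amplitude
  alpha_t <- p$alpha0 * p$alpha_control^t
  fit0 <- state$fit
  pos0 <- state$pos
  for (i in seq_len(pop)) {
    x <- state$pos[i, ]
    moved <- FALSE
    for (j in seq_len(pop)) {
      if (fit0[j] < fit0[i]) {
        d <- pos0[j, ] - x
        beta <- beta0 * exp(-p$absorption * sum(d^2))
        x <- x + beta * d + alpha_t * (stats::runif(D) - 0.5)
        moved <- TRUE
      }
    }
    if (!moved)  # brightest firefly: random walk only
      x <- x + alpha_t * (stats::runif(D) - 0.5)
    state$pos[i, ] <- clamp01(x)
  }
  state_eval(state, ev)
}
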