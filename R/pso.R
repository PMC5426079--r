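#' Swarm configuration
#'
#' Defaults are the published operating point: 200 particles, at most 200
#' generations, acceleration coefficients 0.5/0.5, inertia decaying linearly
#' from 1 to 0.2, search box k in \[100, 4000\] and alpha in \[0.001, 4\],
#' and convergence when the global best is stationary for 4 consecutive
#' generations.
#'
#' @param n_p swarm size (>= 2).
#' @param t_max maximum number of generations.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param w_max,w_min inertia bounds for the linear decay.
#' @param k_bounds,alpha_bounds search-box intervals for the two
#'   parameters.
#' @param patience consecutive stagnant generations that trigger
#'   convergence.
#' @param seed RNG seed making the run reproducible.
#' @param init `"grid"` (deterministic uniform grid, default) or
#'   `"random"` (seeded uniform draws).
#' @return an object of class `swarm_config`.
#' @export
swarm_config <- function(n_p = 200, t_max = 200, c1 = 0.5, c2 = 0.5,
                         w_max = 1.0, w_min = 0.2,
                         k_bounds = c(100, 4000),
                         alpha_bounds = c(0.001, 4.000),
                         patience = 4, seed = 1L,
                         init = c("grid", "random")) {
  stopifnot(n_p >= 2, t_max >= 1, w_max >= w_min,
            k_bounds[2] > k_bounds[1], alpha_bounds[2] > alpha_bounds[1],
            patience >= 1)
  structure(list(n_p = as.integer(n_p), t_max = as.integer(t_max),
                 c1 = c1, c2 = c2, w_max = w_max, w_min = w_min,
                 k_bounds = k_bounds, alpha_bounds = alpha_bounds,
                 patience = as.integer(patience), seed = as.integer(seed),
                 init = match.arg(init)),
            class = "swarm_config")
}

#' Linearly decaying inertia weight
#'
#' `w(t) = w_max - (w_max - w_min) * t / t_max`, so `w(0) = w_max` and
#' `w(t_max) = w_min`.
#'
#' @param t generation index in `0..t_max`.
#' @param cfg a [swarm_config()].
#' @return the inertia weight.
#' @export
inertia_weight <- function(t, cfg = swarm_config()) {
  # algebraically w_max - (w_max - w_min) * t / t_max; written from the
  # w_min end so both endpoints are exact in floating point
  cfg$w_min + (cfg$w_max - cfg$w_min) * (1 - t / cfg$t_max)
}

# factor n_p into an r x c grid (r along k, c along alpha) with the pair
# whose ratio is closest to 2:1 on a log scale; 200 -> 20 x 10, 50 -> 10x5,
# 4 -> 2x2.  Primes >= 4 have no pair with both sides >= 2.
grid_shape <- function(n_p) {
  divs <- which(n_p %% seq_len(n_p) == 0)
  cand <- lapply(divs, function(c) c(r = n_p / c, c = c))
  cand <- Filter(function(p) p["r"] >= p["c"], cand)
  if (n_p >= 4) cand <- Filter(function(p) p["c"] >= 2, cand)
  if (length(cand) == 0) return(NULL)
  score <- vapply(cand, function(p) abs(log(p["r"] / p["c"]) - log(2)), 0)
  cand[[which.min(score)]]
}

#' Initialize the particle swarm
#'
#' Deterministic uniform grid placement over the (k, alpha) box at cell
#' centers (20 x 10 for the default 200 particles), velocities zero.  If
#' `n_p` admits no grid with both sides at least 2 (prime swarm sizes), or
#' when `cfg$init = "random"`, placement falls back to seeded uniform
#' random draws (with a notice in the grid case).
#'
#' @param cfg a [swarm_config()].
#' @return data frame with one row per particle: `k`, `alpha`, `v_k`,
#'   `v_alpha`, `best_k`, `best_alpha`, `best_fit`.
#' @export
initialize_swarm <- function(cfg = swarm_config()) {
  kb <- cfg$k_bounds; ab <- cfg$alpha_bounds
  random <- cfg$init == "random"
  if (!random) {
    shape <- grid_shape(cfg$n_p)
    if (is.null(shape)) {
      message("swarm size ", cfg$n_p,
              " not factorable into a grid; using seeded random placement")
      random <- TRUE
    }
  }
  if (random) {
    set.seed(cfg$seed)
    k <- runif(cfg$n_p, kb[1], kb[2])
    a <- runif(cfg$n_p, ab[1], ab[2])
  } else {
    kc <- kb[1] + (seq_len(shape["r"]) - 0.5) / shape["r"] * diff(kb)
    ac <- ab[1] + (seq_len(shape["c"]) - 0.5) / shape["c"] * diff(ab)
    g <- expand.grid(k = kc, alpha = ac)
    k <- g$k; a <- g$alpha
  }
  data.frame(k = k, alpha = a, v_k = 0, v_alpha = 0,
             best_k = NA_real_, best_alpha = NA_real_,
             best_fit = -Inf)
}

#' Velocity and position update of one particle
#'
#' `v <- w v + c1 r1 (p_i - x) + c2 r2 (p_g - x)`, `x <- x + v`, with `r1`,
#' `r2` uniform(0,1) drawn independently per dimension; the position is then
#' clamped to the search box and any clamped component's velocity is
#' zeroed.
#'
#' @param p one-row data frame as produced by [initialize_swarm()] (with
#'   personal best set).
#' @param p_g numeric `c(k, alpha)` global best position.
#' @param w inertia weight.
#' @param cfg a [swarm_config()].
#' @return the updated one-row data frame.
#' @export
update_particle <- function(p, p_g, w, cfg = swarm_config()) {
  r1 <- runif(2); r2 <- runif(2)
  x <- c(p$k, p$alpha)
  v <- c(p$v_k, p$v_alpha)
  pb <- c(p$best_k, p$best_alpha)
  v <- w * v + cfg$c1 * r1 * (pb - x) + cfg$c2 * r2 * (p_g - x)
  x <- x + v
  lo <- c(cfg$k_bounds[1], cfg$alpha_bounds[1])
  hi <- c(cfg$k_bounds[2], cfg$alpha_bounds[2])
  clamped <- x < lo | x > hi
  x <- pmin(pmax(x, lo), hi)
  v[clamped] <- 0
  p$k <- x[1]; p$alpha <- x[2]; p$v_k <- v[1]; p$v_alpha <- v[2]
  p
}

#' Particle swarm optimization over the (k, alpha) box
#'
#' Maximizes `fitness(k, alpha)`.  The swarm is initialized (generation 0
#' evaluates every particle and seeds the personal and global bests), then
#' iterates velocity/position updates with linearly decaying inertia until
#' the global best position is stationary (movement below 1e-9 in
#' box-normalized coordinates) for `patience` consecutive generations, or
#' `t_max` is reached.  Identical positions are evaluated once (cache);
#' personal and global bests are replaced only by strictly better fitness,
#' so the best fitness is non-decreasing.
#'
#' @param fitness function of `(k, alpha)` returning a finite scalar.
#' @param cfg a [swarm_config()].
#' @return list with `best` (`c(k, alpha)`), `best_fit`, and `trace`
#'   (data frame: `generation`, `w`, `k_best`, `alpha_best`, `f_best`).
#' @export
pso_optimize <- function(fitness, cfg = swarm_config()) {
  swarm <- initialize_swarm(cfg)
  set.seed(cfg$seed + 1L) # grid init consumes no RNG; keep streams separate
  cache <- new.env(hash = TRUE, parent = emptyenv())
  evalf <- function(k, alpha) {
    key <- sprintf("%.17g|%.17g", k, alpha)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- fitness(k, alpha)
    if (!is.finite(f))
      stop(sprintf("non-finite fitness at (k=%g, alpha=%g)", k, alpha),
           call. = FALSE)
    cache[[key]] <- f
    f
  }

  fit <- mapply(evalf, swarm$k, swarm$alpha)
  swarm$best_k <- swarm$k
  swarm$best_alpha <- swarm$alpha
  swarm$best_fit <- fit
  g <- which.max(fit)
  p_g <- c(swarm$k[g], swarm$alpha[g])
  f_g <- fit[g]

  box <- c(diff(cfg$k_bounds), diff(cfg$alpha_bounds))
  trace <- data.frame(generation = 0L, w = inertia_weight(0, cfg),
                      k_best = p_g[1], alpha_best = p_g[2], f_best = f_g)
  stagnant <- 0L
  for (t in seq_len(cfg$t_max)) {
    w <- inertia_weight(t, cfg)
    prev_pg <- p_g
    for (i in seq_len(cfg$n_p)) {
      swarm[i, ] <- update_particle(swarm[i, ], p_g, w, cfg)
      f <- evalf(swarm$k[i], swarm$alpha[i])
      if (f > swarm$best_fit[i]) {
        swarm$best_fit[i] <- f
        swarm$best_k[i] <- swarm$k[i]
        swarm$best_alpha[i] <- swarm$alpha[i]
      }
      if (f > f_g) {
        f_g <- f
        p_g <- c(swarm$k[i], swarm$alpha[i])
      }
    }
    trace <- rbind(trace, data.frame(generation = t, w = w,
                                     k_best = p_g[1], alpha_best = p_g[2],
                                     f_best = f_g))
    moved <- max(abs(p_g - prev_pg) / box)
    stagnant <- if (moved < 1e-9) stagnant + 1L else 0L
    if (stagnant >= cfg$patience) break
  }
  list(best = c(k = p_g[1], alpha = p_g[2]), best_fit = f_g, trace = trace)
}
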