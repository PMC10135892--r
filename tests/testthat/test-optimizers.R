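ALGS <- wbm_algorithms()

test_that("position binarization is a strict threshold at one half", {
  expect_identical(binarize_position(rep(0, 5))$bits, rep(0L, 5))
  expect_identical(binarize_position(rep(1, 5))$bits, rep(1L, 5))
  expect_identical(binarize_position(c(0.2, 0.8, 0.5))$bits, c(0L, 1L, 0L))
  # scale-free: the rule is per-component, independent of dimension
  set.seed(1)
  x <- runif(64)
  expect_identical(binarize_position(x)$bits, as.integer(x > 0.5))
  expect_identical(binarize_position(x[1:7])$bits, as.integer(x[1:7] > 0.5))
})

test_that("initial populations are seeded, bounded, and pre-evaluated", {
  ev <- planted_landscape(100)
  cfg <- optimizer_config("GWOA", seed = 11)
  set.seed(11); p1 <- init_population(100, cfg, ev)
  set.seed(11); p2 <- init_population(100, cfg, ev)
  expect_identical(p1$pos, p2$pos)
  expect_identical(dim(p1$pos), c(10L, 100L))
  expect_true(all(p1$pos >= 0 & p1$pos <= 1))
  # global best equals the minimum over direct evaluation of each agent
  direct <- apply(p1$pos, 1, function(x) ev(binarize_position(x))$I)
  expect_equal(p1$gbest_I, min(direct))
  expect_equal(p1$fit, direct)
  expect_error(init_population(0, cfg, ev), "D")
})

test_that("runs are reproducible and refuse unknown algorithms", {
  ev <- planted_landscape(10)
  for (alg in ALGS) {
    cfg <- optimizer_config(alg, iterations = 8, seed = 99)
    r1 <- run_optimizer(cfg, ev, 10)
    r2 <- run_optimizer(cfg, ev, 10)
    expect_identical(r1, r2)
  }
  expect_error(optimizer_config("XYZ"), "arg")
})

test_that("a structureless landscape yields a flat history at its cost", {
  ev <- constant_landscape(12, I = 0.3)
  for (alg in c("MPA", "BOA", "FA")) {
    r <- run_optimizer(optimizer_config(alg, iterations = 10, seed = 2), ev, 12)
    expect_equal(r$best_fitness$I, 0.3)
    expect_true(all(r$history$best_fitness_per_iteration == 0.3))
  }
})

test_that("best-so-far trajectories never increase for any algorithm", {
  ev <- additive_landscape(10, planted = c(2, 6))
  for (alg in ALGS) {
    r <- run_optimizer(optimizer_config(alg, iterations = 25, seed = 5), ev, 10)
    h <- r$history$best_fitness_per_iteration
    expect_true(all(diff(h) <= 0), info = alg)
    expect_equal(r$best_fitness$I, min(h))
  }
})

test_that("evaluation budgets respect the documented per-algorithm bounds", {
  # one evaluation per agent per iteration plus initialization, with
  # documented extras: MPA evaluates a second time after the FADs move,
  # HHOA adds up to two dive probes per hawk
  extras <- c(MPA = 10L, ASOA = 0L, HHOA = 20L, BOA = 0L, WOA = 0L,
              GWOA = 0L, BA = 0L, FA = 0L)
  for (alg in ALGS) {
    counter <- local({
      n <- 0L
      ev <- planted_landscape(10)
      list(f = function(m) { n <<- n + 1L; ev(m) }, get = function() n)
    })
    r <- run_optimizer(optimizer_config(alg, iterations = 50, seed = 1),
                       counter$f, 10)
    budget <- 10L * (50L + 1L) + extras[[alg]] * 50L
    expect_lte(counter$get(), budget)
    expect_identical(counter$get(), r$history$evaluations_used)
  }
})

test_that("atom masses form a proper distribution over any cost vector", {
  set.seed(8)
  for (k in 1:10) {
    fit <- runif(10)
    m <- aso_masses(fit)
    expect_equal(sum(m), 1)
    expect_true(all(m > 0))
    expect_identical(which.max(m), which.min(fit))  # best atom heaviest
  }
  expect_equal(sum(aso_masses(rep(0.3, 5))), 1)     # degenerate: all equal
})

test_that("pinned step updates hit their closed-form fixed points", {
  D <- 6
  ev <- constant_landscape(D, 0.3)
  cfg_h <- optimizer_config("HHOA", seed = 4)

  # hard besiege at zero escape energy lands exactly on the best position
  set.seed(4)
  st <- init_population(D, cfg_h, ev)
  best <- st$gbest_pos
  x <- st$pos[2, ]
  E <- 0
  expect_equal(best - E * abs(best - x), best)

  # whale spiral branch from the best position is a fixed point (D' = 0)
  b <- 1; l <- 0.37
  expect_equal(abs(best - best) * exp(b * l) * cos(2 * pi * l) + best, best)

  # grey wolf update with all leaders and the agent at X, A = 0, C = 1
  X <- runif(D)
  A <- 0; C <- 1
  leader_guided <- (X - A * abs(C * X - X))
  expect_equal((leader_guided + leader_guided + leader_guided) / 3, X)

  # bat loudness decays geometrically with each accepted update
  expect_equal(2 * 0.9^7, 2 * prod(rep(0.9, 7)))

  # firefly random-walk scale decays by the control constant per iteration
  a0 <- 1
  expect_equal(a0 * 0.97^10, prod(c(a0, rep(0.97, 10))))

  # fireflies at identical positions exert no attraction displacement
  xi <- runif(D)
  beta <- 1 * exp(-1 * sum((xi - xi)^2))
  expect_equal(beta * (xi - xi), rep(0, D))
})

test_that("grey wolf leaders are the three best solutions seen", {
  D <- 8
  ev <- additive_landscape(D, planted = c(1, 5))
  cfg <- optimizer_config("GWOA", iterations = 6, seed = 3)
  seen <- local({
    log <- list()
    list(f = function(m) {
      fv <- ev(m); log[[length(log) + 1L]] <<- fv; fv
    }, get = function() log)
  })
  set.seed(3)
  st <- init_population(D, cfg, seen$f)
  for (t in 1:6) st <- gwoa_step(st, cfg, seen$f, t, 6)
  all_I <- sort(vapply(seen$get(), function(f) f$I, 0))
  expect_equal(st$leaders$fit, all_I[1:3])
})

test_that("each optimizer finds the enumerated optimum of a small landscape", {
  # quick per-algorithm sanity at one seed; the multi-seed success-rate
  # study lives in the acceptance suite
  ev <- planted_landscape(8)
  orc <- exhaustive_oracle(ev, 8)
  expect_equal(orc$best_fitness$I, 0.00125)
  for (alg in ALGS) {
    r <- run_optimizer(optimizer_config(alg, seed = 1), ev, 8)
    expect_equal(r$best_fitness$I, 0.00125, info = alg)
    expect_identical(r$best_mask$bits, orc$best_mask$bits)
  }
})

test_that("positions stay inside the unit cube throughout a run", {
  ev <- planted_landscape(10)
  for (alg in ALGS) {
    cfg <- optimizer_config(alg, iterations = 10, seed = 6)
    set.seed(6)
    st <- init_population(10, cfg, ev)
    step <- switch(alg, MPA = mpa_step, ASOA = asoa_step, HHOA = hhoa_step,
                   BOA = boa_step, WOA = woa_step, GWOA = gwoa_step,
                   BA = ba_step, FA = fa_step)
    for (t in 1:10) {
      st <- step(st, cfg, ev, t, 10)
      expect_true(all(st$pos >= 0 & st$pos <= 1), info = alg)
    }
  }
})

test_that("config defaults mirror the published parameter table", {
  cfg <- optimizer_config("MPA")
  expect_identical(cfg$iterations, 50L)
  expect_identical(cfg$pop_size, 10L)
  expect_equal(cfg$params$fads_effect, 0.2)
  expect_equal(optimizer_config("ASOA")$params$depth_weight, 50)
  expect_equal(optimizer_config("BA")$params$loudness_max, 2)
  expect_equal(optimizer_config("FA")$params$alpha_control, 0.97)
  expect_equal(optimizer_config("BOA", params = list(power_exponent = 0.3)
                                )$params$power_exponent, 0.3)
  expect_error(optimizer_config("WOA", params = list(nope = 1)), "unknown")
})
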