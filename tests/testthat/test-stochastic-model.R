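# Telegraph model: closed forms, the event-driven simulator and the
# marked-Poisson population sampler.

test_that("model_params validates its inputs", {
  expect_error(model_params(-1, 1, 1, 30, 1, 0.1), "non-negative")
  expect_error(model_params(1, 1, 1, 2.5, 1, 0.1), "integer")
  expect_error(model_params(1, 1, 1, 0, 1, 0.1), "integer")
  expect_error(model_params(Inf, 1, 1, 30, 1, 0.1), "finite")
  p <- model_params(0.1, 0.2, 0.85, 30, 2.33, 0.05)
  expect_s3_class(p, "model_params")
  expect_identical(p$n_steps, 30L)
})

test_that("mean production rate follows alpha*gamma/(alpha+beta)", {
  expect_equal(mean_production_rate(model_params(1, 1, 1, 30, 1, 0.1)), 0.5)
  expect_equal(mean_production_rate(model_params(2, 0, 0.7, 30, 1, 0.1)), 0.7)
  expect_equal(mean_production_rate(model_params(0.1, 0.1, 0.85, 30, 1, 0.1)),
               0.425)
  expect_error(mean_production_rate(model_params(0, 0, 1, 30, 1, 0.1)),
               "undefined")
})

test_that("steady-state means follow Little's law", {
  p0 <- model_params(0.5, 0.5, 0, 30, 1, 0.1)
  expect_equal(unname(steady_state_means(p0)), c(0, 0))
  # r = 1: alpha = beta, gamma = 2
  p <- model_params(1, 1, 2, 10, 5, 0.5)
  expect_equal(unname(steady_state_means(p)), c(2, 2))
  expect_error(steady_state_means(model_params(1, 1, 1, 30, 0, 0.1)), "k > 0")
  expect_error(steady_state_means(model_params(1, 1, 1, 30, 1, 0)), "delta > 0")
})

test_that("half-life is ln2 over delta and the product is exact", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(log(2) / 20.26), 20.26)
  expect_equal(half_life(log(2) / 13.53), 13.53)
  expect_error(half_life(0), "> 0")
  for (d in c(0.01, 0.05, 1.7)) expect_identical(half_life(d) * d, log(2))
})

test_that("simulate_cell handles degenerate parameters and bad inputs", {
  p0 <- model_params(1, 1, 0, 30, 1, 0.1)
  cc <- simulate_cell(p0, 500, seed = 1)
  expect_identical(c(cc$nuclear, cc$cytoplasmic), c(0L, 0L))
  p <- model_params(1, 1, 1, 5, 1, 0.1)
  expect_error(simulate_cell(p, 0, seed = 1), "> 0")
  expect_error(simulate_cell(p, -5, seed = 1), "> 0")
})

test_that("event-driven cytoplasmic counts approach the birth-death limit", {
  # near-instant processing, promoter always on: cytoplasmic ~ Poisson(gamma/delta)
  p <- model_params(alpha = 50, beta = 0, gamma = 1, n_steps = 1, k = 200,
                    delta = 0.1)
  cells <- vapply(1:200, function(i) {
    simulate_cell(p, 150, seed = 1000 + i)$cytoplasmic
  }, integer(1))
  expect_lt(abs(mean(cells) - 10), 3 * mc_se(cells))
})

test_that("population means agree with the closed-form oracle (both methods)", {
  p <- model_params(0.1, 0.1, 0.85, 30, 2.33, log(2) / 13.53)
  ss <- steady_state_means(p)
  pop <- simulate_population(p, 10000, 500, seed = 5)
  expect_lt(abs(mean(pop$nuclear) - ss["nuclear"]), 3 * mc_se(pop$nuclear))
  expect_lt(abs(mean(pop$cytoplasmic) - ss["cytoplasmic"]),
            3 * mc_se(pop$cytoplasmic))
  pop_ssa <- simulate_population(p, 300, 500, seed = 6, method = "ssa")
  expect_lt(abs(mean(pop_ssa$nuclear) - ss["nuclear"]),
            3 * mc_se(pop_ssa$nuclear))
  expect_lt(abs(mean(pop_ssa$cytoplasmic) - ss["cytoplasmic"]),
            3 * mc_se(pop_ssa$cytoplasmic))
})

test_that("the two simulation routes agree in distribution", {
  p <- model_params(0.3, 0.5, 1.2, 10, 1.0, 0.05)
  a <- simulate_population(p, 400, 400, seed = 21, method = "ssa")
  b <- simulate_population(p, 4000, 400, seed = 22, method = "marking")
  for (col in c("nuclear", "cytoplasmic")) {
    ks <- suppressWarnings(stats::ks.test(a[[col]], b[[col]]))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("counts are Poisson in the always-on fast-processing limit", {
  p <- model_params(alpha = 50, beta = 0, gamma = 1, n_steps = 1, k = 500,
                    delta = 0.1)
  pop <- simulate_population(p, 10000, 500, seed = 9)
  x <- pop$cytoplasmic
  lambda <- 1 / 0.1
  brk <- c(-0.5, seq(2.5, 18.5), Inf)
  obs <- table(cut(x, brk))
  pr <- diff(c(0, stats::ppois(c(2, 3:18), lambda), 1))
  chi <- sum((as.vector(obs) - length(x) * pr)^2 / (length(x) * pr))
  pval <- stats::pchisq(chi, df = length(pr) - 1L, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("simulation is deterministic and extends populations stably", {
  p <- model_params(0.2, 0.3, 1, 30, 2, 0.05)
  a <- simulate_population(p, 200, 500, seed = 7)
  b <- simulate_population(p, 200, 500, seed = 7)
  expect_identical(a, b)
  big <- simulate_population(p, 400, 500, seed = 7)
  expect_identical(big[1:200, ], a[1:200, ])
  s1 <- simulate_cell(p, 500, seed = 3)
  s2 <- simulate_cell(p, 500, seed = 3)
  expect_identical(s1, s2)
})

test_that("counts are invariant under time rescaling (seeded equality)", {
  scale <- 4  # a power of two scales every rate exactly in binary
  p1 <- model_params(0.2, 0.3, 1, 10, 2, 0.05)
  p2 <- model_params(0.2 * scale, 0.3 * scale, 1 * scale, 10, 2 * scale,
                     0.05 * scale)
  a <- simulate_population(p1, 300, 500, seed = 31)
  b <- simulate_population(p2, 300, 500 / scale, seed = 31)
  expect_identical(a, b)
  a2 <- simulate_population(p1, 50, 500, seed = 32, method = "ssa")
  b2 <- simulate_population(p2, 50, 500 / scale, seed = 32, method = "ssa")
  expect_identical(a2, b2)
})

test_that("count distributions round-trip through TSV", {
  p <- model_params(0.2, 0.3, 1, 30, 2, 0.05)
  pop <- simulate_population(p, 50, 300, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_counts(pop, path)
  back <- read_counts(path)
  expect_equal(as.data.frame(back), as.data.frame(pop))
  unlink(path)
})

test_that("the internal deviate generators match their target laws", {
  for (lam in c(5, 200)) {
    x <- senseDynamics:::.poisson_draws_cpp(50000L, lam, 42)
    expect_lt(abs(mean(x) - lam), 4 * mc_se(x))
    expect_lt(abs(stats::var(x) / lam - 1), 0.05)
  }
  g <- senseDynamics:::.gamma_draws_cpp(50000L, 30, 2.33, 7)
  expect_lt(abs(mean(g) - 30 / 2.33), 4 * mc_se(g))
  expect_lt(abs(stats::var(g) - 30 / 2.33^2) / (30 / 2.33^2), 0.05)
})
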