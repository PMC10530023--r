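test_that("parameter validation enforces the documented bounds", {
  p <- model_params()
  # the published default set
  expect_equal(unlist(p[c("r", "m", "m_v", "a", "B", "c_R", "tau", "mu",
                          "A", "L", "K")]),
               c(r = 1, m = 0, m_v = 0, a = 1e-8, B = 100, c_R = 0.01,
                 tau = 0.01, mu = 1e-4, A = 5e-4, L = 1e-3, K = 1e8))
  expect_identical(p$mutation_model, "per_replication")
  expect_error(model_params(mu = -1), "negative")
  expect_error(model_params(B = 0.5), "burst")
  expect_error(model_params(K = 0), "K")
  expect_error(model_params(tau = NaN), "non-finite")
  expect_error(pop_state(S = -1), "negative")
})

test_that("genotype growth rates follow the cost structure", {
  p <- model_params()
  gr <- genotype_growth_rates(p, V = 12345)
  expect_equal(gr[["r_R"]], exp(-0.01), tolerance = 1e-12)
  expect_equal(gr[["r_D"]], gr[["r_R"]])
  expect_equal(gr[["r_S"]], 1)
  # toxicity exponent: tau*a*V = 0.01 * 1e-8 * 1e8 = 0.01
  expect_equal(genotype_growth_rates(p, V = 1e8)[["r_C"]], exp(-0.01),
               tolerance = 1e-12)
  # no toxicity cost without tau, or without phage
  expect_equal(genotype_growth_rates(model_params(tau = 0), 1e9)[["r_C"]], 1)
  expect_equal(genotype_growth_rates(p, 0)[["r_C"]], 1)
  expect_error(genotype_growth_rates(p, -1), ">= 0")
})

test_that("cost ordering: CRISPR beats sm at low phage and loses at high", {
  p <- model_params()
  lo <- genotype_growth_rates(p, V = 0)
  expect_identical(lo[["r_C"]], lo[["r_S"]])
  expect_lt(lo[["r_R"]], lo[["r_S"]])
  # crossover when a*V*tau > c_R, i.e. V > c_R/(tau*a) = 1e8
  hi <- genotype_growth_rates(p, V = 1e10)
  expect_lt(hi[["r_C"]], hi[["r_R"]])
})

test_that("derivatives vanish at the phage-free logistic equilibrium", {
  p <- model_params(mu = 0)
  d <- model_derivatives(pop_state(S = p$K), p)
  expect_equal(unname(d$derivatives), rep(0, 5))
})

test_that("no spacer uptake without phage", {
  p <- model_params()
  st <- pop_state(S = 1e6, C = 1e5, V = 0)
  d <- model_derivatives(st, p)
  expect_identical(d$breakdown[["acquisition_S"]], 0)
  g <- 1 - total_hosts(st) / p$K
  expect_equal(d$derivatives[["C"]],
               p$r * g * 1e5 - p$mu * p$r * g * 1e5 - p$L * 1e5,
               tolerance = 1e-12)
})

test_that("derivatives equal signed flux sums on random valid states", {
  set.seed(41)
  for (i in 1:25) {
    p <- model_params(m = runif(1, 0, 0.1), m_v = runif(1, 0, 0.5),
                      mutation_model = sample(c("per_replication",
                                                "per_capita"), 1),
                      acquisition_from_R = runif(1) < 0.5,
                      rescue_on_acquisition = runif(1) < 0.5)
    st <- random_state(p$K)
    d <- model_derivatives(st, p)
    expect_identical(d$derivatives, flux_balance(d$breakdown))
    expect_true(all(d$breakdown >= 0))
  }
})

test_that("compiled right-hand side agrees with the R derivatives", {
  set.seed(42)
  for (i in 1:10) {
    p <- model_params(acquisition_from_R = i %% 2 == 0,
                      rescue_on_acquisition = i %% 3 == 0)
    st <- random_state(p$K)
    d_r <- model_derivatives(st, p)$derivatives
    d_c <- crisprdyn:::.ode_rhs_cpp(as.numeric(unclass(st)),
                                    crisprdyn:::param_vector(p),
                                    crisprdyn:::switch_vector(p))
    expect_equal(unname(d_r), d_c, tolerance = 1e-13)
  }
})

test_that("derivatives match a central finite difference of the trajectory", {
  p <- model_params()
  st <- pop_state(S = 1e6, V = 1e4)
  h <- 1e-4
  ctl <- solver_options(rtol = 1e-12, atol = 1e-14, n_out = 3)
  fwd <- integrate_batch(st, p, 2 * h, control = ctl)$states
  # central difference approximates the derivative at the midpoint t = h
  d <- model_derivatives(as_pop_state_test(fwd[2, ]), p)$derivatives
  fd <- (fwd[3, ] - fwd[1, ]) / (2 * h)
  for (v in c("S", "R", "C", "V"))
    expect_equal(fd[[v]], d[[v]], tolerance = 1e-6)
})

test_that("CRISPR cells are a phage sink when no sensitive hosts remain", {
  p <- model_params(m_v = 0.1)
  d <- model_derivatives(pop_state(C = 1e7, V = 1e6), p)
  expect_equal(d$derivatives[["V"]],
               -p$a * 1e6 * 1e7 - p$m_v * 1e6, tolerance = 1e-12)
  expect_lt(d$derivatives[["V"]], 0)
})
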