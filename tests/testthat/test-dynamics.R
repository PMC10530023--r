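test_that("the all-zero state is absorbing", {
  tr <- integrate_batch(pop_state(), model_params(), 20)
  expect_true(all(tr$states == 0))
})

test_that("phage-free, mutation-free growth matches the closed-form logistic", {
  p <- model_params(mu = 0, A = 0)
  S0 <- p$K / 100
  tr <- integrate_batch(pop_state(S = S0), p, 20,
                        control = solver_options(n_out = 201))
  for (tt in c(5, 10, 20)) {
    i <- which.min(abs(tr$times - tt))
    expect_equal(unname(tr$states[i, "S"]),
                 logistic_closed_form(tr$times[i], S0, p$r, p$K),
                 tolerance = 1e-6)
  }
})

test_that("the solution is converged with respect to the tolerances", {
  p <- model_params()
  st <- pop_state(S = 1e6, V = 1e4)
  f1 <- final_state(integrate_batch(st, p, 20,
                                    control = solver_options()))
  f2 <- final_state(integrate_batch(st, p, 20,
                                    control = solver_options(rtol = 1e-9,
                                                             atol = 1e-13)))
  expect_equal(as.numeric(unclass(f1)), as.numeric(unclass(f2)),
               tolerance = 1e-8)
})

test_that("transfers dilute hosts and phage by their factors", {
  st <- pop_state(S = 1e8, V = 1e7)
  pr <- transfer_protocol(dilution = 0.01, phage_dilution = 0.01)
  out <- unclass(apply_transfer(st, pr))
  expect_equal(out[["S"]], 1e6)
  expect_equal(out[["V"]], 1e5)
  # identity protocol
  id <- apply_transfer(st, transfer_protocol(dilution = 1,
                                             phage_dilution = 1))
  expect_equal(unclass(id), unclass(st))
  # frequencies are invariant: the dilution is genotype-blind
  set.seed(7)
  for (i in 1:10) {
    s <- random_state()
    d <- runif(1, 0.001, 1)
    pr2 <- transfer_protocol(dilution = d, phage_dilution = runif(1, 0.01, 1))
    expect_equal(genotype_frequencies(apply_transfer(s, pr2)),
                 genotype_frequencies(s), tolerance = 1e-12)
  }
})

test_that("a one-transfer protocol reduces to a single batch", {
  p <- model_params()
  st <- pop_state(S = 1e6, V = 1e4)
  a <- run_protocol(st, p, transfer_protocol(n_transfers = 1))
  b <- integrate_batch(st, p, 20)
  expect_equal(a$states, b$states)
  expect_equal(a$times, b$times)
})

test_that("phage drop by exactly the dilution factor at each boundary", {
  p <- model_params()
  tr <- run_protocol(pop_state(S = 1e6, V = 1e4), p, transfer_protocol())
  pre <- tr$states[tr$boundaries, ]
  expect_equal(tr$boundary_states[, "V"], unname(pre[, "V"] * 0.01),
               tolerance = 1e-12)
  expect_equal(tr$boundary_states[, "S"], unname(pre[, "S"] * 0.01),
               tolerance = 1e-12)
  expect_true(all(diff(tr$times) > 0))
})

test_that("final-day frequencies agree with a fixed-step Euler oracle", {
  p <- model_params()
  rk <- run_protocol(pop_state(S = 1e6, V = 1e4), p, transfer_protocol())
  f_rk <- genotype_frequencies(final_state(rk))
  y_eu <- euler_protocol(1e6, 1e4, p, dt = 1e-3)
  f_eu <- y_eu[1:4] / sum(y_eu[1:4])
  expect_true(all(abs(unname(f_rk) - unname(f_eu)) < 1e-3))
})

test_that("design grids are deterministic and refuse empty designs", {
  d <- bundled_design("inoculum_sweep")
  g1 <- run_design_grid(d, model_params())
  g2 <- run_design_grid(d, model_params())
  expect_identical(g1, g2)
  expect_error(experiment_design(data.frame()), "empty")
})

test_that("no CRISPR immunity ever arises without phage", {
  d <- experiment_design(data.frame(V0 = 0, K = 1e8,
                                    inoculum_fraction = 0.01))
  g <- run_design_grid(d, model_params())
  expect_true(all(g$f_C == 0))
  expect_true(all(g$f_D == 0))
})

test_that("double resistance stays rare over the default 3-transfer run", {
  tr <- run_protocol(pop_state(S = 1e6, V = 1e4), model_params(),
                     transfer_protocol())
  met <- selection_trajectory(tr)
  expect_lt(max(met$f_D, na.rm = TRUE), 0.01)
})

test_that("MOI-matched and fixed-dose inoculum sweeps differ only via V0", {
  p <- model_params()
  fixed <- run_design_grid(bundled_design("inoculum_sweep"), p)
  moi <- run_design_grid(bundled_design("moi_matched_sweep"), p)
  # same inoculum fractions, different doses -> different CRISPR outcomes
  expect_equal(fixed$inoculum_fraction, moi$inoculum_fraction)
  expect_false(isTRUE(all.equal(fixed$f_C, moi$f_C)))
  # at the shared treatment (S0 = K/10, V0 = 1e6 in both) results coincide
  i <- which(fixed$inoculum_fraction == 0.1)
  j <- which(moi$inoculum_fraction == 0.1)
  expect_equal(fixed$f_C[i], moi$f_C[j], tolerance = 1e-10)
})
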