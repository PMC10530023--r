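test_that("genotype frequencies normalise and fail on empty populations", {
  f <- genotype_frequencies(pop_state(S = 2.5e7, R = 2.5e7, C = 2.5e7,
                                      D = 2.5e7))
  expect_equal(unname(f), rep(0.25, 4))
  expect_equal(genotype_frequencies(pop_state(S = 1e8))[["f_S"]], 1)
  expect_error(genotype_frequencies(pop_state(V = 1e5)), "undefined")
  set.seed(11)
  for (i in 1:10)
    expect_equal(sum(genotype_frequencies(random_state())), 1,
                 tolerance = 1e-12)
})

test_that("linkage disequilibrium follows f_S f_D - f_R f_C", {
  expect_equal(linkage_disequilibrium(c(f_S = .25, f_R = .25, f_C = .25,
                                        f_D = .25)), 0)
  expect_equal(linkage_disequilibrium(c(f_S = .5, f_R = .3, f_C = .2,
                                        f_D = 0)), -0.06)
  expect_equal(linkage_disequilibrium(c(f_S = .4, f_R = .3, f_C = .2,
                                        f_D = .1)), -0.02)
  expect_equal(linkage_disequilibrium(pop_state(S = 4e7, R = 3e7, C = 2e7,
                                                D = 1e7)), -0.02)
})

test_that("selection coefficients match their closed forms", {
  p <- model_params()
  # V = 0, only S and R, N/K = 0.5: s_R = r*g*(e^{-c_R} - 1)
  st <- pop_state(S = 2.5e7, R = 2.5e7)
  rep1 <- selection_coefficients(st, p)
  expect_equal(rep1$s_R, 0.5 * (exp(-0.01) - 1), tolerance = 1e-10)
  expect_equal(rep1$s_R, -0.0049750, tolerance = 1e-4)
  expect_true(is.na(rep1$s_C))  # CRISPR allele absent in an S/R population
  # only S and C, a*V = 0.01, N/K = 0.5: s_C = 0.5*(e^{-tau aV} - 1) + aV
  st2 <- pop_state(S = 2.5e7, C = 2.5e7, V = 1e6)
  rep2 <- selection_coefficients(st2, p)
  expect_equal(rep2$s_C, 0.5 * (exp(-0.01 * 0.01) - 1) + 0.01,
               tolerance = 1e-10)
  expect_equal(rep2$s_C, 0.0099500, tolerance = 1e-4)
  expect_true(is.na(rep2$s_R))
  # monomorphic population: neither coefficient is defined
  expect_error(selection_coefficients(pop_state(S = 1e6), p), "undefined")
})

test_that("selection components sum to the total", {
  set.seed(13)
  p <- model_params()
  for (i in 1:10) {
    st <- random_state()
    rep <- selection_coefficients(st, p)
    expect_equal(sum(rep$components$s_R), rep$s_R, tolerance = 1e-10)
    expect_equal(sum(rep$components$s_C), rep$s_C, tolerance = 1e-10)
  }
})

test_that("s equals the logit-frequency derivative when supply is off", {
  # mu = 0, A = 0, L = 0: allele frequencies change by selection only
  p <- model_params(mu = 0, A = 0, L = 0)
  st <- pop_state(S = 4e7, R = 1e6, C = 2e6, D = 1e4, V = 1e7)
  h <- 2e-4  # truncation error is O(h^2) via the fast phage dynamics
  ctl <- solver_options(rtol = 1e-12, atol = 1e-14, n_out = 3)
  tr <- integrate_batch(st, p, 2 * h, control = ctl)
  # the central difference estimates the derivative at the midpoint t = h
  s_now <- selection_coefficients(as_pop_state_test(tr$states[2, ]), p)
  logit <- function(x) log(x / (1 - x))
  fc <- function(i, carriers) {
    fr <- tr$states[i, c("S", "R", "C", "D")]
    sum(fr[carriers]) / sum(fr)
  }
  d_logit_R <- (logit(fc(3, c("R", "D"))) - logit(fc(1, c("R", "D")))) /
    (2 * h)
  d_logit_C <- (logit(fc(3, c("C", "D"))) - logit(fc(1, c("C", "D")))) /
    (2 * h)
  expect_equal(s_now$s_R, d_logit_R, tolerance = 1e-4)
  expect_equal(s_now$s_C, d_logit_C, tolerance = 1e-4)
})

test_that("negative LD emerges during the default transient", {
  tr <- run_protocol(pop_state(S = 1e6, V = 1e4), model_params(),
                     transfer_protocol())
  met <- selection_trajectory(tr)
  expect_true(all(met$LD <= 1e-12))
  expect_lt(min(met$LD), 0)
})

test_that("LD is identically zero when one locus is monomorphic", {
  # mu = 0 and no R/D at start: surface locus never polymorphic
  p <- model_params(mu = 0)
  tr <- run_protocol(pop_state(S = 1e6, V = 1e4), p, transfer_protocol())
  met <- selection_trajectory(tr)
  expect_true(all(met$f_R == 0))
  expect_true(all(met$f_D == 0))
  expect_true(all(met$LD == 0))
  # A = 0 and no C/D at start: CRISPR locus never polymorphic
  p2 <- model_params(A = 0)
  met2 <- selection_trajectory(run_protocol(pop_state(S = 1e6, V = 1e4),
                                            p2, transfer_protocol()))
  expect_true(all(met2$LD == 0))
})

test_that("interference: faster spacer acquisition weakens sm selection", {
  ic <- interference_curve(acquisition_values = c(5e-5, 5e-4, 5e-3))
  expect_equal(nrow(ic), 3)
  expect_true(all(diff(ic$final_f_R) < 0))
  expect_true(all(diff(ic$integrated_s_R) < 0))
  # single value reduces to a single protocol run
  one <- interference_curve(acquisition_values = 5e-4)
  expect_equal(nrow(one), 1)
  expect_equal(one$final_f_R, ic$final_f_R[2], tolerance = 1e-12)
  expect_error(interference_curve(acquisition_values = c(0, 1e-4)), "> 0")
})
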