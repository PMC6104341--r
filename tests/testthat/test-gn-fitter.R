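test_that("gn_step solves the normal equations", {
  # zero residual: already at the optimum
  Z <- cbind(1:5, (1:5)^2)
  expect_equal(unname(gn_step(Z, rep(0, 5))), c(0, 0))

  # identity Jacobian: update is minus the residual
  expect_equal(unname(gn_step(diag(2), c(1, 2))), c(-1, -2))

  # brute-force explicit-inverse oracle on a well-conditioned 50 x 3 system
  set.seed(5)
  Z <- matrix(rnorm(150), 50, 3)
  r <- rnorm(50)
  expect_equal(unname(gn_step(Z, r)),
               drop(-solve(t(Z) %*% Z) %*% t(Z) %*% r),
               tolerance = 1e-10)

  # rank deficiency is reported with the degenerate column named
  Zd <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(gn_step(Zd, rnorm(6)), "singular.*degenerate")
  expect_error(gn_step(matrix(1, 2, 3), rnorm(2)), "fewer observations")
})

test_that("linearized Peleg fit is closed-form exact and equals one GN step", {
  cv <- noiseless_curve("peleg", table1$peleg$white, t = 1:120)
  lin <- fit_peleg_linear(cv)
  expect_equal(lin$k1, 0.010, tolerance = 1e-12)
  expect_equal(lin$k2, 1.43, tolerance = 1e-12)
  expect_false(lin$near_singular)

  # OLS == a single Gauss-Newton step in the transformed (t/eps vs t) space,
  # which is linear in (k1, k2): start anywhere, one step lands on the OLS fit
  set.seed(8)
  cvn <- simulate_curve(sim_config("peleg", table1$peleg$white, seed = 8))
  linn <- fit_peleg_linear(cvn)
  t <- cvn$time[cvn$time > 0]
  z <- t / cvn$strain[cvn$time > 0]
  start <- c(k1 = 1, k2 = 1)
  Z <- cbind(k1 = rep(1, length(t)), k2 = t)
  step <- gn_step(Z, drop(Z %*% start) - z)
  expect_equal(unname(start + step), c(linn$k1, linn$k2), tolerance = 1e-10)

  # constant strain degenerates the regression (intercept ~ 0)
  flat <- creep_curve(1:10, rep(0.5, 10))
  expect_warning(res <- fit_peleg_linear(flat), "near-singular")
  expect_true(res$near_singular)

  # non-positive strain at t > 0 is a data error
  expect_error(fit_peleg_linear(creep_curve(1:5, c(0, 1, 2, 3, 4) / 10)),
               "positive")
})

test_that("noiseless roundtrips recover generating parameters", {
  # proposed model, all three rice fixtures, eps0 fixed at its fixture value
  spec <- creep_model("powerlaw", fixed = c(eps0 = 0.6))
  for (g in names(table1$powerlaw)) {
    truth <- table1$powerlaw[[g]]
    f <- creep_fit(noiseless_curve("powerlaw", truth), spec)
    expect_true(f$converged)
    expect_lt(rel_err(f$params, truth), 1e-4)
    expect_lt(f$sum_sq, 1e-12)
  }

  # perturbed start x(1.5, 0.7, 1.3, 0.8) still converges to truth
  truth <- table1$powerlaw$white
  f <- creep_fit(noiseless_curve("powerlaw", truth), spec,
                 init = truth * c(1.5, 0.7, 1.3, 0.8))
  expect_lt(rel_err(f$params, truth), 1e-4)
  expect_lt(f$sum_sq, 1e-12)

  # eps0 estimated jointly recovers it too
  f_free <- creep_fit(noiseless_curve("powerlaw", truth),
                      creep_model("powerlaw"))
  expect_lt(rel_err(f_free$params, truth), 1e-4)

  # four-parameter model with its 6-order-of-magnitude parameter spread
  truth <- table1$purkayastha$white
  f <- creep_fit(noiseless_curve("purkayastha", truth), "purkayastha")
  expect_true(f$converged)
  expect_lt(rel_err(f$params, truth), 1e-3)
})

test_that("noiseless identifiability holds on a seeded parameter grid", {
  set.seed(101)
  for (m in names(table1)) {
    base <- table1[[m]][["white"]]
    for (i in 1:10) {
      p <- base * exp(rnorm(length(base), 0, 0.2))
      t <- if (m == "peleg") 1:120 else 0:120
      f <- creep_fit(noiseless_curve(m, p, t), m)
      expect_lt(rel_err(f$params, p), 1e-4)
    }
  }
})

test_that("objective is non-increasing across accepted iterations", {
  set.seed(9)
  for (i in 1:5) {
    cfg <- sim_config("powerlaw", table1$powerlaw$white, seed = 900 + i)
    f <- creep_fit(simulate_curve(cfg),
                   creep_model("powerlaw", fixed = c(eps0 = 0.6)))
    expect_true(all(diff(f$s_path) <= 0))
    expect_lte(f$sum_sq, f$s_path[1])
  }
})

test_that("time rescaling transforms k1 by 60^n and leaves k2, n, eps0", {
  cv_s <- noiseless_curve("powerlaw", table1$powerlaw$white)
  cv_min <- creep_curve(cv_s$time / 60, cv_s$strain)
  spec <- creep_model("powerlaw", fixed = c(eps0 = 0.6))
  f_s <- creep_fit(cv_s, spec)
  f_min <- creep_fit(cv_min, spec)
  expect_equal(f_s$params[["k1"]] / f_min$params[["k1"]],
               60^f_s$params[["n"]], tolerance = 1e-6)
  expect_equal(f_min$params[["n"]], f_s$params[["n"]], tolerance = 1e-6)
  expect_equal(f_min$params[["k2"]], f_s$params[["k2"]], tolerance = 1e-6)
  expect_equal(f_min$params[["eps0"]], f_s$params[["eps0"]])
})

test_that("default initializer is sane and its preconditions hold", {
  # exactly-peleg data: the initializer is already the exact solution
  cv <- noiseless_curve("peleg", table1$peleg$white, t = 1:120)
  expect_equal(unname(creep_init("peleg", cv)), c(0.010, 1.43),
               tolerance = 1e-10)

  # fixture curve: within an order of magnitude of the truth, and GN
  # converges from it
  truth <- table1$powerlaw$white
  cvw <- noiseless_curve("powerlaw", truth)
  init <- creep_init("powerlaw", cvw)
  expect_true(all(init / truth > 0.1 & init / truth < 10))
  expect_true(creep_fit(cvw, creep_model("powerlaw", fixed = c(eps0 = 0.6)),
                        init = init)$converged)

  expect_error(creep_init("powerlaw", creep_curve(1:5, rep(0.3, 5))), "flat")
  expect_error(creep_init("powerlaw",
                          creep_curve(1:5, c(0.5, 0.4, 0.3, 0.2, 0.1))),
               "increase")
})

test_that("non-convergence is reported, not thrown", {
  cfg <- sim_config("powerlaw", table1$powerlaw$white, seed = 3)
  f <- creep_fit(simulate_curve(cfg),
                 creep_model("powerlaw", fixed = c(eps0 = 0.6)),
                 control = gn_control(max_iter = 1))
  expect_false(f$converged)
  expect_s3_class(f, "creep_fit")
})
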