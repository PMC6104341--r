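test_that("power-law model evaluates its closed form and limits", {
  spec <- creep_model("powerlaw")
  p <- c(eps0 = 1, k1 = 41.88, k2 = 6.24, n = 0.59)

  # strain at t = 0 is exactly eps0 (0^n = 0 for n > 0)
  expect_identical(creep_strain(spec, p, 0), 1)
  expect_identical(creep_strain(spec, c(eps0 = 0.37, k1 = 2, k2 = 3,
                                        n = 1.7), 0), 0.37)

  # hand arithmetic of the closed form at t = 120 s:
  # u = 120^0.59; eps = 1 + u/(41.88 + 6.24 u) = 1.114615935627891
  expect_equal(creep_strain(spec, p, 120), 1.114615935627891,
               tolerance = 1e-12)

  # asymptote eps0 (1 + 1/k2), approached by t = 1e12 within 1e-6 relative
  expect_equal(creep_strain(spec, p, 1e12), 1 * (1 + 1 / 6.24),
               tolerance = 1e-6)
})

test_that("Peleg and Purkayastha models evaluate their closed forms", {
  t <- c(0, 1, 10, 120)
  expect_equal(creep_strain(creep_model("peleg"), c(k1 = 0.010, k2 = 1.43),
                            t),
               c(0, 1 / 1.44, 10 / 14.31, 120 / 171.61))
  p <- c(k0 = 0.65, k1 = 0.0001, k2 = 137.8, k3 = 17.21)
  expect_equal(creep_strain(creep_model("purkayastha"), p, t),
               0.65 + 1e-4 * t + t / (137.8 + 17.21 * t))
})

test_that("parameter and time preconditions are enforced", {
  spec <- creep_model("powerlaw")
  expect_error(creep_strain(spec, c(0.6, -1, 6, 0.5), 0:10), "out of bounds")
  expect_error(creep_strain(spec, c(0.6, 41, 6, 0), 0:10), "out of bounds")
  expect_error(creep_strain(spec, c(0.6, 41, 6), 0:10), "expected 4")
  expect_error(creep_strain(spec, c(0.6, 41, 6, 0.5), c(3, 1, 2)), "sorted")
  expect_error(creep_strain(spec, c(0.6, 41, 6, 0.5), c(-1, 0, 1)),
               "non-negative")
  # purkayastha k1 may sit at zero, other parameters may not
  pspec <- creep_model("purkayastha")
  expect_silent(creep_strain(pspec, c(0.65, 0, 137.8, 17.21), 0:10))
  expect_error(creep_strain(pspec, c(0, 1e-4, 137.8, 17.21), 0:10),
               "out of bounds")
})

test_that("analytic Jacobians match closed forms and finite differences", {
  t <- 0:120
  # peleg: d eps/d k1 = -t/(k1 + k2 t)^2, negative for t > 0
  J <- creep_jacobian(creep_model("peleg"), c(k1 = 0.010, k2 = 1.43), t)
  expect_equal(J[, "k1"], ifelse(t > 0, -t / (0.010 + 1.43 * t)^2, 0))
  expect_true(all(J[t > 0, "k1"] < 0))

  # powerlaw at t = 0: d eps/d eps0 = 1, and the n-column is the limit 0
  Jp <- creep_jacobian(creep_model("powerlaw"),
                       c(eps0 = 0.6, k1 = 41.88, k2 = 6.24, n = 0.59), t)
  expect_identical(unname(Jp[1, "eps0"]), 1)
  expect_identical(unname(Jp[1, "n"]), 0)

  # central finite differences on t > 0, every model at its fixture values
  for (m in names(table1)) {
    p <- table1[[m]][["white"]]
    spec <- creep_model(m)
    J <- creep_jacobian(spec, p, t)
    for (k in seq_along(p)) {
      h <- 1e-6 * abs(p[k])
      pp <- p; pp[k] <- p[k] + h
      pm <- p; pm[k] <- p[k] - h
      fd <- (creep_strain(spec, pp, t) - creep_strain(spec, pm, t)) / (2 * h)
      keep <- t > 0 & abs(fd) > 1e-12
      expect_lt(max(abs(J[keep, k] - fd[keep]) / abs(fd[keep])), 1e-4)
    }
  }
})

test_that("derived quantities follow the model algebra", {
  # peleg: asymptotic strain is 1/k2
  d <- creep_derived(creep_model("peleg"), c(k1 = 0.010, k2 = 1.43))
  expect_equal(d$asymptotic_strain, 1 / 1.43)
  expect_identical(d$initial_strain, 0)

  # powerlaw: eps0(1 + 1/k2); k2 -> infinity gives ideal elasticity (no creep)
  d <- creep_derived(creep_model("powerlaw"),
                     c(eps0 = 0.6, k1 = 41.88, k2 = 6.24, n = 0.59))
  expect_equal(d$asymptotic_strain, 0.6 * (1 + 1 / 6.24))
  d_inf <- creep_derived(creep_model("powerlaw"),
                         c(eps0 = 0.6, k1 = 41.88, k2 = 1e12, n = 0.59))
  expect_equal(d_inf$asymptotic_strain, 0.6, tolerance = 1e-11)

  # E0 = stress/eps0; 20 N on a 30-mm probe is 20/(pi 0.015^2) Pa
  stress <- 20 / (pi * 0.015^2)
  d <- creep_derived(creep_model("powerlaw"),
                     c(eps0 = 0.5, k1 = 41.88, k2 = 6.24, n = 0.59),
                     stress = stress)
  expect_equal(d$initial_modulus, stress / 0.5)
  expect_error(creep_derived(creep_model("powerlaw"),
                             c(0.5, 41.88, 6.24, 0.59), stress = -1),
               "positive")

  # purkayastha: unbounded flow for k1 > 0, bounded without it
  expect_identical(
    creep_derived(creep_model("purkayastha"),
                  c(0.65, 1e-4, 137.8, 17.21))$asymptotic_strain, Inf)
  expect_equal(
    creep_derived(creep_model("purkayastha"),
                  c(0.65, 0, 137.8, 17.21))$asymptotic_strain,
    0.65 + 1 / 17.21)
})

test_that("creep is monotone, bounded by its asymptote, and the asymptote
           ignores n", {
  t <- seq(0, 120, by = 0.5)
  set.seed(42)
  for (i in 1:25) {
    p <- c(eps0 = runif(1, 0.1, 1), k1 = exp(runif(1, -2, 5)),
           k2 = exp(runif(1, -2, 3)), n = runif(1, 0.1, 2))
    eps <- creep_strain(creep_model("powerlaw"), p, t)
    expect_true(all(diff(eps) >= 0))
    asy <- creep_derived(creep_model("powerlaw"), p)$asymptotic_strain
    expect_lte(max(eps), asy)

    # same parameters, different n: identical asymptote
    p2 <- p; p2["n"] <- p["n"] * 3
    expect_equal(creep_strain(creep_model("powerlaw"), p2, 1e300),
                 creep_strain(creep_model("powerlaw"), p, 1e300),
                 tolerance = 1e-8)

    pp <- c(k1 = exp(runif(1, -5, 0)), k2 = exp(runif(1, -1, 2)))
    epp <- creep_strain(creep_model("peleg"), pp, t)
    expect_true(all(diff(epp) >= 0))
    expect_lte(max(epp), 1 / pp[["k2"]])
  }
})
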