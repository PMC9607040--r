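test_that("beta-squared identity holds to machine precision on a dense grid", {
  worst <- 0
  for (al in c(0.05, 0.1, 0.3, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2))
    for (R in 10^seq(0, 4.5, length.out = 10))
      for (chi in seq(0, 0.9, length.out = 10))
        for (l1 in c(0, 10^seq(-3, 4, length.out = 9))) {
          p <- flow_params(al, R, chi = chi, lambda1 = l1)
          mc <- mode_constants(p)
          r <- Mod(mc$beta^2 - (al^2 - 1i * al * (1 - 1i * al * l1) * R)) /
            max(Mod(mc$beta2), al^2)
          worst <- max(worst, r)
        }
  expect_lt(worst, 1e-14)
})

test_that("nu satisfies the compatibility relation and matches polyroot", {
  for (p in list(rep_params(), flow_params(1, 1e4, chi = 0.6, lambda1 = 5),
                 flow_params(0.1, 100, chi = 0.001, lambda1 = 0))) {
    mc <- mode_constants(p)
    expect_lt(dispersion_residual(mc), 1e-10)
    # independent root-finder on the dispersion polynomial in nu
    al <- p$alpha; chi <- p$chi
    co <- c(-(mc$gamma * al^2 - 1i * al * chi * mc$beta2), 0,
            mc$gamma - 1i * al * chi)
    roots <- polyroot(co)
    r <- roots[which.min(Mod(roots - mc$nu))]
    expect_lt(Mod(r - mc$nu) / Mod(mc$nu), 1e-10)
  }
})

test_that("branch convention gives non-negative real parts", {
  for (p in figure_grid()) {
    mc <- mode_constants(p)
    expect_gte(Re(mc$beta), 0)
    expect_gte(Re(mc$nu), 0)
  }
})

test_that("the acoustic mode deforms continuously to the incompressible limit", {
  base <- list(alpha = 0.5, reynolds = 10, lambda1 = 0.5)
  nu_at <- function(chi)
    mode_constants(flow_params(0.5, 10, chi = chi, lambda1 = 0.5))$nu
  # Richardson extrapolation of nu(chi) to chi = 0 against nu = alpha
  n1 <- nu_at(1e-8); n2 <- nu_at(1e-10)
  nu0 <- (100 * n2 - n1) / 99
  expect_lt(Mod(nu0 - base$alpha), 1e-8)
  # exact limit
  expect_equal(mode_constants(flow_params(0.5, 10, chi = 0))$nu, 0.5 + 0i,
               tolerance = 1e-14)
})

test_that("constants vary continuously along fine one-parameter sweeps", {
  jump <- function(z) max(Mod(diff(z))) / stats::median(Mod(z))
  nus <- betas <- complex(200)
  als <- seq(0.05, 2, length.out = 200)
  for (i in seq_along(als)) {
    mc <- mode_constants(flow_params(als[i], 100, chi = 0.3, lambda1 = 0.5))
    nus[i] <- mc$nu; betas[i] <- mc$beta
  }
  expect_lt(jump(nus), 0.05)
  expect_lt(jump(betas), 0.05)
  chis <- seq(1e-4, 0.9, length.out = 200)
  for (i in seq_along(chis)) {
    mc <- mode_constants(flow_params(0.5, 1e4, chi = chis[i], lambda1 = 5))
    nus[i] <- mc$nu; betas[i] <- mc$beta
  }
  expect_lt(jump(nus), 0.05)
  expect_lt(jump(betas), 0.05)
})

test_that("constants are variant-independent and Newtonian at lambda1 = 0", {
  p_lin <- flow_params(0.7, 40, chi = 0.2, lambda1 = 0, variant = "linear")
  p_ucm <- flow_params(0.7, 40, chi = 0.2, lambda1 = 0, variant = "ucm")
  m1 <- mode_constants(p_lin); m2 <- mode_constants(p_ucm)
  expect_identical(m1$gamma, m2$gamma)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$nu, m2$nu)
  # Newtonian specialisation of the printed formulas
  expect_identical(m1$gamma, 40 - 1i * 0.7 * 0.2 / 3)
  expect_identical(m1$beta2, 0.7^2 - 1i * 0.7 * 40)
})

test_that("JSON serialisation keeps real and imaginary parts separate", {
  mc <- mode_constants(rep_params())
  js <- jsonlite::fromJSON(mode_constants_json(mc))
  expect_equal(js$beta$re, Re(mc$beta))
  expect_equal(js$beta$im, Im(mc$beta))
  expect_equal(js$nu$re, Re(mc$nu))
})
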