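test_that("the mean forcing is real, even, and variant-blind at lambda1 = 0", {
  y <- seq(-1, 1, length.out = 41)
  for (variant in c("linear", "ucm")) {
    p <- rep_params(variant)
    fo <- first_order(p)
    f <- mean_forcing(fo, y)           # real_part() inside errors if complex
    expect_type(f, "double")
    expect_equal(f, rev(f), tolerance = 1e-10)
  }
  p0l <- flow_params(0.5, 10, chi = 0.3, lambda1 = 0, variant = "linear")
  p0u <- flow_params(0.5, 10, chi = 0.3, lambda1 = 0, variant = "ucm")
  expect_identical(mean_forcing(first_order(p0l), y),
                   mean_forcing(first_order(p0u), y))
})

test_that("the Reynolds-stress part of f matches a finite-difference oracle", {
  p <- rep_params("linear")            # linear variant: f is the d/dy term only
  fo <- first_order(p)
  y <- seq(-0.9, 0.9, length.out = 21)
  h <- 1e-5
  pair <- function(yy) {
    s <- first_order_fields(fo, yy, derivatives = FALSE)
    Re(s$U1 * Conj(s$V1) + Conj(s$U1) * s$V1)
  }
  fd <- (pair(y + h) - pair(y - h)) / (2 * h)
  f <- mean_forcing(fo, y)
  expect_equal(f, fd, tolerance = 1e-6)
})

test_that("the convected block of f matches a finite-difference-free direct formula", {
  p <- rep_params("ucm")
  fo <- first_order(p)
  y <- seq(-0.8, 0.8, length.out = 17)
  s <- first_order_fields(fo, y)
  al <- p$alpha
  blk <- 4 * al^2 * Mod(s$U1)^2 -
    2 * al^2 * 2 * Re(s$U1 * Conj(s$P1)) +
    2i * al * (s$V1 * Conj(s$dU1) - Conj(s$V1) * s$dU1) +
    1i * al * (Conj(s$V1) * s$dP1 - s$V1 * Conj(s$dP1)) -
    2 * Re(s$dU1 * Conj(s$dP1))
  f_lin <- mean_forcing(fo, y, params = rep_params("linear"))
  f_ucm <- mean_forcing(fo, y)
  expect_lt(max(abs(Im(blk))), 1e-12 * max(Mod(blk)))
  expect_equal(f_ucm - f_lin, p$lambda1 * Re(blk), tolerance = 1e-10)
})

test_that("integrate_E reproduces closed forms and the exact path", {
  q <- integrate_E(function(y) rep(1, length(y)))
  expect_equal(q$E1, 0.5, tolerance = 1e-10)
  expect_equal(q$E(c(-0.5, 0.5)), c(0.125, 0.125), tolerance = 1e-10)
  q2 <- integrate_E(function(y) cos(pi * y))
  expect_equal(q2$E(0.7), (1 - cos(0.7 * pi)) / pi^2, tolerance = 1e-10)
})

test_that("closed-form E agrees with adaptive quadrature and brute force", {
  p <- flow_params(0.5, 10, chi = 0.3, lambda1 = 0)   # Fig 2a Newtonian member
  so <- second_order(p)
  g <- seq(-1, 1, length.out = 1025)
  bf <- brute_force_double_integral(so$f, g)
  expect_lt(max(abs(so$E(g) - bf$E)), 1e-8)
  qE <- integrate_E(so$f)
  ys <- c(-0.8, -0.3, 0.4, 1)
  expect_equal(so$E(ys), qE$E(ys), tolerance = 1e-8)
})

test_that("transverse mean flow: D1 vanishes and V20 has the required structure", {
  p <- rep_params()
  so <- second_order(p)
  expect_lt(abs(so$D1), 1e-10)
  expect_lt(abs(so$V20(0)), 1e-14)            # odd function through the origin
  # wall balance: V20(+-1) equals the wave-transfer flux -+Re V1'(+-1)
  w <- first_order_fields(so$field, c(-1, 1))
  expect_equal(so$V20(1), -Re(w$dV1[2]), tolerance = 1e-12)
  expect_equal(so$V20(-1), Re(w$dV1[1]), tolerance = 1e-12)
  # V20 odd
  y <- seq(0.1, 0.9, length.out = 9)
  expect_equal(so$V20(y), -so$V20(-y), tolerance = 1e-12)
  # incompressible limit: V20 identically zero
  so0 <- second_order(flow_params(0.5, 10, chi = 0, lambda1 = 0.5))
  expect_lt(max(abs(so0$V20(seq(-1, 1, 0.25)))), 1e-14)
  expect_lt(abs(mean_transverse_V20(so0$field, 0.5)), 1e-14)
})

test_that("axial wall constants: D2 vanishes, both wall conditions hold", {
  for (p in list(rep_params(), rep_params("linear"),
                 flow_params(1, 1e4, chi = 0.6, lambda1 = 5))) {
    so <- second_order(p)
    expect_lt(abs(so$D2), 1e-10 * max(abs(so$D3), 1))
    w <- first_order_fields(so$field, c(-1, 1))
    expect_lt(abs(so$U20(1) + Re(w$dU1[2])), 1e-10 * max(1, abs(so$D3)))
    expect_lt(abs(so$U20(-1) - Re(w$dU1[1])), 1e-10 * max(1, abs(so$D3)))
    # U20 even
    y <- seq(0.1, 0.9, length.out = 9)
    expect_equal(so$U20(y), so$U20(-y), tolerance = 1e-10)
  }
})

test_that("solve_wall_constants handles the degenerate quiet-wall case", {
  # with E identically zero the constants are set by the wall derivative only
  p <- rep_params()
  fo <- first_order(p)
  cst <- solve_wall_constants(fo, c(0, 0))
  w <- first_order_fields(fo, c(-1, 1))
  expect_equal(unname(cst["D3"]), -Re(w$dU1[2]), tolerance = 1e-12)
  expect_lt(abs(cst[["D2"]]), 1e-12 * max(1, abs(cst[["D3"]])))
  expect_equal(mean_axial_U20(function(y) rep(0, length(y)),
                              cst[["D2"]], cst[["D3"]], p, 0.3),
               cst[["D3"]], tolerance = 1e-14)
})

test_that("mean velocity and flux scale exactly as epsilon squared", {
  base <- list(alpha = 0.5, reynolds = 10, chi = 0.3, lambda1 = 0.5)
  o1 <- observables(as_flow_params(c(base, epsilon = 0.1)))
  o2 <- observables(as_flow_params(c(base, epsilon = 0.2)))
  expect_equal(o2$Q / o1$Q, 4, tolerance = 1e-12)
  y <- seq(-1, 1, length.out = 11)
  expect_equal(o2$mean_u(y), 4 * o1$mean_u(y), tolerance = 1e-12)
})
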