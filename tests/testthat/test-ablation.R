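circle_points <- function(n, a, b, phi = 0, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  base <- cbind(a * cos(th), b * sin(th)) * (1 + rnorm(n, 0, noise))
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  out <- base %*% t(rot)
  data.frame(x = out[, 1], y = out[, 2])
}

test_that("ellipse fitting recovers exact geometry", {
  circ <- fit_ellipse(circle_points(60, 10, 10))
  expect_equal(circ$semi_axes, c(10, 10), tolerance = 1e-6)
  ax <- fit_ellipse(circle_points(100, 20, 10))
  expect_equal(ax$semi_axes, c(20, 10), tolerance = 1e-6)
  expect_equal(ax$orientation, 0, tolerance = 1e-6)
  expect_error(fit_ellipse(data.frame(x = 1:10, y = 2 * (1:10))),
               "degenerate|collinear")
  expect_error(fit_ellipse(data.frame(x = 1:3, y = c(1, 2, 1))),
               "at least 5")
})

test_that("rotated noisy outlines stay within recovery tolerances", {
  pts <- circle_points(100, 20, 10, phi = 30 * pi / 180, noise = 0.01,
                       seed = 4)
  fit <- fit_ellipse(pts)
  expect_equal(fit$semi_axes[1], 20, tolerance = 0.02)
  expect_equal(fit$semi_axes[2], 10, tolerance = 0.02)
  expect_lt(abs(fit$orientation - 30), 2)
  # minimum-enclosing variant agrees on a clean circle
  mvee <- fit_ellipse(circle_points(60, 10, 10), method = "enclosing")
  expect_equal(mvee$semi_axes, c(10, 10), tolerance = 1e-4)
})

test_that("lab-frame deformation matches the closed-form rotation", {
  fit <- fit_ellipse(circle_points(200, 20, 10, phi = 30 * pi / 180))
  lab <- lab_frame_deformation(fit)
  mxx <- 400 * cos(pi / 6)^2 + 100 * sin(pi / 6)^2
  myy <- 400 * sin(pi / 6)^2 + 100 * cos(pi / 6)^2
  expect_equal(lab$L_ap, 2 * sqrt(mxx), tolerance = 1e-4)
  expect_equal(lab$L_dv, 2 * sqrt(myy), tolerance = 1e-4)
  # a circle has no shear in any frame
  circ <- fit_ellipse(circle_points(60, 10, 10))
  expect_equal(lab_frame_deformation(circ, rotation_deg = 37)$shear, 0,
               tolerance = 1e-6)
  # trace is invariant under co-rotation
  l0 <- lab_frame_deformation(fit, 0)
  l1 <- lab_frame_deformation(fit, 25)
  expect_equal(l0$L_ap^2 + l0$L_dv^2, l1$L_ap^2 + l1$L_dv^2,
               tolerance = 1e-9)
})

test_that("hencky strain obeys its algebra", {
  expect_equal(hencky_strain(10, 10), 0)
  expect_equal(hencky_strain(exp(1) * 5, 5), 1, tolerance = 1e-12)
  expect_equal(hencky_strain(45.54, 41.21), 0.0999, tolerance = 1e-3)
  # antisymmetry and additivity along a path
  expect_equal(hencky_strain(45, 41), -hencky_strain(41, 45))
  expect_equal(hencky_strain(45, 41),
               hencky_strain(45, 43) + hencky_strain(43, 41),
               tolerance = 1e-12)
  expect_error(hencky_strain(-1, 5), "positive")
})

test_that("recoil velocities are plain finite differences", {
  rs <- recoil_series(c(50, 48, 47), dt = 5)
  expect_equal(rs$velocity$velocity, c(-0.4, -0.2))
  expect_equal(rs$velocity$speed, c(0.4, 0.2))
  flat <- recoil_series(rep(30, 5), dt = 2)
  expect_true(all(flat$velocity$velocity == 0))
  # exponential relaxation decays geometrically frame over frame
  s <- gen_ablation_series(50, 41, tau = 30, dt = 5, n_frames = 12)
  v <- recoil_series(s$length, dt = 5)$velocity$velocity
  expect_equal(v[-1] / v[-length(v)], rep(exp(-5 / 30), length(v) - 1),
               tolerance = 1e-9)
})

test_that("relaxation time recovers the generating timescale", {
  s <- gen_ablation_series(50, 41, tau = 30, dt = 5, n_frames = 20)
  tau <- relaxation_time(recoil_series(s$length, dt = 5))
  # discrete mid-frame estimator closed form, -> tau as dt -> 0
  delta <- 5 / 30
  expect_equal(as.numeric(tau),
               5 * (1 + exp(-delta)) / (2 * (1 - exp(-delta))),
               tolerance = 1e-9)
  expect_equal(as.numeric(tau), 30, tolerance = 0.005)
  fine <- gen_ablation_series(50, 41, tau = 30, dt = 0.1, n_frames = 600)
  expect_equal(as.numeric(relaxation_time(recoil_series(fine$length, 0.1))),
               30, tolerance = 1e-4)
  # constant-velocity series has no defined relaxation time
  lin <- recoil_series(seq(50, 45, length.out = 10), dt = 5)
  expect_true(is.na(relaxation_time(lin)))
  # 1% noise, 60 frames: within 10%
  noisy <- gen_ablation_series(50, 41, tau = 30, dt = 2, n_frames = 60,
                               sigma = 0.5 * 0.01 * 50, seed = 3)
  tn <- relaxation_time(recoil_series(noisy$length, dt = 2))
  expect_equal(as.numeric(tn), 30, tolerance = 0.1)
})

test_that("junction recoil estimators agree on exponential separations", {
  a <- data.frame(x = c(0, 0), y = c(0, 0))
  b <- data.frame(x = c(2, 2.6), y = c(0, 0))
  expect_equal(junction_recoil(a, b, dt = 0.5), 1.2)
  static <- data.frame(x = rep(1, 4), y = rep(0, 4))
  expect_equal(junction_recoil(static, static + 2, dt = 0.5), 0)
  # exponential separation: fitted v0 matches the analytic initial slope
  tau <- 4; d0 <- 2; dinf <- 5
  tt <- seq(0, 10, by = 0.5)
  d <- dinf - (dinf - d0) * exp(-tt / tau)
  va <- data.frame(x = rep(0, length(tt)), y = 0)
  vb <- data.frame(x = d, y = 0)
  v0 <- junction_recoil(va, vb, dt = 0.5, mode = "exponential_fit")
  expect_equal(v0, (dinf - d0) / tau, tolerance = 0.05 * (dinf - d0) / tau)
})
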