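#' Fit an ellipse to boundary points
#'
#' Default method is the direct least-squares conic fit constrained to an
#' ellipse (numerically stable Fitzgibbon formulation), applied to the
#' segmented outline of an excised tissue disc or larval epidermal cell.
#' `method = "enclosing"` instead computes the minimum-area enclosing
#' ellipse (Khachiyan iteration), for workflows that interpret the bounding
#' outline strictly.
#'
#' @param points Data frame or matrix with columns `x`, `y` (\eqn{\mu m});
#'   at least 5 non-collinear points.
#' @param method `"direct"` (least-squares, default) or `"enclosing"`.
#' @return An `ellipse_fit`: list with `center` (length-2), `shape_tensor`
#'   (symmetric positive-definite 2x2 with eigenvalues equal to the squared
#'   semi-axes, \eqn{\mu m^2}), `semi_axes` (long, short; \eqn{\mu m}) and
#'   `orientation` (degrees of the long axis from the x/AP axis, in
#'   (-90, 90]).
#' @export
fit_ellipse <- function(points, method = c("direct", "enclosing")) {
  method <- match.arg(method)
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  if (nrow(pts) < 5) abort("need at least 5 points")
  ctr <- colMeans(pts)
  p <- sweep(pts, 2, ctr)
  if (rcond_2x2(crossprod(p) / nrow(p)) < 1e-12) {
    abort("degenerate (collinear) points: ellipse fit impossible")
  }
  fit <- if (method == "direct") fit_ellipse_direct(p) else fit_ellipse_mvee(p)
  fit$center <- fit$center + ctr
  fit
}

rcond_2x2 <- function(m) {
  e <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(e)) == 0) return(0)
  min(abs(e)) / max(abs(e))
}

# stable direct least-squares ellipse fit on centred points
fit_ellipse_direct <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  tmat <- -solve(s3, t(s2))
  m <- s1 + s2 %*% tmat
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2) # inv(C1) %*% M
  ev <- eigen(m)
  v <- Re(ev$vectors)
  cond <- 4 * v[1, ] * v[3, ] - v[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0) abort("no ellipse solution: degenerate input")
  a1 <- v[, k[1]]
  coefs <- c(a1, as.numeric(tmat %*% a1)) # a b c d e f
  conic_to_ellipse(coefs)
}

conic_to_ellipse <- function(cf) {
  a <- cf[1]; b <- cf[2]; cc <- cf[3]; d <- cf[4]; e <- cf[5]; f <- cf[6]
  amat <- matrix(c(a, b / 2, b / 2, cc), 2)
  ctr <- solve(2 * amat, -c(d, e))
  fc <- a * ctr[1]^2 + b * ctr[1] * ctr[2] + cc * ctr[2]^2 +
    d * ctr[1] + e * ctr[2] + f
  q <- amat / (-fc) # (x-c)' Q (x-c) = 1
  eg <- eigen(q, symmetric = TRUE)
  if (any(eg$values <= 0)) abort("no ellipse solution: degenerate input")
  axes <- 1 / sqrt(eg$values) # ascending eigenvalue = long axis first
  long_vec <- eg$vectors[, which.min(eg$values)]
  ang <- atan2(long_vec[2], long_vec[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  if (ang <= -90) ang <- ang + 180
  semi <- sort(axes, decreasing = TRUE)
  rot <- matrix(c(cos(ang * pi / 180), sin(ang * pi / 180),
                  -sin(ang * pi / 180), cos(ang * pi / 180)), 2)
  s <- rot %*% diag(semi^2) %*% t(rot)
  structure(list(center = as.numeric(ctr), shape_tensor = s,
                 semi_axes = semi, orientation = ang),
            class = "ellipse_fit")
}

# minimum-volume enclosing ellipse (Khachiyan)
fit_ellipse_mvee <- function(p, tol = 1e-7, max_iter = 2000) {
  n <- nrow(p)
  q <- rbind(t(p), 1)
  u <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    xmat <- q %*% (u * t(q))
    m <- colSums(q * solve(xmat, q))
    j <- which.max(m)
    step <- (m[j] - 3) / (3 * (m[j] - 1))
    if (step < tol) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  c0 <- as.numeric(t(p) %*% u)
  amat <- solve(t(p) %*% (u * p) - tcrossprod(c0)) / 2
  eg <- eigen(amat, symmetric = TRUE)
  axes <- 1 / sqrt(eg$values)
  long_vec <- eg$vectors[, which.min(eg$values)]
  ang <- atan2(long_vec[2], long_vec[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  semi <- sort(axes, decreasing = TRUE)
  rot <- matrix(c(cos(ang * pi / 180), sin(ang * pi / 180),
                  -sin(ang * pi / 180), cos(ang * pi / 180)), 2)
  s <- rot %*% diag(semi^2) %*% t(rot)
  structure(list(center = c0, shape_tensor = s, semi_axes = semi,
                 orientation = ang),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat("<ellipse_fit> semi-axes ", round(x$semi_axes[1], 3), " x ",
      round(x$semi_axes[2], 3), ", orientation ",
      round(x$orientation, 2), " deg\n", sep = "")
  invisible(x)
}

#' @rdname fit_ellipse
#' @param x An `ellipse_fit`.
#' @param ... Unused.
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    center_x = x$center[1], center_y = x$center[2],
    semi_long = x$semi_axes[1], semi_short = x$semi_axes[2],
    orientation_deg = x$orientation
  )
}

#' Axis lengths of an ellipse in the lab (AP/DV) frame
#'
#' Rotates the ellipse shape tensor into the lab frame,
#' `M' = R M t(R)`, and converts the diagonal entries into full axis
#' lengths along x (anterior-posterior) and y (dorsal-ventral); the
#' normalized off-diagonal entry is reported as the shear component, which
#' for near-axis-aligned tissue deformations is close to zero.
#'
#' @param ellipse An `ellipse_fit` from [fit_ellipse()].
#' @param rotation_deg Additional rotation applied to the lab frame
#'   (degrees, anticlockwise); 0 keeps the fitted frame.
#' @return One-row tibble with `L_ap`, `L_dv` (\eqn{\mu m}) and `shear`
#'   (dimensionless).
#' @export
lab_frame_deformation <- function(ellipse, rotation_deg = 0) {
  th <- rotation_deg * pi / 180
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m <- r %*% ellipse$shape_tensor %*% t(r)
  tibble::tibble(
    L_ap = 2 * sqrt(m[1, 1]),
    L_dv = 2 * sqrt(m[2, 2]),
    shear = m[1, 2] / sqrt(m[1, 1] * m[2, 2])
  )
}

#' Hencky (true) strain
#'
#' `epsilon = ln(L / L_r)`: the natural log of the non-ablated axis length
#' over the relaxed axis length. Positive strain means the tissue was
#' stretched before ablation (it relaxes inward). Hencky strains are
#' additive along a deformation path and antisymmetric under exchanging the
#' two states.
#'
#' @param l Non-ablated (reference) axis length, > 0.
#' @param l_relaxed Relaxed axis length, > 0.
#' @return Dimensionless strain(s).
#' @export
hencky_strain <- function(l, l_relaxed) {
  if (any(l <= 0) || any(l_relaxed <= 0)) abort("lengths must be positive")
  log(l / l_relaxed)
}

#' Recoil of an ablated axis over time
#'
#' Converts a per-frame axis-length series into recoil velocities between
#' successive frames: `v_i = (L_{i+1} - L_i) / dt` (signed; a stretched disc
#' relaxing inward gives negative velocities — the `speed` column carries
#' the magnitude). Velocities are interval quantities and are attached to
#' the mid-frame time and mid-frame length.
#'
#' @param lengths Axis length per frame (\eqn{\mu m}), >= 2 frames.
#' @param dt Frame interval (s), > 0.
#' @param t0 Time of the first frame (s).
#' @return A `recoil_series`: list with `frames` (tibble `time`, `length`)
#'   and `velocity` (tibble `mid_time`, `mid_length`, `velocity`, `speed`).
#' @export
recoil_series <- function(lengths, dt, t0 = 0) {
  if (length(lengths) < 2) abort("need at least 2 frames")
  if (dt <= 0) abort("dt must be positive")
  n <- length(lengths)
  tt <- t0 + (seq_len(n) - 1) * dt
  v <- diff(lengths) / dt
  structure(
    list(
      frames = tibble::tibble(time = tt, length = lengths),
      velocity = tibble::tibble(
        mid_time = (tt[-n] + tt[-1]) / 2,
        mid_length = (lengths[-n] + lengths[-1]) / 2,
        velocity = v,
        speed = abs(v)
      ),
      dt = dt
    ),
    class = "recoil_series"
  )
}

#' @export
print.recoil_series <- function(x, ...) {
  cat("<recoil_series> ", nrow(x$frames), " frames, dt = ", x$dt, " s\n",
      sep = "")
  invisible(x)
}

#' Relaxation time from a recoil series
#'
#' Fits an ordinary least-squares line to recoil velocity as a function of
#' mid-frame axis length and returns the inverse of the absolute gradient.
#' For an exponentially relaxing (Kelvin-Voigt-like) axis the velocity is
#' linear in length with slope `-1/tau`, so the estimator recovers the
#' relaxation time (exactly as the frame interval becomes small). A slope
#' whose magnitude falls below `tol` means no detectable relaxation and the
#' relaxation time is reported as `NA`.
#'
#' @param series A [recoil_series()].
#' @param tol Minimum absolute slope (1/s) for a defined relaxation time.
#' @return Relaxation time (s), or `NA` if undefined; the fitted slope and
#'   intercept are attached as attributes.
#' @export
relaxation_time <- function(series, tol = 1e-8) {
  v <- series$velocity
  if (nrow(v) < 3) abort("need at least 3 velocity points")
  if (sd(v$mid_length) == 0) abort("no length variation")
  fit <- lm(velocity ~ mid_length, data = v)
  slope <- coef(fit)[["mid_length"]]
  tau <- if (abs(slope) < tol) NA_real_ else 1 / abs(slope)
  attr(tau, "slope") <- slope
  attr(tau, "intercept") <- coef(fit)[[1]]
  tau
}

#' Initial recoil velocity of an ablated junction
#'
#' Tracks the separation of the two vertices flanking a cut junction and
#' estimates the initial recoil velocity, either from the first frame
#' interval (default) or from the initial slope of an exponential fit
#' `d(t) = d_inf - (d_inf - d0) exp(-t/tau)`, whose analytic initial slope
#' is `(d_inf - d0)/tau`. If the exponential fit fails to converge the
#' first-interval estimate is returned with a warning.
#'
#' @param vertex_a,vertex_b Data frames or matrices of per-frame vertex
#'   positions with columns `x`, `y` (\eqn{\mu m}).
#' @param dt Frame interval (s).
#' @param mode `"first_interval"` or `"exponential_fit"` (needs >= 5
#'   frames).
#' @return Recoil velocity v0 (\eqn{\mu m/s}).
#' @export
junction_recoil <- function(vertex_a, vertex_b, dt,
                            mode = c("first_interval", "exponential_fit")) {
  mode <- match.arg(mode)
  a <- as.matrix(as.data.frame(vertex_a)[, c("x", "y")])
  b <- as.matrix(as.data.frame(vertex_b)[, c("x", "y")])
  if (nrow(a) != nrow(b)) abort("vertex series have different lengths")
  d <- sqrt(rowSums((a - b)^2))
  n <- length(d)
  if (n < 2) abort("need at least 2 frames")
  v_first <- (d[2] - d[1]) / dt
  if (mode == "first_interval") return(v_first)
  if (n < 5) abort("exponential_fit needs at least 5 frames")
  tt <- (seq_len(n) - 1) * dt
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ dinf - (dinf - d0) * exp(-tt / tau),
      data = data.frame(d = d, tt = tt),
      start = list(d0 = d[1], dinf = d[n], tau = max(tt) / 3),
      lower = c(d0 = 0, dinf = 0, tau = dt / 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("exponential fit diverged: falling back to first_interval")
    return(v_first)
  }
  cf <- coef(fit)
  (cf[["dinf"]] - cf[["d0"]]) / cf[["tau"]]
}
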