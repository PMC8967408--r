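#' Dimensionless parameters of the elastic-foundation disc model
#'
#' The excised tissue disc is modelled as a 2D linear elastic material
#' (area modulus \eqn{\bar K}, shear modulus \eqn{\bar\mu}) carrying a
#' uniform anisotropic active tension \eqn{diag(\zeta_x, \zeta_y)} and
#' tethered to its substrate by elastic links of stiffness per area k.
#' Lengths are normalized by the disc radius R and stresses by \eqn{\bar K},
#' so the free parameters are `k_hat` = \eqn{k R^2/\bar K},
#' `zeta_x_hat` = \eqn{\zeta_x/\bar K}, `zeta_y_hat` = \eqn{\zeta_y/\bar K}
#' and `mu_hat` = \eqn{\bar\mu/\bar K} (fixed at 1 by default).
#'
#' @param k_hat Dimensionless foundation stiffness, >= 0.
#' @param zeta_x_hat,zeta_y_hat Dimensionless active tensions along the AP
#'   (x) and DV (y) axes.
#' @param mu_hat Dimensionless shear modulus, > 0.
#' @return A `continuum_params` list.
#' @export
continuum_params <- function(k_hat, zeta_x_hat, zeta_y_hat, mu_hat = 1) {
  stopifnot(k_hat >= 0, mu_hat > 0)
  structure(list(k_hat = k_hat, zeta_x_hat = zeta_x_hat,
                 zeta_y_hat = zeta_y_hat, mu_hat = mu_hat),
            class = "continuum_params")
}

# structured polar mesh of the unit disc: centre node + n_radial rings of
# n_angular nodes each
disc_mesh <- function(n_radial = 32, n_angular = 2 * n_radial) {
  r <- seq_len(n_radial) / n_radial
  th <- 2 * pi * (seq_len(n_angular) - 1) / n_angular
  nodes <- rbind(
    c(0, 0),
    cbind(rep(r, each = n_angular) * cos(th),
          rep(r, each = n_angular) * sin(th))
  )
  node_id <- function(i, j) { # ring i >= 1, angular j (1-based, wraps)
    1L + (i - 1L) * n_angular + ((j - 1L) %% n_angular) + 1L
  }
  tri <- vector("list", n_radial)
  j <- seq_len(n_angular)
  tri[[1]] <- cbind(1L, node_id(1L, j), node_id(1L, j + 1L))
  for (i in seq_len(n_radial - 1L)) {
    a <- node_id(i, j); b <- node_id(i, j + 1L)
    c2 <- node_id(i + 1L, j); d <- node_id(i + 1L, j + 1L)
    tri[[i + 1L]] <- rbind(cbind(a, c2, d), cbind(a, d, b))
  }
  tri <- do.call(rbind, tri)
  boundary <- node_id(n_radial, j)
  list(nodes = nodes, tri = tri, boundary = boundary,
       n_radial = n_radial, n_angular = n_angular)
}

# assemble stiffness, lumped foundation mass and active-tension load vectors
disc_system <- function(mu_hat = 1, resolution = 32) {
  mesh <- disc_mesh(resolution)
  nodes <- mesh$nodes
  tri <- mesh$tri
  ne <- nrow(tri)
  nn <- nrow(nodes)
  kbar <- 1
  dmat <- matrix(c(kbar + mu_hat, kbar - mu_hat, 0,
                   kbar - mu_hat, kbar + mu_hat, 0,
                   0, 0, mu_hat), 3, 3)
  x <- matrix(nodes[tri, 1], ne, 3)
  y <- matrix(nodes[tri, 2], ne, 3)
  b1 <- y[, 2] - y[, 3]; b2 <- y[, 3] - y[, 1]; b3 <- y[, 1] - y[, 2]
  c1 <- x[, 3] - x[, 2]; c2 <- x[, 1] - x[, 3]; c3 <- x[, 2] - x[, 1]
  area2 <- x[, 1] * b1 + x[, 2] * b2 + x[, 3] * b3 # 2 * area (signed)
  area <- area2 / 2
  bb <- cbind(b1, b2, b3) / area2 # dN_i/dx per element
  cc <- cbind(c1, c2, c3) / area2 # dN_i/dy per element

  # element stiffness entries K_e[p, q] for dof pairs; assemble via triplets
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  idx <- function(node, comp) 2L * (node - 1L) + comp
  for (p in 1:3) {
    for (q in 1:3) {
      # B_p' D B_q, with B_p = [[b_p, 0], [0, c_p], [c_p, b_p]]
      kxx <- dmat[1, 1] * bb[, p] * bb[, q] + dmat[3, 3] * cc[, p] * cc[, q]
      kxy <- dmat[1, 2] * bb[, p] * cc[, q] + dmat[3, 3] * cc[, p] * bb[, q]
      kyx <- dmat[1, 2] * cc[, p] * bb[, q] + dmat[3, 3] * bb[, p] * cc[, q]
      kyy <- dmat[1, 1] * cc[, p] * cc[, q] + dmat[3, 3] * bb[, p] * bb[, q]
      np <- tri[, p]; nq <- tri[, q]
      ii <- c(ii, idx(np, 1L), idx(np, 1L), idx(np, 2L), idx(np, 2L))
      jj <- c(jj, idx(nq, 1L), idx(nq, 2L), idx(nq, 1L), idx(nq, 2L))
      vv <- c(vv, kxx * area, kxy * area, kyx * area, kyy * area)
    }
  }
  kmat <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(2 * nn, 2 * nn))

  # lumped foundation mass: area/3 to each vertex, both components
  mdiag <- numeric(2 * nn)
  mnode <- numeric(nn)
  for (p in 1:3) {
    acc <- rowsum_at(area / 3, tri[, p], nn)
    mnode <- mnode + acc
  }
  mdiag[seq(1, 2 * nn, by = 2)] <- mnode
  mdiag[seq(2, 2 * nn, by = 2)] <- mnode

  # load vectors for unit zeta_x and unit zeta_y:
  # f_v = -int sigma_a : eps(v) dA  ->  per element, node p:
  #   fx(p) = -zeta_x * b_p * area ; fy(p) = -zeta_y * c_p * area
  fx <- numeric(2 * nn)
  fy <- numeric(2 * nn)
  for (p in 1:3) {
    fx[seq(1, 2 * nn, by = 2)] <- fx[seq(1, 2 * nn, by = 2)] -
      rowsum_at(bb[, p] * area, tri[, p], nn)
    fy[seq(2, 2 * nn, by = 2)] <- fy[seq(2, 2 * nn, by = 2)] -
      rowsum_at(cc[, p] * area, tri[, p], nn)
  }

  centroids <- cbind(rowMeans(x), rowMeans(y))
  list(mesh = mesh, kmat = kmat, mdiag = mdiag, fx = fx, fy = fy,
       bb = bb, cc = cc, tri = tri, centroids = centroids,
       mu_hat = mu_hat, nn = nn)
}

rowsum_at <- function(vals, index, n) {
  out <- numeric(n)
  agg <- rowsum(vals, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# strains per element from a nodal displacement vector
element_strains <- function(sys, u) {
  ux <- matrix(u[2L * (sys$tri - 1L) + 1L], nrow(sys$tri), 3)
  uy <- matrix(u[2L * (sys$tri - 1L) + 2L], nrow(sys$tri), 3)
  exx <- rowSums(sys$bb * ux)
  eyy <- rowSums(sys$cc * uy)
  exy <- 0.5 * (rowSums(sys$cc * ux) + rowSums(sys$bb * uy))
  list(exx = exx, eyy = eyy, exy = exy)
}

solve_system <- function(sys, k_hat, zeta_x, zeta_y) {
  amat <- sys$kmat + Matrix::Diagonal(x = sys$mdiag * k_hat)
  as.numeric(Matrix::solve(amat, zeta_x * sys$fx + zeta_y * sys$fy))
}

# uniform-strain closed form for the free disc (k = 0)
free_disc_field <- function(sys, params) {
  ziso <- (params$zeta_x_hat + params$zeta_y_hat) / 2
  zdev <- (params$zeta_x_hat - params$zeta_y_hat) / 2
  tr <- -ziso / 1
  dev <- -zdev / params$mu_hat
  exx <- (tr + dev) / 2
  eyy <- (tr - dev) / 2
  u <- numeric(2 * sys$nn)
  u[seq(1, 2 * sys$nn, by = 2)] <- exx * sys$mesh$nodes[, 1]
  u[seq(2, 2 * sys$nn, by = 2)] <- eyy * sys$mesh$nodes[, 2]
  u
}

#' Solve the elastic disc under active tension on an elastic foundation
#'
#' Solves linear mechanical equilibrium on the unit disc: the divergence of
#' the elastic stress plus the uniform active tension balances the
#' foundation restoring force `k u`, with zero total traction on the rim
#' (post-ablation free boundary). Discretization is a linear-triangle finite
#' element method on a structured polar mesh; `k_hat = 0` uses the exact
#' uniform-strain solution of the free disc.
#'
#' @param params A [continuum_params()].
#' @param resolution Number of radial element rings (default 32; the angular
#'   resolution is twice that).
#' @return A `deformation_field`: tibble with one row per element centroid —
#'   `x`, `y`, `r` (normalized by disc radius), `ux`, `uy` (displacement),
#'   `area_change` (relative area change, the strain trace),
#'   `exx_minus_eyy` and `exy` (anisotropic/traceless strain components) —
#'   with attributes `ring_displacement` (mean radial displacement of the
#'   rim), `params`, and the solver system for downstream prediction.
#' @export
solve_disc <- function(params, resolution = 32) {
  sys <- disc_system(params$mu_hat, resolution)
  u <- if (params$k_hat < 1e-12) {
    free_disc_field(sys, params)
  } else {
    solve_system(sys, params$k_hat, params$zeta_x_hat, params$zeta_y_hat)
  }
  field_from_solution(sys, u, params)
}

field_from_solution <- function(sys, u, params) {
  st <- element_strains(sys, u)
  cen <- sys$centroids
  ux_c <- rowMeans(matrix(u[2L * (sys$tri - 1L) + 1L], nrow(sys$tri), 3))
  uy_c <- rowMeans(matrix(u[2L * (sys$tri - 1L) + 2L], nrow(sys$tri), 3))
  out <- tibble::tibble(
    x = cen[, 1], y = cen[, 2], r = sqrt(cen[, 1]^2 + cen[, 2]^2),
    ux = ux_c, uy = uy_c,
    area_change = st$exx + st$eyy,
    exx_minus_eyy = st$exx - st$eyy,
    exy = st$exy
  )
  bn <- sys$mesh$boundary
  bx <- sys$mesh$nodes[bn, 1]; by <- sys$mesh$nodes[bn, 2]
  ur <- u[2L * (bn - 1L) + 1L] * bx + u[2L * (bn - 1L) + 2L] * by
  structure(out,
            ring_displacement = mean(ur),
            params = params,
            nodal_u = u,
            system = sys,
            class = c("deformation_field", class(out)))
}

#' Closed-form axisymmetric displacement profile
#'
#' Independent reference solution for [solve_disc()] under isotropic active
#' tension. The axisymmetric radial equilibrium reduces to a modified Bessel
#' equation of order one with decay parameter
#' \eqn{\lambda = \sqrt{k / (\bar K + \bar\mu)}} (normalized units), giving
#' `u_r(r) = A I_1(lambda r)` with the constant fixed by the free-rim
#' traction condition
#' \eqn{(\bar K + \bar\mu) u' + (\bar K - \bar\mu) u/r = -\zeta} at r = 1.
#' At `k_hat = 0` the profile degenerates to the linear free-disc solution
#' `u_r = -zeta_iso r / 2`.
#'
#' @param k_hat Dimensionless foundation stiffness, >= 0.
#' @param zeta_iso Isotropic active tension / \eqn{\bar K}.
#' @param mu_hat Shear modulus / \eqn{\bar K}.
#' @param r Radial grid (normalized), defaults to 200 points on (0, 1].
#' @return Tibble with `r` and `u_r`.
#' @export
axisym_reference <- function(k_hat, zeta_iso, mu_hat = 1,
                             r = seq(0.005, 1, length.out = 200)) {
  stopifnot(k_hat >= 0)
  if (k_hat < 1e-12) {
    return(tibble::tibble(r = r, u_r = -zeta_iso * r / 2))
  }
  lam <- sqrt(k_hat / (1 + mu_hat))
  i1p <- besselI(lam, 0) - besselI(lam, 1) / lam
  aa <- -zeta_iso / ((1 + mu_hat) * lam * i1p + (1 - mu_hat) * besselI(lam, 1))
  tibble::tibble(r = r, u_r = aa * besselI(lam * r, 1))
}

# evaluate a field at arbitrary points: values of the nearest element
# centroid (strains are piecewise constant on the linear-triangle mesh)
predict_field_at <- function(field, points) {
  px <- points[, 1]; py <- points[, 2]
  fx <- field$x; fy <- field$y
  idx <- vapply(seq_along(px), function(i) {
    which.min((fx - px[i])^2 + (fy - py[i])^2)
  }, integer(1))
  field[idx, c("ux", "uy", "area_change", "exx_minus_eyy", "exy")]
}

#' Bin a deformation field into radial (and angular) profiles
#'
#' Averages the relative area change and the anisotropic strain component
#' over equal-width radial bins, and optionally over angular bins, returning
#' the spatial profiles that the model is fitted to, together with the rim
#' (outer-ring) displacement.
#'
#' @param field A `deformation_field` (from [solve_disc()],
#'   [gen_deformation()] or read from file).
#' @param n_r_bins Number of radial bins on `[0, 1]`.
#' @param n_theta_bins Optional number of angular bins for an angular
#'   profile (folded to `[0, pi)`; orientation is axial).
#' @return List with `radial` (tibble `bin`, `r_mid`, `area_change`,
#'   `elongation`, `n`), `angular` (or `NULL`) and `ring_displacement`.
#' @export
sample_observables <- function(field, n_r_bins = 8, n_theta_bins = NULL) {
  r <- sqrt(field$x^2 + field$y^2)
  bin <- pmin(pmax(ceiling(r * n_r_bins), 1L), n_r_bins)
  radial <- tibble::tibble(bin = bin,
                           area_change = field$area_change,
                           elongation = field$exx_minus_eyy) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      area_change = mean(.data$area_change),
      elongation = mean(.data$elongation),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(r_mid = (.data$bin - 0.5) / n_r_bins, .after = "bin")
  empty <- setdiff(seq_len(n_r_bins), radial$bin)
  if (length(empty) > 0) {
    warn(paste0("empty radial bin(s): ", paste(empty, collapse = ", ")))
  }
  angular <- NULL
  if (!is.null(n_theta_bins)) {
    th <- atan2(field$y, field$x) %% pi
    tbin <- pmin(floor(th / pi * n_theta_bins) + 1L, n_theta_bins)
    angular <- tibble::tibble(bin = tbin,
                              area_change = field$area_change) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(area_change = mean(.data$area_change),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(theta_mid = (.data$bin - 0.5) * pi / n_theta_bins,
                    .after = "bin")
  }
  list(radial = radial, angular = angular,
       ring_displacement = attr(field, "ring_displacement"))
}

#' Edge localization of the post-ablation area change
#'
#' Ratio of the mean absolute relative area change in the outer 25% radial
#' annulus (r > 0.75) to that in the inner half-radius disc (r <= 0.5).
#' A homogeneous contraction gives 1; a stiff foundation confines the
#' deformation to the rim and drives the index far above 1. Returns `Inf`
#' (with a warning) if the inner mean vanishes.
#'
#' @param field A `deformation_field`.
#' @return Dimensionless ratio.
#' @export
edge_localization_index <- function(field) {
  r <- sqrt(field$x^2 + field$y^2)
  outer_mean <- mean(abs(field$area_change[r > 0.75]))
  inner_mean <- mean(abs(field$area_change[r <= 0.5]))
  if (inner_mean == 0) {
    warn("inner-disc mean area change is zero")
    return(Inf)
  }
  outer_mean / inner_mean
}

#' Fit the elastic-foundation disc model to an observed deformation field
#'
#' Nonlinear least squares over `(k_hat, zeta_x_hat, zeta_y_hat)` with
#' `mu_hat` held fixed. The objective stacks three observable blocks —
#' radially binned relative area change, radially binned anisotropic strain
#' `exx - eyy`, and the rim displacement — each normalized by the empirical
#' spread of its observed values so heterogeneous units carry comparable
#' weight. Because the forward model is linear in the active tensions, the
#' tensions are profiled out by linear least squares at each candidate
#' `k_hat`; `k_hat` itself is found by a coarse logarithmic grid search
#' refined with one-dimensional optimization. When the objective is flat in
#' `k_hat` (nearly uniform deformation), the fit is flagged as weakly
#' identified instead of failing. Optional bootstrap over sample points
#' gives percentile confidence intervals.
#'
#' @param observed A `deformation_field` or data frame with columns `x`,
#'   `y`, `area_change`, `exx_minus_eyy`; a `ring_displacement` attribute
#'   is used when present.
#' @param mu_hat Fixed shear modulus ratio.
#' @param resolution Forward-solver resolution (radial rings).
#' @param n_r_bins Radial bins per block.
#' @param k_grid Candidate `k_hat` grid for the coarse search.
#' @param n_boot Bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap resampling.
#' @return A `continuum_fit`: list with `params` ([continuum_params()]),
#'   `residual`, `k_flat` (logical identifiability flag), `boot`
#'   (tibble of replicates or `NULL`) and `ci` (tibble or `NULL`).
#'   Supports [tidy()] and [glance()].
#' @export
fit_continuum <- function(observed, mu_hat = 1, resolution = 32,
                          n_r_bins = 8,
                          k_grid = 10^seq(-2, 2, length.out = 13),
                          n_boot = 0, seed = NULL) {
  obs <- tibble::as_tibble(observed)
  if (nrow(obs) < 20) abort("need at least 20 sample points")
  ring_obs <- attr(observed, "ring_displacement")
  sys <- disc_system(mu_hat, resolution)

  # model fields for unit zeta_x / zeta_y at each k, evaluated at the
  # observed points, cached across bootstrap replicates
  pts <- cbind(obs$x, obs$y)
  cen_idx <- vapply(seq_len(nrow(pts)), function(i) {
    which.min((sys$centroids[, 1] - pts[i, 1])^2 +
                (sys$centroids[, 2] - pts[i, 2])^2)
  }, integer(1))
  unit_cache <- new.env(parent = emptyenv())
  unit_at <- function(k_hat) {
    key <- sprintf("%.12g", k_hat)
    if (!is.null(unit_cache[[key]])) return(unit_cache[[key]])
    u_x <- solve_system(sys, k_hat, 1, 0)
    u_y <- solve_system(sys, k_hat, 0, 1)
    comp <- function(u) {
      st <- element_strains(sys, u)
      bn <- sys$mesh$boundary
      ur <- u[2L * (bn - 1L) + 1L] * sys$mesh$nodes[bn, 1] +
        u[2L * (bn - 1L) + 2L] * sys$mesh$nodes[bn, 2]
      list(area = (st$exx + st$eyy)[cen_idx],
           elong = (st$exx - st$eyy)[cen_idx],
           ring = mean(ur))
    }
    out <- list(x = comp(u_x), y = comp(u_y))
    unit_cache[[key]] <- out
    out
  }

  r_obs <- sqrt(obs$x^2 + obs$y^2)
  bin <- pmin(pmax(ceiling(r_obs * n_r_bins), 1L), n_r_bins)
  bin_means <- function(v, idx) {
    as.numeric(tapply(v[idx], bin[idx], mean))
  }
  block_weights <- function(idx) {
    wa <- sd(obs$area_change[idx]); we <- sd(obs$exx_minus_eyy[idx])
    c(area = 1 / max(wa, 1e-12), elong = 1 / max(we, 1e-12),
      ring = if (!is.null(ring_obs)) 1 / max(abs(ring_obs), 1e-12) else 0)
  }

  fit_at_k <- function(k_hat, idx) {
    un <- unit_at(k_hat)
    w <- block_weights(idx)
    yvec <- c(w["area"] * bin_means(obs$area_change, idx),
              w["elong"] * bin_means(obs$exx_minus_eyy, idx),
              if (!is.null(ring_obs)) w["ring"] * ring_obs)
    xcol <- function(u) {
      c(w["area"] * bin_means(u$area, idx),
        w["elong"] * bin_means(u$elong, idx),
        if (!is.null(ring_obs)) w["ring"] * u$ring)
    }
    xmat <- cbind(xcol(un$x), xcol(un$y))
    keep <- complete.cases(cbind(yvec, xmat))
    z <- qr.solve(xmat[keep, , drop = FALSE], yvec[keep])
    resid <- sum((yvec[keep] - xmat[keep, ] %*% z)^2)
    list(zeta = z, residual = resid)
  }

  run_fit <- function(idx, refine = TRUE) {
    res_grid <- vapply(k_grid, function(k) fit_at_k(k, idx)$residual,
                       numeric(1))
    k_best <- k_grid[which.min(res_grid)]
    if (refine) {
      lo <- log10(k_best) - 0.5; hi <- log10(k_best) + 0.5
      op <- optimize(function(lk) fit_at_k(10^lk, idx)$residual, c(lo, hi))
      if (op$objective < min(res_grid)) k_best <- 10^op$minimum
    }
    best <- fit_at_k(k_best, idx)
    spread <- (max(res_grid) - min(res_grid)) /
      max(min(res_grid), 1e-300)
    list(k_hat = k_best, zeta_x = best$zeta[1], zeta_y = best$zeta[2],
         residual = best$residual, k_flat = spread < 1e-4)
  }

  idx_all <- seq_len(nrow(obs))
  main <- run_fit(idx_all)

  boot <- NULL; ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- purrr::map_dfr(seq_len(n_boot), function(b) {
      idx <- sample(idx_all, replace = TRUE)
      fb <- run_fit(idx, refine = FALSE)
      tibble::tibble(k_hat = fb$k_hat, zeta_x_hat = fb$zeta_x,
                     zeta_y_hat = fb$zeta_y)
    })
    ci <- tidyr::pivot_longer(boot, dplyr::everything(),
                              names_to = "term", values_to = "value") |>
      dplyr::group_by(.data$term) |>
      dplyr::summarise(lower = quantile(.data$value, 0.025),
                       upper = quantile(.data$value, 0.975),
                       .groups = "drop")
  }

  structure(
    list(params = continuum_params(main$k_hat, main$zeta_x, main$zeta_y,
                                   mu_hat),
         residual = main$residual, k_flat = main$k_flat,
         boot = boot, ci = ci, n_points = nrow(obs)),
    class = "continuum_fit"
  )
}

#' @export
print.continuum_fit <- function(x, ...) {
  p <- x$params
  cat("<continuum_fit> k_hat = ", signif(p$k_hat, 4),
      ", zeta_x_hat = ", signif(p$zeta_x_hat, 4),
      ", zeta_y_hat = ", signif(p$zeta_y_hat, 4),
      " (mu_hat fixed at ", p$mu_hat, ")\n", sep = "")
  if (x$k_flat) cat("  note: objective nearly flat in k_hat (wide CI)\n")
  invisible(x)
}

#' @rdname fit_continuum
#' @param x A `continuum_fit`.
#' @param ... Unused.
#' @export
tidy.continuum_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("k_hat", "zeta_x_hat", "zeta_y_hat"),
    estimate = c(x$params$k_hat, x$params$zeta_x_hat, x$params$zeta_y_hat)
  )
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' @rdname fit_continuum
#' @export
glance.continuum_fit <- function(x, ...) {
  tibble::tibble(residual = x$residual, k_flat = x$k_flat,
                 n_points = x$n_points, mu_hat = x$params$mu_hat)
}

#' Read and write deformation-field tables
#'
#' TSV with columns `point_id, x_norm, y_norm, ux, uy, area_change,
#' exx_minus_eyy, exy`; the rim displacement travels in a JSON sidecar
#' (same path with extension `.ring.json`) when jsonlite is available.
#'
#' @param field A `deformation_field` or compatible tibble.
#' @param path TSV path.
#' @return `read_deformation()` a `deformation_field` tibble;
#'   `write_deformation()` the field, invisibly.
#' @export
write_deformation <- function(field, path) {
  out <- tibble::tibble(
    point_id = seq_len(nrow(field)),
    x_norm = field$x, y_norm = field$y, ux = field$ux, uy = field$uy,
    area_change = field$area_change,
    exx_minus_eyy = field$exx_minus_eyy, exy = field$exy
  )
  readr::write_tsv(out, path, progress = FALSE)
  ring <- attr(field, "ring_displacement")
  if (!is.null(ring) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(ring_displacement = ring),
                         paste0(path, ".ring.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(field)
}

#' @rdname write_deformation
#' @export
read_deformation <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble::tibble(
    x = raw$x_norm, y = raw$y_norm, r = sqrt(raw$x_norm^2 + raw$y_norm^2),
    ux = raw$ux, uy = raw$uy, area_change = raw$area_change,
    exx_minus_eyy = raw$exx_minus_eyy, exy = raw$exy
  )
  side <- paste0(path, ".ring.json")
  ring <- NULL
  if (file.exists(side) && requireNamespace("jsonlite", quietly = TRUE)) {
    ring <- jsonlite::read_json(side)$ring_displacement
  }
  structure(out, ring_displacement = ring,
            class = c("deformation_field", class(out)))
}
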