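#' Noise specification for synthetic observables
#'
#' @param kind `"gaussian_additive"` or `"gaussian_multiplicative"`.
#' @param sigma Noise scale, >= 0 (absolute for additive, fractional for
#'   multiplicative).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind = c("gaussian_multiplicative",
                                "gaussian_additive"), sigma = 0) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0)
  structure(list(kind = kind, sigma = sigma), class = "noise_spec")
}

apply_noise <- function(x, noise) {
  if (noise$sigma == 0) return(x)
  z <- rnorm(length(x))
  switch(noise$kind,
         gaussian_additive = x + noise$sigma * z,
         gaussian_multiplicative = x * (1 + noise$sigma * z))
}

#' Generate a simulated lineage forest with synthetic geometry
#'
#' Wraps [simulate_growth()] and optionally populates per-frame apical
#' areas and centroids. The area model is a bookkeeping fixture, not a
#' mechanical claim: each daughter starts with exactly half its mother's
#' final area (so areas are conserved across divisions) and relaxes
#' exponentially toward a set point over a timescale `area_tau`. Centroids
#' place founders on a jittered hexagonal packing and daughters next to
#' their mother; one centroid row is recorded per cell at birth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param geometry Populate `areas` and `centroids` tables?
#' @param frame_step Frame spacing of the area table (h).
#' @param area_setpoint Target apical area (\eqn{\mu m^2}).
#' @param area_tau Area relaxation timescale (h).
#' @param cell_spacing Centroid packing distance (\eqn{\mu m}).
#' @return A [lineage_forest()].
#' @export
gen_forest <- function(config = sim_config(), seed = NULL, geometry = TRUE,
                       frame_step = 0.5, area_setpoint = 20, area_tau = 2,
                       cell_spacing = 5) {
  res <- simulate_growth(config, seed)
  forest <- res$forest
  if (!geometry) return(forest)
  cells <- forest$cells
  n <- nrow(cells)
  ord <- order(cells$birth_time, cells$cell_id)
  birth_area <- numeric(n)
  names(birth_area) <- cells$cell_id
  area_at <- function(i, t) {
    area_setpoint + (birth_area[i] - area_setpoint) *
      exp(-(t - cells$birth_time[i]) / area_tau)
  }
  pos <- matrix(NA_real_, n, 2, dimnames = list(cells$cell_id, c("x", "y")))
  founder_rows <- which(is.na(cells$parent_id))
  nf <- length(founder_rows)
  ncol_hex <- ceiling(sqrt(nf))
  for (fi in seq_along(founder_rows)) {
    row <- (fi - 1) %/% ncol_hex
    col <- (fi - 1) %% ncol_hex
    pos[founder_rows[fi], ] <- cell_spacing *
      c(col + 0.5 * (row %% 2), row * sqrt(3) / 2) +
      rnorm(2, 0, 0.1 * cell_spacing)
  }
  for (i in ord) {
    if (is.na(cells$parent_id[i])) {
      birth_area[i] <- area_setpoint * exp(rnorm(1, 0, 0.1))
    } else {
      mi <- match(cells$parent_id[i], cells$cell_id)
      birth_area[i] <- area_at(mi, cells$end_time[mi]) / 2
      if (anyNA(pos[i, ])) {
        pos[i, ] <- pos[mi, ] + rnorm(2, 0, 0.4 * cell_spacing)
      }
    }
  }
  grid <- seq(config$t_start, config$t_end, by = frame_step)
  areas <- purrr::map_dfr(seq_len(n), function(i) {
    tt <- grid[grid >= cells$birth_time[i] & grid < cells$end_time[i]]
    if (cells$end_fate[i] == "censored" &&
        abs(cells$end_time[i] - config$t_end) < 1e-9) {
      tt <- grid[grid >= cells$birth_time[i] & grid <= cells$end_time[i]]
    }
    if (length(tt) == 0) return(NULL)
    tibble::tibble(cell_id = cells$cell_id[i], t = tt, area = area_at(i, tt))
  })
  centroids <- tibble::tibble(cell_id = cells$cell_id,
                              t = cells$birth_time,
                              x = pos[, 1], y = pos[, 2])
  forest$areas <- areas
  forest$centroids <- centroids
  forest
}

#' Generate a noisy post-ablation deformation field
#'
#' Runs the forward continuum solver ([solve_disc()]), samples
#' `n_points` element centroids uniformly, and perturbs the observables
#' (`area_change`, `exx_minus_eyy`, `exy` and the rim displacement) with
#' the requested noise — the standard fixture for parameter-recovery tests
#' of [fit_continuum()]. The generating parameters are attached as the
#' `generator_params` attribute.
#'
#' @param params A [continuum_params()].
#' @param n_points Number of sample points.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param resolution Forward-solver resolution.
#' @return A `deformation_field` tibble of sampled points with attributes
#'   `ring_displacement` and `generator_params`.
#' @export
gen_deformation <- function(params, n_points = 200,
                            noise = noise_spec(sigma = 0), seed = NULL,
                            resolution = 32) {
  if (!is.null(seed)) set.seed(seed)
  field <- solve_disc(params, resolution)
  n_points <- min(n_points, nrow(field))
  idx <- sort(sample(nrow(field), n_points))
  out <- field[idx, ]
  out$area_change <- apply_noise(out$area_change, noise)
  out$exx_minus_eyy <- apply_noise(out$exx_minus_eyy, noise)
  out$exy <- apply_noise(out$exy, noise)
  ring <- apply_noise(attr(field, "ring_displacement"), noise)
  attr(out, "ring_displacement") <- ring
  attr(out, "generator_params") <- params
  attr(out, "nodal_u") <- NULL
  attr(out, "system") <- NULL
  out
}

#' Preset FUCCI phase compositions
#'
#' Class fractions (G1, S, G2/M) of the measured nucleus populations at two
#' reference stages: during the proliferation pause most cells accumulate
#' in G2 (12 hAPF preset: 18% G1, 50% G2/M), while in the expansion phase
#' the distribution shifts toward G1 (16 hAPF preset: 44% G1, 36% G2/M).
#'
#' @param stage `"12hAPF"` or `"16hAPF"`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
fucci_preset <- function(stage = c("12hAPF", "16hAPF")) {
  stage <- match.arg(stage)
  switch(stage,
         "12hAPF" = c(G1 = 0.18, S = 0.32, G2M = 0.50),
         "16hAPF" = c(G1 = 0.44, S = 0.20, G2M = 0.36))
}

#' Generate a synthetic FUCCI nucleus population
#'
#' Two-channel nucleus intensities drawn from class-conditional log-normal
#' distributions: G1 nuclei are GFP-high/RFP-low, S nuclei the inverse,
#' G2/M nuclei high in both. Class-conditional medians are separated by
#' `separation`-fold (default 8) with a channel noise `sdlog` small enough
#' that the classes stay well separated on the ratio scale, so recovery by
#' [fucci_phase_call()] is limited by composition, not by overlap. Class
#' counts are deterministic (rounded `fractions * n`); the ground-truth
#' label is kept in `true_phase`.
#'
#' @param fractions Named fractions `(G1, S, G2M)` summing to 1.
#' @param n Number of nuclei.
#' @param seed Integer seed.
#' @param separation Fold separation of high vs low channel medians.
#' @param sdlog Log-scale channel noise SD.
#' @param base Low-channel median intensity (a.u.).
#' @param t Frame time (hAPF) recorded in the output.
#' @return Tibble with `nucleus_id`, `t`, `gfp`, `rfp`, `true_phase`.
#' @export
gen_fucci <- function(fractions, n, seed = NULL, separation = 8,
                      sdlog = 0.15, base = 100, t = 0) {
  if (abs(sum(fractions) - 1) > 1e-6) abort("fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  lo <- log(base)
  hi <- log(base * separation)
  cls <- rep(c("G1", "S", "G2M"), counts[c("G1", "S", "G2M")])
  gfp_mean <- ifelse(cls == "S", lo, hi)
  rfp_mean <- ifelse(cls == "G1", lo, hi)
  tibble::tibble(
    nucleus_id = sprintf("n%04d", seq_len(n)),
    t = t,
    gfp = stats::rlnorm(n, gfp_mean, sdlog),
    rfp = stats::rlnorm(n, rfp_mean, sdlog),
    true_phase = cls
  )
}

#' Generate an exponentially relaxing axis-length time series
#'
#' Kelvin-Voigt-like relaxation fixture
#' `L(t) = L_inf + (L0 - L_inf) exp(-t/tau)` plus optional additive
#' Gaussian noise, for testing [recoil_series()] and [relaxation_time()].
#'
#' @param l0 Initial axis length (\eqn{\mu m}).
#' @param l_inf Relaxed axis length (\eqn{\mu m}).
#' @param tau Relaxation time (s), > 0.
#' @param dt Frame interval (s).
#' @param n_frames Number of frames.
#' @param sigma Additive noise SD (\eqn{\mu m}).
#' @param seed Integer seed.
#' @return Tibble with `time` (s) and `length` (\eqn{\mu m}).
#' @export
gen_ablation_series <- function(l0, l_inf, tau, dt, n_frames, sigma = 0,
                                seed = NULL) {
  stopifnot(tau > 0, dt > 0, n_frames >= 2)
  if (!is.null(seed)) set.seed(seed)
  tt <- (seq_len(n_frames) - 1) * dt
  len <- l_inf + (l0 - l_inf) * exp(-tt / tau)
  if (sigma > 0) len <- len + rnorm(n_frames, 0, sigma)
  tibble::tibble(time = tt, length = len)
}

#' Generate synthetic junction measurements
#'
#' Junction angles uniform on `[0, 90]` degrees (from the DV axis) with
#' intensities from an angular profile plus additive Gaussian noise.
#'
#' @param profile Function of angle (degrees) returning mean intensity, or
#'   a single number for a flat profile.
#' @param n Number of junctions.
#' @param sigma Additive noise SD (a.u.).
#' @param seed Integer seed.
#' @return Tibble with `junction_id`, `angle_deg`, `length_um`,
#'   `intensity`.
#' @export
gen_junctions <- function(profile, n, sigma = 0, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(profile)) {
    lvl <- profile
    profile <- function(theta) rep(lvl, length(theta))
  }
  angle <- runif(n, 0, 90)
  tibble::tibble(
    junction_id = sprintf("j%04d", seq_len(n)),
    angle_deg = angle,
    length_um = stats::rlnorm(n, log(3), 0.3),
    intensity = pmax(profile(angle) + rnorm(n, 0, sigma), 0)
  )
}
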