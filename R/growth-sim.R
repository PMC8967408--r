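#' Arrest schedule: time-dependent probabilities of cell-cycle exit
#'
#' Parameterizes the two Hill curves governing proliferative arrest at each
#' division: `p(t)`, the probability that a division at time `t` creates at
#' least one arrested daughter, and `alpha(t)`, the probability that it
#' creates two arrested daughters conditional on creating at least one.
#'
#' @param p_half_time,p_exponent,p_plateau Hill parameters of `p(t)`
#'   (hAPF, dimensionless, probability).
#' @param alpha_half_time,alpha_exponent,alpha_plateau Same for `alpha(t)`.
#' @return An `arrest_schedule` list.
#' @export
arrest_schedule <- function(p_half_time = 26, p_exponent = 40, p_plateau = 1,
                            alpha_half_time = 26, alpha_exponent = 40,
                            alpha_plateau = 1) {
  stopifnot(p_exponent > 0, alpha_exponent > 0,
            p_plateau >= 0, p_plateau <= 1,
            alpha_plateau >= 0, alpha_plateau <= 1)
  structure(list(p_half_time = p_half_time, p_exponent = p_exponent,
                 p_plateau = p_plateau, alpha_half_time = alpha_half_time,
                 alpha_exponent = alpha_exponent,
                 alpha_plateau = alpha_plateau),
            class = "arrest_schedule")
}

arrest_p <- function(schedule, t) {
  hill(t, schedule$p_half_time, schedule$p_exponent, schedule$p_plateau)
}

arrest_alpha <- function(schedule, t) {
  hill(t, schedule$alpha_half_time, schedule$alpha_exponent,
       schedule$alpha_plateau)
}

#' Simulation configuration for histoblast population growth
#'
#' The default configuration is the base case: three developmental phases of
#' the cell-cycle-time law separated at `cleavage_end` (3.3 hAPF) and
#' `pause_end` (14.7 hAPF); a proliferation pause in
#' `[pause_start, pause_end) = [12.5, 14.7)` during which due divisions are
#' deferred to `pause_end` (cells keep ageing, so the release produces a
#' division burst); cleavage-phase cycle times with mean 2.7 h; an
#' expansion-phase mean cycle time given by a cubic polynomial of birth time
#' (centred at 22 hAPF) averaging about 4.5 h over 15-28 hAPF with a shallow
#' minimum near 22 hAPF; a bridge phase between `cleavage_end` and
#' `pause_end` whose mean is pinned to the expansion curve's starting value
#' at 15 hAPF; coefficient of variation 0.22 and sister correlation 0.55 in
#' the expansion phase; an arrest schedule rising sharply from about 0 at
#' 24 hAPF to about 1 at 28 hAPF; and a small probability for newborns to
#' become sensory organ precursors (SOPs) inside a time window.
#'
#' @param n_init Number of founder cells at `t_start`.
#' @param t_start,t_end Simulated time span (hAPF).
#' @param cleavage_end End of the cleavage phase (hAPF).
#' @param pause_start,pause_end Proliferation pause window (hAPF).
#' @param cleavage_mean,cleavage_cv Mean (h) and CV of cleavage cycle times.
#' @param expansion_mean_curve Numeric coefficients `c0..c3` of the cubic
#'   mean cycle time (h) in powers of `(t - 22)` with `t` the birth time.
#' @param expansion_cv CV of bridge- and expansion-phase cycle times.
#' @param sister_rho Correlation of sister cycle times, in `(-1, 1)`.
#' @param arrest An [arrest_schedule()].
#' @param sop_prob Probability that a non-arrested newborn inside
#'   `sop_window` becomes an SOP.
#' @param sop_window Length-2 numeric (hAPF).
#' @param min_cycle Truncation floor (h): sister pairs with any component
#'   below it are redrawn jointly, preserving the correlation.
#' @param seed Optional default seed used by [simulate_growth()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_init = 16, t_start = 0, t_end = 33,
                       cleavage_end = 3.3, pause_start = 12.5,
                       pause_end = 14.7, cleavage_mean = 2.7,
                       cleavage_cv = 0.10,
                       expansion_mean_curve = c(4.42, -0.0703, 0.0017, 0.0032),
                       expansion_cv = 0.22, sister_rho = 0.55,
                       arrest = arrest_schedule(), sop_prob = 0.02,
                       sop_window = c(16, 22), min_cycle = 0.5,
                       seed = NULL) {
  stopifnot(t_start < cleavage_end, cleavage_end < pause_start,
            pause_start < pause_end, pause_end < t_end,
            cleavage_cv > 0, expansion_cv > 0,
            abs(sister_rho) < 1, sop_prob >= 0, sop_prob <= 1,
            min_cycle > 0, n_init >= 1)
  structure(list(
    n_init = n_init, t_start = t_start, t_end = t_end,
    cleavage_end = cleavage_end, pause_start = pause_start,
    pause_end = pause_end, cleavage_mean = cleavage_mean,
    cleavage_cv = cleavage_cv, expansion_mean_curve = expansion_mean_curve,
    expansion_cv = expansion_cv, sister_rho = sister_rho, arrest = arrest,
    sop_prob = sop_prob, sop_window = sop_window, min_cycle = min_cycle,
    seed = seed
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_config <- function() sim_config()

#' Cycle-time law: mean and SD as a function of birth time
#'
#' Three-phase law indexed by the cell's birth time: cleavage parameters
#' before `cleavage_end`; the expansion cubic from `pause_end` on; in
#' between, the mean is held at the expansion curve's value at 15 hAPF
#' (the starting value of the expansion phase) with the expansion CV.
#'
#' @param config A [sim_config()].
#' @param t Birth times (hAPF).
#' @return Tibble with `t`, `mean` (h), `sd` (h).
#' @export
cycle_time_law <- function(config, t) {
  cubic <- function(t) {
    s <- t - 22
    cf <- config$expansion_mean_curve
    cf[1] + cf[2] * s + cf[3] * s^2 + cf[4] * s^3
  }
  bridge_mean <- cubic(15)
  m <- ifelse(t < config$cleavage_end, config$cleavage_mean,
              ifelse(t < config$pause_end, bridge_mean, cubic(t)))
  cv <- ifelse(t < config$cleavage_end, config$cleavage_cv,
               config$expansion_cv)
  tibble::tibble(t = t, mean = m, sd = cv * m)
}

#' Draw correlated sister cycle times
#'
#' Sister pairs are drawn from a bivariate normal with identical marginals
#' `N(mean, (cv * mean)^2)` and correlation `rho`. Pairs in which either
#' component falls below `min_cycle` are redrawn jointly (the truncation
#' floor guards against non-positive cycle times while preserving the
#' correlation structure); exceeding `max_redraws` consecutive full-vector
#' redraw sweeps signals degenerate parameters.
#'
#' @param n Number of pairs.
#' @param mean Marginal mean (h), > 0.
#' @param cv Coefficient of variation, > 0.
#' @param rho Correlation, `|rho| < 1` (or exactly +1 for identical twins).
#' @param min_cycle Truncation floor (h).
#' @param max_redraws Redraw cap.
#' @return Tibble with columns `t1`, `t2` (h).
#' @export
draw_sister_cycle_times <- function(n, mean, cv, rho, min_cycle = 0.5,
                                    max_redraws = 1000) {
  stopifnot(mean > 0, cv >= 0, abs(rho) <= 1)
  s <- cv * mean
  draw <- function(k) {
    z1 <- rnorm(k)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(k)
    cbind(mean + s * z1, mean + s * z2)
  }
  out <- draw(n)
  bad <- which(out[, 1] < min_cycle | out[, 2] < min_cycle)
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > max_redraws) {
      abort("redraw cap exceeded: degenerate cycle-time parameters")
    }
    out[bad, ] <- draw(length(bad))
    bad <- bad[out[bad, 1] < min_cycle | out[bad, 2] < min_cycle]
  }
  tibble::tibble(t1 = out[, 1], t2 = out[, 2])
}

# single-cell truncated draw used for founders
draw_single_cycle <- function(mean, sd, min_cycle, max_redraws = 1000) {
  for (i in seq_len(max_redraws)) {
    x <- rnorm(1, mean, sd)
    if (x >= min_cycle) return(x)
  }
  abort("redraw cap exceeded: degenerate cycle-time parameters")
}

defer_pause <- function(t_due, config) {
  ifelse(t_due >= config$pause_start & t_due < config$pause_end,
         config$pause_end, t_due)
}

#' Simulate histoblast population growth
#'
#' Event-driven stochastic simulation. Founders draw their cycle times
#' independently from the law at `t_start`. At each division at time `t`,
#' the outcome is classified through the arrest schedule: with probability
#' `p(t)` at least one daughter is arrested, and conditionally with
#' probability `alpha(t)` both are (the single arrested side is chosen
#' uniformly). Daughters draw their cycle times as a correlated sister pair
#' from the law indexed by their birth time `t`. Non-arrested newborns
#' inside `sop_window` become SOPs with probability `sop_prob`; arrested
#' cells and SOPs persist without dividing. Divisions due inside
#' `[pause_start, pause_end)` are deferred to `pause_end` (cells still age,
#' yielding a synchronized burst on release). The run halts at `t_end` and
#' survivors are censored there. Identical seed and configuration give a
#' bitwise-identical forest.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; falls back to `config$seed`.
#' @return A `sim_result`: list with `forest` (a [lineage_forest()] whose
#'   cells carry `arrested` and `is_sop` flags), `config` and `seed`.
#' @export
simulate_growth <- function(config = sim_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  cap <- 4096L
  id <- character(cap); parent <- character(cap)
  birth <- numeric(cap); endt <- numeric(cap)
  fate <- character(cap); arrested <- logical(cap); sop <- logical(cap)
  due <- rep(NA_real_, cap) # division time of cycling cells, NA otherwise
  n <- 0L

  grow <- function() {
    cap2 <- cap * 2L
    length(id) <<- cap2; length(parent) <<- cap2
    length(birth) <<- cap2; length(endt) <<- cap2
    length(fate) <<- cap2; length(arrested) <<- cap2; length(sop) <<- cap2
    length(due) <<- cap2
    cap <<- cap2
  }
  add_cell <- function(par, b, d) {
    if (n + 1L > cap) grow()
    n <<- n + 1L
    id[n] <<- sprintf("c%06d", n)
    parent[n] <<- par
    birth[n] <<- b
    endt[n] <<- NA_real_
    fate[n] <<- NA_character_
    arrested[n] <<- FALSE
    sop[n] <<- FALSE
    due[n] <<- d
    n
  }

  law0 <- cycle_time_law(config, config$t_start)
  for (i in seq_len(config$n_init)) {
    ct <- draw_single_cycle(law0$mean, law0$sd, config$min_cycle)
    add_cell(NA_character_, config$t_start,
             defer_pause(config$t_start + ct, config))
  }

  in_sop_window <- function(t) {
    t >= config$sop_window[1] & t <= config$sop_window[2]
  }

  repeat {
    active <- which(!is.na(due[seq_len(n)]))
    if (length(active) == 0) break
    i <- active[which.min(due[active])]
    t <- due[i]
    if (t >= config$t_end) break
    # mother divides
    due[i] <- NA_real_
    endt[i] <- t
    fate[i] <- "divided"
    # arrest classification
    p <- arrest_p(config$arrest, t)
    a <- arrest_alpha(config$arrest, t)
    arr <- c(FALSE, FALSE)
    if (runif(1) < p) {
      if (runif(1) < a) {
        arr <- c(TRUE, TRUE)
      } else {
        side <- if (runif(1) < 0.5) 1 else 2
        arr[side] <- TRUE
      }
    }
    law <- cycle_time_law(config, t)
    pair <- draw_sister_cycle_times(1, law$mean, law$sd / law$mean,
                                    config$sister_rho, config$min_cycle)
    cts <- c(pair$t1, pair$t2)
    for (k in 1:2) {
      j <- add_cell(id[i], t, NA_real_)
      if (arr[k]) {
        arrested[j] <- TRUE
      } else if (in_sop_window(t) && runif(1) < config$sop_prob) {
        sop[j] <- TRUE
      } else {
        due[j] <- defer_pause(t + cts[k], config)
      }
    }
  }

  live <- seq_len(n)
  open <- is.na(endt[live])
  endt[live][open] <- config$t_end
  fate[live][open] <- "censored"

  cells <- tibble::tibble(
    cell_id = id[live], parent_id = parent[live], birth_time = birth[live],
    end_time = endt[live], end_fate = fate[live], is_sop = sop[live],
    arrested = arrested[live]
  )
  forest <- lineage_forest(cells, movie_end = config$t_end,
                           roi_label = "simulated")
  structure(list(forest = forest, config = config, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> seed:", if (is.null(x$seed)) "none" else x$seed, "\n")
  print(x$forest)
  invisible(x)
}

#' Cell-class counts over time
#'
#' Counts cycling, arrested and SOP cells alive on a time grid (a cell is
#' alive at t when `birth_time <= t < end_time`; at `t_end` censored cells
#' are counted as alive). With `normalize_at`, all series are divided by the
#' total count at that time.
#'
#' @param result A `sim_result` from [simulate_growth()], or a
#'   [lineage_forest()] with `arrested` labels.
#' @param grid_step Grid spacing (h).
#' @param normalize_at Optional time (hAPF) at which the total is scaled
#'   to 1.
#' @return Tibble with `time`, `cycling`, `arrested`, `sop`, `total` (and
#'   their `*_norm` companions if `normalize_at` is set).
#' @export
class_counts <- function(result, grid_step = 0.5, normalize_at = NULL) {
  forest <- if (inherits(result, "sim_result")) result$forest else result
  cells <- forest$cells
  t_end <- forest$movie_end
  grid <- seq(min(cells$birth_time), t_end, by = grid_step)
  alive_at <- function(t) {
    cells$birth_time <= t & (t < cells$end_time |
                               (t >= t_end & cells$end_fate == "censored"))
  }
  counts <- purrr::map_dfr(grid, function(t) {
    al <- alive_at(t)
    arr <- al & !is.na(cells$arrested) & cells$arrested
    sp <- al & cells$is_sop
    tibble::tibble(
      time = t,
      arrested = sum(arr),
      sop = sum(sp & !arr),
      cycling = sum(al) - sum(arr) - sum(sp & !arr),
      total = sum(al)
    )
  })
  counts <- counts[, c("time", "cycling", "arrested", "sop", "total")]
  if (!is.null(normalize_at)) {
    if (normalize_at < min(grid) || normalize_at > max(grid)) {
      abort("normalize_at lies outside the simulated span")
    }
    ref <- counts$total[which.min(abs(counts$time - normalize_at))]
    counts <- dplyr::mutate(
      counts,
      dplyr::across(c("cycling", "arrested", "sop", "total"),
                    ~ .x / ref, .names = "{.col}_norm")
    )
  }
  counts
}
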