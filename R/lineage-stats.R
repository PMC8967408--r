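#' Cell-cycle times of divided cells
#'
#' Extracts one entry per divided cell: the time between its birth and its
#' own division (hours). Censored, extruded and sensory-organ-precursor (SOP)
#' cells are excluded; the collection may be empty.
#'
#' @param forest A [lineage_forest()].
#' @return Tibble with columns `cell_id`, `birth_time` (hAPF) and
#'   `cycle_time` (h).
#' @export
cycle_times <- function(forest) {
  cells <- forest$cells
  div <- cells[cells$end_fate == "divided" & !cells$is_sop, ]
  tibble::tibble(
    cell_id = div$cell_id,
    birth_time = div$birth_time,
    cycle_time = div$end_time - div$birth_time
  )
}

#' Summarise a cycle-time distribution
#'
#' Mean, standard deviation and coefficient of variation (CV = sd/mean) of a
#' set of cell-cycle times. The sample (n-1) standard deviation is used:
#' per-movie sample sizes are small enough that the population estimator
#' would be noticeably biased.
#'
#' @param entries Data frame with a `cycle_time` column, as returned by
#'   [cycle_times()], or a bare numeric vector.
#' @return One-row tibble with `n`, `mean` (h), `sd` (h), `cv`.
#' @export
cycle_time_summary <- function(entries) {
  ct <- if (is.data.frame(entries)) entries$cycle_time else as.numeric(entries)
  ct <- ct[!is.na(ct)]
  if (length(ct) < 2) abort("cycle_time_summary needs at least 2 entries")
  m <- mean(ct)
  s <- sd(ct)
  tibble::tibble(n = length(ct), mean = m, sd = s, cv = s / m)
}

# step-function machinery for the alive-cell count -------------------------

# cumulative integral of the alive count: C(t) = int_{t0}^{t} N(s) ds
alive_count_fun <- function(forest) {
  cells <- forest$cells
  ev <- sort(unique(c(cells$birth_time, cells$end_time)))
  nev <- length(ev)
  delta <- tabulate(match(cells$birth_time, ev), nbins = nev) -
    tabulate(match(cells$end_time, ev), nbins = nev)
  n_at <- cumsum(delta) # N on [ev_i, ev_{i+1})
  cint <- c(0, cumsum(n_at[-length(n_at)] * diff(ev)))
  list(
    n = function(t) {
      i <- findInterval(t, ev)
      ifelse(i == 0, 0, n_at[pmax(i, 1)])
    },
    cum = function(t) {
      i <- findInterval(t, ev)
      out <- numeric(length(t))
      inside <- i >= 1
      ii <- i[inside]
      out[inside] <- cint[ii] + n_at[ii] * (t[inside] - ev[ii])
      out
    }
  )
}

#' Per-capita cell division rate with top-hat smoothing
#'
#' At each grid time t, the rate is the number of division events inside the
#' top-hat window `[t - window/2, t + window/2)` divided by
#' `window * Nbar(t)`, where `Nbar(t)` is by default the time-average of the
#' alive-cell count over the same window (a cell is alive at s when
#' `birth_time <= s < end_time`). Set `denominator = "instantaneous"` to use
#' `N(t)` instead. Grid times where `Nbar(t) = 0` are reported as `NA`.
#'
#' @param forest A [lineage_forest()].
#' @param window Top-hat window width (h); default 0.875.
#' @param grid_step Grid spacing (h).
#' @param t_range Length-2 numeric; defaults to the span of the forest.
#' @param denominator `"window_mean"` (default) or `"instantaneous"`.
#' @return A `rate_series`: tibble with `time` (hAPF), `n_events`, `nbar`
#'   and `rate` (per cell per hour), with attributes `window` and
#'   `grid_step`.
#' @export
division_rate <- function(forest, window = 0.875, grid_step = 0.125,
                          t_range = NULL,
                          denominator = c("window_mean", "instantaneous")) {
  if (window <= 0) abort("window must be positive")
  denominator <- match.arg(denominator)
  cells <- forest$cells
  t_range <- t_range %||% c(min(cells$birth_time), forest$movie_end)
  grid <- seq(t_range[1], t_range[2], by = grid_step)
  div_t <- sort(cells$end_time[cells$end_fate == "divided"])
  lo <- grid - window / 2
  hi <- grid + window / 2
  n_ev <- findInterval(hi, div_t, left.open = TRUE) -
    findInterval(lo, div_t, left.open = TRUE)
  ac <- alive_count_fun(forest)
  nbar <- if (denominator == "window_mean") {
    (ac$cum(hi) - ac$cum(lo)) / window
  } else {
    ac$n(grid)
  }
  rate <- ifelse(nbar > 0, n_ev / (window * nbar), NA_real_)
  structure(
    tibble::tibble(time = grid, n_events = n_ev, nbar = nbar, rate = rate),
    window = window, grid_step = grid_step,
    class = c("rate_series", class(tibble::tibble()))
  )
}

#' Fourier spectrum of the division rate
#'
#' Magnitude of the discrete Fourier transform of the division-rate series
#' restricted to times before `t_max`, normalized to its value at zero
#' frequency. The series must be on a uniform grid. By default no zero
#' padding is applied: with a plain DFT the rectangular-window leakage of
#' the large zero-frequency component vanishes exactly at the bin
#' frequencies, so the oscillatory peak is not masked; `pad_factor > 1`
#' interpolates the spectrum but re-introduces DC sidelobes.
#'
#' @param series A `rate_series` from [division_rate()] (or any data frame
#'   with `time` and `rate` columns on a uniform grid).
#' @param t_max Only times strictly before `t_max` (hAPF) enter the
#'   transform; default 28.5.
#' @param pad_factor Zero-padding factor (integer >= 1).
#' @return Tibble with `frequency` (1/h, up to the Nyquist frequency) and
#'   `magnitude` (dimensionless, 1 at zero frequency).
#' @export
division_rate_spectrum <- function(series, t_max = 28.5, pad_factor = 1) {
  tt <- series$time
  dt <- diff(tt)
  if (length(dt) < 2 || any(abs(dt - dt[1]) > 1e-8 * dt[1])) {
    abort("time grid is not uniform: resample the series first")
  }
  keep <- tt < t_max
  x <- series$rate[keep]
  if (anyNA(x)) abort("rate contains NA inside the requested window")
  n <- length(x)
  if (n < 4) abort("too few samples before t_max")
  npad <- n * max(1L, as.integer(pad_factor))
  f <- fft(c(x, rep(0, npad - n)))
  mag <- Mod(f) / Mod(f[1])
  freq <- (seq_len(npad) - 1) / (npad * dt[1])
  half <- freq <= 1 / (2 * dt[1]) + 1e-12
  tibble::tibble(frequency = freq[half], magnitude = mag[half])
}

#' Dominant non-zero frequency of a spectrum
#'
#' Returns the frequency of the largest local maximum of the magnitude at
#' strictly positive frequency (the zero-frequency lobe decays monotonically
#' and is not a local maximum).
#'
#' @param spectrum Tibble from [division_rate_spectrum()].
#' @return Frequency (1/h), or `NA` if no interior local maximum exists.
#' @export
dominant_frequency <- function(spectrum) {
  m <- spectrum$magnitude
  f <- spectrum$frequency
  n <- length(m)
  if (n < 3) return(NA_real_)
  i <- 2:(n - 1)
  is_peak <- m[i] > m[i - 1] & m[i] >= m[i + 1] & f[i] > 0
  peaks <- i[is_peak]
  if (length(peaks) == 0) return(NA_real_)
  f[peaks[which.max(m[peaks])]]
}

# prominence of local maxima of a series (edge-bounded)
peak_prominences <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  peaks <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1):(p - 1)])
    right <- x[(p + 1):n]
    higher_r <- which(right > h)
    rmax <- if (length(higher_r)) p + min(higher_r) else n
    rmin <- min(x[(p + 1):rmax])
    h - max(lmin, rmin)
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Count prominent peaks of a rate series
#'
#' Number of local maxima located in `[t_start, t_end]` whose topographic
#' prominence is at least `min_prominence` times the rate maximum inside the
#' window. Prominences are computed on the full series supplied (not just
#' the window), so a peak near the window edge keeps its true surrounding
#' valleys; pass a series that extends somewhat beyond the window for
#' edge-robust counts.
#'
#' @inheritParams division_rate_spectrum
#' @param t_start,t_end Window bounds (hAPF).
#' @param min_prominence Prominence threshold as a fraction of the window
#'   maximum; default 0.1.
#' @return Integer count.
#' @export
count_peaks <- function(series, t_start, t_end, min_prominence = 0.1) {
  if (t_start >= t_end) abort("t_start must precede t_end")
  ok <- !is.na(series$rate)
  x <- series$rate[ok]
  tt <- series$time[ok]
  in_win <- tt >= t_start & tt <= t_end
  if (sum(in_win) < 3 || length(x) < 3) return(0L)
  pk <- peak_prominences(x)
  keep <- in_win[pk$peaks]
  sum(pk$prominence[keep] >= min_prominence * max(x[in_win]))
}

#' Decompose cumulative tissue-area expansion
#'
#' Splits the cumulative log expansion of total apical tissue area into the
#' contributions of cell division, mean cell-area change and cell loss
#' (extrusion), frame interval by frame interval. Writing total area
#' `A = N * abar` (cell count times mean cell area), per interval
#' `dln A = ln((N + d)/N) + ln(N'/(N + d)) + dln abar`, where `d` is the
#' number of divisions in the interval and `N'` the next frame's count; the
#' three terms are the division, extrusion (negative) and area-change
#' contributions and the split is exact by construction. This is the
#' isotropic part of the tissue deformation only.
#'
#' @param forest A [lineage_forest()] whose `areas` table covers every alive
#'   cell at every frame.
#' @return A `growth_decomposition`: tibble with `time` and cumulative
#'   columns `cum_total`, `cum_division`, `cum_area_change`,
#'   `cum_extrusion` (dimensionless, zero at the first frame).
#' @export
growth_decomposition <- function(forest) {
  if (is.null(forest$areas)) abort("forest carries no area table")
  cells <- forest$cells
  areas <- forest$areas
  frames <- sort(unique(areas$t))
  n_f <- length(frames)
  if (n_f < 2) abort("need at least two frames")
  tot_area <- numeric(n_f)
  n_alive <- integer(n_f)
  for (j in seq_len(n_f)) {
    t <- frames[j]
    # censored cells count as present on their final frame
    alive <- cells$cell_id[
      cells$birth_time <= t &
        (t < cells$end_time |
           (cells$end_fate == "censored" & abs(cells$end_time - t) < 1e-9))
    ]
    a <- areas[areas$t == t, ]
    miss <- setdiff(alive, a$cell_id)
    if (length(miss) > 0) {
      abort(paste0("cell ", miss[1], ": no area at frame t = ", t))
    }
    a <- a[a$cell_id %in% alive, ]
    tot_area[j] <- sum(a$area)
    n_alive[j] <- length(alive)
  }
  div_t <- cells$end_time[cells$end_fate == "divided"]
  ext_t <- cells$end_time[cells$end_fate == "extruded"]
  d_div <- numeric(n_f - 1)
  d_area <- numeric(n_f - 1)
  d_ext <- numeric(n_f - 1)
  for (j in seq_len(n_f - 1)) {
    d <- sum(div_t > frames[j] & div_t <= frames[j + 1])
    n0 <- n_alive[j]
    n1 <- n_alive[j + 1]
    d_div[j] <- log((n0 + d) / n0)
    d_ext[j] <- log(n1 / (n0 + d))
    d_area[j] <- log((tot_area[j + 1] / n1) / (tot_area[j] / n0))
  }
  out <- tibble::tibble(
    time = frames,
    cum_total = c(0, cumsum(d_div + d_ext + d_area)),
    cum_division = c(0, cumsum(d_div)),
    cum_area_change = c(0, cumsum(d_area)),
    cum_extrusion = c(0, cumsum(d_ext))
  )
  class(out) <- c("growth_decomposition", class(out))
  out
}

#' Cycle-time pairs and their correlation
#'
#' `cycle_time_pairs()` extracts pairs of cell-cycle times from a forest:
#' either mother-daughter pairs (one pair per mother-daughter combination,
#' up to two per mother) or sister pairs (one per sibling couple, with the
#' within-pair order randomized to avoid ordering bias, since the Pearson
#' coefficient of unordered pairs depends on how they are laid out).
#' `pair_correlations()` reports the Pearson and Spearman coefficients.
#' Only divided, non-SOP cells enter.
#'
#' @param forest A [lineage_forest()].
#' @param pairing `"sister"` or `"mother_daughter"`.
#' @param birth_window Optional length-2 numeric: keep only pairs in which
#'   both members were born inside this window (hAPF).
#' @param seed Optional seed for the sister-pair ordering.
#' @return `cycle_time_pairs()`: tibble with `t1`, `t2` (h).
#'   `pair_correlations()`: one-row tibble with `pairing`, `pearson`,
#'   `spearman`, `n_pairs`.
#' @export
cycle_time_pairs <- function(forest, pairing = c("sister", "mother_daughter"),
                             birth_window = NULL, seed = NULL) {
  pairing <- match.arg(pairing)
  cells <- forest$cells
  ct <- cycle_times(forest)
  ct_of <- setNames(ct$cycle_time, ct$cell_id)
  birth_of <- setNames(cells$birth_time, cells$cell_id)
  if (pairing == "mother_daughter") {
    kids <- cells[!is.na(cells$parent_id), ]
    kids <- kids[kids$cell_id %in% ct$cell_id & kids$parent_id %in% ct$cell_id, ]
    pairs <- tibble::tibble(
      t1 = unname(ct_of[kids$parent_id]),
      t2 = unname(ct_of[kids$cell_id]),
      b1 = unname(birth_of[kids$parent_id]),
      b2 = unname(birth_of[kids$cell_id])
    )
  } else {
    kids <- cells[!is.na(cells$parent_id), ]
    kids <- kids[kids$cell_id %in% ct$cell_id, ]
    sib <- split(kids$cell_id, kids$parent_id)
    sib <- sib[lengths(sib) == 2]
    if (!is.null(seed)) set.seed(seed)
    flip <- runif(length(sib)) < 0.5
    a <- vapply(sib, `[`, character(1), 1)
    b <- vapply(sib, `[`, character(1), 2)
    first <- ifelse(flip, b, a)
    second <- ifelse(flip, a, b)
    pairs <- tibble::tibble(
      t1 = unname(ct_of[first]), t2 = unname(ct_of[second]),
      b1 = unname(birth_of[first]), b2 = unname(birth_of[second])
    )
  }
  if (!is.null(birth_window)) {
    keep <- pairs$b1 >= birth_window[1] & pairs$b1 <= birth_window[2] &
      pairs$b2 >= birth_window[1] & pairs$b2 <= birth_window[2]
    pairs <- pairs[keep, ]
  }
  pairs[, c("t1", "t2")]
}

#' @rdname cycle_time_pairs
#' @export
pair_correlations <- function(forest, pairing = c("sister", "mother_daughter"),
                              birth_window = NULL, seed = NULL) {
  pairing <- match.arg(pairing)
  pairs <- cycle_time_pairs(forest, pairing, birth_window, seed)
  if (nrow(pairs) < 2) abort("need at least 2 complete pairs")
  if (var(pairs$t1) == 0 || var(pairs$t2) == 0) {
    abort("zero variance in one pair member: correlation undefined")
  }
  tibble::tibble(
    pairing = pairing,
    pearson = cor(pairs$t1, pairs$t2),
    spearman = cor(pairs$t1, pairs$t2, method = "spearman"),
    n_pairs = nrow(pairs)
  )
}

#' Label arrested cells
#'
#' A cell is arrested when it is censored at the end of the movie without
#' having divided, is not a sensory organ precursor and was not extruded:
#' the operational definition of proliferative (G0/G1) arrest in tracked
#' movies. Cells censored before `movie_end` (lost tracks) are not labelled.
#' With `min_followup > 0`, cells born within `min_followup` hours of
#' `movie_end` are excluded from the arrested class (left `FALSE`); the
#' default keeps them, matching the plain movie-end definition.
#'
#' @param forest A [lineage_forest()].
#' @param min_followup Minimum observation time (h) required to call a
#'   censored cell arrested; default 0 (off).
#' @param frame_tol Tolerance (h) when comparing `end_time` to `movie_end`.
#' @return The forest with a filled logical `arrested` column.
#' @export
label_arrested <- function(forest, min_followup = 0, frame_tol = 1e-6) {
  cells <- forest$cells
  at_end <- cells$end_time >= forest$movie_end - frame_tol
  arrested <- cells$end_fate == "censored" & at_end & !cells$is_sop
  if (min_followup > 0) {
    arrested <- arrested &
      (forest$movie_end - cells$birth_time >= min_followup)
  }
  forest$cells$arrested <- arrested
  forest
}

#' Arrest probabilities p(t) and alpha(t) with Hill fits
#'
#' For every division, classifies its outcome by the number of arrested
#' daughters (0, 1 or 2), bins divisions by division time (left-closed
#' bins anchored at integer hAPF) and estimates, per bin, the probability
#' `p` that a division creates at least one arrested daughter and the
#' conditional probability `alpha` that it creates two given at least one.
#' Hill curves `plateau * t^n / (t_half^n + t^n)` are then fitted to both by
#' weighted least squares (weights = per-bin division counts); the fitted
#' `t_half` is the arrest switch time.
#'
#' @param forest A [lineage_forest()]; arrest labels are computed with
#'   [label_arrested()] if absent.
#' @param bin_width Bin width (h); default 1.
#' @return An `arrest_fit` object: list with `empirical` (tibble of
#'   `bin_mid`, `n_div`, `n_ge1`, `n_two`, `p_hat`, `alpha_hat`), `p_fit`
#'   and `alpha_fit` ([fit_hill()] objects) and `bin_width`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
arrest_probabilities <- function(forest, bin_width = 1) {
  cells <- forest$cells
  if (all(is.na(cells$arrested))) {
    forest <- label_arrested(forest)
    cells <- forest$cells
  }
  mothers <- cells[cells$end_fate == "divided", ]
  kid_arr <- tapply(cells$arrested[!is.na(cells$parent_id)],
                    cells$parent_id[!is.na(cells$parent_id)],
                    function(a) sum(a, na.rm = TRUE))
  n_arr <- as.integer(kid_arr[mothers$cell_id])
  t_div <- mothers$end_time
  bin <- floor(t_div / bin_width) * bin_width
  emp <- tibble::tibble(bin = bin, n_arr = n_arr) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_div = dplyr::n(),
      n_ge1 = sum(.data$n_arr >= 1),
      n_two = sum(.data$n_arr == 2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_mid = .data$bin + bin_width / 2,
      p_hat = .data$n_ge1 / .data$n_div,
      alpha_hat = ifelse(.data$n_ge1 > 0, .data$n_two / .data$n_ge1, NA_real_)
    )
  p_fit <- tryCatch(
    fit_hill(emp, t = "bin_mid", p = "p_hat", weights = "n_div"),
    error = function(e) NULL
  )
  a_emp <- emp[!is.na(emp$alpha_hat), ]
  alpha_fit <- tryCatch(
    fit_hill(a_emp, t = "bin_mid", p = "alpha_hat", weights = "n_ge1"),
    error = function(e) NULL
  )
  structure(
    list(empirical = emp, p_fit = p_fit, alpha_fit = alpha_fit,
         bin_width = bin_width),
    class = "arrest_fit"
  )
}

#' @export
print.arrest_fit <- function(x, ...) {
  cat("<arrest_fit> ", nrow(x$empirical), " bins of ", x$bin_width, " h\n",
      sep = "")
  if (!is.null(x$p_fit) && x$p_fit$converged) {
    cat("  p(t): t_half = ", round(x$p_fit$coef[["t_half"]], 2),
        " hAPF, exponent = ", round(x$p_fit$coef[["exponent"]], 1),
        ", plateau = ", round(x$p_fit$coef[["plateau"]], 3), "\n", sep = "")
  } else {
    cat("  p(t): fit failed (empirical curve available)\n")
  }
  invisible(x)
}

#' @rdname arrest_probabilities
#' @param x An `arrest_fit`.
#' @param ... Unused.
#' @export
tidy.arrest_fit <- function(x, ...) {
  out <- list()
  if (!is.null(x$p_fit)) {
    out$p <- dplyr::mutate(tidy(x$p_fit), curve = "p", .before = 1)
  }
  if (!is.null(x$alpha_fit)) {
    out$alpha <- dplyr::mutate(tidy(x$alpha_fit), curve = "alpha", .before = 1)
  }
  dplyr::bind_rows(out)
}

#' @rdname arrest_probabilities
#' @export
glance.arrest_fit <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x$empirical),
    n_divisions = sum(x$empirical$n_div),
    p_converged = !is.null(x$p_fit) && x$p_fit$converged,
    alpha_converged = !is.null(x$alpha_fit) && x$alpha_fit$converged,
    switch_time = if (!is.null(x$p_fit) && x$p_fit$converged)
      x$p_fit$coef[["t_half"]] else NA_real_
  )
}

#' Fraction of newborn cells that are arrested
#'
#' Bins cells created by division by their birth time and reports the
#' fraction of newborns in each bin that never divide again (arrested).
#'
#' @inheritParams arrest_probabilities
#' @return Tibble with `bin_mid` (hAPF), `n_born`, `frac_arrested`.
#' @export
fraction_arrested_created <- function(forest, bin_width = 1) {
  cells <- forest$cells
  if (all(is.na(cells$arrested))) {
    forest <- label_arrested(forest)
    cells <- forest$cells
  }
  born <- cells[!is.na(cells$parent_id), ]
  bin <- floor(born$birth_time / bin_width) * bin_width
  tibble::tibble(bin = bin, arrested = born$arrested) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_born = dplyr::n(),
      frac_arrested = mean(.data$arrested, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin_mid = .data$bin + bin_width / 2, .after = "bin")
}

#' Binned x-y relation with per-bin SEM
#'
#' Bins paired observations by the x variable (equal-count bins by default,
#' or equal-width) and reports per-bin means with the standard error of the
#' mean, the standard display for cycle-time-versus-geometry relations.
#'
#' @param data Data frame.
#' @param x,y Columns (tidy evaluation).
#' @param n_bins Number of bins (>= 1).
#' @param method `"equal_count"` or `"equal_width"`.
#' @return Tibble with `bin`, `x_mean`, `y_mean`, `y_sem`, `n`.
#' @export
binned_relation <- function(data, x, y, n_bins = 10,
                            method = c("equal_count", "equal_width")) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) == 0) abort("empty input")
  if (n_bins < 1) abort("n_bins must be >= 1")
  bin <- if (method == "equal_count") {
    as.integer(cut(rank(xv, ties.method = "first"),
                   breaks = n_bins, labels = FALSE))
  } else {
    brk <- seq(min(xv), max(xv), length.out = n_bins + 1)
    brk[length(brk)] <- brk[length(brk)] + 1e-9 * max(1, abs(brk[length(brk)]))
    findInterval(xv, brk, rightmost.closed = TRUE)
  }
  tibble::tibble(bin = bin, x = xv, y = yv) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      x_mean = mean(.data$x),
      y_mean = mean(.data$y),
      y_sem = sd(.data$y) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Spatial correlation of neighbouring cycle times
#'
#' For every divided cell with a recorded centroid, finds the nearest
#' contemporaneous divided cell (alive at the focal cell's birth, positions
#' taken at the recorded frame closest to that time; distance ties broken
#' by lowest `cell_id`) and correlates the two cycle times. An absence of
#' spatial patterning in cycle times yields a coefficient near zero.
#'
#' @param forest A [lineage_forest()] with a `centroids` table.
#' @return One-row tibble with `pairing = "neighbor"`, `pearson`,
#'   `spearman`, `n_pairs`.
#' @export
neighbor_cycle_correlation <- function(forest) {
  if (is.null(forest$centroids)) abort("forest carries no centroid table")
  cells <- forest$cells
  ct <- cycle_times(forest)
  cent <- forest$centroids
  pos_at <- function(id, t) {
    rows <- cent[cent$cell_id == id, ]
    if (nrow(rows) == 0) return(c(NA_real_, NA_real_))
    k <- which.min(abs(rows$t - t))
    c(rows$x[k], rows$y[k])
  }
  eligible <- ct$cell_id
  t1 <- numeric(0); t2 <- numeric(0)
  for (i in seq_along(eligible)) {
    id <- eligible[i]
    b <- ct$birth_time[i]
    p <- pos_at(id, b)
    if (anyNA(p)) next
    alive <- cells$cell_id[cells$birth_time <= b & b < cells$end_time]
    others <- setdiff(intersect(alive, eligible), id)
    others <- sort(others)
    if (length(others) == 0) next
    d <- vapply(others, function(o) {
      q <- pos_at(o, b)
      if (anyNA(q)) return(Inf)
      sqrt(sum((p - q)^2))
    }, numeric(1))
    if (all(!is.finite(d))) next
    nn <- others[which.min(d)] # which.min takes the first (lowest id) on ties
    t1 <- c(t1, ct$cycle_time[i])
    t2 <- c(t2, ct$cycle_time[match(nn, ct$cell_id)])
  }
  if (length(t1) < 2) abort("fewer than 2 contemporaneous pairs")
  if (var(t1) == 0 || var(t2) == 0) {
    abort("zero variance: correlation undefined")
  }
  tibble::tibble(
    pairing = "neighbor",
    pearson = cor(t1, t2),
    spearman = cor(t1, t2, method = "spearman"),
    n_pairs = length(t1)
  )
}
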