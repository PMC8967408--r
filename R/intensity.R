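#' Bin junctional intensity by junction angle
#'
#' Junction orientation is axial (a junction at 100 degrees is the same
#' junction as one at -80), measured from the DV axis and folded into
#' `[0, 90]`. Intensities (e.g. junctional myosin II) are binned every
#' `bin_width` degrees and summarized by median and interquartile range,
#' computed with linear-interpolation quantiles.
#'
#' @param junctions Data frame with columns `angle_deg` (in `[0, 90]`) and
#'   `intensity` (arbitrary units, >= 0).
#' @param bin_width Bin width in degrees (default 5).
#' @return Tibble with `angle_lo`, `angle_mid`, `median`, `iqr`, `n`
#'   (empty bins reported with `n = 0`).
#' @export
bin_junction_intensity <- function(junctions, bin_width = 5) {
  if (nrow(junctions) == 0) abort("empty junction table")
  if (any(junctions$angle_deg < 0 | junctions$angle_deg > 90)) {
    abort("angles must lie in [0, 90] degrees")
  }
  edges <- seq(0, 90, by = bin_width)
  bin <- pmin(findInterval(junctions$angle_deg, edges), length(edges) - 1)
  filled <- tibble::tibble(bin = bin, intensity = junctions$intensity) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(median = median(.data$intensity),
                     iqr = IQR(.data$intensity),
                     n = dplyr::n(), .groups = "drop")
  tibble::tibble(bin = seq_len(length(edges) - 1)) |>
    dplyr::left_join(filled, by = "bin") |>
    dplyr::mutate(
      angle_lo = edges[.data$bin],
      angle_mid = edges[.data$bin] + bin_width / 2,
      n = dplyr::coalesce(.data$n, 0L)
    ) |>
    dplyr::select("angle_lo", "angle_mid", "median", "iqr", "n")
}

#' Normalize a pre-pupal ECM intensity series to its 13 hAPF value
#'
#' Basal extracellular-matrix reporter intensities measured through the
#' pre-pupal stages are rescaled so the value at the reference time
#' (13 hAPF, the first time point after head eversion once movement has
#' ceased) equals 1. The sample nearest the reference time (within half the
#' median frame interval) provides the reference value. The operation is
#' idempotent.
#'
#' @param series Data frame with columns `t` (hAPF) and `intensity`.
#' @param ref_time Reference time (hAPF), default 13.
#' @return The series with an added `normalized` column.
#' @export
normalize_prepupal_ecm <- function(series, ref_time = 13) {
  s <- tibble::as_tibble(series)
  dtt <- median(diff(sort(unique(s$t))))
  k <- which.min(abs(s$t - ref_time))
  if (abs(s$t[k] - ref_time) > dtt / 2 + 1e-9) {
    abort("series does not cover the reference time")
  }
  ref <- s$intensity[k]
  if (ref == 0) abort("zero intensity at the reference time")
  dplyr::mutate(s, normalized = .data$intensity / ref)
}

#' Normalize pupal ECM intensities under LECs and histoblasts
#'
#' The background `B` is the mean of the five frames with the lowest mean
#' intensity under the larval epidermal cells (LECs). Both series are
#' background-subtracted (`I - B`) and then scaled by a common factor so the
#' transformed initial LEC value equals 1; with `method = "divide"` the
#' subtracted series are instead divided by `B`. By construction the
#' minimum of the normalized LEC series is close to zero.
#'
#' @param series_lec,series_hist Data frames with `t` and `intensity`
#'   columns (LEC series needs >= `n_lowest` frames).
#' @param n_lowest Number of lowest LEC frames defining the background.
#' @param method `"subtract_rescale"` (default) or `"divide"`.
#' @return Tibble with columns `t`, `intensity`, `normalized`, `tissue`
#'   (`"lec"` / `"histoblast"`).
#' @export
normalize_pupal_ecm <- function(series_lec, series_hist, n_lowest = 5,
                                method = c("subtract_rescale", "divide")) {
  method <- match.arg(method)
  lec <- tibble::as_tibble(series_lec)
  hist <- tibble::as_tibble(series_hist)
  if (nrow(lec) < n_lowest) {
    abort(paste0("LEC series needs at least ", n_lowest, " frames"))
  }
  b <- mean(sort(lec$intensity)[seq_len(n_lowest)])
  scale <- if (method == "subtract_rescale") {
    first <- lec$intensity[which.min(lec$t)] - b
    if (first == 0) abort("initial LEC value equals the background")
    first
  } else {
    if (b == 0) abort("zero background")
    b
  }
  dplyr::bind_rows(
    dplyr::mutate(lec, normalized = (.data$intensity - b) / scale,
                  tissue = "lec"),
    dplyr::mutate(hist, normalized = (.data$intensity - b) / scale,
                  tissue = "histoblast")
  )
}

#' Per-frame FUCCI channel totals, normalized to the first frame
#'
#' Sums the GFP (G1/G2 reporter GFP-E2F1) and RFP (S/G2/M reporter
#' RFP-CycB) nucleus intensities per frame and divides each channel's
#' series by its total in the first frame, so both series start at 1.
#'
#' @param records Data frame with columns `t`, `gfp`, `rfp`.
#' @return Tibble with `t`, `channel` (`"gfp"`/`"rfp"`), `total`,
#'   `normalized`.
#' @export
fucci_total_series <- function(records) {
  totals <- tibble::as_tibble(records) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(gfp = sum(.data$gfp), rfp = sum(.data$rfp),
                     .groups = "drop") |>
    dplyr::arrange(.data$t) |>
    tidyr::pivot_longer(c("gfp", "rfp"), names_to = "channel",
                        values_to = "total")
  out <- totals |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(normalized = .data$total / dplyr::first(.data$total)) |>
    dplyr::ungroup()
  if (any(!is.finite(out$normalized))) {
    abort("zero channel total in the first frame")
  }
  out
}

#' Call cell-cycle phase from FUCCI channel ratios
#'
#' Each nucleus intensity is normalized by the mean over all nuclei in the
#' frame, per channel; the ratio `r = normalized RFP / normalized GFP` then
#' classifies the phase: `r < theta_low` means GFP only (G1),
#' `r > theta_high` means RFP dominant (S), in between both markers are
#' present (G2/M). The call depends only on the ratio, so it is invariant
#' under rescaling either channel's gain. Nuclei with zero intensity in
#' both channels are left unclassified.
#'
#' @param records Data frame with columns `nucleus_id`, `gfp`, `rfp`
#'   (>= 2 nuclei).
#' @param thresholds Length-2 numeric `(theta_low, theta_high)`; defaults
#'   `c(0.5, 2)`.
#' @return The records with added `gfp_norm`, `rfp_norm`, `ratio` and
#'   `phase` (`"G1"`, `"S"`, `"G2M"` or `"unclassified"`) columns.
#' @export
fucci_phase_call <- function(records, thresholds = c(0.5, 2)) {
  rec <- tibble::as_tibble(records)
  if (nrow(rec) < 2) abort("need at least 2 nuclei")
  rec$gfp_norm <- rec$gfp / mean(rec$gfp)
  rec$rfp_norm <- rec$rfp / mean(rec$rfp)
  rec$ratio <- ifelse(rec$gfp_norm > 0, rec$rfp_norm / rec$gfp_norm, Inf)
  rec$phase <- dplyr::case_when(
    rec$gfp == 0 & rec$rfp == 0 ~ "unclassified",
    rec$ratio < thresholds[1] ~ "G1",
    rec$ratio > thresholds[2] ~ "S",
    .default = "G2M"
  )
  rec
}
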