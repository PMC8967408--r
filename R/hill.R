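#' Hill function of developmental time
#'
#' `hill(t) = plateau * t^n / (t_half^n + t^n)`, evaluated in the numerically
#' stable form `plateau / (1 + (t_half/t)^n)` so that large exponents do not
#' overflow. Used to describe the sharp rise of the per-division arrest
#' probabilities p(t) and alpha(t).
#'
#' @param t Time (hAPF), non-negative.
#' @param t_half Half-maximum time (hAPF).
#' @param exponent Hill coefficient (> 0).
#' @param plateau Asymptotic value, in `[0, 1]` for probabilities.
#' @return Numeric vector of the same length as `t`.
#' @export
hill <- function(t, t_half, exponent, plateau = 1) {
  out <- ifelse(t <= 0, 0, plateau / (1 + exp(exponent * (log(t_half) - log(pmax(t, 1e-300))))))
  out
}

#' Fit a Hill curve to binned probabilities
#'
#' Weighted nonlinear least squares of `hill(t, t_half, exponent, plateau)`
#' against empirical per-bin probabilities, with weights proportional to the
#' number of events per bin (binomial weighting). Used by
#' [arrest_probabilities()] to extract the switch time of cell-cycle exit.
#'
#' @param data Data frame with the predictor and response columns.
#' @param t,p Column names (strings) of bin time and empirical probability.
#' @param weights Optional column name of per-bin weights (e.g. counts).
#' @param plateau_max Upper bound for the plateau (default 1).
#' @param start Optional named list of starting values
#'   (`t_half`, `exponent`, `plateau`).
#' @return An object of class `hill_fit`: list with `coef` (named vector),
#'   `fitted`, `data`, `converged`, and the underlying `nls` object (or
#'   `NULL` on failure). Supports [tidy()] and [glance()].
#' @export
fit_hill <- function(data, t = "t", p = "p", weights = NULL,
                     plateau_max = 1, start = NULL) {
  df <- tibble::tibble(t = data[[t]], p = data[[p]])
  df$w <- if (!is.null(weights)) data[[weights]] else rep(1, nrow(df))
  df <- df[complete.cases(df) & df$w > 0, ]
  if (nrow(df) < 3) abort("fit_hill needs at least 3 non-empty bins")
  if (is.null(start)) {
    pl0 <- min(max(max(df$p), 0.05), plateau_max)
    crossing <- df$t[df$p >= pl0 / 2]
    th0 <- if (length(crossing) > 0) min(crossing) else median(df$t)
    start <- list(t_half = th0, exponent = 8, plateau = pl0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ hill(t, t_half, exponent, plateau),
      data = df, start = start, weights = df$w,
      lower = c(t_half = min(df$t) / 2, exponent = 0.1, plateau = 1e-3),
      upper = c(t_half = max(df$t) * 2, exponent = 200, plateau = plateau_max),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  structure(
    list(
      coef = if (!is.null(fit)) coef(fit) else c(t_half = NA_real_, exponent = NA_real_, plateau = NA_real_),
      fitted = if (!is.null(fit)) as.numeric(stats::fitted(fit)) else rep(NA_real_, nrow(df)),
      data = df,
      converged = !is.null(fit),
      fit = fit
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>", if (x$converged) "" else "(fit failed)", "\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = c("t_half", "exponent", "plateau"),
                          estimate = NA_real_, std.error = NA_real_))
  }
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2])
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  rss <- if (x$converged) sum(x$data$w * (x$data$p - x$fitted)^2) else NA_real_
  tibble::tibble(converged = x$converged, n_bins = nrow(x$data),
                 weighted_rss = rss)
}
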