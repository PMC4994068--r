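#' Spatial ROI average of a movie stack
#'
#' Per-frame unweighted mean over the pixels inside the mask — the standard
#' way optical traces are extracted from small-chip imaging movies.
#'
#' @param stack A `frames x rows x cols` numeric array (see [render_movie()]
#'   or [read_movie_tiff()]).
#' @param mask Logical matrix of the same spatial dimensions.
#' @param sample_rate Sampling rate in Hz used for the time axis when the
#'   stack carries no `time_s` attribute.
#'
#' @return A trace tibble.
#' @export
roi_average <- function(stack, mask, sample_rate = 125) {
  if (!any(mask)) stop("`mask` must select at least one pixel", call. = FALSE)
  if (!identical(dim(stack)[2:3], dim(mask))) {
    stop("`mask` dimensions must match the stack frames", call. = FALSE)
  }
  v <- apply(stack, 1, function(frame) mean(frame[mask]))
  t <- attr(stack, "time_s")
  if (is.null(t)) t <- (seq_along(v) - 1) / sample_rate
  tibble::tibble(time_s = t, value = v)
}

#' Fit a double-exponential photobleaching baseline
#'
#' Least-squares fit of `b(t) = a_fast exp(-t/tau_fast) + a_slow
#' exp(-t/tau_slow) + offset` to a raw fluorescence trace, compensating for
#' rapid plus slow photobleaching. The stimulus/response window can (and by
#' default should) be excluded so the response does not bias the baseline.
#' The fit is multi-started over a grid of tau decades and the best
#' (lowest-SSE) converged fit is returned, with components ordered so
#' `tau_fast_s < tau_slow_s`.
#'
#' @param trace A raw fluorescence trace tibble.
#' @param exclude_window Optional `c(start_s, end_s)` to exclude from the
#'   fit (typically odor onset - 0.2 s to offset + 4 s).
#' @param tau_grid Time-constant starting values, seconds.
#'
#' @return An object of class `bleach_fit`: the [bleach_model()] parameters
#'   plus fit diagnostics; supports [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
fit_bleach <- function(trace, exclude_window = NULL,
                       tau_grid = c(0.3, 1, 3, 10, 30, 100)) {
  trace <- as_trace(trace)
  keep <- rep(TRUE, nrow(trace))
  if (!is.null(exclude_window)) {
    keep <- trace$time_s < exclude_window[1] | trace$time_s > exclude_window[2]
  }
  t <- trace$time_s[keep]
  yv <- trace$value[keep]
  if (length(yv) < 10) {
    stop("need at least 10 samples outside the excluded window", call. = FALSE)
  }

  # degenerate flat trace: amplitudes zero, offset = mean
  if (stats::sd(yv) < 1e-12 * max(abs(yv), 1)) {
    model <- bleach_model(0, 0, tau_grid[1], tau_grid[length(tau_grid)], mean(yv))
    return(structure(
      c(model, list(sse = 0, rmse = 0, n = length(yv), converged = TRUE)),
      class = c("bleach_fit", "bleach_model")
    ))
  }

  span <- max(yv) - min(yv)
  resid_fn <- function(par) {
    yv - (par[1] * exp(-t / par[3]) + par[2] * exp(-t / par[4]) + par[5])
  }
  best <- NULL
  starts <- expand.grid(tf = tau_grid, ts = tau_grid)
  starts <- starts[starts$tf < starts$ts, ]
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(span / 2, span / 2, starts$tf[i], starts$ts[i], min(yv)),
        fn = resid_fn,
        lower = c(-Inf, -Inf, 1e-4, 1e-4, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$info == 0 || fit$info == 9) next
    sse <- fit$deviance
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop("bleach fit failed to converge from any starting point (",
         nrow(starts), " starts, n = ", length(yv), ")", call. = FALSE)
  }
  cf <- stats::setNames(best$fit$par, c("af", "as", "tf", "ts", "off"))
  if (cf[["tf"]] > cf[["ts"]]) {
    cf <- c(af = cf[["as"]], as = cf[["af"]], tf = cf[["ts"]], ts = cf[["tf"]],
            off = cf[["off"]])
  }
  if (cf[["tf"]] == cf[["ts"]]) cf[["ts"]] <- cf[["ts"]] * (1 + 1e-9)
  model <- bleach_model(cf[["af"]], cf[["as"]], cf[["tf"]], cf[["ts"]], cf[["off"]])
  structure(
    c(model, list(
      sse = best$sse, rmse = sqrt(best$sse / length(yv)),
      n = length(yv), converged = TRUE
    )),
    class = c("bleach_fit", "bleach_model")
  )
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat("Double-exponential bleach fit\n")
  cat(sprintf("  b(t) = %.4g exp(-t/%.4g) + %.4g exp(-t/%.4g) + %.4g\n",
              x$a_fast, x$tau_fast_s, x$a_slow, x$tau_slow_s, x$offset))
  cat(sprintf("  n = %d, RMSE = %.4g\n", x$n, x$rmse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bleach fit
#'
#' @param x A `bleach_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @method tidy bleach_fit
#' @export
tidy.bleach_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a_fast", "a_slow", "tau_fast_s", "tau_slow_s", "offset"),
    estimate = c(x$a_fast, x$a_slow, x$tau_fast_s, x$tau_slow_s, x$offset)
  )
}

#' @rdname tidy.bleach_fit
#' @method glance bleach_fit
#' @export
glance.bleach_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, rmse = x$rmse, nobs = x$n, converged = x$converged)
}

#' Remove a fitted bleach baseline from a trace
#'
#' `divide` mode (default) returns `F(t) / b(t)`, giving a flat unit baseline
#' consistent with multiplicative bleaching and a subsequent dF/F; `subtract`
#' returns `F(t) - b(t) + offset`, preserving absolute units.
#'
#' @param trace A raw fluorescence trace tibble.
#' @param model A [bleach_model()] (or `bleach_fit`).
#' @param mode `"divide"` or `"subtract"`.
#'
#' @return A detrended trace tibble.
#' @export
detrend <- function(trace, model, mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  trace <- as_trace(trace)
  b <- bleach_baseline(model, trace$time_s)
  v <- if (mode == "divide") {
    if (any(b <= 0)) stop("baseline must be positive in divide mode", call. = FALSE)
    trace$value / b
  } else {
    trace$value - b + model$offset
  }
  tibble::tibble(time_s = trace$time_s, value = v)
}

#' Iterated box-car smoothing
#'
#' Applies `rounds` successive centered moving averages of odd `width`
#' (default eight rounds, the conventional post-correction smoothing for
#' small-chip voltage imaging). Edges are handled by reflection so repeated
#' rounds do not droop at the endpoints. Width 1 is the identity.
#'
#' @param trace A trace tibble.
#' @param width Odd window width in samples.
#' @param rounds Number of smoothing passes. Default 8.
#'
#' @return A smoothed trace tibble.
#' @export
boxcar <- function(trace, width = 3, rounds = 8) {
  if (width %% 2 == 0 || width < 1) {
    stop("`width` must be an odd positive sample count", call. = FALSE)
  }
  trace <- as_trace(trace)
  v <- trace$value
  if (width > 1) {
    h <- (width - 1) / 2
    for (r in seq_len(rounds)) {
      padded <- c(rev(v[2:(h + 1)]), v, rev(v[(length(v) - h):(length(v) - 1)]))
      v <- as.numeric(stats::filter(padded, rep(1 / width, width), sides = 2))
      v <- v[(h + 1):(h + length(trace$value))]
    }
  }
  tibble::tibble(time_s = trace$time_s, value = v)
}

#' Percent dF/F relative to a pre-stimulus baseline window
#'
#' `100 * (F - F0) / F0` with `F0` the mean over the baseline window, as
#' plotted on the dF/F axes of imaging figures.
#'
#' @param trace A (detrended) trace tibble.
#' @param baseline_window `c(start_s, end_s)`, a nonempty pre-stimulus window.
#'
#' @return A trace tibble in percent dF/F, with attributes
#'   `baseline_window` and `f0`.
#' @export
dff <- function(trace, baseline_window) {
  trace <- as_trace(trace)
  in_base <- trace$time_s >= baseline_window[1] & trace$time_s <= baseline_window[2]
  if (!any(in_base)) stop("baseline window contains no samples", call. = FALSE)
  f0 <- mean(trace$value[in_base])
  if (f0 <= 0) stop("baseline mean F0 must be positive", call. = FALSE)
  out <- tibble::tibble(time_s = trace$time_s, value = 100 * (trace$value - f0) / f0)
  attr(out, "baseline_window") <- baseline_window
  attr(out, "f0") <- f0
  out
}

#' Full fluorescence preprocessing chain
#'
#' Convenience wrapper: bleach fit (optionally excluding the response
#' window), divide-mode detrend, iterated box-car smoothing, percent dF/F.
#' For a dimming voltage indicator set `invert = TRUE` so responses come out
#' positive.
#'
#' @param trace A raw fluorescence trace tibble.
#' @param baseline_window Pre-stimulus window for dF/F, seconds.
#' @param exclude_window Window excluded from the bleach fit, seconds.
#' @param width,rounds Box-car parameters.
#' @param mode Detrend mode.
#' @param invert Multiply the final dF/F by -1 (dimming indicators).
#'
#' @return A percent dF/F trace tibble with a `bleach_fit` attribute.
#' @export
process_trace <- function(trace, baseline_window, exclude_window = NULL,
                          width = 3, rounds = 8, mode = "divide",
                          invert = FALSE) {
  fit <- fit_bleach(trace, exclude_window = exclude_window)
  out <- trace |>
    detrend(fit, mode = mode) |>
    boxcar(width = width, rounds = rounds) |>
    dff(baseline_window)
  if (invert) out$value <- -out$value
  attr(out, "bleach_fit") <- fit
  out
}
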