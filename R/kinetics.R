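# Aggregation kinetics: sigmoidal fits of dye-binding fluorescence curves,
# endpoint percent inhibition, the relative-concentration potency statistic
# (mM of inhibitor per 1% inhibition at a fixed endpoint) and dose-response
# summaries.

#' Construct a kinetic curve table
#'
#' Long-format container for plate-reader time series. Multiple curves live
#' in one data frame distinguished by `compound`, `dose` and `replicate`.
#'
#' @param time Times in minutes (strictly increasing within a curve).
#' @param signal Fluorescence (arbitrary units), same length as `time`.
#' @param compound Condition label (e.g. compound name or `"control"`).
#' @param dose Dose in mM.
#' @param replicate Replicate identifier.
#' @return A data frame with columns `time`, `signal`, `compound`, `dose`,
#'   `replicate`.
#' @export
kinetic_curve <- function(time, signal, compound = "control", dose = 0,
                          replicate = 1L) {
  stopifnot(length(time) == length(signal), !is.unsorted(time, strictly = TRUE))
  data.frame(time = time, signal = signal, compound = compound,
             dose = dose, replicate = replicate)
}

# average replicates of one condition onto the union time grid
.mean_curve <- function(curve) {
  agg <- stats::aggregate(signal ~ time, data = curve, FUN = mean)
  agg[order(agg$time), , drop = FALSE]
}

# signal at an endpoint, linearly interpolated between bracketing samples
.endpoint_signal <- function(curve, endpoint) {
  mc <- .mean_curve(curve)
  if (endpoint < min(mc$time) || endpoint > max(mc$time)) {
    stop("endpoint ", endpoint, " min is outside the sampled range [",
         min(mc$time), ", ", max(mc$time), "]")
  }
  stats::approx(mc$time, mc$signal, xout = endpoint)$y
}

#' Fit a sigmoidal growth model to an aggregation curve
#'
#' Least-squares fit of `signal = baseline + amplitude / (1 + exp(-rate *
#' (time - t_half)))` (logistic; the default) or the Gompertz form `baseline
#' + amplitude * exp(-exp(-rate * (time - t_half)))`. The lag time is the
#' standard tangent construction at the inflection point: `t_half - 2/rate`
#' for the logistic model, `t_half - (e - 1)/rate` for Gompertz.
#'
#' Non-convergence does not raise an error: the returned fit is flagged
#' (`status = "non-converged"`) and carries the start values and residual sum
#' of squares. A flat curve is flagged `status = "flat"` with amplitude 0 and
#' undefined lag.
#'
#' @param curve Data frame with columns `time` (min) and `signal` (a.u.);
#'   at least 6 points. Replicates are averaged per time point.
#' @param model `"logistic"` or `"gompertz"`.
#' @return An object of class `sigmoid_fit` with components `coefficients`
#'   (baseline, amplitude, rate, t_half), `lag_time`, `rss`, `status`,
#'   `model`, `data`, `fitted.values`, `residuals`.
#' @export
fit_sigmoid <- function(curve, model = c("logistic", "gompertz")) {
  model <- match.arg(model)
  mc <- .mean_curve(curve)
  if (nrow(mc) < 6L) stop("need at least 6 time points to fit a sigmoid")
  t <- mc$time; y <- mc$signal
  fun <- if (model == "logistic") {
    function(t, p) p[1] + p[2] / (1 + exp(-p[3] * (t - p[4])))
  } else {
    function(t, p) p[1] + p[2] * exp(-exp(-p[3] * (t - p[4])))
  }
  lag_of <- function(rate, t_half) {
    if (model == "logistic") t_half - 2 / rate
    else t_half - (exp(1) - 1) / rate
  }
  rng <- diff(range(y))
  if (rng < 1e-10 || rng < 1e-8 * max(abs(y), 1)) {
    cf <- c(baseline = mean(y), amplitude = 0, rate = NA_real_,
            t_half = NA_real_)
    fit <- structure(list(coefficients = cf, lag_time = NA_real_,
                          rss = sum((y - mean(y))^2), status = "flat",
                          model = model, data = mc,
                          fitted.values = rep(mean(y), length(y)),
                          residuals = y - mean(y)),
                     class = "sigmoid_fit")
    return(fit)
  }
  # start values: baseline and amplitude from the range, t_half where the
  # curve crosses half-rise, rate from the 25-75% rise interval
  b0 <- min(y); a0 <- rng
  half <- b0 + a0 / 2
  t50 <- t[which.min(abs(y - half))]
  t25 <- t[which.min(abs(y - (b0 + 0.25 * a0)))]
  t75 <- t[which.min(abs(y - (b0 + 0.75 * a0)))]
  r0 <- if (t75 > t25) 2.2 / (t75 - t25) else 4 / diff(range(t))
  start <- list(baseline = b0, amplitude = a0, rate = r0, t_half = t50)
  frm <- if (model == "logistic") {
    y ~ baseline + amplitude / (1 + exp(-rate * (t - t_half)))
  } else {
    y ~ baseline + amplitude * exp(-exp(-rate * (t - t_half)))
  }
  env <- list(y = y, t = t)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(frm, data = env, start = start,
                      lower = c(-Inf, 0, 1e-8, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(nls_fit)) {
    p0 <- unlist(start)
    fitted0 <- fun(t, p0)
    return(structure(list(coefficients = c(baseline = p0[[1]],
                                           amplitude = p0[[2]],
                                           rate = p0[[3]], t_half = p0[[4]]),
                          lag_time = lag_of(p0[[3]], p0[[4]]),
                          rss = sum((y - fitted0)^2),
                          status = "non-converged", model = model, data = mc,
                          fitted.values = fitted0, residuals = y - fitted0),
                     class = "sigmoid_fit"))
  }
  cf <- stats::coef(nls_fit)
  fitted_v <- as.numeric(stats::fitted(nls_fit))
  structure(list(coefficients = cf,
                 lag_time = if (cf[["amplitude"]] > 1e-8 * rng)
                   lag_of(cf[["rate"]], cf[["t_half"]]) else NA_real_,
                 rss = sum(stats::residuals(nls_fit)^2),
                 status = "ok", model = model, data = mc,
                 fitted.values = fitted_v, residuals = y - fitted_v),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Sigmoid fit (%s), status: %s\n", x$model, x$status))
  cat(sprintf("  baseline  %10.4g a.u.\n  amplitude %10.4g a.u.\n",
              cf[["baseline"]], cf[["amplitude"]]))
  cat(sprintf("  rate      %10.4g /min\n  t_half    %10.4g min\n",
              cf[["rate"]], cf[["t_half"]]))
  cat(sprintf("  lag time  %10.4g min\n  RSS       %10.4g\n",
              x$lag_time, x$rss))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
fitted.sigmoid_fit <- function(object, ...) object$fitted.values

#' @export
residuals.sigmoid_fit <- function(object, ...) object$residuals

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else
    if (is.data.frame(newdata)) newdata$time else newdata
  p <- object$coefficients
  if (object$status == "flat") return(rep(p[["baseline"]], length(t)))
  if (object$model == "logistic") {
    p[["baseline"]] + p[["amplitude"]] /
      (1 + exp(-p[["rate"]] * (t - p[["t_half"]])))
  } else {
    p[["baseline"]] + p[["amplitude"]] *
      exp(-exp(-p[["rate"]] * (t - p[["t_half"]])))
  }
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  n <- nrow(object$data)
  sigma <- sqrt(object$rss / max(n - 4, 1))
  out <- list(coefficients = object$coefficients, lag_time = object$lag_time,
              rss = object$rss, sigma = sigma, n = n, status = object$status,
              model = object$model)
  class(out) <- "summary.sigmoid_fit"
  out
}

#' @export
print.summary.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit summary (%s, %d points, status %s)\n",
              x$model, x$n, x$status))
  print(round(x$coefficients, 6))
  cat(sprintf("lag time %.4g min, residual sd %.4g a.u., RSS %.4g\n",
              x$lag_time, x$sigma, x$rss))
  invisible(x)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$signal, xlab = "time (min)",
                 ylab = "signal (a.u.)", ...)
  tt <- seq(min(x$data$time), max(x$data$time), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' @export
simulate.sigmoid_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  sigma <- sqrt(object$rss / max(n - 4, 1))
  mu <- predict(object, object$data$time)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(n, sd = sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(time = object$data$time, out)
}

#' Percent inhibition at an endpoint
#'
#' `100 * (1 - treated(endpoint) / control(endpoint))` on baseline-subtracted,
#' replicate-averaged signals, with the endpoint value linearly interpolated
#' between the bracketing samples. Negative values indicate acceleration of
#' aggregation and are allowed.
#'
#' @param treated,control Kinetic-curve data frames (columns `time`,
#'   `signal`, optionally `replicate`); both must span the endpoint.
#' @param endpoint Endpoint in minutes (default 1000).
#' @param baseline Baseline handling: `"first"` subtracts each curve's first
#'   (averaged) sample, `"fitted"` subtracts the fitted sigmoid baseline,
#'   `"none"` uses raw signals.
#' @return Percent inhibition (scalar; may be negative).
#' @export
percent_inhibition <- function(treated, control, endpoint = 1000,
                               baseline = c("first", "fitted", "none")) {
  baseline <- match.arg(baseline)
  base_of <- function(curve) {
    switch(baseline,
           first = .mean_curve(curve)$signal[1],
           fitted = fit_sigmoid(curve)$coefficients[["baseline"]],
           none = 0)
  }
  tr <- .endpoint_signal(treated, endpoint) - base_of(treated)
  ct <- .endpoint_signal(control, endpoint) - base_of(control)
  if (!is.finite(ct) || ct <= 0) {
    stop("control endpoint signal is not positive after baseline subtraction")
  }
  100 * (1 - tr / ct)
}

#' Relative concentration: mM of inhibitor per 1% inhibition
#'
#' The potency statistic: inhibitor concentration divided by the percent
#' inhibition at the endpoint. It estimates the minimal concentration
#' required to inhibit 1% of fibrillization; lower values mean more potent
#' compounds. For non-positive inhibition (non-inhibitors/accelerators) the
#' value is undefined and `NA` is returned.
#'
#' @param concentration Concentration(s) in mM.
#' @param inhibition Percent inhibition value(s).
#' @return Numeric vector (mM per 1% inhibition); `NA` where
#'   `inhibition <= 0`, with attribute `non_inhibitor` flagging those entries.
#' @export
relative_concentration <- function(concentration, inhibition) {
  stopifnot(length(concentration) == length(inhibition) ||
              length(concentration) == 1L || length(inhibition) == 1L)
  out <- ifelse(inhibition > 0, concentration / inhibition, NA_real_)
  attr(out, "non_inhibitor") <- !(inhibition > 0)
  out
}

#' Dose-response table and matrix
#'
#' Summarizes a grouped curve set against a designated control: per compound
#' and dose, the baseline-subtracted endpoint signal, the endpoint difference
#' versus control (positive = inhibition/rescue, negative = acceleration),
#' percent inhibition (mean and s.d. across replicates) and the relative
#' concentration.
#'
#' @param curves Long-format curve data frame (columns `time`, `signal`,
#'   `compound`, `dose`, `replicate`).
#' @param control_label Value of `compound` identifying the control.
#' @param endpoint Endpoint in minutes.
#' @param baseline Passed to [percent_inhibition()].
#' @return A list of class `dose_response`: `table` (one row per compound x
#'   dose) and `matrix` (compound x dose endpoint differences vs control).
#' @export
dose_response <- function(curves, control_label = "control", endpoint = 1000,
                          baseline = c("first", "fitted", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("time", "signal", "compound", "dose") %in% names(curves)))
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  control <- curves[curves$compound == control_label, , drop = FALSE]
  if (nrow(control) == 0L) {
    stop("no control curves labeled '", control_label, "'")
  }
  ctrl_end <- .endpoint_signal(control, endpoint) -
    switch(baseline, first = .mean_curve(control)$signal[1],
           fitted = fit_sigmoid(control)$coefficients[["baseline"]],
           none = 0)
  groups <- unique(curves[curves$compound != control_label,
                          c("compound", "dose")])
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    cmp <- groups$compound[k]; d <- groups$dose[k]
    sub <- curves[curves$compound == cmp & curves$dose == d, , drop = FALSE]
    inh <- percent_inhibition(sub, control, endpoint, baseline)
    per_rep <- vapply(unique(sub$replicate), function(r) {
      percent_inhibition(sub[sub$replicate == r, , drop = FALSE], control,
                         endpoint, baseline)
    }, numeric(1))
    data.frame(compound = cmp, dose = d,
               endpoint_signal = ctrl_end * (1 - inh / 100),
               diff_vs_control = ctrl_end * inh / 100,
               percent_inhibition = inh,
               inhibition_sd = if (length(per_rep) > 1) stats::sd(per_rep)
                               else NA_real_,
               relative_concentration =
                 as.numeric(relative_concentration(d, inh)))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  compounds <- unique(tab$compound)
  doses <- sort(unique(tab$dose))
  mat <- matrix(NA_real_, length(compounds), length(doses),
                dimnames = list(compounds, as.character(doses)))
  for (k in seq_len(nrow(tab))) {
    mat[tab$compound[k], as.character(tab$dose[k])] <- tab$diff_vs_control[k]
  }
  structure(list(table = tab, matrix = mat, endpoint = endpoint,
                 control = control_label), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response at", x$endpoint, "min vs control '", x$control, "'\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Per-compound potency table
#'
#' Convenience extraction from [dose_response()]: one row per compound and
#' dose with percent inhibition and relative concentration, ranked by
#' potency (ascending relative concentration; non-inhibitors last).
#'
#' @inheritParams dose_response
#' @return Data frame sorted by relative concentration.
#' @export
potency_table <- function(curves, control_label = "control", endpoint = 1000,
                          baseline = "first") {
  dr <- dose_response(curves, control_label, endpoint, baseline)
  tab <- dr$table
  tab$non_inhibitor <- !(tab$percent_inhibition > 0)
  tab[order(tab$non_inhibitor, tab$relative_concentration), , drop = FALSE]
}
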