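# Confined-diffusion (Kusumi-form) fitting of MSD curves.

# Single-exponential confined-diffusion model for one axis: a particle
# diffusing with coefficient D in a reflecting interval of length L has
#   MSD(t) = (L^2/6) * (1 - exp(-12 D t / L^2))  [+ offset],
# the standard single-exponential approximation of the Kusumi confined-
# diffusion series. Asymptote L^2/6 (+ offset); initial slope 2 D t.
msd_confined_model <- function(t, L, D, offset = 0) {
  (L^2 / 6) * (1 - exp(-12 * D * t / L^2)) + offset
}

#' Fit a confined-diffusion model to an MSD curve
#'
#' Weighted nonlinear least squares of
#' `MSD(t) = (L^2/6) * (1 - exp(-12*D*t/L^2)) [+ offset]`
#' against lag time, with weights equal to the number of displacement pairs
#' behind each MSD point. `L` is the confinement length on the curve's axis
#' and `D` the short-time diffusion coefficient; the optional constant
#' `offset` absorbs a localization-noise floor (off by default). Fitting
#' uses Levenberg-Marquardt with a small multi-start grid; a fit that fails
#' to converge from every start is returned flagged
#' (`converged = FALSE`, `plateau_reached = FALSE`).
#'
#' A fit is classified `plateau_reached` when the fitted `L` does not exceed
#' the cell dimension on that axis *and* the observation span covers at
#' least three relaxation times `L^2 / (12 D)` — curves still rising at the
#' longest measured lag (apparent confinement larger than the cell) are the
#' tracks one excludes from confinement averages.
#'
#' @param curve an `msd_curve` from [compute_msd()] or [average_msd()] with
#'   at least 4 lag points.
#' @param cell_dim cell dimension on the curve's axis (um); `Inf` disables
#'   the size check.
#' @param with_offset fit the constant noise-floor term?
#' @return A `confinement_fit` with components `L` (um), `D` (um^2/s),
#'   `offset` (um^2), `rss` (weighted, um^4), `plateau_reached`,
#'   `converged`, `asymptote` (`L^2/6 + offset`), plus the data. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' lags <- seq(10, 600, 10)
#' curve <- structure(
#'   data.frame(lag_s = lags,
#'              msd_um2 = msd_confined_model(lags, L = 0.6, D = 2e-3),
#'              n_pairs = rev(seq_along(lags))),
#'   class = c("msd_curve", "data.frame"), axis = "long")
#' fit <- fit_confinement(curve, cell_dim = 3)
#' coef(fit) # recovers L = 0.6, D = 2e-3
#' @export
fit_confinement <- function(curve, cell_dim = Inf, with_offset = FALSE) {
  if (!is.data.frame(curve) || nrow(curve) < 4L)
    stop("need an MSD curve with at least 4 lag points", call. = FALSE)
  t <- curve$lag_s
  m <- curve$msd_um2
  w <- if (!is.null(curve$n_pairs)) as.numeric(curve$n_pairs) else rep(1, length(t))
  axis <- attr(curve, "axis") %||% "long"

  # starting values: plateau from the tail, D from the initial secant
  plateau0 <- max(mean(m[t >= stats::quantile(t, 0.7)]), max(m) * 0.5, 1e-12)
  L0 <- sqrt(6 * plateau0)
  D0 <- max(m[1] / (2 * t[1]), 1e-12)
  starts <- expand.grid(L = L0 * c(0.5, 1, 2), D = D0 * c(0.3, 1, 3))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- if (with_offset)
      list(L = starts$L[i], D = starts$D[i], offset = 0)
    else list(L = starts$L[i], D = starts$D[i])
    fml <- if (with_offset)
      m ~ (L^2 / 6) * (1 - exp(-12 * D * t / L^2)) + offset
    else m ~ (L^2 / 6) * (1 - exp(-12 * D * t / L^2))
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = data.frame(t = t, m = m), start = st,
                        weights = w,
                        lower = if (with_offset) c(1e-6, 1e-12, 0)
                                else c(1e-6, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    # flagged non-convergent fit: report the heuristic starts
    out <- list(L = L0, D = D0, offset = 0, rss = NA_real_,
                converged = FALSE, plateau_reached = FALSE)
  } else {
    cf <- stats::coef(best$fit)
    out <- list(L = unname(cf["L"]), D = unname(cf["D"]),
                offset = if (with_offset) unname(cf["offset"]) else 0,
                rss = best$rss, converged = TRUE)
    relax <- out$L^2 / (12 * out$D)
    out$plateau_reached <- (out$L <= cell_dim) && (max(t) >= 3 * relax)
  }
  out$asymptote <- out$L^2 / 6 + out$offset
  out$axis <- axis
  out$cell_dim <- cell_dim
  out$with_offset <- with_offset
  out$data <- data.frame(lag_s = t, msd_um2 = m, n_pairs = w)
  class(out) <- "confinement_fit"
  out
}

#' @export
print.confinement_fit <- function(x, ...) {
  cat(sprintf("Confined-diffusion fit (%s axis)\n", x$axis))
  cat(sprintf("  L = %.4g um, D = %.4g um^2/s%s\n", x$L, x$D,
              if (x$with_offset) sprintf(", offset = %.3g um^2", x$offset) else ""))
  cat(sprintf("  asymptote L^2/6%s = %.4g um^2, plateau %sreached%s\n",
              if (x$with_offset) " + offset" else "", x$asymptote,
              if (x$plateau_reached) "" else "not ",
              if (x$converged) "" else " (fit did not converge)"))
  invisible(x)
}

#' @export
coef.confinement_fit <- function(object, ...) {
  if (object$with_offset)
    c(L = object$L, D = object$D, offset = object$offset)
  else c(L = object$L, D = object$D)
}

#' @export
predict.confinement_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$lag_s
       else if (is.data.frame(newdata)) newdata$lag_s else as.numeric(newdata)
  msd_confined_model(t, object$L, object$D, object$offset)
}

#' @export
fitted.confinement_fit <- function(object, ...) predict(object)

#' @export
residuals.confinement_fit <- function(object, ...) {
  object$data$msd_um2 - fitted(object)
}

#' @export
summary.confinement_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 relaxation_s = object$L^2 / (12 * object$D),
                 rmse = sqrt(mean(res^2)), n = nrow(object$data)),
            class = "summary.confinement_fit")
}

#' @export
print.summary.confinement_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  relaxation time L^2/(12 D) = %.3g s; RMSE = %.3g um^2 over %d lags\n",
              x$relaxation_s, x$rmse, x$n))
  invisible(x)
}

#' @export
plot.confinement_fit <- function(x, ...) {
  plot(x$data$lag_s, x$data$msd_um2, pch = 16, xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)), ...)
  tt <- seq(0, max(x$data$lag_s), length.out = 200)
  lines(tt, msd_confined_model(tt, x$L, x$D, x$offset))
  abline(h = x$asymptote, lty = 3)
  invisible(x)
}
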