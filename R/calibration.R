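#' Fit the chain-length calibration CL = a (R2/eta) + b
#'
#' The central model of the package: across chemically similar oils the
#' viscosity-normalized transverse relaxation rate R2/eta is proportional to
#' molecular weight, and hence to the carbon chain length CL of the dominant
#' acyl/backbone chain. The calibration is an ordinary least-squares fit of
#' CL on R2/eta over liquid reference oils.
#'
#' Records must provide \code{chain_length} and either \code{r2_over_eta}
#' directly or both \code{r2_per_s} and \code{viscosity_cp} (from which the
#' predictor is derived). Only liquid records with a positive predictor enter
#' the fit; solids lack a meaningful bulk viscosity.
#'
#' @param records a data.frame of oil records, e.g. [oil_table()]\code{("table1")}
#'   or the output of [read_oil_table()].
#' @return an object of class \code{"cl_calibration"}: list with
#'   \code{slope_a}, \code{intercept_b}, \code{coefficients} (named
#'   \code{b, a}), \code{n_samples}, \code{r_squared}, \code{rmse_cl},
#'   \code{residuals} (named by oil), \code{fitted}, \code{data},
#'   \code{predictor_range} and the underlying \code{lm} fit.
#' @examples
#' cal <- fit_calibration(oil_table("table1"))
#' cal
#' predict(cal, r2_over_eta = 0.370726)   # oleic acid -> 18 carbons
#' @seealso [predict.cl_calibration()], [loo_cross_validate()]
#' @export
fit_calibration <- function(records) {
  records <- .calibration_records(records)
  if (nrow(records) < 3L)
    stop("calibration needs at least 3 liquid records with CL and R2/eta",
         call. = FALSE)
  if (stats::sd(records$r2_over_eta) == 0)
    stop("degenerate fit: zero variance in the R2/eta predictor", call. = FALSE)
  fit <- stats::lm(chain_length ~ r2_over_eta, data = records)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  names(res) <- records$name
  tss <- sum((records$chain_length - mean(records$chain_length))^2)
  structure(
    list(
      slope_a = unname(cf[["r2_over_eta"]]),
      intercept_b = unname(cf[["(Intercept)"]]),
      coefficients = c(b = unname(cf[["(Intercept)"]]),
                       a = unname(cf[["r2_over_eta"]])),
      n_samples = nrow(records),
      r_squared = 1 - sum(res^2) / tss,
      rmse_cl = sqrt(mean(res^2)),
      residuals = res,
      fitted = stats::fitted(fit),
      data = records,
      predictor_range = range(records$r2_over_eta),
      lm = fit
    ),
    class = "cl_calibration"
  )
}

# normalize an oil-record table for fitting: keep liquids, derive the
# predictor if absent, check internal consistency when both forms are present
.calibration_records <- function(records) {
  if (!is.data.frame(records))
    stop("'records' must be a data.frame of oil records", call. = FALSE)
  if (!"chain_length" %in% names(records))
    stop("records lack a 'chain_length' column", call. = FALSE)
  if (!"name" %in% names(records))
    records$name <- paste0("oil_", seq_len(nrow(records)))
  if (!"r2_over_eta" %in% names(records)) {
    if (!all(c("r2_per_s", "viscosity_cp") %in% names(records)))
      stop("records need 'r2_over_eta', or 'r2_per_s' plus 'viscosity_cp'",
           call. = FALSE)
    records$r2_over_eta <- records$r2_per_s / records$viscosity_cp
  } else if (all(c("r2_per_s", "viscosity_cp") %in% names(records))) {
    full <- stats::complete.cases(records[c("r2_over_eta", "r2_per_s",
                                            "viscosity_cp")])
    rel <- abs(records$r2_over_eta[full] -
                 records$r2_per_s[full] / records$viscosity_cp[full]) /
      records$r2_over_eta[full]
    if (any(rel > 1e-4))
      warning("r2_over_eta inconsistent with r2_per_s/viscosity_cp beyond ",
              "1e-4 relative for: ",
              paste(records$name[full][rel > 1e-4], collapse = ", "),
              call. = FALSE)
  }
  if ("state" %in% names(records)) records <- records[records$state == "liquid", ]
  ok <- is.finite(records$r2_over_eta) & records$r2_over_eta > 0 &
    is.finite(records$chain_length) & records$chain_length >= 1
  records[ok, , drop = FALSE]
}

#' @export
print.cl_calibration <- function(x, digits = 6, ...) {
  cat("Chain-length calibration: CL = a * (R2/eta) + b\n")
  cat(sprintf("  a = %.*g   b = %.*g   (n = %d oils)\n",
              digits, x$slope_a, digits, x$intercept_b, x$n_samples))
  cat(sprintf("  R^2 = %.4f   RMSE = %.3f carbons\n", x$r_squared, x$rmse_cl))
  invisible(x)
}

#' @export
summary.cl_calibration <- function(object, ...) {
  out <- list(
    coefficients = object$coefficients,
    n_samples = object$n_samples,
    r_squared = object$r_squared,
    rmse_cl = object$rmse_cl,
    predictor_range = object$predictor_range,
    residual_table = data.frame(
      name = object$data$name,
      chain_length = object$data$chain_length,
      r2_over_eta = object$data$r2_over_eta,
      fitted = unname(object$fitted),
      residual = unname(object$residuals)
    )
  )
  class(out) <- "summary.cl_calibration"
  out
}

#' @export
print.summary.cl_calibration <- function(x, ...) {
  cat("Chain-length calibration summary\n")
  cat(sprintf("  CL = %.4f * (R2/eta) %+.4f,  n = %d,  R^2 = %.4f,  RMSE = %.3f\n",
              x$coefficients["a"], x$coefficients["b"], x$n_samples,
              x$r_squared, x$rmse_cl))
  cat(sprintf("  predictor range: [%.4g, %.4g] s^-1 cp^-1\n",
              x$predictor_range[1], x$predictor_range[2]))
  print(x$residual_table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cl_calibration <- function(object, ...) object$coefficients

#' @export
residuals.cl_calibration <- function(object, ...) object$residuals

#' @export
fitted.cl_calibration <- function(object, ...) object$fitted

#' Predict carbon chain length from relaxation data
#'
#' Applies the fitted calibration. Supply either the predictor
#' \code{r2_over_eta} directly, or \code{r2_per_s} together with
#' \code{viscosity_cp}. Predictions outside the training predictor range are
#' flagged as extrapolation; the calibration was established on chain lengths
#' 3-24, and general vegetable oils can exceed that.
#'
#' @param object a fitted \code{"cl_calibration"}.
#' @param r2_over_eta viscosity-normalized rate, s^-1 cp^-1.
#' @param r2_per_s transverse rate, s^-1 (with \code{viscosity_cp}).
#' @param viscosity_cp viscosity, cp.
#' @param ... unused.
#' @return a data.frame with columns \code{r2_over_eta}, \code{cl} (real
#'   prediction), \code{cl_rounded} (nearest integer, ties away from zero)
#'   and \code{extrapolated}.
#' @export
predict.cl_calibration <- function(object, r2_over_eta = NULL,
                                   r2_per_s = NULL, viscosity_cp = NULL, ...) {
  if (is.null(r2_over_eta)) {
    if (is.null(r2_per_s) || is.null(viscosity_cp))
      stop("supply 'r2_over_eta', or 'r2_per_s' plus 'viscosity_cp'",
           call. = FALSE)
    r2_over_eta <- normalize_by_viscosity(r2_per_s, viscosity_cp)
  }
  if (any(!is.finite(r2_over_eta)) || any(r2_over_eta <= 0))
    stop("'r2_over_eta' must be finite and strictly positive", call. = FALSE)
  cl <- object$slope_a * r2_over_eta + object$intercept_b
  data.frame(
    r2_over_eta = r2_over_eta,
    cl = cl,
    cl_rounded = .round_half_away(cl),
    extrapolated = r2_over_eta < object$predictor_range[1] |
      r2_over_eta > object$predictor_range[2]
  )
}

# nearest integer, ties away from zero (round() rounds half to even)
.round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Predict chain length from a rate and a viscosity
#'
#' Thin convenience wrapper around [predict.cl_calibration()].
#'
#' @param model a fitted \code{"cl_calibration"}.
#' @param r2_per_s transverse relaxation rate, s^-1.
#' @param viscosity_cp viscosity, cp.
#' @return as [predict.cl_calibration()].
#' @export
predict_chain_length <- function(model, r2_per_s, viscosity_cp) {
  if (!inherits(model, "cl_calibration"))
    stop("'model' must be a fitted cl_calibration object", call. = FALSE)
  predict(model, r2_per_s = r2_per_s, viscosity_cp = viscosity_cp)
}

#' Calibration scatter plot
#'
#' Chain length against R2/eta with the fitted line, the standard diagnostic
#' view of the calibration.
#'
#' @param x a \code{"cl_calibration"} object.
#' @param ... passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.cl_calibration <- function(x, ...) {
  graphics::plot(x$data$r2_over_eta, x$data$chain_length,
                 xlab = expression(R[2] / eta ~ (s^-1 ~ cp^-1)),
                 ylab = "carbon chain length CL", pch = 19, ...)
  graphics::abline(x$intercept_b, x$slope_a, lty = 2)
  invisible(x)
}

#' Simulate chain-length responses from the fitted calibration
#'
#' Draws new CL values at the training predictor values using the residual
#' standard error of the fit (delegates to the underlying linear model).
#'
#' @param object a \code{"cl_calibration"}.
#' @param nsim number of simulated response sets.
#' @param seed optional RNG seed.
#' @param ... passed on.
#' @return a data.frame, one column per simulation.
#' @export
simulate.cl_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)
}

#' Leave-one-out cross-validation of the calibration
#'
#' Refits the calibration with each oil held out in turn and reports the
#' held-out prediction error, a direct estimate of how well the model
#' transfers to an unseen oil of the same family.
#'
#' @param records oil records as for [fit_calibration()]; at least 4 usable
#'   rows.
#' @return a data.frame with columns \code{name}, \code{chain_length},
#'   \code{predicted}, \code{error} (signed, held-out), with attributes
#'   \code{loo_rmse} and \code{in_sample_rmse}.
#' @export
loo_cross_validate <- function(records) {
  recs <- .calibration_records(records)
  if (nrow(recs) < 4L)
    stop("leave-one-out cross-validation needs at least 4 records",
         call. = FALSE)
  full <- fit_calibration(recs)
  pred <- vapply(seq_len(nrow(recs)), function(i) {
    m <- fit_calibration(recs[-i, , drop = FALSE])
    m$slope_a * recs$r2_over_eta[i] + m$intercept_b
  }, numeric(1))
  out <- data.frame(
    name = recs$name,
    chain_length = recs$chain_length,
    predicted = pred,
    error = pred - recs$chain_length
  )
  attr(out, "loo_rmse") <- sqrt(mean(out$error^2))
  attr(out, "in_sample_rmse") <- full$rmse_cl
  out
}
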