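# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a CPMG echo train
#'
#' Generates a mono-exponential echo train at the default bench acquisition
#' settings (23 MHz, TE 0.3 ms, 1000 echoes, 16 scans), with additive
#' Gaussian noise expressed as a fraction of the initial amplitude. The true
#' T2 can be given directly or looked up by oil name from the bundled
#' reference table (the printed T2 column).
#'
#' @param oil optional oil name from the reference \code{table}
#'   (case-insensitive); an unknown name raises an error listing the
#'   available names.
#' @param t2_ms true transverse relaxation time in ms (used when \code{oil}
#'   is \code{NULL}).
#' @param m0 initial amplitude (default 1).
#' @param noise_sigma_rel Gaussian noise standard deviation as a fraction of
#'   \code{m0}. Default 0.005, consistent with the high signal-to-noise of a
#'   16-scan oil acquisition.
#' @param seed optional integer; fixes the noise bit-for-bit.
#' @param meta acquisition metadata, see [acquisition_defaults()].
#' @param table reference oil table used for name lookup.
#' @return an [echo_train()] object.
#' @examples
#' tr <- make_cpmg(oil = "Tributyrin", noise_sigma_rel = 0)
#' fit_monoexponential(tr)$t2_ms   # 325 ms
#' @export
make_cpmg <- function(oil = NULL, t2_ms = NULL, m0 = 1,
                      noise_sigma_rel = 0.005, seed = NULL,
                      meta = acquisition_defaults(),
                      table = oil_table("table1")) {
  if (!is.null(oil)) {
    i <- match(tolower(oil), tolower(table$name))
    if (is.na(i))
      stop("unknown oil '", oil, "'; available: ",
           paste(table$name, collapse = ", "), call. = FALSE)
    t2_ms <- table$t2_ms[i]
  }
  if (is.null(t2_ms) || !is.finite(t2_ms) || t2_ms <= 0)
    stop("supply a positive 't2_ms' or a known 'oil' name", call. = FALSE)
  if (noise_sigma_rel < 0)
    stop("'noise_sigma_rel' must be nonnegative", call. = FALSE)
  times <- seq_len(meta$n_echoes) * meta$echo_time_ms
  amps <- m0 * exp(-times / t2_ms)
  if (noise_sigma_rel > 0)
    amps <- amps + .with_seed(
      seed, stats::rnorm(length(amps), 0, noise_sigma_rel * m0))
  echo_train(amps, echo_time_ms = meta$echo_time_ms, meta = meta)
}

#' Simulate a CPMG panel for every liquid oil in the reference table
#'
#' One echo train per oil, for exercising the full pipeline
#' (fit, normalize by viscosity, calibrate) without an instrument. The
#' per-oil ground-truth T2 defaults to the value implied by the table's R2
#' column (T2 = 1000/R2): the printed T2 column is rounded to 2-3
#' significant figures, while the R2 column retains the precision of the
#' original fits, and only the latter closes the round trip onto the
#' published calibration. Set \code{t2_source = "t2"} to use the printed T2
#' column instead.
#'
#' @param noise_sigma_rel per-train noise level, fraction of M0.
#' @param seed integer seed; each train gets an independent, reproducible
#'   noise stream.
#' @param t2_source \code{"r2"} (default, unrounded truth from the R2
#'   column) or \code{"t2"} (printed T2 column).
#' @param meta acquisition metadata shared by all trains.
#' @param table reference oil table.
#' @return a list of class \code{"oil_panel"}; each element has \code{record}
#'   (the table row) and \code{train} (an [echo_train()]).
#' @seealso [calibrate_panel()]
#' @export
make_oil_panel <- function(noise_sigma_rel = 0, seed = NULL,
                           t2_source = c("r2", "t2"),
                           meta = acquisition_defaults(),
                           table = oil_table("table1")) {
  t2_source <- match.arg(t2_source)
  liquid <- table[table$state == "liquid", , drop = FALSE]
  seeds <- if (is.null(seed)) vector("list", nrow(liquid))
           else as.list(seed + seq_len(nrow(liquid)))
  panel <- lapply(seq_len(nrow(liquid)), function(i) {
    t2 <- if (t2_source == "r2") 1000 / liquid$r2_per_s[i] else liquid$t2_ms[i]
    list(record = liquid[i, , drop = FALSE],
         train = make_cpmg(t2_ms = t2, noise_sigma_rel = noise_sigma_rel,
                           seed = seeds[[i]], meta = meta))
  })
  class(panel) <- "oil_panel"
  panel
}

#' Run the fit-normalize-calibrate pipeline on a simulated panel
#'
#' Fits every train mono-exponentially, normalizes each recovered R2 by the
#' oil's tabulated viscosity, and fits the chain-length calibration to the
#' result.
#'
#' @param panel an [make_oil_panel()] result.
#' @param method fit method passed to [fit_monoexponential()].
#' @return a \code{"cl_calibration"} object; the assembled records are in its
#'   \code{data} element.
#' @export
calibrate_panel <- function(panel, method = "nonlinear") {
  stopifnot(inherits(panel, "oil_panel"))
  records <- do.call(rbind, lapply(panel, function(el) {
    fit <- fit_monoexponential(el$train, method = method)
    data.frame(
      name = el$record$name,
      chain_length = el$record$chain_length,
      state = el$record$state,
      t2_ms = fit$t2_ms,
      r2_per_s = fit$r2_per_s,
      r2_over_eta = normalize_by_viscosity(fit$r2_per_s,
                                           el$record$viscosity_cp),
      viscosity_cp = el$record$viscosity_cp
    )
  }))
  fit_calibration(records)
}

#' Simulate an IR-CPMG mixture series
#'
#' Convenience front-end to [simulate_ir_cpmg()] for building T1-T2 map test
#' inputs from explicit component lists.
#'
#' @param components components as in [simulate_ir_cpmg()]; an empty list is
#'   an error.
#' @param inversion_times_ms recovery delays.
#' @param noise_sigma additive noise standard deviation (absolute units).
#' @param seed integer seed.
#' @param meta acquisition metadata.
#' @return an \code{"ir_cpmg_series"}.
#' @export
make_ir_cpmg_mixture <- function(components,
                                 inversion_times_ms = default_inversion_times(),
                                 noise_sigma = 0, seed = NULL,
                                 meta = acquisition_defaults()) {
  simulate_ir_cpmg(components, inversion_times_ms = inversion_times_ms,
                   meta = meta, noise_sigma = noise_sigma, seed = seed)
}
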