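#' Default acquisition metadata for a benchtop CPMG experiment
#'
#' The defaults mirror a typical permanent-magnet time-domain acquisition on
#' oils: 23 MHz proton frequency, 0.3 ms echo spacing, 1000 echoes, 16 scans,
#' 250 kHz sampling, 10 s recycle delay.
#'
#' @param frequency_mhz proton Larmor frequency, MHz.
#' @param echo_time_ms CPMG echo spacing TE, ms.
#' @param n_echoes number of echoes acquired.
#' @param n_scans number of accumulated scans.
#' @param sampling_khz receiver sampling rate, kHz.
#' @param tr_s recycle (repetition) delay, seconds.
#' @return a named list of acquisition settings.
#' @export
acquisition_defaults <- function(frequency_mhz = 23, echo_time_ms = 0.3,
                                 n_echoes = 1000, n_scans = 16,
                                 sampling_khz = 250, tr_s = 10) {
  list(frequency_mhz = frequency_mhz, echo_time_ms = echo_time_ms,
       n_echoes = n_echoes, n_scans = n_scans, sampling_khz = sampling_khz,
       tr_s = tr_s)
}

#' Construct a CPMG echo train
#'
#' An echo train is the ordered sequence of echo-top amplitudes from a CPMG
#' acquisition; echo k is recorded at time k*TE.
#'
#' @param amplitudes numeric vector of echo amplitudes (arbitrary units).
#' @param echo_time_ms echo spacing TE in milliseconds.
#' @param meta acquisition metadata, see [acquisition_defaults()].
#' @return an object of class \code{"echo_train"} with elements
#'   \code{amplitudes}, \code{times_ms}, \code{echo_time_ms}, \code{n_echoes},
#'   \code{meta}.
#' @export
echo_train <- function(amplitudes, echo_time_ms = 0.3,
                       meta = acquisition_defaults(echo_time_ms = echo_time_ms,
                                                   n_echoes = length(amplitudes))) {
  if (!is.numeric(amplitudes) || length(amplitudes) < 8L)
    stop("an echo train needs at least 8 numeric amplitudes", call. = FALSE)
  if (any(!is.finite(amplitudes)))
    stop("echo amplitudes must be finite", call. = FALSE)
  if (!is.numeric(echo_time_ms) || echo_time_ms <= 0)
    stop("'echo_time_ms' must be positive", call. = FALSE)
  n <- length(amplitudes)
  structure(
    list(amplitudes = as.numeric(amplitudes),
         times_ms = seq_len(n) * echo_time_ms,
         echo_time_ms = echo_time_ms,
         n_echoes = n,
         meta = meta),
    class = "echo_train"
  )
}

#' @export
print.echo_train <- function(x, ...) {
  cat(sprintf("CPMG echo train: %d echoes, TE = %g ms (%g-%g ms)\n",
              x$n_echoes, x$echo_time_ms, x$times_ms[1],
              x$times_ms[x$n_echoes]))
  cat(sprintf("  first/last amplitude: %.4g / %.4g\n",
              x$amplitudes[1], x$amplitudes[x$n_echoes]))
  invisible(x)
}

#' Read an echo train from a CSV file
#'
#' Expects a header \code{time_ms,amplitude} with one row per echo. Echo times
#' must be an arithmetic progression k*TE. A YAML sidecar with acquisition
#' metadata is read when present (same path with extension \code{.yaml}, or
#' given explicitly).
#'
#' @param path CSV file path.
#' @param meta_path optional YAML sidecar path.
#' @return an [echo_train()] object.
#' @export
read_echo_train <- function(path, meta_path = NULL) {
  d <- utils::read.csv(path)
  need <- c("time_ms", "amplitude")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("echo-train file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  te <- d$time_ms[1]
  k <- round(d$time_ms / te)
  if (any(abs(d$time_ms - k * te) > 1e-6 * te) ||
      any(diff(d$time_ms) <= 0))
    stop("echo times must be strictly increasing multiples of TE", call. = FALSE)
  meta <- acquisition_defaults(echo_time_ms = te, n_echoes = nrow(d))
  if (is.null(meta_path)) {
    cand <- sub("\\.[Cc][Ss][Vv]$", ".yaml", path)
    if (file.exists(cand) && cand != path) meta_path <- cand
  }
  if (!is.null(meta_path)) {
    side <- yaml::read_yaml(meta_path)
    meta[names(side)] <- side
  }
  echo_train(d$amplitude, echo_time_ms = te, meta = meta)
}

#' Write an echo train to CSV (plus optional YAML metadata sidecar)
#'
#' @param train an [echo_train()] object.
#' @param path output CSV path.
#' @param meta_path optional path for the YAML sidecar; \code{NULL} skips it.
#' @return \code{path}, invisibly.
#' @export
write_echo_train <- function(train, path, meta_path = NULL) {
  stopifnot(inherits(train, "echo_train"))
  utils::write.csv(
    data.frame(time_ms = train$times_ms, amplitude = train$amplitudes),
    path, row.names = FALSE)
  if (!is.null(meta_path)) yaml::write_yaml(train$meta, meta_path)
  invisible(path)
}
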