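#' Simulate an inversion-recovery-CPMG acquisition
#'
#' Forward model behind T1-T2 correlation maps. Each mixture component j with
#' longitudinal time T1_j, transverse time T2_j and weight w_j contributes
#' \deqn{A(\tau, t) = \sum_j w_j \,(1 - 2 e^{-\tau/T_{1j}})\, e^{-t/T_{2j}}}
#' at inversion delay \eqn{\tau} and CPMG echo time \eqn{t}, plus optional
#' additive Gaussian noise. Components must satisfy the dipolar constraint
#' T1 >= T2.
#'
#' @param components a data.frame (or coercible matrix/list of triples) with
#'   columns \code{t1_ms}, \code{t2_ms}, \code{weight}.
#' @param inversion_times_ms strictly increasing recovery delays, at least 8.
#' @param meta acquisition metadata; \code{echo_time_ms} and \code{n_echoes}
#'   set the CPMG dimension. See [acquisition_defaults()].
#' @param noise_sigma standard deviation of the additive Gaussian noise, in
#'   the same (arbitrary) units as the weights.
#' @param seed optional integer; fixes the noise realization.
#' @return an object of class \code{"ir_cpmg_series"}: list with
#'   \code{inversion_times_ms}, \code{times_ms}, \code{data} (matrix, one row
#'   per inversion delay), \code{meta}, \code{components}.
#' @export
simulate_ir_cpmg <- function(components,
                             inversion_times_ms = default_inversion_times(),
                             meta = acquisition_defaults(),
                             noise_sigma = 0, seed = NULL) {
  components <- .as_components(components)
  if (any(components$t1_ms < components$t2_ms - 1e-12 * components$t2_ms))
    stop("component with T1 < T2 violates the dipolar constraint T1 >= T2",
         call. = FALSE)
  if (length(inversion_times_ms) < 8L || any(diff(inversion_times_ms) <= 0))
    stop("'inversion_times_ms' must be at least 8 strictly increasing delays",
         call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be nonnegative", call. = FALSE)
  times_ms <- seq_len(meta$n_echoes) * meta$echo_time_ms
  D <- matrix(0, length(inversion_times_ms), length(times_ms))
  for (j in seq_len(nrow(components))) {
    ir <- 1 - 2 * exp(-inversion_times_ms / components$t1_ms[j])
    cp <- exp(-times_ms / components$t2_ms[j])
    D <- D + components$weight[j] * outer(ir, cp)
  }
  if (noise_sigma > 0)
    D <- D + .with_seed(seed, matrix(stats::rnorm(length(D), 0, noise_sigma),
                                     nrow(D), ncol(D)))
  structure(
    list(inversion_times_ms = inversion_times_ms, times_ms = times_ms,
         data = D, meta = meta, components = components),
    class = "ir_cpmg_series"
  )
}

.as_components <- function(components) {
  if (is.null(components) || (is.data.frame(components) && nrow(components) == 0) ||
      (is.list(components) && length(components) == 0))
    stop("'components' must contain at least one (t1_ms, t2_ms, weight) entry",
         call. = FALSE)
  if (!is.data.frame(components)) {
    if (is.list(components))
      components <- do.call(rbind, lapply(components, function(x) {
        x <- as.numeric(x)
        if (length(x) != 3) stop("each component must be (t1_ms, t2_ms, weight)",
                                 call. = FALSE)
        x
      }))
    components <- as.data.frame(components)
    names(components) <- c("t1_ms", "t2_ms", "weight")
  }
  need <- c("t1_ms", "t2_ms", "weight")
  miss <- setdiff(need, names(components))
  if (length(miss))
    stop("components lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(components$weight <= 0) || any(components$t1_ms <= 0) ||
      any(components$t2_ms <= 0))
    stop("component times and weights must be strictly positive", call. = FALSE)
  components
}

#' Default inversion-recovery delay list
#'
#' 24 log-spaced delays from 1 ms to 10 s, covering the full T1 span of the
#' bundled oils.
#'
#' @param n number of delays.
#' @param range_ms min/max delay in ms.
#' @return numeric vector of delays, ms.
#' @export
default_inversion_times <- function(n = 24, range_ms = c(1, 1e4)) {
  exp(seq(log(range_ms[1]), log(range_ms[2]), length.out = n))
}

#' @export
print.ir_cpmg_series <- function(x, ...) {
  cat(sprintf("IR-CPMG series: %d inversion delays x %d echoes (TE = %g ms)\n",
              length(x$inversion_times_ms), length(x$times_ms),
              x$meta$echo_time_ms))
  invisible(x)
}

#' Invert an IR-CPMG series to a T1-T2 correlation map
#'
#' Solves the separable two-dimensional Fredholm problem
#' \deqn{\min_{F \ge 0} \; \|K_1 F K_2^T - D\|_F^2 + \lambda \|F\|_F^2}
#' with inversion-recovery kernel \eqn{K_1[i,j] = 1 - 2 e^{-\tau_i/T_{1j}}}
#' and CPMG kernel \eqn{K_2[i,j] = e^{-t_i/T_{2j}}}. Both kernels are
#' compressed by truncated SVD (the standard trick for 2-D relaxation
#' inversion; the data are projected onto the retained singular subspaces),
#' then the nonnegative Tikhonov problem is solved by projected-gradient
#' descent with the exact Lipschitz step, which decreases the objective
#' monotonically.
#'
#' @param series an [simulate_ir_cpmg()] object (or one read from file).
#' @param t1_grid_ms,t2_grid_ms log-spaced relaxation-time grids; defaults
#'   span 0.1-10000 ms with \code{n_grid} points, covering every oil in the
#'   bundled table. At least 32 points per axis.
#' @param lambda_reg Tikhonov weight, relative to the squared product of the
#'   largest kernel singular values; must be > 0. The default 1e-4 is a
#'   smoothing floor appropriate for the high signal-to-noise of oil signals.
#' @param n_grid grid size used when the grids are not supplied.
#' @param svd_tol singular values below \code{svd_tol} times the largest are
#'   truncated.
#' @param max_iter iteration cap for the projected-gradient solve.
#' @param tol convergence tolerance on the relative objective decrease.
#' @param peak_threshold local maxima below this fraction of the global
#'   maximum are not reported as peaks.
#' @param enforce_t1_ge_t2 when \code{TRUE}, constrain the solution to the
#'   physical half-plane T1 >= T2 (dipolar relaxation forbids T1 < T2). The
#'   constraint eliminates smear onto the unphysical side but pulls
#'   components lying within a grid cell or two of the diagonal onto it, so
#'   it is off by default; peak maxima respect T1 >= T2 either way.
#' @return an object of class \code{"t1t2_map"}: list with
#'   \code{t1_grid_ms}, \code{t2_grid_ms}, \code{amplitude} (n_t1 x n_t2,
#'   nonnegative), \code{lambda_reg}, \code{peaks} (data.frame
#'   \code{t1_ms, t2_ms, mass}, sorted by descending mass), \code{objective}
#'   (per-iteration trace), \code{residual}, \code{converged}, \code{n_iter}.
#' @export
invert_t1t2 <- function(series, t1_grid_ms = NULL, t2_grid_ms = NULL,
                        lambda_reg = 1e-4, n_grid = 64, svd_tol = 1e-8,
                        max_iter = 5000, tol = 1e-10,
                        peak_threshold = 0.05, enforce_t1_ge_t2 = FALSE) {
  stopifnot(inherits(series, "ir_cpmg_series"))
  if (!is.numeric(lambda_reg) || lambda_reg <= 0)
    stop("'lambda_reg' must be strictly positive", call. = FALSE)
  if (is.null(t1_grid_ms))
    t1_grid_ms <- exp(seq(log(0.1), log(1e4), length.out = n_grid))
  if (is.null(t2_grid_ms))
    t2_grid_ms <- exp(seq(log(0.1), log(1e4), length.out = n_grid))
  if (length(t1_grid_ms) < 32L || length(t2_grid_ms) < 32L)
    stop("T1 and T2 grids need at least 32 points per axis", call. = FALSE)

  K1 <- 1 - 2 * exp(-outer(series$inversion_times_ms, t1_grid_ms, "/"))
  K2 <- exp(-outer(series$times_ms, t2_grid_ms, "/"))
  D <- series$data

  # SVD compression of both kernels; project the data accordingly
  s1 <- svd(K1); s2 <- svd(K2)
  k1 <- max(1L, sum(s1$d > svd_tol * s1$d[1]))
  k2 <- max(1L, sum(s2$d > svd_tol * s2$d[1]))
  K1c <- s1$d[1:k1] * t(s1$v[, 1:k1, drop = FALSE])   # k1 x nT1
  K2c <- s2$d[1:k2] * t(s2$v[, 1:k2, drop = FALSE])   # k2 x nT2
  Dc <- t(s1$u[, 1:k1, drop = FALSE]) %*% D %*% s2$u[, 1:k2, drop = FALSE]

  lam <- lambda_reg * (s1$d[1] * s2$d[1])^2
  L <- (s1$d[1] * s2$d[1])^2 + lam   # Lipschitz constant of the gradient

  nT1 <- length(t1_grid_ms); nT2 <- length(t2_grid_ms)
  F <- matrix(0, nT1, nT2)
  # feasible-set projection: nonnegativity, optionally zero on the
  # unphysical T1 < T2 half-plane
  unphysical <- if (enforce_t1_ge_t2) outer(t1_grid_ms, t2_grid_ms, "<")
                else matrix(FALSE, nT1, nT2)
  project <- function(F) { F <- pmax(F, 0); F[unphysical] <- 0; F }
  obj <- function(F, R) sum(R^2) + lam * sum(F^2)
  R <- K1c %*% F %*% t(K2c) - Dc
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj(F, R)
  converged <- FALSE
  it <- 0L
  # accelerated projected gradient (FISTA) with adaptive restart: whenever a
  # momentum step would increase the objective it is rejected and the
  # momentum reset, so the recorded objective decreases monotonically
  F_prev <- F
  tk <- 1
  while (it < max_iter) {
    it <- it + 1L
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- F + ((tk - 1) / tk1) * (F - F_prev)
    Ry <- K1c %*% Y %*% t(K2c) - Dc
    G <- crossprod(K1c, Ry) %*% K2c + lam * Y
    F_new <- project(Y - G / L)
    R_new <- K1c %*% F_new %*% t(K2c) - Dc
    o_new <- obj(F_new, R_new)
    if (o_new > trace[it]) {          # restart: plain gradient step from F
      tk1 <- 1
      G <- crossprod(K1c, R) %*% K2c + lam * F
      F_new <- project(F - G / L)
      R_new <- K1c %*% F_new %*% t(K2c) - Dc
      o_new <- obj(F_new, R_new)
    }
    F_prev <- F; F <- F_new; R <- R_new; tk <- tk1
    trace[it + 1L] <- o_new
    if (trace[it] - trace[it + 1L] <= tol * max(trace[1L], .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  trace <- trace[1:(it + 1L)]
  residual <- sqrt(sum(R^2))
  if (!converged)
    stop(sprintf(paste0("T1-T2 inversion did not converge within %d iterations ",
                        "(residual %.4g); raise 'max_iter' or 'lambda_reg'"),
                 max_iter, residual), call. = FALSE)

  peaks <- .find_peaks(F, t1_grid_ms, t2_grid_ms, peak_threshold)
  structure(
    list(t1_grid_ms = t1_grid_ms, t2_grid_ms = t2_grid_ms, amplitude = F,
         lambda_reg = lambda_reg, peaks = peaks, objective = trace,
         residual = residual, converged = converged, n_iter = it),
    class = "t1t2_map"
  )
}

# local maxima over the 8-neighborhood, above a relative threshold; mass is
# accumulated by assigning every nonzero cell to its nearest peak in
# (log T1, log T2) space
.find_peaks <- function(F, t1, t2, rel_threshold) {
  n1 <- nrow(F); n2 <- ncol(F)
  mx <- max(F)
  empty <- data.frame(t1_ms = numeric(0), t2_ms = numeric(0),
                      mass = numeric(0))
  if (mx <= 0) return(empty)
  is_peak <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    v <- F[i, j]
    if (v < rel_threshold * mx) next
    nb <- F[max(1, i - 1):min(n1, i + 1), max(1, j - 1):min(n2, j + 1)]
    if (v >= max(nb)) is_peak[i, j] <- TRUE
  }
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  # merge plateau-adjacent duplicates: keep one representative per cluster of
  # touching peak cells
  keep <- rep(TRUE, nrow(idx))
  if (nrow(idx) > 1L) {
    for (a in 2:nrow(idx)) for (b in 1:(a - 1)) {
      if (keep[b] && abs(idx[a, 1] - idx[b, 1]) <= 1 &&
          abs(idx[a, 2] - idx[b, 2]) <= 1) { keep[a] <- FALSE; break }
    }
  }
  idx <- idx[keep, , drop = FALSE]
  lp1 <- log(t1[idx[, 1]]); lp2 <- log(t2[idx[, 2]])
  cells <- which(F > 0, arr.ind = TRUE)
  lc1 <- log(t1[cells[, 1]]); lc2 <- log(t2[cells[, 2]])
  mass <- numeric(nrow(idx))
  for (c in seq_len(nrow(cells))) {
    d2 <- (lc1[c] - lp1)^2 + (lc2[c] - lp2)^2
    w <- which.min(d2)
    mass[w] <- mass[w] + F[cells[c, 1], cells[c, 2]]
  }
  out <- data.frame(t1_ms = t1[idx[, 1]], t2_ms = t2[idx[, 2]], mass = mass)
  out[order(-out$mass), , drop = FALSE]
}

#' @export
print.t1t2_map <- function(x, ...) {
  cat(sprintf("T1-T2 correlation map: %d x %d grid, lambda = %g, %d iterations\n",
              length(x$t1_grid_ms), length(x$t2_grid_ms), x$lambda_reg,
              x$n_iter))
  if (nrow(x$peaks)) {
    cat(sprintf("  %d peak(s):\n", nrow(x$peaks)))
    for (i in seq_len(nrow(x$peaks)))
      cat(sprintf("    T1 = %.4g ms, T2 = %.4g ms, mass = %.4g (T1/T2 = %.3g)\n",
                  x$peaks$t1_ms[i], x$peaks$t2_ms[i], x$peaks$mass[i],
                  x$peaks$t1_ms[i] / x$peaks$t2_ms[i]))
  } else cat("  no peaks\n")
  invisible(x)
}

#' Plot a T1-T2 correlation map
#'
#' Filled image of the amplitude distribution on log axes, with the T1 = T2
#' diagonal drawn as a reference: free fluids sit on it, slowed rotation
#' (aggregates) sits above it.
#'
#' @param x a \code{"t1t2_map"} object.
#' @param ... passed to [graphics::image()].
#' @return \code{x}, invisibly.
#' @export
plot.t1t2_map <- function(x, ...) {
  graphics::image(log10(x$t2_grid_ms), log10(x$t1_grid_ms), t(x$amplitude),
                  xlab = "log10 T2 (ms)", ylab = "log10 T1 (ms)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::abline(0, 1, col = "darkgreen", lwd = 2)
  if (nrow(x$peaks))
    graphics::points(log10(x$peaks$t2_ms), log10(x$peaks$t1_ms), pch = 3)
  invisible(x)
}

#' Classify the components of a T1-T2 map
#'
#' Applies the qualitative reading of oil T1-T2 maps: a component with T2
#' under \code{t2_threshold_ms} is a high-viscosity/saturated species (e.g.
#' glycerin); a component lying well above the T1 = T2 line (ratio above
#' \code{ratio_cutoff}) rotates anomalously slowly, indicating aggregates or
#' resin-like association; anything else is a free fluid.
#'
#' @param map a \code{"t1t2_map"} object with at least one peak.
#' @param t2_threshold_ms T2 below which a peak is called viscous/saturated
#'   (default 10 ms).
#' @param ratio_cutoff T1/T2 above which a peak is called an aggregate
#'   (default 2).
#' @return a list with \code{peaks} (the peak table plus a \code{labels}
#'   list-column) and \code{labels}, the union of all per-peak labels.
#' @export
classify_map <- function(map, t2_threshold_ms = 10, ratio_cutoff = 2) {
  stopifnot(inherits(map, "t1t2_map"))
  if (nrow(map$peaks) == 0L)
    stop("cannot classify an empty map (no peaks)", call. = FALSE)
  labs <- lapply(seq_len(nrow(map$peaks)), function(i) {
    t1 <- map$peaks$t1_ms[i]; t2 <- map$peaks$t2_ms[i]
    l <- character(0)
    if (t2 < t2_threshold_ms) l <- c(l, "high-viscosity/saturated")
    if (t1 / t2 > ratio_cutoff) l <- c(l, "aggregate/slow-rotation")
    if (length(l) == 0L) l <- "free-fluid"
    l
  })
  peaks <- map$peaks
  peaks$labels <- labs
  list(peaks = peaks, labels = unique(unlist(labs)))
}

#' Gel / rigid-network formation diagnostic
#'
#' Compares the dominant peak of two maps of the same sample (e.g. before and
#' after cooling). Formation of a rigid gel network immobilizes only a small
#' mass fraction: the bulk oil keeps rotating, so T2 stays put while T1 grows.
#' The diagnostic flags \code{rigid-network formation} when the dominant
#' peak's T2 changes by less than \code{t2_tol} (relative) while its T1 grows
#' by more than \code{t1_growth} (relative).
#'
#' @param map_before,map_after \code{"t1t2_map"} objects, each with at least
#'   one peak.
#' @param t2_tol relative T2 change below which T2 counts as unchanged
#'   (default 0.10).
#' @param t1_growth relative T1 growth above which T1 counts as increased
#'   (default 0.50).
#' @return a list with the dominant-peak coordinates before/after, the
#'   relative changes \code{delta_t1_rel} and \code{delta_t2_rel}, and
#'   \code{flagged} (logical).
#' @export
gel_shift_diagnostic <- function(map_before, map_after,
                                 t2_tol = 0.10, t1_growth = 0.50) {
  stopifnot(inherits(map_before, "t1t2_map"), inherits(map_after, "t1t2_map"))
  if (nrow(map_before$peaks) == 0L || nrow(map_after$peaks) == 0L)
    stop("both maps need a dominant peak for the gel diagnostic", call. = FALSE)
  b <- map_before$peaks[1, ]; a <- map_after$peaks[1, ]
  d1 <- (a$t1_ms - b$t1_ms) / b$t1_ms
  d2 <- (a$t2_ms - b$t2_ms) / b$t2_ms
  list(
    before = c(t1_ms = b$t1_ms, t2_ms = b$t2_ms),
    after = c(t1_ms = a$t1_ms, t2_ms = a$t2_ms),
    delta_t1_rel = d1,
    delta_t2_rel = d2,
    flagged = abs(d2) < t2_tol && d1 > t1_growth
  )
}

#' Read / write an IR-CPMG series as CSV
#'
#' Long format with columns \code{inversion_time_ms,time_ms,amplitude}.
#'
#' @param path CSV path.
#' @param meta acquisition metadata for the reconstructed series.
#' @return [read_ir_cpmg()] returns an \code{"ir_cpmg_series"};
#'   [write_ir_cpmg()] returns \code{path} invisibly.
#' @export
read_ir_cpmg <- function(path, meta = NULL) {
  d <- utils::read.csv(path)
  need <- c("inversion_time_ms", "time_ms", "amplitude")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("series file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  taus <- sort(unique(d$inversion_time_ms))
  times <- sort(unique(d$time_ms))
  D <- matrix(NA_real_, length(taus), length(times))
  D[cbind(match(d$inversion_time_ms, taus), match(d$time_ms, times))] <-
    d$amplitude
  if (anyNA(D))
    stop("series file is not a complete inversion-delay x echo grid",
         call. = FALSE)
  te <- times[1]
  if (is.null(meta))
    meta <- acquisition_defaults(echo_time_ms = te, n_echoes = length(times))
  structure(
    list(inversion_times_ms = taus, times_ms = times, data = D, meta = meta,
         components = NULL),
    class = "ir_cpmg_series"
  )
}

#' @rdname read_ir_cpmg
#' @param series an \code{"ir_cpmg_series"} object.
#' @export
write_ir_cpmg <- function(series, path) {
  stopifnot(inherits(series, "ir_cpmg_series"))
  grid <- expand.grid(time_ms = series$times_ms,
                      inversion_time_ms = series$inversion_times_ms)
  utils::write.csv(
    data.frame(inversion_time_ms = grid$inversion_time_ms,
               time_ms = grid$time_ms,
               amplitude = as.vector(t(series$data))),
    path, row.names = FALSE)
  invisible(path)
}
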