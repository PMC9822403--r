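#' Bundled reference oil tables
#'
#' Two plain-text tables ship with the package: \code{"table1"}, 17 liquid
#' oils with measured T2, R2, R2/eta and viscosity at 20 C, used to establish
#' the chain-length calibration; and \code{"table2"}, the full 29-sample
#' preparation list (molecular weight, state, purity; solids have no
#' viscosity).
#'
#' @param which \code{"table1"} or \code{"table2"}.
#' @return a data.frame of oil records, see [read_oil_table()].
#' @examples
#' nrow(oil_table("table1"))   # 17
#' @export
oil_table <- function(which = c("table1", "table2")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0(ifelse(which == "table1", "table1_oils",
                                 "table2_samples"), ".tsv"),
                   package = "relaxochain", mustWork = TRUE)
  read_oil_table(f)
}

#' Read an oil-record table
#'
#' Accepts TSV or CSV with at least the columns \code{formula}, \code{name},
#' \code{chain_length}, \code{state}. Optional numeric columns
#' (\code{t2_ms}, \code{r2_per_s}, \code{r2_over_eta}, \code{viscosity_cp},
#' \code{mw_gmol}) are parsed with \code{"N/A"} treated as missing; a
#' malformed numeric cell is reported with its line number. States are
#' normalized to \code{liquid}/\code{solid}.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (\code{.tsv} = tab, otherwise comma).
#' @return a data.frame, one row per oil.
#' @export
read_oil_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("N/A", "NA"),
                         colClasses = "character", quote = "\"",
                         check.names = TRUE)
  mandatory <- c("formula", "name", "chain_length", "state")
  miss <- setdiff(mandatory, names(d))
  if (length(miss))
    stop("oil table lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(d) == 0L)
    stop("oil table '", path, "' has no records", call. = FALSE)
  numeric_cols <- intersect(
    c("chain_length", "t2_ms", "r2_per_s", "r2_over_eta", "viscosity_cp",
      "mw_gmol"), names(d))
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.na(d[[col]]) & is.na(parsed))
    if (length(bad))
      stop(sprintf("column '%s': malformed numeric value '%s' on line %d",
                   col, d[[col]][bad[1]], bad[1] + 1L), call. = FALSE)
    d[[col]] <- parsed
  }
  d$state <- ifelse(grepl("^\\s*liquid", d$state, ignore.case = TRUE),
                    "liquid",
                    ifelse(grepl("^\\s*solid", d$state, ignore.case = TRUE),
                           "solid", d$state))
  d
}

#' Run configuration
#'
#' A small configuration object gathering the tunables of a full pipeline
#' run. Serializes losslessly to YAML; unknown keys in a config file are
#' rejected rather than silently ignored.
#'
#' @param acquisition acquisition metadata, see [acquisition_defaults()].
#' @param fit_method mono-exponential fit method.
#' @param n_grid T1-T2 inversion grid size per axis.
#' @param lambda_reg inversion regularization weight.
#' @param output_dir where CLI commands write their outputs.
#' @param verbosity 0 = quiet, 1 = normal.
#' @param seed integer RNG seed for synthetic generation.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(acquisition = acquisition_defaults(),
                       fit_method = "nonlinear", n_grid = 64,
                       lambda_reg = 1e-4, output_dir = ".",
                       verbosity = 1, seed = 1) {
  structure(
    list(acquisition = acquisition, fit_method = fit_method, n_grid = n_grid,
         lambda_reg = lambda_reg, output_dir = output_dir,
         verbosity = verbosity, seed = seed),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- run_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(names(base), collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$acquisition)) {
    bad <- setdiff(names(raw$acquisition), names(base$acquisition))
    if (length(bad))
      stop("unknown acquisition key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    base$acquisition[names(raw$acquisition)] <- raw$acquisition
    raw$acquisition <- NULL
  }
  base[names(raw)] <- raw
  base
}

#' @rdname run_config
#' @param config a \code{"run_config"} object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Export a T1-T2 map as a CSV grid plus a JSON peak list
#'
#' @param map a \code{"t1t2_map"} object.
#' @param grid_path CSV destination for the amplitude grid (long format:
#'   \code{t1_ms,t2_ms,amplitude}).
#' @param peaks_path optional JSON destination for the peak table.
#' @return \code{grid_path}, invisibly.
#' @export
write_t1t2_map <- function(map, grid_path, peaks_path = NULL) {
  stopifnot(inherits(map, "t1t2_map"))
  grid <- expand.grid(t2_ms = map$t2_grid_ms, t1_ms = map$t1_grid_ms)
  utils::write.csv(
    data.frame(t1_ms = grid$t1_ms, t2_ms = grid$t2_ms,
               amplitude = as.vector(t(map$amplitude))),
    grid_path, row.names = FALSE)
  if (!is.null(peaks_path))
    jsonlite::write_json(map$peaks, peaks_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(grid_path)
}
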