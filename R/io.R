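#' Read an exchange-curve CSV file
#'
#' Parses delimited text with header columns \code{time_s}, \code{y34},
#' \code{y36} and optional \code{sigma34}, \code{sigma36}. Lines starting
#' with \code{#} are comments; the decimal separator is \code{.}. Times
#' must be strictly increasing — the parser reports the offending line
#' number otherwise, as it does for missing columns and non-numeric cells.
#'
#' @param path Path to the file.
#' @return A data frame of class \code{"exchange_data"}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_exchange_csv(wex_synth(wex_preset("sr_pH6.0_tw"), n_points = 6), f)
#' read_exchange_csv(f)
#' @export
read_exchange_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  if (!any(keep)) stop("no data lines in ", path, call. = FALSE)
  lineno <- which(keep)          # original line numbers of retained lines
  txt <- raw[keep]
  d <- tryCatch(
    utils::read.csv(text = txt, header = TRUE, colClasses = "character",
                    strip.white = TRUE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("time_s", "y34", "y36")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- intersect(c(need, "sigma34", "sigma36"), names(d))
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !(trimws(d[[cn]]) %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric value '", d[[cn]][bad[1L]], "' in column ", cn,
           " at line ", lineno[bad[1L] + 1L], " of ", path, call. = FALSE)
    d[[cn]] <- v
  }
  d <- d[cols]
  nonmono <- which(diff(d$time_s) <= 0)
  if (length(nonmono))
    stop("times not strictly increasing at line ",
         lineno[nonmono[1L] + 2L], " of ", path, call. = FALSE)
  structure(d, class = c("exchange_data", "data.frame"))
}

#' Write an exchange-curve CSV file
#'
#' Inverse of \code{\link{read_exchange_csv}}; values are written at full
#' double precision so a read/write round trip is lossless. A comment
#' header records the package version and any comment lines supplied.
#'
#' @param data A data frame with \code{time_s}, \code{y34}, \code{y36} and
#'   optional sigma columns.
#' @param path Output path.
#' @param comments Optional character vector written as \code{#} header
#'   lines.
#' @return Invisibly, \code{path}.
#' @export
write_exchange_csv <- function(data, path, comments = character()) {
  data <- as.data.frame(data)
  need <- c("time_s", "y34", "y36")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cols <- intersect(c(need, "sigma34", "sigma36"), names(data))
  hdr <- c(sprintf("# written by wexchange %s",
                   as.character(utils::packageVersion("wexchange"))),
           if (length(comments)) paste("#", comments))
  body <- vapply(seq_len(nrow(data)), function(i)
    paste(vapply(cols, function(cn)
      format(data[[cn]][i], digits = 17, scientific = FALSE, trim = TRUE),
      character(1)), collapse = ","), character(1))
  writeLines(c(hdr, paste(cols, collapse = ","), body), path)
  invisible(path)
}

# ---- declarative run configuration ----------------------------------------

run_config_keys <- function() {
  list(
    top = c("model", "rates", "fixed", "enrichment", "mixing", "s3", "fit",
            "synth", "io"),
    rates = c("k_f1", "k_f2", "k_s1", "k_s2", "k_c1", "k_c2", "preset"),
    enrichment = c("alpha_in", "alpha_f"),
    mixing = c("t_m", "mode", "t_k"),
    s3 = c("enabled", "duration", "k_f", "k_s"),
    fit = c("n_boot", "seed", "n_starts", "a_free"),
    synth = c("n_points", "t_min", "t_max", "noise_sd", "seed"),
    io = c("input", "output"))
}

#' Read a declarative run configuration
#'
#' A YAML document mirroring the command-line inputs: model selection,
#' rate constants (numeric values, or the name of a published preset),
#' the parameters to hold fixed, enrichment/mixing/S3 correction settings,
#' fit options and IO paths. Unknown keys are rejected by name, so typos
#' cannot silently change a run. \code{\link{write_run_config}} is its
#' lossless inverse.
#'
#' @param path Path to a YAML file.
#' @return A named list of class \code{"wex_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  keys <- run_config_keys()
  unknown <- setdiff(names(cfg), keys$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (section in intersect(names(cfg), names(keys)[-1])) {
    bad <- setdiff(names(cfg[[section]]), keys[[section]])
    if (length(bad))
      stop("unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "wex_config")
}

#' Write a run configuration
#'
#' @param config A list (or \code{"wex_config"}) of run settings.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
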