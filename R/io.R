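#' Parse a run configuration (YAML or JSON)
#'
#' Reads a configuration file describing a protocol, tissue, model and solver
#' settings, validates it strictly (unknown keys are rejected, units are fixed
#' by the key names) and returns a normalized `run_config` with constructed
#' [ssfp_protocol()] and [tissue()] objects.
#'
#' Recognized keys: `protocol: {flip_deg, tr_ms, tau_ms, q_per_cm |
#' grad_mT_per_m}`, `tissue: {t1_ms, t2_ms, d, s0}`, `model`, `seed`,
#' `solver: {rel_tol, b_max, d_max}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    stop_dwssfp(sprintf("config file not found: %s", path),
                class = "dwssfp_error_data")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known_top <- c("protocol", "tissue", "model", "seed", "solver")
  check_keys <- function(x, known, where) {
    bad <- setdiff(names(x), known)
    if (length(bad)) {
      stop_dwssfp(sprintf("unknown %s key(s): %s (allowed: %s)", where,
                          paste(bad, collapse = ", "),
                          paste(known, collapse = ", ")),
                  class = "dwssfp_error_schema")
    }
  }
  check_keys(cfg, known_top, "top-level")
  for (req in c("protocol", "tissue")) {
    if (is.null(cfg[[req]])) {
      stop_dwssfp(sprintf("config must contain a '%s' block", req),
                  class = "dwssfp_error_schema")
    }
  }
  check_keys(cfg$protocol,
             c("flip_deg", "tr_ms", "tau_ms", "q_per_cm", "grad_mT_per_m"),
             "protocol")
  check_keys(cfg$tissue, c("t1_ms", "t2_ms", "d", "s0"), "tissue")
  if (!is.null(cfg$solver)) {
    check_keys(cfg$solver, c("rel_tol", "b_max", "d_max"), "solver")
  }
  for (req in c("flip_deg", "tr_ms", "tau_ms")) {
    if (is.null(cfg$protocol[[req]])) {
      stop_dwssfp(sprintf("protocol lacks '%s' (unit: %s)", req,
                          if (req == "flip_deg") "degrees" else "ms"),
                  class = "dwssfp_error_schema")
    }
  }
  for (req in c("t1_ms", "t2_ms")) {
    if (is.null(cfg$tissue[[req]])) {
      stop_dwssfp(sprintf("tissue lacks '%s' (unit: ms)", req),
                  class = "dwssfp_error_schema")
    }
  }
  p <- ssfp_protocol(flip_deg = cfg$protocol$flip_deg,
                     tr_ms = cfg$protocol$tr_ms,
                     tau_ms = cfg$protocol$tau_ms,
                     q_per_cm = cfg$protocol$q_per_cm,
                     grad_mT_per_m = cfg$protocol$grad_mT_per_m)
  tis <- tissue(t1_ms = cfg$tissue$t1_ms, t2_ms = cfg$tissue$t2_ms,
                d = cfg$tissue$d %||% 0, s0 = cfg$tissue$s0 %||% 1)
  model <- cfg$model %||% "buxton"
  if (!model %in% .ssfp_models) {
    stop_dwssfp(sprintf("model must be one of %s",
                        paste(.ssfp_models, collapse = ", ")),
                class = "dwssfp_error_schema")
  }
  structure(
    list(protocol = p, tissue = tis, model = model,
         seed = as.integer(cfg$seed %||% 1L),
         solver = list(rel_tol = cfg$solver$rel_tol %||% 1e-10,
                       b_max = cfg$solver$b_max %||% 20000,
                       d_max = cfg$solver$d_max %||% 0.01),
         source = normalizePath(path)),
    class = "run_config")
}

#' Read a signal table from CSV
#'
#' Expects a header with columns `flip_deg`, `s_dw`, `s_ref` and optionally
#' `stderr` ('.' decimal separator, UTF-8). Malformed or invalid rows are
#' reported with their line numbers; angle columns in radians (e.g.
#' `flip_rad`) are rejected.
#'
#' @param path CSV path.
#' @return A validated tibble (`flip_deg`, `s_dw`, `s_ref`[, `stderr`]).
#' @export
read_signal_table <- function(path) {
  if (!file.exists(path)) {
    stop_dwssfp(sprintf("file not found: %s", path),
                class = "dwssfp_error_data")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if ("flip_rad" %in% names(raw)) {
    stop_dwssfp("column 'flip_rad' rejected: flip angles must be in degrees",
                class = "dwssfp_error_schema")
  }
  need <- c("flip_deg", "s_dw", "s_ref")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop_dwssfp(sprintf("missing column(s): %s",
                        paste(missing, collapse = ", ")),
                class = "dwssfp_error_schema")
  }
  for (col in intersect(c(need, "stderr"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_dwssfp(sprintf("non-numeric %s at data line(s): %s", col,
                          paste(bad, collapse = ", ")),
                  class = "dwssfp_error_data")
    }
    raw[[col]] <- v
  }
  neg <- which(raw$s_dw <= 0 | raw$s_ref <= 0)
  if (length(neg)) {
    stop_dwssfp(sprintf("non-positive signal at data line(s): %s",
                        paste(neg, collapse = ", ")),
                class = "dwssfp_error_data")
  }
  validate_signal_table(raw[intersect(c(need, "stderr"), names(raw))])
}

#' Write a pipeline result to JSON
#'
#' Serializes a [run_translation_pipeline()] result losslessly, embedding a
#' provenance block (package version, model, tolerances, seeds and a hash of
#' the configuration used) so every artifact states how it was produced.
#'
#' @param path Output path (`.json`).
#' @param result A `dwssfp_beff` object.
#' @param config Optional `run_config` whose hash is embedded.
#' @return Invisibly, the path.
#' @export
write_results <- function(path, result, config = NULL) {
  stopifnot(inherits(result, "dwssfp_beff"))
  out <- list(
    dm = result$fit$dm,
    ds = result$fit$ds,
    cov = result$fit$cov,
    degenerate = result$fit$degenerate,
    per_flip = result$per_flip,
    provenance = c(result$provenance,
                   list(config_hash = if (is.null(config)) NULL else
                          rlang::hash(config),
                        written = format(Sys.time(), tz = "UTC"))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a results JSON
#'
#' @param path Path written by [write_results()].
#' @return A list mirroring the serialized structure, with `per_flip` as a
#'   tibble.
#' @export
read_results <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$per_flip <- tibble::as_tibble(out$per_flip)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
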