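#' @importFrom jsonlite toJSON fromJSON write_json read_json
NULL

# Canonical column order of the trajectory table.
.canonical_columns <- function(nms) {
  ord <- c("time_h", "r_ug_ml",
           sort(grep("^B[0-9]+$", nms, value = TRUE)),
           sort(grep("^P[0-9]+$", nms, value = TRUE)),
           sort(grep("^M_[0-9]+_[0-9]+$", nms, value = TRUE)),
           intersect("LY", nms),
           sort(grep("^BP[0-9]+$", nms, value = TRUE)))
  extra <- setdiff(nms, ord)
  if (length(extra))
    stop("unexpected time-series columns: ", paste(extra, collapse = ", "))
  ord
}

#' Write a simulated trajectory to a delimited table
#'
#' Writes the trajectory with the fixed column contract (`time_h, r_ug_ml,
#' B0.., P0.., M_i_j.., LY, BP0, BP1`) regardless of the column order of the
#' input, floating point with 10 significant digits.  The event log goes to
#' a sibling file `<stem>.events.<ext>`.
#'
#' @param ts A `phage_ts` (or any data.frame with contract columns).
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(ts, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- as.data.frame(ts)[, .canonical_columns(names(ts)), drop = FALSE]
  chr <- vapply(df, function(x) sprintf("%.10g", x), character(nrow(df)))
  if (nrow(df) == 1L) chr <- matrix(chr, 1L, dimnames = list(NULL, names(df)))
  if (nrow(df) == 0L)
    chr <- matrix(character(0), 0L, ncol(df), dimnames = list(NULL, names(df)))
  utils::write.table(chr, path, sep = sep, quote = FALSE, row.names = FALSE)
  ev <- attr(ts, "events")
  if (!is.null(ev)) {
    evp <- sub("(\\.[^.]*)?$", paste0(".events.", format),
               path, perl = TRUE)
    utils::write.table(ev, evp, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a trajectory table written by [write_timeseries()]
#'
#' @param path File path (.tsv or .csv).
#' @return A data.frame; if the sibling events file exists it is attached as
#'   the `events` attribute.
#' @export
read_timeseries <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  evp <- sub("(\\.[^.]*)?$", paste0(".events", regmatches(
    path, regexpr("\\.[^.]*$", path))), path, perl = TRUE)
  if (file.exists(evp))
    attr(df, "events") <- utils::read.table(evp, header = TRUE, sep = sep,
                                            stringsAsFactors = FALSE)
  df
}

# ---- scenario <-> config document ------------------------------------------

.cfg_keys <- list(
  top = c("name", "note", "params", "ext", "init", "control", "transfers"),
  params = c("v", "k", "e", "delta", "beta", "lam", "m", "mu",
             "n_orders", "n_phage"),
  ext = c("v_L", "K_L", "eta", "g", "h"),
  init = c("t", "r", "B", "P", "M", "LY", "BP", "extended"),
  control = c("dt", "duration", "seed", "volume", "event_mode",
              "output_every"),
  transfers = c("period", "dilution", "R", "n_transfers",
                "stochastic_rounding"))

.check_keys <- function(lst, where) {
  bad <- setdiff(names(lst), .cfg_keys[[where]])
  if (length(bad))
    stop(sprintf("unknown key%s in '%s': %s (valid: %s)",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", "),
                 paste(.cfg_keys[[where]], collapse = ", ")),
         call. = FALSE)
  invisible(lst)
}

#' Serialize a scenario to a configuration document
#'
#' @param sc A [scenario()].
#' @return A plain nested list mirroring the scenario, suitable for JSON or
#'   YAML serialization; parse -> serialize -> parse is the identity.
#' @export
scenario_to_config <- function(sc) {
  stopifnot(inherits(sc, "phage_scenario"))
  init <- sc$init
  cfg <- list(
    name = sc$name, note = sc$note,
    params = unclass(sc$params),
    ext = if (!is.null(sc$ext)) unclass(sc$ext),
    init = c(list(t = init$t, r = init$r, B = init$B, P = init$P),
             if (any(init$M != 0)) list(M = unclass(init$M)),
             if (isTRUE(init$extended))
               list(LY = init$LY, BP = init$BP, extended = TRUE)),
    control = Filter(Negate(is.null), unclass(sc$control)),
    transfers = if (!is.null(sc$transfers)) unclass(sc$transfers))
  cfg[!vapply(cfg, is.null, logical(1))]
}

#' Build a validated scenario from a configuration document
#'
#' @param cfg A nested list (parsed JSON/YAML).  Unknown keys are rejected
#'   with a message naming the offending field; missing control settings are
#'   filled with the package defaults (and reported via `message()`).
#' @return A [scenario()].
#' @export
config_to_scenario <- function(cfg) {
  .check_keys(cfg, "top")
  if (is.null(cfg$params)) stop("config is missing 'params'", call. = FALSE)
  if (is.null(cfg$init)) stop("config is missing 'init'", call. = FALSE)
  .check_keys(cfg$params, "params")
  .check_keys(cfg$init, "init")
  params <- do.call(model_params, cfg$params)
  ext <- if (!is.null(cfg$ext)) {
    .check_keys(cfg$ext, "ext")
    do.call(extended_params, cfg$ext)
  }
  ctl <- if (is.null(cfg$control)) list() else .check_keys(cfg$control, "control")
  defaults <- setdiff(c("dt", "output_every"), names(ctl))
  control <- do.call(sim_control, ctl)
  if (length(defaults))
    message("config defaults applied: ",
            paste(sprintf("%s = %g", defaults,
                          unlist(control[defaults])), collapse = ", "))
  init_args <- cfg$init
  if (!is.null(init_args$M)) init_args$M <- as.matrix(init_args$M)
  if (!is.null(ext)) init_args$extended <- TRUE
  init <- do.call(community_state, init_args)
  transfers <- if (!is.null(cfg$transfers)) {
    .check_keys(cfg$transfers, "transfers")
    do.call(transfer_schedule, cfg$transfers)
  }
  scenario(params = params, init = init, control = control, ext = ext,
           transfers = transfers,
           name = if (is.null(cfg$name)) "config" else cfg$name,
           note = if (is.null(cfg$note)) "" else cfg$note)
}

#' Save a scenario as a JSON (or YAML) config file
#'
#' @param sc A [scenario()].
#' @param path Destination; `.yaml`/`.yml` selects YAML (requires the
#'   optional yaml package), anything else JSON.
#' @return The path, invisibly.
#' @export
save_config <- function(sc, path) {
  cfg <- scenario_to_config(sc)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML output requires the 'yaml' package; use a .json path")
    writeLines(yaml::as.yaml(cfg), path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Load and validate a scenario config file (JSON or YAML, auto-detected)
#'
#' @param path Config file path.
#' @return A validated [scenario()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON")
    yaml::yaml.load(txt)
  }
  config_to_scenario(cfg)
}
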