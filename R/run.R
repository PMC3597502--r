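#' Run a scenario end-to-end
#'
#' Integrates the (basic or extended) model with the hybrid
#' Euler/Monte-Carlo engine, applying the serial-transfer schedule at each
#' period boundary when one is present.  The RNG is seeded from
#' `scenario$control$seed` at the start of the run, so identical
#' (scenario, seed) pairs give identical trajectories and event logs.
#'
#' @param scenario A [scenario()] (e.g. from [preset_scenario()]).
#' @return A `phage_ts` object: a data.frame of sampled states with the
#'   fixed column contract `time_h, r_ug_ml, B0.., P0.., M_i_j.., LY, BP0,
#'   BP1` (extension columns only for extended scenarios), with attributes
#'   `events` (data.frame `time_h, kind, from_order, to_order, count`),
#'   `scenario`, and `clips` (number of negative-density clips applied).
#' @examples
#' \donttest{
#' ts <- run_scenario(preset_scenario("fig2"))
#' tail(ts)
#' }
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "phage_scenario"))
  params <- scenario$params
  ext <- scenario$ext
  control <- scenario$control
  if (!is.null(control$seed)) set.seed(control$seed)
  env <- .engine_init(scenario$init, params, ext, control)
  dt <- control$dt
  out_steps <- as.integer(round(control$output_every / dt))
  if (!is.null(scenario$transfers)) {
    sch <- scenario$transfers
    sp <- sch$period / dt
    if (abs(sp - round(sp)) > 1e-8 * max(1, sp))
      stop("transfer period must be an integer multiple of dt")
    steps_per <- as.integer(round(sp))
    n_seg <- sch$n_transfers
  } else {
    sch <- NULL
    steps_per <- as.integer(round(control$duration / dt))
    n_seg <- 1L
  }
  g <- env$geom
  extd <- g$extended
  cols <- c("time_h", "r_ug_ml",
            paste0("B", seq_len(g$nb) - 1L),
            paste0("P", seq_len(g$np) - 1L),
            paste0("M_", g$pih - 1L, "_", g$pjp - 1L),
            if (extd) c("LY", paste0("BP", seq_len(g$npers) - 1L)))
  first <- if (extd) c(env$t, env$r, env$B, env$P, env$Mp, env$LY, env$BP)
           else c(env$t, env$r, env$B, env$P, env$Mp)
  chunks <- vector("list", n_seg + 1L)
  chunks[[1L]] <- matrix(first, 1L)
  for (ci in seq_len(n_seg)) {
    env <- .engine_run(env, params, ext, control, steps_per, out_steps)
    chunks[[ci + 1L]] <- env$samples
    if (!is.null(sch) && ci < n_seg)
      env <- .engine_transfer(env, sch, control$volume)
  }
  tab <- as.data.frame(do.call(rbind, chunks))
  names(tab) <- cols
  events <- if (env$nev > 0L) {
    e <- env$ev[seq_len(env$nev), , drop = FALSE]
    data.frame(time_h = e[, 1L],
               kind = c("BIM-creation", "CEM-creation")[e[, 2L]],
               from_order = as.integer(e[, 3L]),
               to_order = as.integer(e[, 4L]),
               count = as.integer(e[, 5L]))
  } else {
    data.frame(time_h = numeric(0), kind = character(0),
               from_order = integer(0), to_order = integer(0),
               count = integer(0))
  }
  structure(tab,
            events = events,
            scenario = scenario,
            clips = env$clips,
            final = .engine_state(env, params),
            class = c("phage_ts", "data.frame"))
}

#' Event log of a simulated trajectory
#'
#' @param ts A `phage_ts` from [run_scenario()].
#' @return A data.frame of discrete BIM/CEM creation events.
#' @export
ts_events <- function(ts) attr(ts, "events")

#' Final state of a simulated trajectory
#'
#' @param ts A `phage_ts` from [run_scenario()].
#' @return The [community_state()] at the end of the run.
#' @export
ts_final_state <- function(ts) attr(ts, "final")

#' @export
print.phage_ts <- function(x, ...) {
  sc <- attr(x, "scenario")
  ev <- attr(x, "events")
  cat(sprintf("<phage_ts> scenario '%s': %d samples over %g h, %d events, %d clips\n",
              if (is.null(sc$name)) "?" else sc$name,
              nrow(x), x$time_h[nrow(x)], nrow(ev), attr(x, "clips")))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ...\n")
  invisible(x)
}
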