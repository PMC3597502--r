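#' Bundle parameters, initial state and control into a reproducible scenario
#'
#' A scenario is the unit of reproducible simulation: model parameters,
#' optional extended-model parameters, an initial state, control settings, an
#' optional serial-transfer schedule, and a free-text provenance note.
#'
#' @param params [model_params()].
#' @param init Initial [community_state()].
#' @param control [sim_control()].
#' @param ext Optional [extended_params()] (extended model).
#' @param transfers Optional [transfer_schedule()].
#' @param name Scenario name.
#' @param note Free-text provenance note.
#' @param protocol Optional protocol metadata (used by the one-step growth
#'   fixture).
#' @return An object of class `phage_scenario`.
#' @export
scenario <- function(params, init, control = sim_control(), ext = NULL,
                     transfers = NULL, name = "custom", note = "",
                     protocol = NULL) {
  stopifnot(inherits(params, "model_params"),
            inherits(init, "community_state"),
            inherits(control, "sim_control"))
  if (!is.null(ext)) stopifnot(inherits(ext, "extended_params"))
  if (!is.null(transfers)) stopifnot(inherits(transfers, "transfer_schedule"))
  if (length(init$B) != params$n_orders || length(init$P) != params$n_phage)
    stop("initial state dimensions do not match 'params' order counts")
  if (!is.null(ext) && !isTRUE(init$extended))
    stop("extended parameters require an extended initial state")
  Lr <- params$lam / control$dt
  if (abs(Lr - round(Lr)) > 1e-8 * max(1, Lr))
    stop(sprintf(
      "latent period lam = %g h must be an integer multiple of dt = %g h",
      params$lam, control$dt))
  structure(list(name = name, params = params, ext = ext, init = init,
                 control = control, transfers = transfers, note = note,
                 protocol = protocol),
            class = "phage_scenario")
}

#' @export
print.phage_scenario <- function(x, ...) {
  cat(sprintf("<phage_scenario> '%s'%s\n", x$name,
              if (nzchar(x$note)) paste0(" - ", x$note) else ""))
  print(x$params)
  if (!is.null(x$ext)) print(x$ext)
  print(x$init)
  cat(sprintf("  control: dt=%g h, duration=%g h, mode=%s, seed=%s\n",
              x$control$dt, x$control$duration, x$control$event_mode,
              if (is.null(x$control$seed)) "none" else x$control$seed))
  if (!is.null(x$transfers))
    cat(sprintf("  transfers: %d x %g h, 1/%g dilution, R=%g ug/ml%s\n",
                x$transfers$n_transfers, x$transfers$period,
                x$transfers$dilution, x$transfers$R,
                if (x$transfers$stochastic_rounding)
                  ", stochastic rounding" else ""))
  invisible(x)
}

# Parameter set of the short-term growth/lysis experiment: the package-wide
# reference parameterization for S. thermophilus DGCC7710 / phage 2972.
.ref_params <- function(n_orders = 1L, n_phage = n_orders, m = 0, mu = 0,
                        v = 1.4) {
  model_params(v = v, k = 1, e = 5e-7, delta = 8e-8, beta = 80, lam = 0.4,
               m = m, mu = mu, n_orders = n_orders, n_phage = n_phage)
}

#' Names of the built-in scenario presets
#' @return Character vector of valid preset names.
#' @export
list_presets <- function() {
  c("fig2", "figS3a", "figS3b", "fig10a", "fig10bcd", "fig11-serial",
    "onestep-protocol")
}

#' Built-in scenario presets
#'
#' Fully specified scenarios mirroring the package's reference simulation
#' experiments with the Streptococcus thermophilus DGCC7710 / phage 2972
#' parameterization (v = 1.4/h, k = 1 ug/ml, e = 5e-7 ug/cell,
#' delta = 8e-8 ml/cell/phage/h, beta = 80, lam = 0.4 h, fresh resource
#' 350 ug/ml, inocula 2e6/ml):
#'
#' * `"fig2"`: wild-type bacteria and phage, no immunity (m = mu = 0); the
#'   model predicts elimination of the sensitive population within ~2 h.
#' * `"figS3a"`: a single-spacer BIM population confronted with a dominant
#'   wild-type phage population plus a single escape-mutant particle.
#' * `"figS3b"`: equal sensitive and single-spacer-immune populations, no
#'   escape phage initially, CEM mutation at mu = 1e-6 per particle.
#' * `"fig10a"`: extended model without the lysis-released compound
#'   (v_L = 0); the two-spacer BIM ascends and phage are lost.
#' * `"fig10bcd"`: extended model with v_L = 1e-6, K_L = 1e6, eta = 1.4,
#'   g = h = 0.01 over 15 daily 1/100 serial transfers; early transfers are
#'   phage-limited, later ones show BIM ascent and phage loss.
#' * `"fig11-serial"`: extended model initiated with wild-type cells and
#'   phage only, 10 daily transfers; the simulation analog of the long-term
#'   serial-passage experiment.
#' * `"onestep-protocol"`: the adsorption phase of the one-step growth
#'   protocol (2e8 cells/ml, 1e6 phage/ml, 15 min, then 1e4-fold dilution);
#'   consumed by [synth_one_step()].
#'
#' Stochastic presets use the `"poisson"` event mode: with these parameter
#' ranges, per-step unit-event probabilities exceed 1 at any practical step
#' size once phage densities are high.
#'
#' @param name Preset name; see [list_presets()].
#' @param seed Optional RNG seed stored in the control settings.
#' @return A [scenario()].
#' @examples
#' preset_scenario("fig2")$params
#' @export
preset_scenario <- function(name, seed = NULL) {
  if (!name %in% list_presets())
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(list_presets(), collapse = ", ")))
  ext10 <- extended_params(v_L = 1e-6, K_L = 1e6, eta = 1.4,
                           g = 0.01, h = 0.01)
  switch(
    name,
    "fig2" = scenario(
      params = .ref_params(),
      init = community_state(r = 350, B = 2e6, P = 2e6),
      control = sim_control(dt = 1e-3, duration = 24, seed = seed),
      name = name,
      note = "short-term WT x WT dynamics, no immunity"),
    "figS3a" = scenario(
      params = .ref_params(n_orders = 2L, m = 0, mu = 0),
      init = community_state(r = 350, B = c(0, 2e6), P = c(2e6, 1)),
      control = sim_control(dt = 1e-3, duration = 24, seed = seed),
      name = name,
      note = "single-spacer BIM vs dominant WT phage plus one CEM particle"),
    "figS3b" = scenario(
      params = .ref_params(n_orders = 2L, m = 0, mu = 1e-6),
      init = community_state(r = 350, B = c(2e6, 2e6), P = c(2e6, 0)),
      control = sim_control(dt = 1e-3, duration = 24, seed = seed,
                            event_mode = "poisson"),
      name = name,
      note = "BIM + WT mixture, CEMs arise by mutation"),
    "fig10a" = scenario(
      params = .ref_params(n_orders = 3L, n_phage = 2L, m = 1e-6, mu = 1e-6),
      ext = extended_params(v_L = 0, K_L = 1e6, eta = 1.4,
                            g = 0.01, h = 0.01),
      init = community_state(r = 350, B = c(2e6, 0, 2e6), P = c(2e6, 0),
                             extended = TRUE),
      control = sim_control(dt = 1e-3, seed = seed, event_mode = "poisson"),
      transfers = transfer_schedule(period = 24, dilution = 100, R = 350,
                                    n_transfers = 4,
                                    stochastic_rounding = TRUE),
      name = name,
      note = "extended model, no LY: two-spacer BIM ascends, phage lost"),
    "fig10bcd" = scenario(
      params = .ref_params(n_orders = 3L, n_phage = 2L, m = 1e-6, mu = 1e-6),
      ext = ext10,
      init = community_state(r = 350, B = c(2e6, 0, 2e6), P = c(2e6, 0),
                             extended = TRUE),
      control = sim_control(dt = 1e-3, seed = seed, event_mode = "poisson"),
      transfers = transfer_schedule(period = 24, dilution = 100, R = 350,
                                    n_transfers = 15,
                                    stochastic_rounding = TRUE),
      name = name,
      note = "extended model with LY over serial transfers"),
    "fig11-serial" = scenario(
      params = .ref_params(n_orders = 3L, n_phage = 2L, m = 1e-6, mu = 1e-6),
      ext = ext10,
      init = community_state(r = 350, B = c(2e6, 0, 0), P = c(2e6, 0),
                             extended = TRUE),
      control = sim_control(dt = 1e-3, seed = seed, event_mode = "poisson"),
      transfers = transfer_schedule(period = 24, dilution = 100, R = 350,
                                    n_transfers = 10,
                                    stochastic_rounding = TRUE),
      name = name,
      note = "WT cells + WT phage over 10 daily transfers"),
    "onestep-protocol" = scenario(
      params = .ref_params(),
      init = community_state(r = 350, B = 2e8, P = 1e6),
      control = sim_control(dt = 1 / 1200, duration = 0.25, seed = seed,
                            output_every = 1 / 12),
      name = name,
      note = "one-step growth protocol, adsorption phase",
      protocol = list(kind = "one_step", dilution = 1e4,
                      design = one_step_design())))
}
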