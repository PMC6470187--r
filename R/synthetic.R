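# Synthetic fed-batch generator with known ground truth.
#
# Three presets emulate the phenotypes of a reference fed-batch process
# (REF: lactate accumulation, productivity peak at 18 pg/cell/day near
# 120 h, peak density 15e6 cells/mL), a CO2-stressed process (COP: early
# productivity peak at 23 pg/cell/day then steady decline, elevated
# lactate, low peak density ~9e6 cells/mL) and a base-free process (NOB:
# switch from lactate production to consumption between 144 and 240 h,
# productivity rising to 20 pg/cell/day near 240 h, stable ATP pools,
# peak density ~13e6 cells/mL). Ground-truth trajectories are smooth
# splines through those anchors; concentrations are integrated from the
# same fed-batch balances the rate estimator assumes, so noise-free
# round-trip recovery is exact up to spline approximation error.

# natural-spline trajectory through anchor points
traj_fun <- function(t_anchor, v_anchor) {
  stats::splinefun(t_anchor, v_anchor, method = "natural")
}

scenario_anchor_sets <- function() {
  list(
    REF = list(
      x6 = list(t = c(0, 48, 96, 144, 192, 216, 240, 264),
                v = c(0.7, 2.3, 6.5, 11.5, 14.5, 15.0, 14.6, 13.8)),
      q_mab = list(t = c(0, 60, 120, 180, 240, 264),
                   v = c(8, 14.5, 18, 16.5, 12, 11)),
      q_glc = list(t = c(0, 48, 82, 120, 154, 200, 238, 264),
                   v = -c(2600, 2200, 1800, 1750, 1700, 1200, 850, 800)),
      q_lac = list(t = c(0, 48, 82, 120, 154, 200, 238, 264),
                   v = c(3800, 3400, 3100, 2950, 2800, 1900, 1150, 1000)),
      q_gln = list(t = c(0, 48, 82, 154, 238, 264),
                   v = -c(200, 160, 120, 80, 40, 30)),
      q_ala = list(t = c(0, 82, 154, 238, 264),
                   v = c(250, 200, 150, 60, 50)),
      axp = data.frame(phase = 1:4,
                       amp = c(0.30, 0.35, 0.45, 0.55),
                       adp = c(0.85, 0.90, 0.95, 1.00),
                       atp = c(3.60, 3.50, 3.20, 2.80)),
      pyr_pool = list(t = c(33, 82, 154, 238), v = c(1.1, 1.5, 2.2, 2.1)),
      ph = list(t = c(0, 48, 120, 264), v = c(6.95, 6.80, 6.80, 6.80)),
      pco2 = list(t = c(0, 83, 120, 180, 264), v = c(90, 110, 90, 100, 120)),
      osmo = list(t = c(0, 120, 238, 264), v = c(300, 360, 440, 450))
    ),
    COP = list(
      x6 = list(t = c(0, 48, 96, 144, 168, 192, 216, 240, 264),
                v = c(0.7, 2.4, 5.5, 8.2, 9.0, 8.7, 8.2, 7.2, 6.2)),
      q_mab = list(t = c(0, 36, 82, 120, 180, 240, 264),
                   v = c(23, 22.8, 19, 15, 10, 6.5, 6)),
      q_glc = list(t = c(0, 48, 82, 120, 154, 200, 238, 264),
                   v = -c(2900, 2400, 2000, 2050, 2100, 1500, 1000, 950)),
      q_lac = list(t = c(0, 48, 82, 120, 154, 200, 238, 264),
                   v = c(4000, 3600, 3400, 3650, 3900, 2600, 1600, 1500)),
      q_gln = list(t = c(0, 48, 82, 154, 238, 264),
                   v = -c(220, 180, 140, 90, 45, 35)),
      q_ala = list(t = c(0, 82, 154, 238, 264),
                   v = c(250, 200, 160, 40, 30)),
      axp = data.frame(phase = 1:4,
                       amp = c(0.25, 0.35, 0.50, 0.30),
                       adp = c(0.80, 0.90, 1.00, 0.80),
                       atp = c(3.80, 3.60, 3.00, 2.50)),
      pyr_pool = list(t = c(33, 82, 154, 238), v = c(1.2, 1.6, 2.2, 2.2)),
      ph = list(t = c(0, 48, 120, 264), v = c(6.95, 6.80, 6.80, 6.80)),
      pco2 = list(t = c(0, 60, 83, 120, 180, 264), v = c(140, 200, 190, 95, 120, 170)),
      osmo = list(t = c(0, 120, 238, 264), v = c(300, 365, 440, 455))
    ),
    NOB = list(
      x6 = list(t = c(0, 48, 96, 144, 192, 216, 240, 264),
                v = c(0.7, 2.3, 6.0, 10.5, 12.6, 13.0, 12.7, 12.2)),
      q_mab = list(t = c(0, 60, 120, 180, 240, 264),
                   v = c(9, 14, 17.5, 19.5, 20, 19.8)),
      q_glc = list(t = c(0, 48, 82, 120, 154, 200, 238, 264),
                   v = -c(2600, 2100, 1700, 1400, 1150, 1100, 1100, 1100)),
      q_lac = list(t = c(0, 48, 82, 120, 154, 180, 210, 238, 264),
                   v = c(3200, 2300, 1400, 550, 100, -120, -180, -180, -160)),
      q_gln = list(t = c(0, 48, 82, 154, 238, 264),
                   v = -c(200, 160, 120, 80, 50, 40)),
      q_ala = list(t = c(0, 82, 154, 238, 264),
                   v = c(240, 200, 120, 30, 25)),
      axp = data.frame(phase = 1:4,
                       amp = c(0.15, 0.12, 0.10, 0.12),
                       adp = c(0.75, 0.72, 0.70, 0.70),
                       atp = c(3.90, 4.00, 4.00, 3.90)),
      pyr_pool = list(t = c(33, 82, 154, 238), v = c(1.1, 1.3, 1.0, 0.7)),
      ph = list(t = c(0, 48, 120, 180, 238, 264), v = c(6.95, 6.80, 6.80, 6.72, 6.62, 6.60)),
      pco2 = list(t = c(0, 83, 120, 180, 264), v = c(85, 105, 90, 130, 220)),
      osmo = list(t = c(0, 120, 238, 264), v = c(300, 340, 357, 360))
    )
  )
}

#' Scenario presets for the synthetic generator
#'
#' Returns ground-truth trajectory functions and process parameters for
#' one of the calibrated presets `"REF"`, `"COP"`, `"NOB"`, or a
#' `"custom"` scenario built from user-supplied trajectories.
#'
#' @param name preset name.
#' @param custom for `name = "custom"`: a list with the same structure as
#'   a preset (fields `x6`, `q_mab`, `q_glc`, `q_lac`, `q_gln`, `q_ala`,
#'   `axp`, optionally `pyr_pool`, `ph`, `pco2`, `osmo`), passed through
#'   unchanged.
#' @param aa_uptake_factor amino-acid uptake relative to the biosynthetic
#'   demand of growth plus antibody synthesis (default 1.4; the surplus
#'   is catabolized).
#' @param model core model used for demand bookkeeping (default
#'   [build_core_model()]).
#' @return A `chofba_scenario` with trajectory functions `X(t)` (cells/mL),
#'   `mu(t)` (1/day, dilution-corrected), `q_mab(t)` (pg/cell/day),
#'   `q_glc`, `q_lac`, `q_gln`, `q_ala`, `q_aa(t)` (named matrix,
#'   fmol/cell/day), AXP pool table and process parameters.
#' @export
scenario_preset <- function(name = c("REF", "COP", "NOB", "custom"),
                            custom = NULL, aa_uptake_factor = 1.4,
                            model = build_core_model()) {
  name <- match.arg(name)
  anchors <- if (name == "custom") {
    assert_that(!is.null(custom), "custom scenario requires `custom` anchors")
    custom
  } else scenario_anchor_sets()[[name]]

  proc <- list(start_volume = 1.0, inoculum = 0.7e6, feed_start = 24,
               feed_rate = 0.03, duration = 264,
               bolus_trigger_g_L = 2, bolus_target_g_L = 4,
               phase_times = c(33, 82, 154, 238))

  fX <- traj_fun(anchors$x6$t, log(anchors$x6$v * 1e6))
  feed0 <- feed_program(start_volume = proc$start_volume,
                        feed_start = proc$feed_start, feed_rate = proc$feed_rate)
  Xfun <- function(t) exp(fX(t))
  mufun <- function(t) fX(t, deriv = 1) * 24 + dilution_at(feed0, t)

  qs <- list(q_mab = traj_fun(anchors$q_mab$t, anchors$q_mab$v),
             q_glc = traj_fun(anchors$q_glc$t, anchors$q_glc$v),
             q_lac = traj_fun(anchors$q_lac$t, anchors$q_lac$v),
             q_gln = traj_fun(anchors$q_gln$t, anchors$q_gln$v),
             q_ala = traj_fun(anchors$q_ala$t, anchors$q_ala$v))

  aa_ids <- setdiff(AA_TABLE$id, c("gln", "ala"))
  bc <- model$biomass_composition
  mc <- model$mab_composition
  dw <- model$cell_dry_weight
  q_aa <- function(t) {
    mu <- pmax(mufun(t), 0)
    vmab <- pg_to_fmol(pmax(qs$q_mab(t), 0), model$mab_molar_mass_kda)
    out <- vapply(aa_ids, function(a)
      -aa_uptake_factor * (mu * dw * (bc[[a]] %||% 0) + vmab * (mc[[a]] %||% 0)),
      numeric(length(t)))
    if (length(t) == 1) out <- matrix(out, 1, dimnames = list(NULL, aa_ids))
    out
  }

  structure(list(name = name, anchors = anchors, process = proc,
                 X = Xfun, mu = mufun, q_mab = qs$q_mab, q_glc = qs$q_glc,
                 q_lac = qs$q_lac, q_gln = qs$q_gln, q_ala = qs$q_ala,
                 q_aa = q_aa, aa_ids = aa_ids,
                 aa_uptake_factor = aa_uptake_factor, model = model),
            class = "chofba_scenario")
}

# ground-truth rate table of a scenario at one time point; the CO2
# evolution rate closes the carbon balance by construction
scenario_rate_table <- function(scenario, t) {
  m <- scenario$model
  aa_q <- drop(scenario$q_aa(t))
  qs <- c(mu = scenario$mu(t), mab = scenario$q_mab(t),
          glucose = scenario$q_glc(t), lactate = scenario$q_lac(t),
          gln = scenario$q_gln(t), ala = scenario$q_ala(t), aa_q)
  carbon <- carbon_counts(m)
  cin <- 6 * abs(qs[["glucose"]]) +
    sum(vapply(c("gln", scenario$aa_ids), function(a)
      carbon[[a]] * max(-qs[[a]], 0), 0)) +
    3 * max(-qs[["lactate"]], 0)
  cout_nonco2 <- 3 * max(qs[["lactate"]], 0) + 3 * max(qs[["ala"]], 0) +
    qs[["mu"]] * m$metabolites$biomass_e$carbon_count +
    pg_to_fmol(qs[["mab"]], m$mab_molar_mass_kda) * m$metabolites$mab_e$carbon_count
  qs[["co2"]] <- cin - cout_nonco2
  rate_table(names(qs), unname(qs), error = 0, time_h = t)
}

#' Build a culture dataset from timecourses
#'
#' @param timecourses nested list: analyte -> list of replicate
#'   [timecourse()] objects.
#' @param feed a [feed_program()].
#' @param pools optional data frame of per-phase intracellular pools
#'   (columns `phase`, `time_h`, `replicate`, `amp`, `adp`, `atp`, ...).
#' @param scenario_name optional label.
#' @return A `chofba_culture_dataset`.
#' @export
culture_dataset <- function(timecourses, feed, pools = NULL,
                            scenario_name = "custom") {
  n_rep <- unique(vapply(timecourses, length, 0L))
  assert_that(length(n_rep) == 1, "all analytes need the same replicate count")
  structure(list(timecourses = timecourses, feed = feed, pools = pools,
                 scenario = scenario_name),
            class = "chofba_culture_dataset")
}

#' @export
print.chofba_culture_dataset <- function(x, ...) {
  cat(sprintf("chofba culture dataset (%s): %d analytes x %d replicates\n",
              x$scenario, length(x$timecourses), length(x$timecourses[[1]])))
  invisible(x)
}

#' Simulate a synthetic fed-batch culture
#'
#' Integrates the fed-batch balances `dX/dt = (mu - D) X`,
#' `d(C_i V)/dt = q_i X V + F c_feed,i` (deSolve, with the glucose bolus
#' rule: concentration below 2 g/L triggers an instantaneous refill to
#' 4 g/L), samples the trajectories at the given interval, and applies
#' multiplicative lognormal noise per replicate. AXP (and pyruvate) pools
#' are emitted at the four phase time points.
#'
#' @param scenario a `chofba_scenario` from [scenario_preset()].
#' @param sampling_interval sampling interval in hours (default 12,
#'   twice daily).
#' @param noise_cv coefficient of variation of the measurement noise for
#'   cell density and titer; metabolite concentrations get `5/3 *
#'   noise_cv` (defaults emulate 3% / 5%). 0 gives noise-free data.
#' @param n_replicates number of replicate cultivations (default 3).
#' @param seed RNG seed; fixed seed gives bit-identical datasets.
#' @return A `chofba_generated_dataset`: list with `dataset`
#'   (a [culture_dataset()]) and `ground_truth` (scenario, dense
#'   trajectories, true rate tables at the phase time points, recorded
#'   bolus events).
#' @export
simulate_fedbatch <- function(scenario, sampling_interval = 12,
                              noise_cv = 0.03, n_replicates = 3, seed = 1) {
  assert_that(inherits(scenario, "chofba_scenario"), "scenario must be a chofba_scenario")
  assert_that(noise_cv >= 0, "noise_cv must be non-negative")
  assert_that(sampling_interval > 0, "sampling_interval must be positive")
  proc <- scenario$process
  m <- scenario$model
  aa_ids <- scenario$aa_ids

  feed_conc <- c(glucose = 40, mab = 0, lactate = 0, gln = 12, ala = 0,
                 setNames(rep(10, length(aa_ids)), aa_ids))
  start_conc <- c(glucose = 6, mab = 0, lactate = 1, gln = 5, ala = 0.5,
                  setNames(rep(5, length(aa_ids)), aa_ids))
  analytes <- names(start_conc)

  feed0 <- feed_program(start_volume = proc$start_volume,
                        feed_start = proc$feed_start, feed_rate = proc$feed_rate,
                        feed_concentrations = feed_conc)

  # state: amounts n_i; glucose in mmol, mab in g, metabolites in mmol
  unit_of <- c(glucose = "g/L", mab = "g/L", lactate = "mmol/L",
               gln = "mmol/L", ala = "mmol/L",
               setNames(rep("mmol/L", length(aa_ids)), aa_ids))
  n0 <- start_conc * proc$start_volume
  n0[["glucose"]] <- glc_g_to_mM(start_conc[["glucose"]]) * proc$start_volume

  q_of <- function(t) {
    c(glucose = scenario$q_glc(t), mab = scenario$q_mab(t),
      lactate = scenario$q_lac(t), gln = scenario$q_gln(t),
      ala = scenario$q_ala(t), drop(scenario$q_aa(t)))
  }
  deriv <- function(t, y, parms) {
    V <- volume_at(feed0, t)
    X <- scenario$X(t)
    q <- q_of(t)[analytes]
    # fmol/cell/day * cells/mL * 1000 mL/L * V L -> fmol/day; 1e-12 -> mmol/day
    dn <- q * X * 1000 * V * 1e-12 / 24
    dn[["mab"]] <- q[["mab"]] * X * 1000 * V * 1e-12 / 24  # pg -> g
    F_Lh <- feed_rate_at(feed0, t) / 24
    dn <- dn + F_Lh * ifelse(analytes == "glucose",
                             glc_g_to_mM(feed_conc[["glucose"]]),
                             feed_conc[analytes])
    if (any(y[analytes != "mab"] < -1e-6))
      stop_chofba("negative amount for '%s' during integration",
                  analytes[which(y < -1e-6)[1]])
    list(dn)
  }
  bolus_log <- new.env()
  bolus_log$events <- data.frame(time_h = numeric(), analyte = character(),
                                 amount = numeric())
  rootfun <- function(t, y, parms) {
    glc_g_L <- glc_mM_to_g(y[["glucose"]] / volume_at(feed0, t))
    glc_g_L - proc$bolus_trigger_g_L
  }
  eventfun <- function(t, y, parms) {
    V <- volume_at(feed0, t)
    target <- glc_g_to_mM(proc$bolus_target_g_L) * V
    added <- target - y[["glucose"]]
    if (added > 0) {   # the root also fires on upward recrossings; ignore those
      bolus_log$events <- rbind(bolus_log$events,
                                data.frame(time_h = t, analyte = "glucose",
                                           amount = glc_mM_to_g(added)))
      y[["glucose"]] <- target
    }
    y
  }
  times <- seq(0, proc$duration, by = 0.5)
  sol <- deSolve::ode(y = setNames(as.numeric(n0), analytes), times = times,
                      func = deriv, parms = NULL, method = "lsodar",
                      rootfunc = rootfun,
                      events = list(func = eventfun, root = TRUE))
  sol <- as.data.frame(sol)

  feed <- feed_program(start_volume = proc$start_volume,
                       feed_start = proc$feed_start, feed_rate = proc$feed_rate,
                       feed_concentrations = feed_conc,
                       bolus_events = bolus_log$events)

  sample_times <- seq(0, proc$duration, by = sampling_interval)
  Vs <- volume_at(feed, sample_times)
  conc_at <- function(analyte) {
    n <- approx(sol$time, sol[[analyte]], xout = sample_times)$y
    C <- n / Vs
    if (analyte == "glucose") C <- glc_mM_to_g(C)
    C
  }
  true_conc <- lapply(analytes, conc_at)
  names(true_conc) <- analytes
  true_X <- scenario$X(sample_times)

  sdlog_of <- function(cv) sqrt(log(1 + cv^2))
  noisy <- function(values, cv, rep_seedless) {
    if (cv == 0) return(values)
    sdl <- sdlog_of(cv)
    values * stats::rlnorm(length(values), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  set.seed(seed)
  tcs <- list()
  tcs$vcd <- lapply(seq_len(n_replicates), function(r)
    timecourse(sample_times, noisy(true_X, noise_cv), unit = "cells/mL"))
  for (an in analytes) {
    cv <- if (an == "mab") noise_cv else noise_cv * 5 / 3
    tcs[[an]] <- lapply(seq_len(n_replicates), function(r)
      timecourse(sample_times, noisy(true_conc[[an]], cv), unit = unit_of[[an]]))
  }

  axp <- scenario$anchors$axp
  pyr <- scenario$anchors$pyr_pool
  pools <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(phase = axp$phase, time_h = proc$phase_times, replicate = r,
               amp = noisy(axp$amp, noise_cv * 5 / 3),
               adp = noisy(axp$adp, noise_cv * 5 / 3),
               atp = noisy(axp$atp, noise_cv * 5 / 3),
               pyr = noisy(approx(pyr$t, pyr$v, xout = proc$phase_times)$y,
                           noise_cv * 5 / 3))
  }))

  process_channels <- data.frame(
    time_h = sample_times,
    ph = traj_fun(scenario$anchors$ph$t, scenario$anchors$ph$v)(sample_times),
    pco2_mbar = traj_fun(scenario$anchors$pco2$t, scenario$anchors$pco2$v)(sample_times),
    osmolality_mosm = traj_fun(scenario$anchors$osmo$t, scenario$anchors$osmo$v)(sample_times))

  dataset <- culture_dataset(tcs, feed, pools = pools,
                             scenario_name = scenario$name)
  dataset$process_channels <- process_channels

  truth <- list(
    scenario = scenario,
    times = sample_times,
    X = true_X,
    concentrations = true_conc,
    rate_tables = lapply(proc$phase_times, function(tp)
      scenario_rate_table(scenario, tp)),
    bolus_events = bolus_log$events)
  names(truth$rate_tables) <- paste0("t", proc$phase_times)

  structure(list(dataset = dataset, ground_truth = truth,
                 noise_cv = noise_cv, seed = seed),
            class = "chofba_generated_dataset")
}
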