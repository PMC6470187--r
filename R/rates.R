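# Cell-specific rates from fed-batch mass balances.
#
# For a continuously fed stirred culture with concentration C (per
# volume), feed concentration C_feed and dilution rate D = F/V, the
# per-volume balance gives the cell-specific rate
#
#   q(t) = [dC/dt + D(t) * (C(t) - C_feed)] / X(t)
#
# with production positive and uptake negative. Sampling drains are
# concentration-neutral (the matching feed reduction compensates the
# volume), so they do not enter the balance. Bolus additions are removed
# from the concentration signal before smoothing, so dC/dt reflects
# consumption only.

#' Create a feed program
#'
#' @param start_volume reactor start volume (L).
#' @param feed_start feed start time (h).
#' @param feed_rate continuous feed rate from `feed_start` on (L/day),
#'   piecewise constant; scalar for a single-rate program.
#' @param feed_concentrations named vector: analyte -> concentration in
#'   the feed (same unit as the analyte's timecourse).
#' @param bolus_events data frame with columns `time_h`, `analyte`,
#'   `amount` (amount added in concentration-unit * L).
#' @param sample_drains data frame with columns `time_h`, `volume_L`
#'   (documented, concentration-neutral).
#' @return A `chofba_feed_program`.
#' @export
feed_program <- function(start_volume = 1.0, feed_start = 24, feed_rate = 0.03,
                         feed_concentrations = numeric(),
                         bolus_events = data.frame(time_h = numeric(),
                                                   analyte = character(),
                                                   amount = numeric()),
                         sample_drains = data.frame(time_h = numeric(),
                                                    volume_L = numeric())) {
  assert_that(start_volume > 0, "start_volume must be positive")
  assert_that(all(feed_rate >= 0), "feed_rate must be non-negative")
  assert_that(nrow(bolus_events) == 0 || all(bolus_events$amount > 0),
              "bolus amounts must be positive")
  structure(list(start_volume = start_volume, feed_start = feed_start,
                 feed_rate = feed_rate, feed_concentrations = feed_concentrations,
                 bolus_events = bolus_events, sample_drains = sample_drains),
            class = "chofba_feed_program")
}

# feed rate (L/day) at time t (h)
feed_rate_at <- function(feed, t) {
  ifelse(t >= feed$feed_start, feed$feed_rate[1], 0)
}

# reactor volume (L) at time t (h); feed from feed_start at feed_rate L/day
volume_at <- function(feed, t) {
  feed$start_volume + pmax(t - feed$feed_start, 0) / 24 * feed$feed_rate[1]
}

# dilution rate D = F/V in 1/day
dilution_at <- function(feed, t) {
  feed_rate_at(feed, t) / volume_at(feed, t)
}

#' Cell-specific rate from smoothed profiles
#'
#' Evaluates `q(t) = [dC/dt + D(t)(C(t) - C_feed)] / X(t)` with `C` in
#' mmol/L (use [specific_rate_mab()] for the antibody in g/L) and `X` in
#' cells/mL; the result is in fmol/cell/day, production positive.
#'
#' @param profile_C smoothed concentration profile (mmol/L).
#' @param profile_X smoothed viable-cell-density profile (cells/mL).
#' @param feed a [feed_program()].
#' @param t analysis time (h), inside both fitted intervals.
#' @param c_feed feed concentration of the analyte (mmol/L; default from
#'   the feed program, 0 if absent).
#' @param analyte analyte name used for the feed-concentration lookup.
#' @return rate in fmol/cell/day.
#' @export
specific_rate <- function(profile_C, profile_X, feed, t, analyte = NULL,
                          c_feed = NULL) {
  X <- predict(profile_X, t)
  assert_that(all(X > 0), "cell density must be positive at the analysis time")
  if (is.null(c_feed)) {
    c_feed <- if (!is.null(analyte) && analyte %in% names(feed$feed_concentrations))
      feed$feed_concentrations[[analyte]] else 0
  }
  C <- predict(profile_C, t)
  dCdt <- predict(profile_C, t, deriv = 1) * 24       # per day
  D <- dilution_at(feed, t)                            # 1/day
  rate <- dCdt + D * (C - c_feed)                      # mmol/L/day
  rate * 1e9 / X                                       # fmol/cell/day
}

#' Cell-specific antibody productivity
#'
#' Same balance as [specific_rate()] with the titer in g/L; returns
#' pg/cell/day.
#'
#' @inheritParams specific_rate
#' @param profile_P smoothed titer profile (g/L).
#' @return q_mAb in pg/cell/day.
#' @export
specific_rate_mab <- function(profile_P, profile_X, feed, t) {
  X <- predict(profile_X, t)
  assert_that(all(X > 0), "cell density must be positive at the analysis time")
  dPdt <- predict(profile_P, t, deriv = 1) * 24        # g/L/day
  D <- dilution_at(feed, t)
  rate <- dPdt + D * predict(profile_P, t)             # g/L/day (no mAb in feed)
  rate * 1e9 / X                                       # pg/cell/day
}

#' Specific growth rate
#'
#' Dilution-corrected net growth `mu(t) = (dX/dt)/X + D(t)` in 1/day;
#' death is lumped into the net rate.
#'
#' @param profile_X smoothed viable-cell-density profile (cells/mL).
#' @param feed a [feed_program()].
#' @param t analysis time (h).
#' @return mu in 1/day.
#' @export
growth_rate <- function(profile_X, feed, t) {
  X <- predict(profile_X, t)
  assert_that(all(X > 0), "cell density must be positive at the analysis time")
  dXdt <- predict(profile_X, t, deriv = 1) * 24
  dXdt / X + dilution_at(feed, t)
}

#' Assemble a rate table
#'
#' @param quantity character vector of rate names (`"glucose"`,
#'   `"lactate"`, `"mu"`, `"mab"`, amino-acid ids, ...).
#' @param value rates: fmol/cell/day for metabolites, 1/day for `mu`,
#'   pg/cell/day for `mab`. Production positive, uptake negative.
#' @param error non-negative rate errors, same units.
#' @param time_h analysis time point.
#' @return data frame of class `chofba_rate_table`.
#' @export
rate_table <- function(quantity, value, error = 0, time_h = NA_real_) {
  assert_that(all(error >= 0, na.rm = TRUE), "rate errors must be non-negative")
  out <- data.frame(quantity = quantity, value = value, error = error,
                    time_h = time_h, stringsAsFactors = FALSE)
  class(out) <- c("chofba_rate_table", "data.frame")
  out
}

#' Combine replicate rate tables
#'
#' Value = mean across replicates, error = sample standard deviation
#' (the error definition used for the measured-rate FBA bounds). A single
#' replicate yields zero errors with a warning.
#'
#' @param tables list of rate tables with identical `quantity` columns.
#' @return a combined `chofba_rate_table`.
#' @export
rate_errors_from_replicates <- function(tables) {
  assert_that(length(tables) >= 1, "need at least one replicate table")
  if (length(tables) == 1) {
    warning("single replicate: rate errors set to zero")
    out <- tables[[1]]
    out$error <- 0
    return(out)
  }
  q <- tables[[1]]$quantity
  for (tb in tables[-1])
    assert_that(identical(tb$quantity, q), "replicate tables must share quantities")
  vals <- vapply(tables, `[[`, numeric(length(q)), "value")
  vals <- matrix(vals, nrow = length(q))
  rate_table(q, rowMeans(vals), apply(vals, 1, sd),
             time_h = tables[[1]]$time_h[1])
}

#' Carbon balance closure of measured rates
#'
#' Closure = carbon leaving in products (lactate and amino acids when
#' produced, biomass, antibody, CO2 when measured) divided by carbon
#' entering from consumed substrates (glucose, consumed amino acids,
#' consumed lactate). Unmeasured CO2 makes the closure fall short of 1
#' and is reported as the unmeasured sink.
#'
#' @param rates a rate table for one time point (fmol/cell/day; `mu` in
#'   1/day, `mab` in pg/cell/day).
#' @param carbon_registry named vector, substrate id -> carbon count;
#'   must contain `glc` and `lac` plus every measured amino acid.
#' @param model a `chofba_model` supplying biomass and antibody carbon
#'   content and unit conversions.
#' @return list with `closure`, `carbon_in`, `carbon_out`
#'   (fmol C/cell/day) and `unmeasured_sinks`.
#' @export
carbon_balance <- function(rates, carbon_registry, model) {
  get_c <- function(id) {
    assert_that(id %in% names(carbon_registry), "missing carbon count for '%s'", id)
    carbon_registry[[id]]
  }
  cin <- 0; cout <- 0
  has_co2 <- FALSE
  for (i in seq_len(nrow(rates))) {
    q <- rates$quantity[i]; v <- rates$value[i]
    if (q == "mu") {
      bio_c <- model$metabolites$biomass_e$carbon_count
      cout <- cout + v * bio_c            # v in 1/day, bio_c fmol C per unit
    } else if (q == "mab") {
      mab_c <- model$metabolites$mab_e$carbon_count
      cout <- cout + pg_to_fmol(v, model$mab_molar_mass_kda) * mab_c
    } else {
      id <- switch(q, glucose = "glc", lactate = "lac", co2 = "co2", q)
      if (q == "co2") has_co2 <- TRUE
      cc <- get_c(id)
      if (v < 0) cin <- cin + abs(v) * cc else cout <- cout + v * cc
    }
  }
  assert_that(cin > 0, "no carbon input measured; closure undefined")
  list(closure = cout / cin, carbon_in = cin, carbon_out = cout,
       unmeasured_sinks = if (has_co2) character() else "co2")
}

#' Read / write fed-batch culture datasets
#'
#' Long-format CSV with columns `time_h`, `analyte`, `value`, `unit`,
#' `replicate`. Units: `cells/mL` for `vcd`, `g/L` for `glucose` and
#' `mab`, `mmol/L` for metabolites.
#'
#' @param path CSV file path.
#' @return for `read_culture_csv`, a data frame in long format.
#' @export
read_culture_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "analyte", "value", "unit", "replicate")
  assert_that(all(need %in% names(df)), "culture CSV must have columns: %s",
              paste(need, collapse = ", "))
  df
}

#' @rdname read_culture_csv
#' @param dataset a `chofba_culture_dataset` (see [simulate_fedbatch()]).
#' @export
write_culture_csv <- function(dataset, path) {
  utils::write.csv(culture_long_format(dataset), path, row.names = FALSE)
  invisible(path)
}

# long-format view of a culture dataset
culture_long_format <- function(dataset) {
  rows <- list()
  for (an in names(dataset$timecourses)) {
    reps <- dataset$timecourses[[an]]
    for (r in seq_along(reps)) {
      tc <- reps[[r]]
      rows[[length(rows) + 1]] <-
        data.frame(time_h = tc$times, analyte = an, value = tc$values,
                   unit = tc$unit, replicate = r)
    }
  }
  do.call(rbind, rows)
}

#' Estimate cell-specific rates from a culture dataset
#'
#' Fits shape-constrained profiles per analyte and replicate (removing
#' recorded bolus steps from bolus-fed analytes before smoothing),
#' derives growth, antibody and metabolite rates at the analysis time
#' points, and combines replicates into mean +/- SD tables.
#'
#' @param dataset a `chofba_culture_dataset` from [simulate_fedbatch()]
#'   or built from [read_culture_csv()] data via [culture_dataset()].
#' @param timepoints analysis times (h), default `c(33, 82, 154, 238)`.
#' @param max_segments maximal spline segments (default 4).
#' @return named list of combined `chofba_rate_table`s, one per time
#'   point, plus attribute `"replicate_tables"`.
#' @export
estimate_rates <- function(dataset, timepoints = c(33, 82, 154, 238),
                           max_segments = 4) {
  feed <- dataset$feed
  analytes <- names(dataset$timecourses)
  n_rep <- length(dataset$timecourses[[1]])
  rep_tables <- vector("list", n_rep)

  # per-point measurement noise per analyte from the replicate scatter
  # (small-sample-unbiased SD, E[s] = c4 * sigma): used both as inverse
  # weights for the heteroscedastic fit and to keep the spline from
  # spending flexibility on noise; log scale for the cell density
  point_errors <- function(an, log_scale = FALSE) {
    if (n_rep < 2) return(NULL)
    vals <- sapply(dataset$timecourses[[an]], `[[`, "values")
    if (log_scale) vals <- log(pmax(vals, 1e-12))
    c4 <- sqrt(2 / (n_rep - 1)) * gamma(n_rep / 2) / gamma((n_rep - 1) / 2)
    s <- apply(vals, 1, sd) / c4
    if (all(is.finite(s)) && any(s > 0)) s else NULL
  }

  for (r in seq_len(n_rep)) {
    profs <- list()
    for (an in analytes) {
      tc <- dataset$timecourses[[an]][[r]]
      if (an == "vcd") {
        # cell density spans orders of magnitude; fit on the log scale
        profs[[an]] <- fit_log_profile(tc, max_segments = max_segments,
                                       errors = point_errors(an, log_scale = TRUE))
        next
      }
      jumps <- bolus_jumps(feed, an, tc)
      nonneg <- nrow(jumps) == 0   # the deconvolved signal may go negative
      tc_fit <- deconvolve_boluses(tc, jumps)
      profs[[an]] <- fit_shape_constrained(tc_fit, max_segments = max_segments,
                                           nonneg = nonneg,
                                           errors = point_errors(an))
    }
    pX <- profs$vcd
    rep_tables[[r]] <- lapply(timepoints, function(tp) {
      qs <- list()
      qs$mu <- growth_rate(pX, feed, tp)
      if ("mab" %in% analytes) qs$mab <- specific_rate_mab(profs$mab, pX, feed, tp)
      for (an in setdiff(analytes, c("vcd", "mab"))) {
        unit <- dataset$timecourses[[an]][[r]]$unit
        cf <- if (an %in% names(feed$feed_concentrations))
          feed$feed_concentrations[[an]] else 0
        # glucose is tracked in g/L; convert both signal and feed to mmol/L
        if (unit == "g/L") {
          q <- specific_rate(rescale_profile(profs[[an]], 1000 / MW_GLUCOSE),
                             pX, feed, tp, c_feed = glc_g_to_mM(cf))
        } else {
          q <- specific_rate(profs[[an]], pX, feed, tp, c_feed = cf)
        }
        qs[[an]] <- q
      }
      rate_table(names(qs), unlist(qs), error = 0, time_h = tp)
    })
  }
  out <- lapply(seq_along(timepoints), function(i) {
    tabs <- lapply(rep_tables, `[[`, i)
    if (n_rep == 1) {
      tb <- tabs[[1]]
    } else {
      tb <- rate_errors_from_replicates(tabs)
    }
    tb
  })
  names(out) <- paste0("t", timepoints)
  attr(out, "replicate_tables") <- rep_tables
  out
}

# recorded bolus events for an analyte, as concentration jumps
bolus_jumps <- function(feed, analyte, tc) {
  ev <- feed$bolus_events
  ev <- ev[ev$analyte == analyte, , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(time_after = numeric(), jump = numeric()))
  jump <- ev$amount / volume_at(feed, ev$time_h)
  # attribute each bolus to the first sample at/after the event
  data.frame(time_after = vapply(ev$time_h, function(t0) {
    at <- tc$times[tc$times >= t0 - 1e-9]
    if (length(at)) at[1] else Inf
  }, 0), jump = jump)
}

# linear rescaling of a fitted profile (unit conversion)
rescale_profile <- function(profile, factor) {
  profile$coef <- profile$coef * factor
  profile$unit <- paste0(profile$unit, " (rescaled)")
  profile
}
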