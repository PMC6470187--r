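# Shared fixtures, built once per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

core_model <- function() fixture("core_model", build_core_model)

aa_ids <- function() {
  m <- core_model()
  setdiff(sub("_e$", "", grep("_e$", names(m$metabolites), value = TRUE)),
          c("glc", "lac", "co2", "o2", "biomass", "mab"))
}

# rate table closing every measured exchange except the overrides
desk_rates <- function(...) {
  over <- list(...)
  rt <- rate_table(c("glucose", "lactate", "mu", "mab", aa_ids()), 0, 0)
  for (q in names(over)) {
    stopifnot(q %in% rt$quantity)
    rt$value[rt$quantity == q] <- over[[q]][1]
    if (length(over[[q]]) > 1) rt$error[rt$quantity == q] <- over[[q]][2]
  }
  rt
}

# minimal hand-made flux problem around a stoichiometric matrix
toy_problem <- function(S, lb, ub, obj_rxn = colnames(S)[1]) {
  obj <- setNames(numeric(ncol(S)), colnames(S))
  obj[obj_rxn] <- 1
  structure(list(S = S, lb = setNames(lb, colnames(S)),
                 ub = setNames(ub, colnames(S)),
                 objective = obj, provenance = list(), model = NULL),
            class = "chofba_flux_problem")
}

ref_noisefree <- function() fixture("ref_noisefree", function()
  simulate_fedbatch(scenario_preset("REF"), sampling_interval = 12,
                    noise_cv = 0, n_replicates = 1, seed = 1))

ref_noisefree_rates <- function() fixture("ref_noisefree_rates", function()
  estimate_rates(ref_noisefree()$dataset))

ref_noisefree_pipeline <- function() fixture("ref_noisefree_pipeline", function()
  run_pipeline(pipeline_config(scenario = "REF", noise_cv = 0,
                               n_replicates = 1, seed = 1)))
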