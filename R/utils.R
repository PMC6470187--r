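# Internal helpers shared across modules.

# Default "effectively unbounded" flux bound (fmol/cell/day). Finite so that
# every linear program stays bounded and the simplex tableau well scaled.
BIG_BOUND <- 1e6

# molar masses used for unit conversion
MW_GLUCOSE <- 180.156  # g/mol
DEFAULT_MAB_KDA <- 150 # generic IgG1 molar mass, kDa

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_chofba <- function(fmt, ..., class = "chofba_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_chofba(fmt, ...)
  invisible(TRUE)
}

# pg/cell/day of antibody -> fmol/cell/day given molar mass in kDa
pg_to_fmol <- function(q_pg, molar_mass_kda = DEFAULT_MAB_KDA) {
  q_pg / molar_mass_kda
}

fmol_to_pg <- function(q_fmol, molar_mass_kda = DEFAULT_MAB_KDA) {
  q_fmol * molar_mass_kda
}

# glucose g/L <-> mmol/L
glc_g_to_mM <- function(g_per_L) g_per_L * 1000 / MW_GLUCOSE
glc_mM_to_g <- function(mM) mM * MW_GLUCOSE / 1000
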