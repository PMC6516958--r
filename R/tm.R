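# Nearest-neighbor melting temperature.
#
# Unified nearest-neighbor thermodynamics with duplex initiation and terminal
# A/T penalties; entropic salt correction 0.368 * (N - 1) * ln[Na+]; Tm at
# total strand concentration C_T via dH / (dS + R ln(C_T / 4)).  Formamide
# depresses the effective Tm linearly (default 0.65 degC per percent).

#' Hybridization conditions for Tm calculation
#'
#' @param na_conc monovalent cation concentration, molar (default 0.39,
#'   i.e. 2x SSC).
#' @param oligo_conc total strand concentration, molar (default 5e-8).
#' @param formamide_pct percent formamide in the hybridization buffer
#'   (default 0; the screening Tm window is defined on the salt-only Tm).
#' @param formamide_coef Tm depression per percent formamide, degC (default
#'   0.65).
#' @return a list of conditions for [melting_temperature()].
#' @export
tm_conditions <- function(na_conc = 0.39, oligo_conc = 5e-8,
                          formamide_pct = 0, formamide_coef = 0.65) {
  stopifnot(na_conc > 0, oligo_conc > 0, formamide_pct >= 0,
            formamide_coef >= 0)
  list(na_conc = na_conc, oligo_conc = oligo_conc,
       formamide_pct = formamide_pct, formamide_coef = formamide_coef)
}

#' Nearest-neighbor melting temperature
#'
#' @param sequence A/C/G/T string, length >= 8.  Ambiguity codes are an
#'   error.
#' @param conditions list from [tm_conditions()].
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(sequence, conditions = tm_conditions()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8)
    abort_np("sequence must be at least 8 nt", "np_param_error")
  if (grepl("[^ACGT]", sequence))
    abort_np("Tm is defined for A/C/G/T sequences only", "np_bad_alphabet")
  cpp_tm_nn(sequence, conditions$na_conc, conditions$oligo_conc,
            conditions$formamide_pct, conditions$formamide_coef)
}
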