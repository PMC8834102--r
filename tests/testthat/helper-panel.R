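# Shared fixtures, built in code. Seed 42 is the frozen study seed used by
# every stochastic check.
STUDY_SEED <- 42L

default_panel <- build_default_panel()

noise_free_model <- function(panel = default_panel, ...) {
  instrument_model(panel, noise_cv = 0, carryover_fraction = 0,
                   seed = STUDY_SEED, ...)
}

# The per-analyte base (LLOQ design) levels stated for the assay, ng/mL.
expected_base_levels <- c(
  "naringenin" = 2,
  "naringenin-7-O-glucuronide" = 20,
  "naringenin-4'-O-glucuronide" = 20,
  "apigenin" = 1,
  "eriodictyol" = 0.5,
  "homoeriodictyol" = 1,
  "hesperetin" = 0.5,
  "hesperetin-7-O-glucuronide" = 4,
  "hesperetin-3'-O-glucuronide" = 4,
  "hesperetin-7-O-sulfate" = 1)

# Assemble a minimal injection table row; used to hand-build fixtures for
# the validation statistics without running the generator.
inj_row <- function(analyte, area, is_area = 1e5, role = "qc", batch = 1L,
                    lot = "lot1", nominal = NA_real_, level = NA_character_,
                    dilution = 1, condition = NA_character_) {
  tibble::tibble(sample_id = "manual", role = role, batch = batch, lot = lot,
                 injection_index = 1L, analyte = analyte, area = area,
                 is_area = is_area, nominal_ng_per_ml = nominal,
                 level_label = level, dilution_factor = dilution,
                 condition = condition)
}
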