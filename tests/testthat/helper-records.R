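# A one-row admission record with every field at a benign reference value;
# override any field by name.
make_record <- function(...) {
  rec <- tibble::tibble(
    admission_id = "A1",
    age_months = 6L,
    sex = "female",
    admission_date = as.Date("2018-06-01"),
    outcome = "discharged",
    resp_rate = 38,
    spo2_percent = 98L,
    conscious_level = "normal",
    muac_cm = 13.5,
    waz = 0,
    wlz = 0
  )
  for (s in sign_fields()) rec[[s]] <- 0L
  rec$alri_discharge_dx <- TRUE
  rec$severe_alri_presentation <- TRUE
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# Small random cohort via the generator (no missingness unless asked).
make_cohort <- function(n, seed = 42L, ...) {
  generate_cohort(generator_config(n_admissions = n, seed = seed, ...))
}
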