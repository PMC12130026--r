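# shared builders for the criterion tests

baseline_patient <- function(id = "base") {
  patient_record(
    id, age_years = 70L, sex = "male",
    medications = medication("N02BE01", daily_dose = 500,
                             duration_days = 5L, indication_code = "pain")
  )
}

unit_to_patient <- function(unit, id = "u1") {
  pimscreen:::unit_patient(list(unit), patient_id = id)
}
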