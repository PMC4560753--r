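# Shared fixtures: the published extreme profiles and small file fixtures,
# all built in code.

max_preoperative_profile <- function() {
  preoperative_profile(
    previous_surgery_count = 2,
    history_postsurgical_adhesions = TRUE,
    concomitant_inflammation_or_infection = TRUE,
    endometriosis = "severe",
    cancer = "local_non_gynaecological",
    radiation = "local",
    keloid_scarring = TRUE,
    prior_intraperitoneal_bleeding = TRUE,
    prior_postoperative_complications = TRUE,
    prior_postoperative_infection = TRUE
  )
}

min_perioperative_profile <- function(...) {
  perioperative_profile(
    duration_minutes = 60,
    surgery_type_site = "laparoscopy_fallopian_tube",
    ...
  )
}

max_perioperative_profile <- function() {
  perioperative_profile(
    adhesion_quality = "dense",
    adhesion_severity = "bowel_involvement",
    bleeding_over_500ml = TRUE,
    duration_minutes = 180,
    complex_or_multiquadrant = TRUE,
    excessive_coagulation = TRUE,
    surgery_type_site = "open_ovary",
    foreign_body_placement = TRUE,
    electrical_scalpel = TRUE,
    peritoneal_closing = TRUE
  )
}

# write a delimited cohort fixture; `rows` is a list of named lists
write_cohort_csv <- function(rows, cols, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(rows, function(r) {
    vals <- lapply(cols, function(c) if (is.null(r[[c]])) "" else r[[c]])
    names(vals) <- cols
    as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

all_absent_preop_row <- function(id) {
  list(
    patient_id = id, previous_surgery_count = "0",
    history_postsurgical_adhesions = "false",
    concomitant_inflammation_or_infection = "false",
    endometriosis = "absent", cancer = "absent", radiation = "absent",
    keloid_scarring = "false", prior_intraperitoneal_bleeding = "false",
    prior_postoperative_complications = "false",
    prior_postoperative_infection = "false"
  )
}

preop_cols <- function() {
  c("patient_id", "previous_surgery_count",
    "history_postsurgical_adhesions",
    "concomitant_inflammation_or_infection", "endometriosis", "cancer",
    "radiation", "keloid_scarring", "prior_intraperitoneal_bleeding",
    "prior_postoperative_complications", "prior_postoperative_infection")
}
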