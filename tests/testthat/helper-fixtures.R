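# Small in-code fixtures used across test files.

tiny_trial_table <- function() {
  data.frame(
    study_id = c("A", "A", "B", "B"),
    n_obs = c(4L, 4L, 6L, 6L),
    stage = "lactating",
    forage_prop = c(60, 60, 75, 75),
    dmi = c(18, 20, 15, 17),
    fa = c(25, 30, 20, 22),
    ee = c(31.3, 37.5, 25, 27.5),
    ndf = c(380, 360, 450, 430),
    ch4_mj = c(21, 23, 18, 20),
    technique = c("tracer", "tracer", "chamber", "chamber"),
    subset = "development",
    stringsAsFactors = FALSE
  )
}

packaged_fixture_path <- function() {
  system.file("extdata", "synthetic_feeding_trials.csv", package = "metanor")
}
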