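# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a two-binary-attribute toy schema for hand-checkable cases
toy_schema <- function() {
  dce_schema(
    attribute = c("a", "b"),
    levels = list(c("a1", "a2"), c("b1", "b2")),
    coding = c("categorical", "categorical")
  )
}

# the study design, built with a modest search budget
study_design <- function() {
  fixture("study_design", function()
    build_paired_design(job_schema(), n_tasks = 24, n_blocks = 3, seed = 1,
                        n_iter = 1500))
}

# homogeneous-preference simulated study at full size
clogit_sim <- function() {
  fixture("clogit_sim", function()
    simulate_study(dgp_preset("clogit"), n_respondents = 352,
                   design = study_design(), seed = 1))
}

# small homogeneous study for cheap structural tests
small_sim <- function() {
  fixture("small_sim", function()
    simulate_study(dgp_preset("clogit"), n_respondents = 40,
                   design = study_design(), seed = 2))
}

encode_pairs <- function(data, schema = job_schema()) {
  ruraldce:::encode_pair_differences(data, schema)
}

lcm_published_coefs_for_test <- function() {
  reference_lcm()$coefficients["class_1"]
}
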