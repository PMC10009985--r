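test_that("an empty interaction spec reduces to the plain fit", {
  sim <- small_sim()
  s <- job_schema()
  f0 <- fit_clogit(sim$data, s)
  f1 <- fit_interactions(sim$data, s, tibble::tibble(coefficient = character(),
                                                     covariate = character()))
  expect_equal(coef(f1), coef(f0))
})

test_that("a young-by-service shift in the DGP is detected", {
  dgp <- dgp_preset("clogit")
  dgp$interactions <- tibble::tibble(coefficient = "serve_oneyear",
                                     covariate = "young", shift = 0.5)
  sim <- simulate_study(dgp, 2000, design = study_design(), seed = 51)
  fit <- fit_interactions(sim$data, job_schema(),
                          tibble::tibble(coefficient = "serve_oneyear",
                                         covariate = "young"))
  expect_true(fit$converged)
  term <- "serve_oneyear:young"
  est <- coef(fit)[[term]]
  se <- fit$se[[term]]
  expect_lt(abs(est - 0.5), 3 * se)
  expect_gt(abs(est / se), 1.96)
})

test_that("absent sex effects test as null at roughly the nominal rate", {
  # no sex effect in the DGP: the male interaction should rarely reject
  rejections <- purrr::map_lgl(1:8, function(i) {
    sim <- simulate_study(dgp_preset("clogit"), 150, design = study_design(),
                          seed = 60 + i)
    fit <- fit_interactions(sim$data, job_schema(),
                            tibble::tibble(coefficient = "drug_adequate",
                                           covariate = "male"))
    term <- "drug_adequate:male"
    abs(coef(fit)[[term]] / fit$se[[term]]) > 1.96
  })
  expect_lte(sum(rejections), 2) # ~5% type-I error across 8 replicates
})

test_that("missing or incomplete covariates and collinearity are errors", {
  sim <- small_sim()
  s <- job_schema()
  spec <- tibble::tibble(coefficient = "serve_oneyear", covariate = "young")
  no_cov <- dplyr::select(sim$data, -age, -sex)
  expect_error(fit_interactions(no_cov, s, spec), "covariate")
  na_cov <- sim$data
  na_cov$age[1] <- NA
  expect_error(fit_interactions(na_cov, s, spec), "complete")
  # duplicating an interaction makes it collinear
  spec2 <- dplyr::bind_rows(spec, spec)
  expect_error(fit_interactions(sim$data, s, spec2), "collinear")
  expect_error(fit_interactions(sim$data, s,
                                tibble::tibble(coefficient = "nope",
                                               covariate = "young")),
               "encoded")
})
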