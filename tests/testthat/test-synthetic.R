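test_that("degenerate mixed DGP collapses to the mean vector", {
  m <- dgp_preset("clogit")$mean
  dgp <- dce_dgp("mixl", mean = m,
                 sd = setNames(rep(0, 6), names(m)))
  prefs <- draw_preferences(dgp, 25, seed = 1)
  for (nm in names(m)) expect_equal(prefs[[nm]], rep(unname(m[nm]), 25))
})

test_that("latent-class membership frequencies match the class shares", {
  prefs <- draw_preferences(dgp_preset("latent_class"), 100000, seed = 1)
  freq <- unname(table(prefs$class)) / 100000
  truth <- c(0.298, 0.417, 0.285)
  # binomial error: 3 * sqrt(p(1-p)/n) < 0.005 for each share
  expect_true(all(abs(as.numeric(freq) - truth) <
                    3 * sqrt(truth * (1 - truth) / 100000)))
})

test_that("mixed-DGP coefficient draws have the specified moments", {
  prefs <- draw_preferences(dgp_preset("mixl"), 100000, seed = 2)
  x <- prefs$house_superior
  expect_lt(abs(mean(x) - 0.28), 3 * 0.65 / sqrt(100000))
  expect_lt(abs(sd(x) - 0.65), 0.01)
  # salary is fixed in this preset
  expect_equal(unique(prefs$salary), 0.0002371)
})

test_that("covariates match the reference sample margins", {
  cov <- make_covariates(100000, seed = 3)
  expect_lt(abs(mean(cov$sex == "male") - 0.75),
            3 * sqrt(0.75 * 0.25 / 100000))
  expect_lt(abs(mean(cov$age) - 24), 0.05)
  expect_true(all(cov$age >= 21 & cov$age <= 28))
})

test_that("choices are driven by utility differences as logistic choice", {
  s <- job_schema()
  des <- study_design()
  asg <- assign_blocks(des, 400, 2, seed = 4)
  # beta = 0: alternative A chosen half the time
  zero <- dce_dgp("clogit",
                  mean = setNames(rep(0, 6), coef_names(s)))
  prefs <- draw_preferences(zero, 400, seed = 4)
  data <- simulate_choices(des, asg, prefs, s, seed = 4)
  pA <- mean(data$chosen[data$alternative == "A"])
  expect_lt(abs(pA - 0.5), 3 * sqrt(0.25 / 6400))
  # dominant salary preference: higher-salary alternative nearly always wins
  rich <- dce_dgp("clogit",
                  mean = setNames(c(0.01, 0, 0, 0, 0, 0), coef_names(s)))
  prefs2 <- draw_preferences(rich, 400, seed = 5)
  data2 <- simulate_choices(des, asg, prefs2, s, seed = 5)
  enc <- encode_pairs(data2)
  diff_salary <- enc$D[, "salary"]
  won <- ifelse(enc$y == 1, diff_salary > 0, diff_salary < 0)
  expect_gt(mean(won[diff_salary != 0]), 0.95)
})

test_that("a fixed utility difference yields its logistic choice frequency", {
  # single task, utility difference 0.5368: P(A) = plogis(0.5368) = 0.6311
  s <- toy_schema()
  des <- tibble::tibble(task_id = c(1L, 1L), block = 1L, alt = c("A", "B"),
                        a = c("a2", "a1"), b = c("b1", "b1"))
  class(des) <- c("dce_design", class(des))
  attr(des, "n_blocks") <- 1L
  asg <- assign_blocks(des, 100000, 1, seed = 6)
  prefs <- draw_preferences(
    dce_dgp("clogit", mean = c(a_a2 = 0.5368, b_b2 = 0)), 100000, seed = 6)
  data <- simulate_choices(des, asg, prefs, s, seed = 6)
  pA <- mean(data$chosen[data$alternative == "A"])
  expect_lt(abs(pA - 0.6311), 3 * sqrt(0.6311 * 0.3689 / 100000) + 1e-4)
})

test_that("simulation is reproducible from the seed", {
  sim1 <- simulate_study(dgp_preset("clogit"), 30, design = study_design(),
                         seed = 9)
  sim2 <- simulate_study(dgp_preset("clogit"), 30, design = study_design(),
                         seed = 9)
  expect_identical(as.data.frame(sim1$data), as.data.frame(sim2$data))
  sim3 <- simulate_study(dgp_preset("clogit"), 30, design = study_design(),
                         seed = 10)
  expect_false(identical(as.data.frame(sim1$data), as.data.frame(sim3$data)))
})

test_that("interaction DGP shifts the targeted coefficient for the dummy", {
  dgp <- dgp_preset("clogit")
  dgp$interactions <- tibble::tibble(coefficient = "serve_oneyear",
                                     covariate = "young", shift = 0.5)
  cov <- make_covariates(500, seed = 7)
  prefs <- draw_preferences(dgp, 500, covariates = cov, seed = 7)
  young <- cov$age <= 24
  expect_equal(unique(prefs$serve_oneyear[young]), 0.47 + 0.5)
  expect_equal(unique(prefs$serve_oneyear[!young]), 0.47)
})
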