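test_that("log-likelihood at beta = 0 is N log(1/2)", {
  sim <- clogit_sim()
  enc <- encode_pairs(sim$data)
  ll <- clogit_loglik(rep(0, 6), enc$D, enc$y)$loglik
  expect_equal(ll, 5632 * log(0.5), tolerance = 1e-10)
  expect_equal(round(ll, 2), -3903.80)
})

test_that("a dominant utility difference drives task likelihood to zero", {
  D <- matrix(1, 1, 1)
  expect_gt(clogit_loglik(500, D, 1)$loglik, -1e-10)
  expect_error(clogit_loglik(Inf, D, 1), "finite")
})

test_that("analytic gradient matches finite differences", {
  sim <- small_sim()
  enc <- encode_pairs(sim$data)
  set.seed(11)
  # scale the salary direction so finite differences are well-conditioned
  scal <- c(1e-4, rep(1, 5))
  beta <- rnorm(6) * scal
  g <- clogit_loglik(beta, enc$D, enc$y)$gradient
  f <- function(b) clogit_loglik(b, enc$D, enc$y)$loglik
  gn <- vapply(1:6, function(j) {
    h <- 1e-6 * scal[j]
    up <- beta; up[j] <- up[j] + h
    dn <- beta; dn[j] <- dn[j] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), gn, tolerance = 1e-6)
})

test_that("choice probabilities within a task sum to one", {
  sim <- small_sim()
  enc <- encode_pairs(sim$data)
  beta <- coef(fit_clogit(sim$data, job_schema()))
  eta <- drop(enc$D %*% beta)
  expect_equal(plogis(eta) + plogis(-eta), rep(1, length(eta)))
})

test_that("the fit recovers the homogeneous DGP within 3 SE", {
  sim <- clogit_sim()
  fit <- fit_clogit(sim$data, job_schema())
  expect_true(fit$converged)
  truth <- dgp_preset("clogit")$mean
  z <- abs((coef(fit) - truth) / fit$se)
  expect_true(all(z < 3))
  # covariance symmetric PSD, SEs = sqrt diagonal
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
  expect_equal(fit$se, sqrt(diag(fit$vcov)))
})

test_that("attribute-independent choices give near-zero coefficients", {
  s <- job_schema()
  des <- study_design()
  asg <- assign_blocks(des, 150, 2, seed = 21)
  zero <- dce_dgp("clogit", mean = setNames(rep(0, 6), coef_names(s)))
  prefs <- draw_preferences(zero, 150, seed = 21)
  data <- simulate_choices(des, asg, prefs, s, seed = 21)
  fit <- fit_clogit(data, s)
  z <- abs(coef(fit) / fit$se)
  expect_true(all(z < 4))
  expect_lt(abs(fit$loglik - 2400 * log(0.5)), 3 * sqrt(2400) * 0.5)
})

test_that("perfect separation is flagged, not raised", {
  # toy data where one attribute decides every choice
  s <- toy_schema()
  data <- tibble::tibble(
    respondent_id = rep(1:20, each = 2),
    task_id = rep(1:20, each = 2),
    alternative = rep(c("A", "B"), 20),
    chosen = rep(c(1L, 0L), 20),
    a = rep(c("a2", "a1"), 20),
    b = rep(c("b1", "b2", "b2", "b1"), 10))
  fit <- fit_clogit(data, s)
  expect_false(fit$converged)
})

test_that("scale invariance: rescaling salary rescales its coefficient", {
  sim <- small_sim()
  s <- job_schema()
  fit1 <- fit_clogit(sim$data, s)
  # same schema with salary measured in thousands of ETB
  s2 <- s
  s2$values[[1]] <- s$values[[1]] / 1000
  fit2 <- fit_clogit(sim$data, s2)
  expect_equal(coef(fit2)[["salary"]], coef(fit1)[["salary"]] * 1000,
               tolerance = 1e-6)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
})

test_that("estimates agree with an independent conditional-logit fit", {
  skip_if_not_installed("survival")
  library(survival)
  sim <- small_sim()
  s <- job_schema()
  fit <- fit_clogit(sim$data, s)
  long <- dplyr::arrange(sim$data, respondent_id, task_id, alternative)
  df <- data.frame(as.matrix(encode_profiles(long, s)),
                   chosen = long$chosen,
                   grp = paste(long$respondent_id, long$task_id))
  ref <- survival::clogit(
    chosen ~ salary + house_superior + drug_adequate + serve_oneyear +
      management_support + workload_normal + survival::strata(grp),
    data = df)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(round(unname(coef(fit))[-1], 4),
               round(unname(coef(ref))[-1], 4))
})
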