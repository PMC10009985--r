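test_that("WTA ratios match hand-computed values from the reference fit", {
  w <- wta(reference_mixl())
  est <- setNames(w$estimate, w$coefficient)
  expect_equal(est[["drug_adequate"]], 1.01 / 0.0002371, tolerance = 1e-10)
  expect_equal(round(est[["drug_adequate"]], 1), 4259.8)
  expect_equal(round(est[["workload_normal"]], 1), 1897.9)
})

test_that("WTA edge cases: zero numerator, vanishing denominator", {
  b <- c(salary = 0.5, house_superior = 0)
  expect_equal(wta(b)$estimate, 0)
  expect_error(wta(c(salary = 0, house_superior = 1)), "unstable")
  expect_error(wta(c(house_superior = 1)), "salary")
})

test_that("WTA is invariant to rescaling all utilities", {
  b <- reference_mixl()$coefficients
  expect_equal(wta(b)$estimate, wta(b * 3.7)$estimate)
})

test_that("delta interval matches the closed-form ratio variance", {
  # uncorrelated toy covariance: Var(a/s) = (Vaa + g^2 Vss)/s^2
  fit <- structure(list(
    coefficients = c(salary = 0.002, house_superior = 1)),
    class = "dce_toyfit")
  V <- diag(c(1e-8, 0.04))
  dimnames(V) <- list(names(fit$coefficients), names(fit$coefficients))
  fit$vcov <- V
  g <- 1 / 0.002
  v_hand <- (0.04 + g^2 * 1e-8) / 0.002^2
  ci <- wta_interval(fit, method = "delta")
  expect_equal(ci$estimate, g)
  expect_equal(ci$conf.high - ci$estimate, qnorm(0.975) * sqrt(v_hand),
               tolerance = 1e-10)
})

test_that("Krinsky-Robb converges to the delta interval when near-linear", {
  # tiny relative uncertainty: ratio is effectively linear in the draws
  fit <- structure(list(
    coefficients = c(salary = 0.002, house_superior = 1)),
    class = "dce_toyfit")
  V <- diag(c(1e-14, 1e-6))
  dimnames(V) <- list(names(fit$coefficients), names(fit$coefficients))
  fit$vcov <- V
  d <- wta_interval(fit, method = "delta")
  k <- wta_interval(fit, method = "krinsky_robb", n_draws = 200000, seed = 1)
  expect_equal(k$conf.low, d$conf.low, tolerance = 0.02)
  expect_equal(k$conf.high, d$conf.high, tolerance = 0.02)
})

test_that("wider coverage gives strictly wider intervals", {
  fit <- reference_mixl()
  i95 <- wta_interval(fit, level = 0.95, seed = 2)
  i99 <- wta_interval(fit, level = 0.99, seed = 2)
  expect_true(all(i99$conf.low < i95$conf.low))
  expect_true(all(i99$conf.high > i95$conf.high))
  expect_true(all(i95$conf.low <= i95$estimate &
                    i95$estimate <= i95$conf.high))
})

test_that("relative importance reproduces the published class pattern", {
  ri <- relative_importance(reference_lcm(), job_schema())
  c3 <- dplyr::filter(ri, class == "class_3")
  expect_equal(c3$range[c3$attribute == "salary"], 0.0006824 * 6792,
               tolerance = 1e-10)
  expect_equal(c3$score[c3$attribute == "management"], 0.179,
               tolerance = 1e-2)
  # salary most important in classes 1 and 3; per-class max score is 1
  for (cl in c("class_1", "class_3")) {
    sub <- dplyr::filter(ri, class == cl)
    expect_equal(sub$attribute[which.max(sub$score)], "salary")
  }
  per_class <- dplyr::filter(ri, class != "pooled")
  tops <- dplyr::summarise(dplyr::group_by(per_class, class),
                           top = max(score), n_top = sum(score == 1))
  expect_true(all(tops$top == 1))
  expect_true(all(tops$n_top == 1))
  expect_true(all(ri$score >= 0 & ri$score <= 1))
})

test_that("pooled scores equal the class scores when one share is 1", {
  fit <- list(coefficients = lcm_published_coefs_for_test(),
              shares = c(class_1 = 1))
  ri <- relative_importance(fit, job_schema())
  pooled <- dplyr::filter(ri, class == "pooled")$score
  single <- dplyr::filter(ri, class == "class_1")$score
  expect_equal(pooled, single)
})

test_that("single-attribute toy model scores 1 for that attribute", {
  s <- dce_schema("a", list(c("a1", "a2")), "categorical")
  fit <- list(coefficients = list(class_1 = c(a_a2 = 0.4)),
              shares = c(class_1 = 1))
  ri <- relative_importance(fit, s)
  expect_equal(ri$score, c(1, 1))
})

test_that("uptake changes reproduce the published prediction table", {
  fit <- reference_mixl()
  s <- job_schema()
  expect_equal(uptake_change(fit, s, "salary", "11320")$estimate, 26.21,
               tolerance = 1e-3)
  expect_equal(uptake_change(fit, s, "salary", "15848")$estimate, 66.69,
               tolerance = 1e-3)
  expect_equal(uptake_change(fit, s, "salary", "9056")$estimate, 0)
  expect_error(uptake_change(fit, s, "salary", "superior"), "belong")
})

test_that("uptake change is antisymmetric and increasing in utility", {
  fit <- reference_mixl()
  s <- job_schema()
  up <- uptake_change(fit, s, "workload", "normal")$estimate
  down <- uptake_change(fit, s, "workload", "heavy",
                        base_level = "normal")$estimate
  p <- plogis(0.45)
  expect_equal(up, 100 * (p - 0.5) / 0.5)
  expect_equal(down, 100 * ((1 - p) - 0.5) / 0.5)
  expect_equal(up, -down)
  tab <- uptake_table(fit, s)
  sal <- dplyr::filter(tab, attribute == "salary")
  expect_true(all(diff(sal$estimate) > 0))
})

test_that("uptake intervals cover the point and shrink with the variance", {
  fit <- reference_mixl()
  s <- job_schema()
  ki <- uptake_interval(fit, s, "housing", "superior", seed = 3)
  expect_true(ki$conf.low <= ki$estimate & ki$estimate <= ki$conf.high)
  tiny <- fit
  tiny$vcov <- fit$vcov * 1e-12
  ti <- uptake_interval(tiny, s, "housing", "superior", seed = 3)
  expect_lt(ti$conf.high - ti$conf.low, 0.01)
  expect_equal(ti$conf.low, ti$estimate, tolerance = 1e-3)
})

test_that("Krinsky-Robb uptake interval matches a brute-force oracle", {
  # one-parameter model: draws of beta ~ N(0.5, 0.1^2)
  s <- dce_schema("a", list(c("a1", "a2")), "categorical")
  fit <- structure(list(coefficients = c(a_a2 = 0.5),
                        vcov = matrix(0.01, 1, 1,
                                      dimnames = list("a_a2", "a_a2"))),
                   class = "dce_toyfit")
  ki <- uptake_interval(fit, s, "a", "a2", n_draws = 100000, seed = 4)
  set.seed(77)
  bb <- rnorm(100000, 0.5, 0.1)
  dd <- 100 * (plogis(bb) - 0.5) / 0.5
  oracle <- unname(quantile(dd, c(0.025, 0.975)))
  expect_equal(ki$conf.low, oracle[1], tolerance = 0.01)
  expect_equal(ki$conf.high, oracle[2], tolerance = 0.01)
})
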