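test_that("zero-SD mixing collapses to the conditional logit likelihood", {
  sim <- small_sim()
  enc <- encode_pairs(sim$data)
  cn <- coef_names(job_schema())
  rand <- setdiff(cn, "salary")
  draws <- ruraldce:::halton_normal_draws(40, 25, 5)
  m <- dgp_preset("clogit")$mean
  ll_mix <- mixl_loglik(m, setNames(rep(0, 5), rand), enc$D, enc$y,
                        enc$respondent, draws)$loglik
  ll_c <- clogit_loglik(m, enc$D, enc$y)$loglik
  expect_equal(ll_mix, ll_c, tolerance = 1e-10)
})

test_that("simulated likelihood agrees with brute-force Monte Carlo", {
  # 5-respondent toy panel, Halton R = 2000 vs pseudo-random R = 200000
  s <- job_schema()
  des <- study_design()
  asg <- assign_blocks(des, 5, 2, seed = 31)
  dgp <- dgp_preset("mixl")
  prefs <- draw_preferences(dgp, 5, seed = 31)
  data <- simulate_choices(des, asg, prefs, s, seed = 31)
  enc <- encode_pairs(data)
  rand <- setdiff(coef_names(s), "salary")
  sd <- dgp$sd[rand]
  halton_ll <- mixl_loglik(dgp$mean, sd, enc$D, enc$y, enc$respondent,
                           ruraldce:::halton_normal_draws(5, 2000, 5))$loglik
  # independent oracle: plain pseudo-random normal draws, direct averaging
  set.seed(99)
  R <- 200000
  s_sign <- ifelse(enc$y == 1, 1, -1)
  Ds <- enc$D * s_sign
  base <- drop(Ds %*% dgp$mean)
  Dr <- Ds[, rand]
  ll_mc <- 0
  for (i in 1:5) {
    rows <- enc$respondent == i
    Z <- matrix(rnorm(R * 5), R, 5)
    eta <- matrix(base[rows], sum(rows), R) +
      Dr[rows, ] %*% t(Z %*% diag(sd))
    ll_mc <- ll_mc + log(mean(exp(colSums(log(plogis(eta))))))
  }
  expect_equal(halton_ll, ll_mc, tolerance = 0.01)
})

test_that("likelihood is largest near the generating parameters", {
  sim <- clogit_sim() # homogeneous data, reuse as a large fixture
  enc <- encode_pairs(sim$data)
  cn <- coef_names(job_schema())
  rand <- setdiff(cn, "salary")
  draws <- ruraldce:::halton_normal_draws(352, 50, 5)
  truth <- dgp_preset("clogit")$mean
  sd0 <- setNames(rep(0.05, 5), rand)
  ll_true <- mixl_loglik(truth, sd0, enc$D, enc$y, enc$respondent,
                         draws)$loglik
  worse <- truth * 2
  ll_off <- mixl_loglik(worse, sd0, enc$D, enc$y, enc$respondent,
                        draws)$loglik
  expect_gt(ll_true, ll_off)
})

test_that("doubling the draw count barely moves the likelihood", {
  sim <- small_sim()
  enc <- encode_pairs(sim$data)
  rand <- setdiff(coef_names(job_schema()), "salary")
  m <- dgp_preset("mixl")$mean
  sd <- dgp_preset("mixl")$sd[rand]
  ll1 <- mixl_loglik(m, sd, enc$D, enc$y, enc$respondent,
                     ruraldce:::halton_normal_draws(40, 250, 5))$loglik
  ll2 <- mixl_loglik(m, sd, enc$D, enc$y, enc$respondent,
                     ruraldce:::halton_normal_draws(40, 500, 5))$loglik
  expect_lt(abs(ll1 - ll2), 0.05 * abs(ll1) / sqrt(250))
})

test_that("draw count must be positive and shapes consistent", {
  enc <- encode_pairs(small_sim()$data)
  rand <- setdiff(coef_names(job_schema()), "salary")
  m <- dgp_preset("mixl")$mean
  expect_error(mixl_loglik(m, m[rand], enc$D, enc$y, enc$respondent,
                           array(0, c(40, 0, 5))), "draw")
  expect_error(mixl_loglik(m, m[rand], enc$D, enc$y, enc$respondent,
                           array(0, c(3, 10, 5))), "slice")
})
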