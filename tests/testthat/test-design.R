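test_that("the study design has 24 tasks, 48 profiles, 3 blocks of 8", {
  des <- study_design()
  expect_equal(length(unique(des$task_id)), 24)
  expect_equal(nrow(des), 48)
  blocks <- dplyr::distinct(tibble::as_tibble(des), task_id, block)
  expect_equal(sort(unique(blocks$block)), 1:3)
  expect_equal(unname(table(blocks$block)), rep(8L, 3), ignore_attr = TRUE)
  # blocks partition the tasks
  expect_equal(sort(blocks$task_id), 1:24)
  # no task pairs a profile with itself
  attrs <- job_schema()$attribute
  A <- des[des$alt == "A", attrs]
  B <- des[des$alt == "B", attrs]
  expect_true(all(rowSums(as.matrix(A) != as.matrix(B)) > 0))
})

test_that("design construction is deterministic in the seed", {
  d1 <- build_paired_design(job_schema(), seed = 7, n_iter = 300)
  d2 <- build_paired_design(job_schema(), seed = 7, n_iter = 300)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- build_paired_design(job_schema(), seed = 8, n_iter = 300)
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("search penalty is non-increasing and level balance is tight", {
  des <- study_design()
  trace <- attr(des, "penalty_trace")
  expect_true(all(diff(trace) <= 1e-12))
  # each 2-level attribute's level counts differ by at most 2 over 48 profiles
  lb <- attr(des, "diagnostics")$level_balance
  binary <- dplyr::filter(lb, attribute != "salary")
  spread <- dplyr::summarise(dplyr::group_by(binary, attribute),
                             d = max(n) - min(n))
  expect_true(all(spread$d <= 2))
  expect_equal(sum(lb$n[lb$attribute == "salary"]), 48)
})

test_that("zero prior makes every task utility-balanced at exactly 1/2", {
  des <- study_design()
  ub <- attr(des, "diagnostics")$utility_balance
  expect_equal(ub$p_A, rep(0.5, 24))
  expect_true(all(ub$p_A > 0 & ub$p_A < 1))
})

test_that("infeasible task counts are rejected", {
  expect_error(build_paired_design(toy_schema(), n_tasks = 10, n_blocks = 1,
                                   seed = 1, n_iter = 10),
               "distinct profile pairs")
  expect_error(build_paired_design(job_schema(), n_tasks = 24, n_blocks = 5),
               "divisible")
  expect_error(build_paired_design(job_schema(), prior = c(1, 2)), "length")
})

test_that("diagnostics of a constructed toy design match hand computation", {
  # two tasks over the 2x2 factorial: (a1b1 vs a2b2), (a1b2 vs a2b1)
  s <- toy_schema()
  des <- tibble::tibble(
    task_id = c(1L, 1L, 2L, 2L),
    block = 1L,
    alt = c("A", "B", "A", "B"),
    a = c("a1", "a2", "a1", "a2"),
    b = c("b1", "b2", "b2", "b1"))
  d <- diagnose_design(des, s, prior = c(1, 1))
  # every level appears twice among the 4 profiles
  expect_equal(d$level_balance$n, rep(2L, 4))
  # encoded columns: a2 = (0,1,0,1), b2 = (0,1,1,0) -> correlation 0
  expect_equal(d$orthogonality$max_abs_cor, 0)
  # no attribute repeats within a task
  expect_equal(d$overlap$n_same, c(0, 0))
  expect_equal(attr(d$overlap, "mean"), 0)
  # utilities: task 1 dU = -2 -> plogis(-2); task 2 dU = 0 -> 0.5
  expect_equal(d$utility_balance$p_A, c(plogis(-2), 0.5))
  expect_equal(attr(d$utility_balance, "max_dev"), 0.5 - plogis(-2))
})

test_that("design pairing identical profiles on all but one attribute", {
  s <- job_schema()
  prof <- tibble::tibble(salary = "9056", housing = "basic",
                         drug_supply = "inadequate",
                         service_years = "two_years",
                         management = "unsupportive", workload = "heavy")
  alt <- dplyr::mutate(prof, workload = "normal")
  des <- dplyr::bind_cols(
    tibble::tibble(task_id = c(1L, 1L), block = 1L, alt = c("A", "B")),
    dplyr::bind_rows(prof, alt))
  d <- diagnose_design(des, s)
  expect_equal(d$overlap$n_same, 5)
})

test_that("block assignment gives each respondent 16 tasks, pairs uniform", {
  des <- study_design()
  asg <- assign_blocks(des, n_respondents = 352, blocks_per_respondent = 2,
                       seed = 1)
  tasks <- respondent_tasks(des, asg)
  per <- dplyr::count(dplyr::distinct(tasks, respondent_id, task_id),
                      respondent_id)
  expect_equal(unique(per$n), 16)
  # all blocks -> all 24 tasks
  asg_all <- assign_blocks(des, 10, blocks_per_respondent = 3, seed = 1)
  tasks_all <- respondent_tasks(des, asg_all)
  expect_equal(dplyr::n_distinct(tasks_all$task_id[
    tasks_all$respondent_id == 1]), 24)
  expect_error(assign_blocks(des, 10, blocks_per_respondent = 4), "exceed")
  # the three unordered block pairs are equally likely
  big <- assign_blocks(des, 10000, 2, seed = 3)
  pairs <- dplyr::summarise(dplyr::group_by(big, respondent_id),
                            key = paste(sort(block), collapse = "-"),
                            .groups = "drop")
  counts <- table(pairs$key)
  expect_equal(length(counts), 3)
  chi <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(chi$p.value, 0.001)
})
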