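# Long-format choice data: one row per respondent x task x alternative.
# This is the single input format all estimators consume.

choice_id_cols <- c("respondent_id", "task_id", "alternative", "chosen")

#' Validate a long-format choice dataset
#'
#' Checks the structural invariants every estimator relies on: each
#' (respondent, task) group has exactly two alternatives with exactly one
#' chosen; attribute levels belong to the schema; covariates, when present,
#' are complete and ages fall in the configured range.
#'
#' @param data A tibble with columns `respondent_id`, `task_id`,
#'   `alternative`, `chosen` (0/1), one column per schema attribute, and
#'   optionally `age` and `sex`.
#' @param schema A [dce_schema].
#' @param age_range Plausible integer age support used for a range warning
#'   (default `c(21, 28)`, the study's young/adult grouping support).
#' @return A tibble of violations with columns `rule`, `where`, `message`
#'   and `severity` (`"error"` or `"warning"`); zero rows iff the dataset is
#'   valid.
#' @export
validate_choices <- function(data, schema, age_range = c(21, 28)) {
  v <- list()
  add <- function(rule, where, message, severity = "error") {
    tibble::tibble(rule = rule, where = where, message = message,
                   severity = severity)
  }
  need <- c(choice_id_cols, schema$attribute)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    return(add("columns", paste(missing_cols, collapse = ","),
               paste("missing column(s):", paste(missing_cols, collapse = ", "))))
  }
  grp <- dplyr::summarise(
    dplyr::group_by(data, .data$respondent_id, .data$task_id),
    n_alt = dplyr::n(), n_chosen = sum(.data$chosen), .groups = "drop")
  bad_alt <- dplyr::filter(grp, .data$n_alt != 2L)
  if (nrow(bad_alt))
    v <- c(v, purrr::pmap(bad_alt, function(respondent_id, task_id, n_alt, n_chosen)
      add("two_alternatives",
          sprintf("respondent %s task %s", respondent_id, task_id),
          sprintf("task has %d alternative(s), expected 2", n_alt))))
  bad_ch <- dplyr::filter(grp, .data$n_alt == 2L, .data$n_chosen != 1)
  if (nrow(bad_ch))
    v <- c(v, purrr::pmap(bad_ch, function(respondent_id, task_id, n_alt, n_chosen)
      add("one_chosen",
          sprintf("respondent %s task %s", respondent_id, task_id),
          sprintf("task has %d chosen alternative(s), expected exactly 1",
                  n_chosen))))
  for (i in seq_len(nrow(schema))) {
    at <- schema$attribute[i]
    bad <- which(!as.character(data[[at]]) %in% schema$levels[[i]])
    if (length(bad))
      v <- c(v, list(add("known_level", sprintf("row %d", bad[1]),
                         sprintf("attribute '%s' has %d row(s) with unknown levels (first: '%s')",
                                 at, length(bad), data[[at]][bad[1]]))))
  }
  if ("age" %in% names(data)) {
    if (anyNA(data$age))
      v <- c(v, list(add("covariate_complete", "age",
                         "missing age for some respondents", "warning")))
    out_of_range <- stats::na.omit(unique(
      data$respondent_id[data$age < age_range[1] | data$age > age_range[2]]))
    if (length(out_of_range))
      v <- c(v, list(add("age_range", paste(head(out_of_range, 3), collapse = ","),
                         sprintf("%d respondent(s) with age outside [%d, %d]",
                                 length(out_of_range), age_range[1], age_range[2]),
                         "warning")))
  }
  if ("sex" %in% names(data)) {
    bad <- which(!is.na(data$sex) & !data$sex %in% c("male", "female"))
    if (length(bad))
      v <- c(v, list(add("sex_levels", sprintf("row %d", bad[1]),
                         "sex must be 'male' or 'female'")))
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(rule = character(), where = character(),
                   message = character(), severity = character())
}

#' Observation counts of a choice dataset
#'
#' One observation is one (respondent, task) pair: a dataset of 352
#' respondents each answering 16 paired tasks has 5,632 observations
#' (11,264 rows).
#'
#' @param data A long-format choice dataset.
#' @return A one-row tibble: `n_respondents`, `n_tasks_per_respondent`
#'   (modal value), `n_observations`, `n_rows`.
#' @export
n_observations <- function(data) {
  per <- dplyr::summarise(dplyr::group_by(data, .data$respondent_id),
                          n_tasks = dplyr::n_distinct(.data$task_id),
                          .groups = "drop")
  tibble::tibble(
    n_respondents = nrow(per),
    n_tasks_per_respondent = as.integer(names(sort(table(per$n_tasks),
                                                   decreasing = TRUE))[1]),
    n_observations = sum(per$n_tasks),
    n_rows = nrow(data)
  )
}

#' Read / write long-format choice data as CSV
#'
#' Comma-separated UTF-8 with header; columns `respondent_id`, `task_id`,
#' `alternative`, `chosen`, one column per attribute, and optional `age`,
#' `sex`. Reading validates against the schema and errors on structural
#' violations (warnings are reported as warnings).
#'
#' @param data A choice dataset tibble.
#' @param path File path.
#' @param schema A [dce_schema] used for validation on read.
#' @return `write_choice_csv` returns `path` invisibly; `read_choice_csv`
#'   returns the validated tibble.
#' @export
write_choice_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_choice_csv
#' @export
read_choice_csv <- function(path, schema) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            respondent_id = "i", task_id = "i",
                            alternative = "c", chosen = "i",
                            age = "i", sex = "c", .default = "c"))
  rep <- validate_choices(data, schema)
  errs <- dplyr::filter(rep, .data$severity == "error")
  if (nrow(errs))
    abort(paste0("invalid choice data: ", errs$message[1],
                 " (", errs$where[1], ")",
                 if (nrow(errs) > 1) sprintf(" and %d more", nrow(errs) - 1)))
  wrns <- dplyr::filter(rep, .data$severity == "warning")
  if (nrow(wrns)) warn(paste(wrns$message, collapse = "; "))
  data
}

# Encoded per-task difference matrix: x_A - x_B per task, response 1 if A
# chosen; the sufficient representation for two-alternative conditional
# logit. Rows ordered by (respondent, task).
encode_pair_differences <- function(data, schema, extra_cols = NULL) {
  rep <- validate_choices(data, schema)
  errs <- rep[rep$severity == "error", ]
  if (nrow(errs)) abort(paste0("invalid choice data: ", errs$message[1]))
  data <- dplyr::arrange(data, .data$respondent_id, .data$task_id,
                         .data$alternative)
  X <- as.matrix(encode_profiles(data, schema))
  if (!is.null(extra_cols)) X <- cbind(X, as.matrix(data[, extra_cols]))
  first <- seq(1L, nrow(data), by = 2L)
  D <- X[first, , drop = FALSE] - X[first + 1L, , drop = FALSE]
  y <- data$chosen[first]
  list(D = D, y = y,
       respondent = data$respondent_id[first],
       task = data$task_id[first])
}
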