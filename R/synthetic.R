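# Synthetic respondents under random utility theory: systematic utility x'b
# plus i.i.d. standard Gumbel noise, so paired choices are logistic in the
# utility difference. Three preference structures: homogeneous (clogit),
# independent-normal random coefficients (mixl), and a finite mixture of
# preference classes (latent_class).

#' Specify a data-generating process
#'
#' @param kind `"clogit"` (every respondent shares `mean`), `"mixl"`
#'   (respondent coefficients drawn independently normal with `mean` and
#'   `sd`) or `"latent_class"` (each respondent belongs to one latent class
#'   drawn from `class_shares`, with that class's coefficient vector).
#' @param mean Named coefficient vector (clogit, mixl).
#' @param sd Named non-negative vector of random-coefficient standard
#'   deviations (mixl); entries of 0 make a coefficient fixed.
#' @param class_coefficients List of named coefficient vectors, one per
#'   class (latent_class).
#' @param class_shares Positive class shares summing to 1 (latent_class).
#' @param interactions Optional tibble with columns `coefficient` (encoded
#'   column name), `covariate` (`"male"` or `"young"`) and `shift`: the
#'   named coefficient is shifted additively for respondents with that
#'   covariate equal to 1 (e.g. a stronger one-year-service preference for
#'   young respondents).
#' @return A list of class `dce_dgp`.
#' @seealso [dgp_preset()] for the reference-study presets.
#' @export
dce_dgp <- function(kind = c("clogit", "mixl", "latent_class"), mean = NULL,
                    sd = NULL, class_coefficients = NULL, class_shares = NULL,
                    interactions = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("clogit", "mixl")) {
    if (is.null(mean) || is.null(names(mean)))
      abort("'mean' must be a named coefficient vector")
    if (kind == "mixl") {
      if (is.null(sd)) sd <- setNames(rep(0, length(mean)), names(mean))
      sd <- sd[names(mean)]
      sd[is.na(sd)] <- 0
      names(sd) <- names(mean)
      if (any(sd < 0)) abort("sd entries must be >= 0")
    }
  } else {
    if (is.null(class_coefficients) || is.null(class_shares))
      abort("latent_class needs class_coefficients and class_shares")
    if (length(class_coefficients) != length(class_shares))
      abort("one coefficient vector per class share required")
    if (any(class_shares <= 0) || abs(sum(class_shares) - 1) > 1e-8)
      abort("class shares must be positive and sum to 1")
  }
  structure(list(kind = kind, mean = mean, sd = sd,
                 class_coefficients = class_coefficients,
                 class_shares = class_shares,
                 interactions = interactions),
            class = "dce_dgp")
}

#' Draw respondent-level preference coefficients
#'
#' @param dgp A [dce_dgp()].
#' @param n_respondents Number of respondents.
#' @param covariates Optional covariate table from [make_covariates()];
#'   required when the DGP has interaction shifts.
#' @param seed Integer seed.
#' @return A tibble with `respondent_id`, a `class` column for latent-class
#'   DGPs, and one column per coefficient.
#' @examples
#' draw_preferences(dgp_preset("latent_class"), 5, seed = 1)
#' @export
draw_preferences <- function(dgp, n_respondents, covariates = NULL, seed = 1) {
  withr_seed(seed, {
    if (dgp$kind == "latent_class") {
      cls <- sample.int(length(dgp$class_shares), n_respondents,
                        replace = TRUE, prob = dgp$class_shares)
      B <- do.call(rbind, dgp$class_coefficients)[cls, , drop = FALSE]
      out <- dplyr::bind_cols(
        tibble::tibble(respondent_id = seq_len(n_respondents), class = cls),
        tibble::as_tibble(B))
    } else {
      k <- length(dgp$mean)
      B <- matrix(rep(dgp$mean, each = n_respondents), n_respondents, k,
                  dimnames = list(NULL, names(dgp$mean)))
      if (dgp$kind == "mixl") {
        Z <- matrix(rnorm(n_respondents * k), n_respondents, k)
        B <- B + Z %*% diag(dgp$sd, k)
      }
      out <- dplyr::bind_cols(
        tibble::tibble(respondent_id = seq_len(n_respondents)),
        tibble::as_tibble(B))
    }
    if (!is.null(dgp$interactions)) {
      if (is.null(covariates))
        abort("interaction DGP requires a covariate table")
      cov <- dplyr::arrange(covariates, .data$respondent_id)
      dummies <- list(male = as.numeric(cov$sex == "male"),
                      young = as.numeric(cov$age <= 24))
      for (i in seq_len(nrow(dgp$interactions))) {
        co <- dgp$interactions$coefficient[i]
        dm <- dummies[[dgp$interactions$covariate[i]]]
        out[[co]] <- out[[co]] + dgp$interactions$shift[i] * dm
      }
    }
    out
  })
}

#' Draw respondent covariates
#'
#' Emulates the reference sample: sex Bernoulli with 75% male; integer age
#' with mean about 24 and standard deviation about 1.3, truncated to
#' 21-28 years.
#'
#' @param n_respondents Number of respondents.
#' @param seed Integer seed.
#' @param p_male Probability of male (default 0.75).
#' @param age_mean,age_sd Latent normal age parameters before rounding and
#'   truncation (defaults 24 and 1.3).
#' @param age_range Integer truncation bounds (default 21-28).
#' @return A tibble `respondent_id`, `age`, `sex`.
#' @export
make_covariates <- function(n_respondents, seed = 1, p_male = 0.75,
                            age_mean = 24, age_sd = 1.3,
                            age_range = c(21, 28)) {
  withr_seed(seed, {
    sex <- ifelse(runif(n_respondents) < p_male, "male", "female")
    age <- as.integer(pmin(pmax(round(rnorm(n_respondents, age_mean, age_sd)),
                                age_range[1]), age_range[2]))
    tibble::tibble(respondent_id = seq_len(n_respondents), age = age,
                   sex = sex)
  })
}

#' Simulate paired choices
#'
#' For each respondent task, each alternative's utility is its encoded
#' attribute vector times the respondent's coefficients plus independent
#' standard Gumbel noise (drawn by inverse CDF, `-log(-log(U))`); the
#' alternative with the larger utility is chosen. Equivalently the
#' probability of choosing A is `plogis((x_A - x_B)' beta)`.
#'
#' @param design A `dce_design`.
#' @param assignment Block assignment from [assign_blocks()].
#' @param preferences Per-respondent coefficients from [draw_preferences()].
#' @param schema The [dce_schema].
#' @param covariates Optional covariate table joined onto the output.
#' @param seed Integer seed for the Gumbel noise.
#' @return A long choice dataset tibble (two rows per task) with columns
#'   `respondent_id`, `task_id`, `alternative`, `chosen`, the attribute
#'   level columns and any covariates.
#' @export
simulate_choices <- function(design, assignment, preferences, schema,
                             covariates = NULL, seed = 1) {
  long <- respondent_tasks(design, assignment)
  missing_resp <- setdiff(unique(long$respondent_id),
                          preferences$respondent_id)
  if (length(missing_resp))
    abort(sprintf("preferences missing for %d respondent(s)",
                  length(missing_resp)))
  X <- as.matrix(encode_profiles(long, schema))
  B <- as.matrix(dplyr::arrange(preferences, .data$respondent_id)[, colnames(X)])
  withr_seed(seed, {
    eta <- rowSums(X * B[long$respondent_id, , drop = FALSE])
    gumbel <- -log(-log(runif(nrow(long))))
    u <- eta + gumbel
    out <- dplyr::mutate(long, .u = u) |>
      dplyr::group_by(.data$respondent_id, .data$task_id) |>
      dplyr::mutate(chosen = as.integer(.data$.u == max(.data$.u))) |>
      dplyr::ungroup() |>
      dplyr::select(-".u", -"block") |>
      dplyr::rename(alternative = "alt")
    if (!is.null(covariates))
      out <- dplyr::left_join(out, covariates, by = "respondent_id")
    out
  })
}

#' Simulate a full study
#'
#' One call from schema to choice data under the reference study layout:
#' builds (or reuses) a 24-task, 3-block paired design, assigns each of
#' `n_respondents` two blocks (16 tasks), draws covariates and preferences,
#' and simulates choices. Stage seeds are derived from `seed` with
#' [child_seed()].
#'
#' @param dgp A [dce_dgp()] (default the mixed-logit reference preset).
#' @param n_respondents Number of respondents (default 352).
#' @param schema A [dce_schema] (default [job_schema()]).
#' @param design Optional pre-built `dce_design` to reuse.
#' @param seed Integer global seed.
#' @param n_iter Design-search iterations when building the design.
#' @return A list: `design`, `assignment`, `covariates`, `preferences`,
#'   `data` (the simulated choice dataset).
#' @examples
#' sim <- simulate_study(dgp_preset("clogit"), n_respondents = 20, seed = 1,
#'                       n_iter = 200)
#' n_observations(sim$data)
#' @export
simulate_study <- function(dgp = dgp_preset("mixl"), n_respondents = 352,
                           schema = job_schema(), design = NULL, seed = 1,
                           n_iter = 2000) {
  if (is.null(design))
    design <- build_paired_design(schema, n_tasks = 24, n_blocks = 3,
                                  seed = child_seed(seed, 1), n_iter = n_iter)
  assignment <- assign_blocks(design, n_respondents, 2,
                              seed = child_seed(seed, 2))
  covariates <- make_covariates(n_respondents, seed = child_seed(seed, 3))
  preferences <- draw_preferences(dgp, n_respondents, covariates,
                                  seed = child_seed(seed, 4))
  data <- simulate_choices(design, assignment, preferences, schema,
                           covariates, seed = child_seed(seed, 5))
  list(design = design, assignment = assignment, covariates = covariates,
       preferences = preferences, data = data)
}
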