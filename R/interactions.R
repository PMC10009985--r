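# Attribute x covariate interactions: conditional logit with extra columns
# equal to an encoded attribute difference times a respondent dummy
# (male, or "young" = age 21-24 vs adults 25-28).

#' Fit a conditional logit with attribute-covariate interactions
#'
#' Appends to the encoded design matrix one column per requested
#' interaction, equal to the attribute's difference column multiplied by a
#' respondent-level dummy, and fits the conditional logit by
#' Newton-Raphson. Wald z-tests for the interaction terms come from the
#' usual inverse-Hessian covariance.
#'
#' @param data A long-format choice dataset containing `age` and/or `sex`
#'   columns as required by `spec`.
#' @param schema A [dce_schema].
#' @param spec A tibble with columns `coefficient` (an encoded column name,
#'   e.g. `"serve_oneyear"`) and `covariate` (`"male"` or `"young"`); one
#'   row per interaction. An empty spec reduces to [fit_clogit()].
#' @param young_max Oldest age counted as "young" (default 24).
#' @return A `dce_clogit` object whose coefficient vector includes the
#'   interaction terms (named `<coefficient>:<covariate>`), with an
#'   `interactions` attribute listing them.
#' @examples
#' dgp <- dgp_preset("clogit")
#' dgp$interactions <- tibble::tibble(coefficient = "serve_oneyear",
#'                                    covariate = "young", shift = 0.5)
#' sim <- simulate_study(dgp, n_respondents = 100, seed = 1, n_iter = 200)
#' fit <- fit_interactions(sim$data, job_schema(),
#'                         tibble::tibble(coefficient = "serve_oneyear",
#'                                        covariate = "young"))
#' tidy(fit)
#' @export
fit_interactions <- function(data, schema, spec, young_max = 24) {
  if (is.null(spec) || nrow(spec) == 0) return(fit_clogit(data, schema))
  if (!all(spec$coefficient %in% coef_names(schema)))
    abort("spec$coefficient must name encoded columns of the schema")
  if (!all(spec$covariate %in% c("male", "young")))
    abort("spec$covariate must be 'male' or 'young'")
  need <- c(if ("male" %in% spec$covariate) "sex",
            if ("young" %in% spec$covariate) "age")
  missing_cov <- setdiff(need, names(data))
  if (length(missing_cov))
    abort(paste("data lacks covariate column(s):",
                paste(missing_cov, collapse = ", ")))
  if (anyNA(data[, need]))
    abort("covariates must be complete for all included respondents")
  enc <- encode_pair_differences(data, schema)
  resp <- dplyr::distinct(data, .data$respondent_id,
                          dplyr::across(dplyr::any_of(c("age", "sex"))))
  resp <- dplyr::arrange(resp, .data$respondent_id)
  dummies <- list(
    male = setNames(as.numeric(resp$sex == "male"), resp$respondent_id),
    young = setNames(as.numeric(resp$age <= young_max), resp$respondent_id))
  inter_cols <- purrr::pmap(spec[, c("coefficient", "covariate")],
                            function(coefficient, covariate) {
    enc$D[, coefficient] * dummies[[covariate]][as.character(enc$respondent)]
  })
  names(inter_cols) <- paste0(spec$coefficient, ":", spec$covariate)
  D2 <- cbind(enc$D, do.call(cbind, inter_cols))
  qr_rank <- qr(D2)$rank
  if (qr_rank < ncol(D2)) {
    # name the offending columns for the error
    drop_idx <- qr(D2)$pivot[(qr_rank + 1):ncol(D2)]
    abort(paste("collinear interaction column(s):",
                paste(colnames(D2)[drop_idx], collapse = ", ")))
  }
  fit <- newton_clogit(D2, enc$y)
  vc <- tryCatch(solve(-fit$hessian), error = function(e)
    matrix(NA_real_, ncol(D2), ncol(D2)))
  dimnames(vc) <- list(colnames(D2), colnames(D2))
  structure(list(
    coefficients = setNames(fit$beta, colnames(D2)),
    vcov = vc,
    se = setNames(sqrt(pmax(diag(vc), 0)), colnames(D2)),
    loglik = fit$loglik,
    n_obs = nrow(D2),
    n_respondents = length(unique(enc$respondent)),
    iterations = fit$iterations,
    converged = fit$converged,
    cluster_se = FALSE,
    interactions = names(inter_cols)
  ), class = "dce_clogit")
}
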