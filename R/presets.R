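# Published preference estimates of the motivating rural-job DCE among
# graduating Ethiopian medical students. These are the reference conditions
# the synthetic-data generator emulates and the inputs to the worked
# post-estimation examples. All utility units; salary coefficient per
# ETB/month.

mixl_published <- list(
  mean = c(salary = 0.0002371, house_superior = 0.28, drug_adequate = 1.01,
           serve_oneyear = 0.47, management_support = 0.44,
           workload_normal = 0.45),
  se = c(salary = 0.0000248, house_superior = 0.11, drug_adequate = 0.12,
         serve_oneyear = 0.10, management_support = 0.10,
         workload_normal = 0.09),
  sd = c(house_superior = 0.65, drug_adequate = 1.13, serve_oneyear = 0.98,
         management_support = 0.74, workload_normal = 0.01),
  se_sd = c(house_superior = 0.12, drug_adequate = 0.14, serve_oneyear = 0.11,
            management_support = 0.14, workload_normal = 0.23)
)

lcm_published <- list(
  coefficients = list(
    class_1 = c(salary = 0.0003078, house_superior = 0.86,
                drug_adequate = 1.47, serve_oneyear = 1.69,
                management_support = -0.22, workload_normal = 0.31),
    class_2 = c(salary = 4.53e-06, house_superior = 0.16,
                drug_adequate = 0.91, serve_oneyear = -0.08,
                management_support = 0.71, workload_normal = 0.48),
    class_3 = c(salary = 0.0006824, house_superior = -0.26,
                drug_adequate = -0.09, serve_oneyear = -0.01,
                management_support = 0.83, workload_normal = 0.56)
  ),
  se = list(
    class_1 = c(salary = 0.0000855, house_superior = 0.28, drug_adequate = 0.38,
                serve_oneyear = 0.30, management_support = 0.40,
                workload_normal = 0.34),
    class_2 = c(salary = 0.0000429, house_superior = 0.17, drug_adequate = 0.17,
                serve_oneyear = 0.19, management_support = 0.14,
                workload_normal = 0.14),
    class_3 = c(salary = 0.0001103, house_superior = 0.30, drug_adequate = 0.30,
                serve_oneyear = 0.29, management_support = 0.26,
                workload_normal = 0.29)
  ),
  shares = c(class_1 = 0.298, class_2 = 0.417, class_3 = 0.285)
)

#' Published mixed-logit reference estimates
#'
#' The mixed-logit coefficient means, random-coefficient standard deviations
#' and standard errors published by the motivating rural-job preference
#' study (352 medical students, 16 paired tasks each). Salary is a fixed
#' (non-random) coefficient; the five binary attributes have normally
#' distributed random coefficients.
#'
#' The returned object has the same class as a [fit_mixl()] result, so all
#' post-estimation functions accept it. Because the study published standard
#' errors but not the full covariance matrix, the object carries a diagonal
#' covariance approximation (`vcov_type = "diagonal_published"`): point
#' estimates computed from it are exact, intervals are illustrative only.
#'
#' @return A `dce_mixl` object.
#' @examples
#' uptake_change(reference_mixl(), job_schema(), "drug_supply", "adequate")
#' @export
reference_mixl <- function() {
  p <- mixl_published
  nm <- c(names(p$mean), paste0("sd_", names(p$sd)))
  V <- diag(c(p$se, p$se_sd)^2)
  dimnames(V) <- list(nm, nm)
  structure(list(
    coefficients = p$mean,
    sd = p$sd,
    se = p$se,
    se_sd = p$se_sd,
    vcov = V,
    vcov_type = "diagonal_published",
    random = names(p$sd),
    loglik = NA_real_,
    n_obs = 5632L,
    n_respondents = 352L,
    n_draws = 2000L,
    draw_type = "halton",
    converged = NA,
    source = "published"
  ), class = "dce_mixl")
}

#' Published latent-class reference estimates
#'
#' The three-class latent-class logit estimates of the motivating study:
#' per-class coefficient vectors, standard errors and class shares
#' 29.8% / 41.7% / 28.5%. Class 1 values salary, housing, supplies and a
#' shorter service year; class 2 values supplies, management and workload
#' but not salary; class 3 is dominated by salary and management.
#'
#' @return A `dce_lcm` object accepted by [relative_importance()] and the
#'   tidiers. As with [reference_mixl()], only point estimates are exact.
#' @examples
#' relative_importance(reference_lcm(), job_schema())
#' @export
reference_lcm <- function() {
  p <- lcm_published
  structure(list(
    n_classes = 3L,
    coefficients = p$coefficients,
    se = p$se,
    shares = p$shares,
    loglik = NA_real_,
    aic = NA_real_,
    posterior = NULL,
    trace = numeric(),
    converged = NA,
    source = "published"
  ), class = "dce_lcm")
}

#' Data-generating-process presets
#'
#' Ready-made [dce_dgp()] objects reproducing the reference study
#' conditions: `"clogit"` (homogeneous preferences at the mixed-logit means),
#' `"mixl"` (normal random coefficients with the published means and SDs,
#' salary fixed) and `"latent_class"` (the published three-class structure
#' with shares 0.298/0.417/0.285).
#'
#' @param kind One of `"clogit"`, `"mixl"`, `"latent_class"`.
#' @return A `dce_dgp` object.
#' @examples
#' dgp_preset("mixl")
#' @export
dgp_preset <- function(kind = c("mixl", "clogit", "latent_class")) {
  kind <- match.arg(kind)
  m <- mixl_published
  switch(kind,
    clogit = dce_dgp("clogit", mean = m$mean),
    mixl = dce_dgp("mixl", mean = m$mean,
                   sd = c(salary = 0, m$sd)[names(m$mean)]),
    latent_class = dce_dgp("latent_class",
                           class_coefficients = lcm_published$coefficients,
                           class_shares = lcm_published$shares)
  )
}
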