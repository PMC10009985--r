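# Post-estimation statistics defined on fitted (or published) coefficient
# vectors: willingness-to-accept ratios, class-share-weighted relative
# importance, and marginal uptake-rate changes for single attribute-level
# policy moves.

fit_coefs <- function(fit) {
  if (is.numeric(fit)) return(fit)
  if (!is.null(fit$coefficients) && is.numeric(fit$coefficients))
    return(fit$coefficients)
  coef(fit)
}

fit_vcov <- function(fit) {
  if (is.list(fit) && !is.null(fit$vcov)) return(fit$vcov)
  tryCatch(vcov(fit), error = function(e) NULL)
}

#' Willingness to accept (salary compensation)
#'
#' Each non-salary coefficient divided by the salary coefficient, in
#' ETB/month: the monthly salary change that leaves utility unchanged when
#' the attribute moves from its reference to the named level. Positive
#' values are the compensation respondents require to forgo the better
#' level.
#'
#' @param fit A `dce_mixl`, `dce_clogit` or named coefficient vector
#'   containing `salary`.
#' @param coefficients Which coefficients to convert (default all
#'   non-salary ones).
#' @param tol Smallest admissible `|beta_salary|`; below it the ratio is
#'   numerically unstable and an error is raised.
#' @return A tibble of class `dce_wta`: `coefficient`, `estimate`
#'   (ETB/month).
#' @examples
#' wta(reference_mixl())
#' @export
wta <- function(fit, coefficients = NULL, tol = 1e-10) {
  b <- fit_coefs(fit)
  if (!"salary" %in% names(b)) abort("fit has no 'salary' coefficient")
  if (abs(b[["salary"]]) < tol)
    abort("salary coefficient too close to zero; WTA ratio unstable")
  coefficients <- coefficients %||% setdiff(names(b), "salary")
  out <- tibble::tibble(coefficient = coefficients,
                        estimate = unname(b[coefficients] / b[["salary"]]))
  class(out) <- c("dce_wta", class(out))
  out
}

#' Willingness-to-accept interval
#'
#' Adds an uncertainty interval to each WTA ratio. `method = "delta"` uses
#' the first-order variance of the ratio
#' \eqn{g = \beta_a/\beta_s}:
#' \eqn{Var(g) \approx (V_{aa} - 2 g V_{as} + g^2 V_{ss})/\beta_s^2}.
#' `method = "krinsky_robb"` draws coefficient vectors from the
#' multivariate normal implied by the fit's covariance, forms the ratio per
#' draw and reports percentile bounds.
#'
#' @param fit A fitted model with `coef()` and `vcov()` (e.g. `dce_mixl`).
#' @param coefficients Coefficients to convert (default all non-salary).
#' @param method `"delta"` or `"krinsky_robb"`.
#' @param n_draws Krinsky-Robb draws (default 10000).
#' @param seed Seed for the Krinsky-Robb draws.
#' @param level Interval coverage (default 0.95).
#' @return A `dce_wta` tibble with `estimate`, `conf.low`, `conf.high`,
#'   `method`.
#' @export
wta_interval <- function(fit, coefficients = NULL,
                         method = c("krinsky_robb", "delta"),
                         n_draws = 10000, seed = 1, level = 0.95) {
  method <- match.arg(method)
  b <- fit_coefs(fit)
  V <- fit_vcov(fit)
  if (is.null(V) || anyNA(V)) abort("fit has no usable covariance matrix")
  V <- V[names(b), names(b), drop = FALSE]
  base <- wta(fit, coefficients)
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    ci <- purrr::map(base$coefficient, function(a) {
      g <- b[[a]] / b[["salary"]]
      v <- (V[a, a] - 2 * g * V[a, "salary"] + g^2 * V["salary", "salary"]) /
        b[["salary"]]^2
      if (v < 0) v <- 0
      c(g - z * sqrt(v), g + z * sqrt(v))
    })
  } else {
    draws <- kr_draws(b, V, n_draws, seed)
    ci <- purrr::map(base$coefficient, function(a) {
      r <- draws[, a] / draws[, "salary"]
      unname(quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2)))
    })
  }
  out <- dplyr::mutate(base,
                       conf.low = purrr::map_dbl(ci, 1),
                       conf.high = purrr::map_dbl(ci, 2),
                       method = method, level = level)
  class(out) <- c("dce_wta", class(out))
  out
}

# multivariate normal parameter draws (Krinsky-Robb)
kr_draws <- function(b, V, n_draws, seed) {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    abort("covariance matrix is not positive semi-definite")
  withr_seed(seed, MASS::mvrnorm(n_draws, b, V + diag(1e-12, nrow(V))))
}

#' Relative importance of attributes
#'
#' For each latent class, an attribute's range is the utility difference
#' between its best and worst level: `|beta| * (max - min)` of the numeric
#' levels for the linear salary attribute, `|beta|` for a binary attribute.
#' Ranges are normalised within class by the largest range, so the most
#' important attribute in each class scores exactly 1. Pooled scores
#' weight the per-class normalised scores by the class shares
#' (`pooling = "scores"`, default) or normalise the share-weighted raw
#' ranges instead (`pooling = "ranges"`).
#'
#' @param fit A `dce_lcm` (fitted or [reference_lcm()]), or a list with
#'   elements `coefficients` (list of named vectors) and `shares`.
#' @param schema A [dce_schema].
#' @param pooling `"scores"` or `"ranges"`.
#' @return A tibble of class `dce_importance`: `class` (labels plus
#'   `"pooled"`), `attribute`, `range`, `score`, `share`.
#' @examples
#' relative_importance(reference_lcm(), job_schema())
#' @export
relative_importance <- function(fit, schema, pooling = c("scores", "ranges")) {
  pooling <- match.arg(pooling)
  betas <- if (inherits(fit, "dce_lcm")) fit$coefficients else fit$coefficients
  shares <- fit$shares
  if (is.null(betas) || is.null(shares))
    abort("fit must carry per-class coefficients and shares")
  per_class <- purrr::imap(betas, function(b, cl) {
    rng <- purrr::pmap_dbl(schema, function(attribute, coding, reference,
                                            levels, values, codes) {
      if (coding == "linear")
        abs(b[[codes[[1]]]]) * (max(values) - min(values))
      else
        # binary: one dummy; multi-level: span of {0, dummy coefs}
        diff(range(c(0, b[codes[[1]]])))
    })
    tibble::tibble(class = cl, attribute = schema$attribute, range = rng,
                   score = rng / max(rng),
                   share = unname(shares[[cl]]))
  })
  tab <- dplyr::bind_rows(per_class)
  pooled <- dplyr::summarise(
    dplyr::group_by(tab, .data$attribute),
    range = sum(.data$range * .data$share),
    score = if (pooling == "scores") sum(.data$score * .data$share) else
      NA_real_,
    .groups = "drop")
  if (pooling == "ranges") pooled$score <- pooled$range / max(pooled$range)
  pooled <- dplyr::mutate(pooled, class = "pooled", share = 1) |>
    dplyr::select(dplyr::all_of(names(tab)))
  out <- dplyr::bind_rows(tab, pooled) |>
    dplyr::arrange(match(.data$class, unique(.data$class)),
                   match(.data$attribute, schema$attribute))
  class(out) <- c("dce_importance", class(out))
  out
}

#' Marginal uptake-rate change for an attribute-level move
#'
#' The predicted change in the probability that a job is chosen when one
#' attribute moves from a base level to a policy level, all other
#' attributes held constant, in a paired comparison against the otherwise
#' identical base job. With utility difference
#' \eqn{\delta = \beta' \Delta x} the policy job is chosen with
#' probability \eqn{P = \mathrm{logistic}(\delta)}, and the uptake change
#' is reported as the relative change from the even-odds base,
#' \eqn{\Delta\% = 100 (P - 0.5)/0.5} percentage points.
#'
#' Point predictions use the coefficient means only; with
#' `simulate = TRUE` (mixed-logit fits) the choice probability is instead
#' averaged over normal coefficient draws.
#'
#' @param fit A fitted model or named coefficient vector.
#' @param schema A [dce_schema].
#' @param attribute Attribute name.
#' @param policy_level Level moved to.
#' @param base_level Level moved from (default the attribute's reference,
#'   or its lowest value for linear attributes).
#' @param simulate Average the probability over random-coefficient draws
#'   instead of plugging in the means (requires a `dce_mixl` fit).
#' @param n_draws,seed Draws for `simulate = TRUE`.
#' @return A one-row tibble of class `dce_uptake`: `attribute`,
#'   `base_level`, `policy_level`, `estimate` (percentage points).
#' @examples
#' uptake_change(reference_mixl(), job_schema(), "salary", "11320")  # 26.21
#' @export
uptake_change <- function(fit, schema, attribute, policy_level,
                          base_level = NULL, simulate = FALSE,
                          n_draws = 10000, seed = 1) {
  b <- fit_coefs(fit)
  base_level <- base_level %||% default_base_level(schema, attribute)
  ld <- level_delta(schema, attribute, base_level, policy_level)
  delta_x <- setNames(rep(0, length(b)), names(b))
  delta_x[ld$code] <- ld$delta
  d <- sum(b * delta_x)
  if (simulate) {
    if (!inherits(fit, "dce_mixl"))
      abort("simulate = TRUE requires a mixed-logit fit")
    sd_full <- setNames(rep(0, length(b)), names(b))
    sd_full[names(fit$sd)] <- fit$sd
    sim_sd <- sqrt(sum((delta_x * sd_full)^2))
    p <- withr_seed(seed, mean(plogis(rnorm(n_draws, d, sim_sd))))
  } else {
    p <- plogis(d)
  }
  out <- tibble::tibble(attribute = attribute, base_level = base_level,
                        policy_level = policy_level,
                        estimate = 100 * (p - 0.5) / 0.5)
  class(out) <- c("dce_uptake", class(out))
  out
}

default_base_level <- function(schema, attribute) {
  row <- schema[schema$attribute == attribute, ]
  if (nrow(row) != 1L) abort(sprintf("unknown attribute '%s'", attribute))
  if (row$coding == "linear")
    row$levels[[1]][which.min(row$values[[1]])]
  else row$reference
}

#' Uptake-rate change with an uncertainty interval
#'
#' Krinsky-Robb (default) or delta-method interval on the uptake change of
#' [uptake_change()]. Krinsky-Robb draws coefficient vectors from the
#' fit's covariance and takes percentile bounds of the per-draw uptake
#' change; the delta method propagates
#' \eqn{d\Delta\%/d\beta = 200\, p(1-p)\, \Delta x}.
#'
#' @inheritParams uptake_change
#' @param method `"krinsky_robb"` or `"delta"`.
#' @param n_draws Krinsky-Robb draws.
#' @param seed Seed for the draws.
#' @param level Interval coverage.
#' @return A one-row `dce_uptake` tibble with `conf.low`, `conf.high`,
#'   `method`.
#' @export
uptake_interval <- function(fit, schema, attribute, policy_level,
                            base_level = NULL,
                            method = c("krinsky_robb", "delta"),
                            n_draws = 10000, seed = 1, level = 0.95) {
  method <- match.arg(method)
  b <- fit_coefs(fit)
  V <- fit_vcov(fit)
  if (is.null(V) || anyNA(V)) abort("fit has no usable covariance matrix")
  point <- uptake_change(fit, schema, attribute, policy_level, base_level)
  base_level <- point$base_level
  ld <- level_delta(schema, attribute, base_level, policy_level)
  delta_x <- setNames(rep(0, length(b)), names(b))
  delta_x[ld$code] <- ld$delta
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    d <- sum(b * delta_x)
    p <- plogis(d)
    grad <- 200 * p * (1 - p) * delta_x
    v <- drop(t(grad) %*% V[names(b), names(b)] %*% grad)
    ci <- point$estimate + c(-1, 1) * z * sqrt(max(v, 0))
  } else {
    draws <- kr_draws(b, V[names(b), names(b), drop = FALSE], n_draws, seed)
    dd <- 100 * (plogis(draws %*% delta_x) - 0.5) / 0.5
    ci <- unname(quantile(dd, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  out <- dplyr::mutate(point, conf.low = ci[1], conf.high = ci[2],
                       method = method, level = level)
  class(out) <- c("dce_uptake", class(out))
  out
}

#' Uptake-change table for every non-reference move
#'
#' Applies [uptake_change()] (and optionally [uptake_interval()]) to every
#' improvement move of the schema: each salary level above the base, and
#' each binary attribute's non-reference level.
#'
#' @inheritParams uptake_interval
#' @param interval Add Krinsky-Robb intervals.
#' @return A `dce_uptake` tibble, one row per move.
#' @examples
#' uptake_table(reference_mixl(), job_schema())
#' @export
uptake_table <- function(fit, schema, interval = FALSE, n_draws = 10000,
                         seed = 1, level = 0.95) {
  moves <- purrr::pmap(schema, function(attribute, coding, reference, levels,
                                        values, codes) {
    base <- default_base_level(schema, attribute)
    tibble::tibble(attribute = attribute,
                   policy_level = setdiff(levels, base),
                   base_level = base)
  }) |> dplyr::bind_rows()
  rows <- purrr::pmap(moves, function(attribute, policy_level, base_level) {
    if (interval)
      uptake_interval(fit, schema, attribute, policy_level, base_level,
                      n_draws = n_draws, seed = seed, level = level)
    else uptake_change(fit, schema, attribute, policy_level, base_level)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dce_uptake", class(out))
  out
}
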