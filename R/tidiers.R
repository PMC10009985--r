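# broom-style tidiers for the fitted objects

#' Tidy a conditional logit fit
#'
#' @param x A `dce_clogit`.
#' @param conf.int Add Wald confidence bounds.
#' @param conf.level Coverage for `conf.int`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (and `conf.low`/`conf.high` if requested).
#' @export
tidy.dce_clogit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$coefficients / x$se),
    p.value = 2 * pnorm(-abs(unname(x$coefficients / x$se))))
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out <- dplyr::mutate(out,
                         conf.low = .data$estimate - z * .data$std.error,
                         conf.high = .data$estimate + z * .data$std.error)
  }
  out
}

#' @rdname tidy.dce_clogit
#' @export
glance.dce_clogit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik,
                 AIC = 2 * length(x$coefficients) - 2 * x$loglik,
                 nobs = x$n_obs, n_respondents = x$n_respondents,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a mixed logit fit
#'
#' One row per parameter; `component` is `"mean"` or `"sd"`.
#'
#' @param x A `dce_mixl`.
#' @param ... Unused.
#' @return A tibble `term`, `component`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.dce_mixl <- function(x, ...) {
  est <- c(x$coefficients, x$sd)
  se <- c(x$se, x$se_sd)
  comp <- c(rep("mean", length(x$coefficients)), rep("sd", length(x$sd)))
  tibble::tibble(term = c(names(x$coefficients), names(x$sd)),
                 component = comp,
                 estimate = unname(est),
                 std.error = unname(se),
                 statistic = unname(est / se),
                 p.value = 2 * pnorm(-abs(unname(est / se))))
}

#' @rdname tidy.dce_mixl
#' @export
glance.dce_mixl <- function(x, ...) {
  k <- length(x$coefficients) + length(x$sd)
  tibble::tibble(logLik = x$loglik, AIC = 2 * k - 2 * x$loglik,
                 nobs = x$n_obs, n_respondents = x$n_respondents,
                 n_draws = x$n_draws, draw_type = x$draw_type,
                 converged = x$converged)
}

#' Tidy a latent class fit
#'
#' One row per class x coefficient.
#'
#' @param x A `dce_lcm`.
#' @param ... Unused.
#' @return A tibble `class`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `share`.
#' @export
tidy.dce_lcm <- function(x, ...) {
  purrr::imap(x$coefficients, function(b, cl) {
    se <- x$se[[cl]]
    tibble::tibble(class = cl, term = names(b), estimate = unname(b),
                   std.error = unname(se),
                   statistic = unname(b / se),
                   p.value = 2 * pnorm(-abs(unname(b / se))),
                   share = unname(x$shares[[cl]]))
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.dce_lcm
#' @export
glance.dce_lcm <- function(x, ...) {
  tibble::tibble(n_classes = x$n_classes, logLik = x$loglik, AIC = x$aic,
                 converged = x$converged)
}
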