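# Conditional logit for two-alternative choice tasks. With exactly two
# alternatives per task the conditional logit likelihood reduces to a
# binary logistic model on the within-task attribute difference
# d = x_A - x_B with response "A chosen", which is what these routines use.

#' Conditional logit log-likelihood, gradient and Hessian
#'
#' Pure function evaluating the panel-pooled conditional logit
#' log-likelihood \eqn{\sum_t \log P(\mathrm{chosen}_t)} with analytic
#' gradient and Hessian, on the per-task difference representation.
#'
#' @param beta Coefficient vector.
#' @param D Numeric matrix of per-task attribute differences (x_A - x_B),
#'   one row per task.
#' @param y 0/1 vector, 1 if alternative A was chosen.
#' @param weights Optional non-negative per-task weights (used by the
#'   latent-class M-step).
#' @return A list `loglik`, `gradient`, `hessian`.
#' @examples
#' # at beta = 0 every task has probability 1/2
#' D <- matrix(rnorm(20), 10, 2)
#' clogit_loglik(c(0, 0), D, rep(1, 10))$loglik  # 10 * log(0.5)
#' @export
clogit_loglik <- function(beta, D, y, weights = NULL) {
  if (any(!is.finite(beta))) abort("beta must be finite")
  if (length(beta) != ncol(D)) abort("beta length must match ncol(D)")
  if (is.null(weights)) weights <- rep(1, nrow(D))
  eta <- drop(D %*% beta)
  # log P(chosen): P(A) = plogis(eta), P(B) = plogis(-eta)
  s <- ifelse(y == 1, 1, -1)
  ll <- sum(weights * log_plogis(s * eta))
  p <- plogis(eta)                      # P(choose A)
  resid <- y - p
  grad <- drop(crossprod(D, weights * resid))
  w2 <- weights * p * (1 - p)
  hess <- -crossprod(D * w2, D)
  list(loglik = ll, gradient = grad, hessian = hess)
}

# Newton-Raphson with step-halving; shared by fit_clogit and the LCM M-step
newton_clogit <- function(D, y, weights = NULL, beta0 = NULL, tol = 1e-6,
                          max_iter = 100) {
  k <- ncol(D)
  beta <- beta0 %||% rep(0, k)
  ev <- clogit_loglik(beta, D, y, weights)
  converged <- FALSE
  diverged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(ev$gradient)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(ev$hessian, -ev$gradient),
                     error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    # step-halving to guarantee ascent
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      evc <- clogit_loglik(cand, D, y, weights)
      if (evc$loglik >= ev$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + lambda * step
    ev <- evc
    # runaway coefficients signal (quasi-)complete separation
    if (max(abs(drop(D %*% beta))) > 30 && max(abs(ev$gradient)) > tol &&
        it == max_iter) diverged <- TRUE
  }
  # an enormous fitted utility difference signals (quasi-)separation: the
  # gradient can vanish while the MLE runs off to infinity
  sep <- max(abs(drop(D %*% beta))) > 12
  list(beta = beta, loglik = ev$loglik, gradient = ev$gradient,
       hessian = ev$hessian, iterations = it,
       converged = converged && !diverged && !sep)
}

#' Fit a conditional logit model
#'
#' Newton-Raphson maximisation from beta = 0, declaring convergence when
#' the gradient max-norm drops below `tol`. The covariance matrix is the
#' inverse of the negative Hessian at the optimum; clustered (by
#' respondent) sandwich standard errors are available with
#' `cluster_se = TRUE`. Non-convergence (for example under complete
#' separation, where the MLE is infinite) is flagged on the returned
#' object, not raised.
#'
#' @param data A long-format choice dataset (see [validate_choices()]).
#' @param schema A [dce_schema].
#' @param cluster_se Use respondent-clustered sandwich standard errors.
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `dce_clogit`: `coefficients`, `vcov`, `se`,
#'   `loglik`, `n_obs` (tasks), `n_respondents`, `iterations`, `converged`.
#' @examples
#' sim <- simulate_study(dgp_preset("clogit"), n_respondents = 40, seed = 1,
#'                       n_iter = 200)
#' fit <- fit_clogit(sim$data, job_schema())
#' tidy(fit)
#' @export
fit_clogit <- function(data, schema, cluster_se = FALSE, tol = 1e-6,
                       max_iter = 100) {
  enc <- encode_pair_differences(data, schema)
  fit <- newton_clogit(enc$D, enc$y, tol = tol, max_iter = max_iter)
  info <- -fit$hessian
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(enc$D), ncol(enc$D))
  })
  if (cluster_se && !anyNA(vc)) {
    p <- plogis(drop(enc$D %*% fit$beta))
    sc <- enc$D * (enc$y - p)
    G <- rowsum(sc, enc$respondent)
    vc <- vc %*% crossprod(G) %*% vc
  }
  dimnames(vc) <- list(colnames(enc$D), colnames(enc$D))
  structure(list(
    coefficients = setNames(fit$beta, colnames(enc$D)),
    vcov = vc,
    se = setNames(sqrt(pmax(diag(vc), 0)), colnames(enc$D)),
    loglik = fit$loglik,
    n_obs = nrow(enc$D),
    n_respondents = length(unique(enc$respondent)),
    iterations = fit$iterations,
    converged = fit$converged,
    cluster_se = cluster_se
  ), class = "dce_clogit")
}

#' @export
coef.dce_clogit <- function(object, ...) object$coefficients

#' @export
vcov.dce_clogit <- function(object, ...) object$vcov

#' @export
logLik.dce_clogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.dce_clogit <- function(x, ...) {
  cat("Conditional logit (", x$n_obs, " paired tasks, ",
      x$n_respondents, " respondents)\n", sep = "")
  if (!x$converged) cat("  ** did not converge **\n")
  print(round(cbind(estimate = x$coefficients, std.error = x$se), 6))
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}
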