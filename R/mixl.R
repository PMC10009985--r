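# Panel mixed logit by simulated maximum likelihood. Random coefficients
# are independent normals; the likelihood of each respondent's panel of
# paired choices is averaged over quasi-random (Halton) coefficient draws,
# transformed from uniforms by the inverse normal CDF.

#' Simulated panel mixed-logit log-likelihood
#'
#' For respondent i and draw r, the conditional likelihood is the product
#' over the respondent's tasks of the paired logit probabilities at the
#' drawn coefficient vector; the simulated likelihood averages this product
#' over draws before taking logs (the panel, not the pooled, estimator):
#' \deqn{\ell = \sum_i \log \frac{1}{R} \sum_r \prod_{t \in i}
#'   P_{t}(\beta_{ir})}
#'
#' @param mean Named vector of coefficient means (all attributes).
#' @param sd Named vector of random-coefficient standard deviations (subset
#'   of `names(mean)`); interpreted by absolute value.
#' @param D Per-task difference matrix (chosen convention: see `y`).
#' @param y 0/1 vector, 1 if the first (A) alternative was chosen.
#' @param respondent Respondent id per task row.
#' @param draws Standard-normal draw array
#'   `[n_respondents x R x length(sd)]`, e.g. from Halton sequences;
#'   dimension order must match `names(sd)`.
#' @param gradient Also return the analytic gradient.
#' @return A list `loglik` and, if requested, `gradient` (named, means then
#'   `sd_*` terms).
#' @export
mixl_loglik <- function(mean, sd, D, y, respondent, draws,
                        gradient = FALSE) {
  if (length(dim(draws)) != 3L) abort("draws must be a 3-d array")
  R <- dim(draws)[2]
  if (R == 0) abort("at least one draw is required")
  rand <- names(sd)
  if (!all(rand %in% names(mean))) abort("sd names must be a subset of mean")
  resp_idx <- match(respondent, sort(unique(respondent)))
  n_resp <- max(resp_idx)
  if (dim(draws)[1] != n_resp)
    abort("draws must have one slice per respondent")
  s <- ifelse(y == 1, 1, -1)             # sign so that s*eta is the chosen side
  Ds <- D * s                            # rows now chosen-minus-other
  base <- drop(Ds %*% mean[colnames(D)])
  Dr <- Ds[, rand, drop = FALSE]
  sd_abs <- abs(sd)
  logL <- matrix(0, n_resp, R)
  for (r in seq_len(R)) {
    Zr <- draws[, r, , drop = FALSE]
    dim(Zr) <- c(n_resp, length(rand))
    eta <- base + drop((Dr * Zr[resp_idx, , drop = FALSE]) %*% sd_abs)
    logL[, r] <- rowsum(log_plogis(eta), resp_idx)[, 1]
  }
  m <- apply(logL, 1, max)
  W <- exp(logL - m)                     # n_resp x R, relative likelihoods
  sw <- rowSums(W)
  ll <- sum(m + log(sw / R))
  out <- list(loglik = ll)
  if (gradient) {
    Wn <- W / sw                         # per-draw posterior weights
    g_mean <- numeric(ncol(D))
    g_sd <- numeric(length(rand))
    for (r in seq_len(R)) {
      Zr <- draws[, r, , drop = FALSE]
      dim(Zr) <- c(n_resp, length(rand))
      Zrow <- Zr[resp_idx, , drop = FALSE]
      eta <- base + drop((Dr * Zrow) %*% sd_abs)
      q <- plogis(-eta)                  # 1 - P(chosen)
      wt <- Wn[resp_idx, r]
      g_mean <- g_mean + drop(crossprod(Ds, wt * q))
      g_sd <- g_sd + drop(crossprod(Dr * Zrow, wt * q))
    }
    g_sd <- g_sd * sign(ifelse(sd == 0, 1, sd))   # chain rule for |sd|
    out$gradient <- setNames(c(g_mean, g_sd),
                             c(colnames(D), paste0("sd_", rand)))
  }
  out
}

#' Fit a panel mixed logit by simulated maximum likelihood
#'
#' Maximises the simulated log-likelihood over coefficient means and
#' random-coefficient standard deviations with BFGS and the analytic
#' gradient. Draws are respondent-partitioned Halton sequences (one prime
#' base per random coefficient: 2, 3, 5, 7, 11, ...), burn-in 50,
#' transformed to normals by the inverse CDF; optional random-shift
#' scrambling. Standard deviations are unconstrained during optimisation
#' and reported as absolute values. Standard errors come from the inverse
#' of a central-difference Hessian of the simulated log-likelihood.
#'
#' @param data A long-format choice dataset.
#' @param schema A [dce_schema].
#' @param random Character vector of coefficients with random (normal)
#'   taste variation. Default: every attribute except `salary`, which is
#'   kept fixed so coefficient ratios (WTA) are well defined.
#' @param R Number of Halton draws per respondent (default 2000).
#' @param seed Integer seed (used only when `scramble = TRUE`).
#' @param scramble Random-shift the Halton sequences.
#' @param burn Halton burn-in (default 50).
#' @param init Optional named start values; defaults to the conditional
#'   logit estimates with small positive starting SDs.
#' @param max_iter BFGS iteration cap.
#' @return An object of class `dce_mixl`: `coefficients` (means), `sd`,
#'   `se`, `se_sd`, `vcov` (means then `sd_*`), `loglik`, `n_draws`,
#'   `converged`, plus bookkeeping fields.
#' @examples
#' \donttest{
#' sim <- simulate_study(dgp_preset("mixl"), n_respondents = 60, seed = 1,
#'                       n_iter = 200)
#' fit <- fit_mixl(sim$data, job_schema(), R = 100)
#' tidy(fit)
#' }
#' @export
fit_mixl <- function(data, schema, random = NULL, R = 2000, seed = 1,
                     scramble = FALSE, burn = 50, init = NULL,
                     max_iter = 200) {
  cn <- coef_names(schema)
  random <- random %||% setdiff(cn, "salary")
  if (!all(random %in% cn)) abort("unknown coefficient in 'random'")
  enc <- encode_pair_differences(data, schema)
  n_resp <- length(unique(enc$respondent))
  k_r <- length(random)
  draws <- halton_normal_draws(n_resp, R, k_r, burn = burn,
                               scramble = scramble, seed = seed)
  # start from the homogeneous fit; modest SD start keeps |sd| smooth
  if (is.null(init)) {
    cl <- newton_clogit(enc$D, enc$y)
    init <- c(setNames(cl$beta, cn), setNames(rep(0.1, k_r),
                                              paste0("sd_", random)))
  }
  nm <- c(cn, paste0("sd_", random))
  eval_cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (identical(eval_cache$key, key)) return(eval_cache$val)
    val <- mixl_loglik(setNames(par[seq_along(cn)], cn),
                       setNames(par[-seq_along(cn)], random),
                       enc$D, enc$y, enc$respondent, draws, gradient = TRUE)
    eval_cache$key <- key
    eval_cache$val <- val
    val
  }
  # scale salary internally (per 1000 ETB) so BFGS sees comparable magnitudes
  scale_vec <- setNames(rep(1, length(nm)), nm)
  if ("salary" %in% cn) scale_vec["salary"] <- 1000
  fn <- function(par) -evaluate(par / scale_vec)$loglik
  gr <- function(par) -evaluate(par / scale_vec)$gradient / scale_vec
  opt <- optim(init * scale_vec, fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-10))
  par <- opt$par / scale_vec
  # observed information by central differences of the analytic gradient
  H <- numeric_hessian(function(p) evaluate(p)$gradient, par,
                       rel_h = 1e-4)
  vc <- tryCatch(solve(-(H + t(H)) / 2), error = function(e)
    matrix(NA_real_, length(par), length(par)))
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc), 0))
  structure(list(
    coefficients = setNames(par[seq_along(cn)], cn),
    sd = abs(setNames(par[-seq_along(cn)], random)),
    se = setNames(se[seq_along(cn)], cn),
    se_sd = setNames(se[-seq_along(cn)], random),
    vcov = vc,
    vcov_type = "observed_information",
    random = random,
    loglik = -opt$value,
    n_obs = nrow(enc$D),
    n_respondents = n_resp,
    n_draws = R,
    draw_type = if (scramble) "scrambled_halton" else "halton",
    converged = opt$convergence == 0,
    source = "fitted"
  ), class = "dce_mixl")
}

# central-difference Jacobian of a gradient function (the Hessian)
numeric_hessian <- function(grad_fn, par, rel_h = 1e-4) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- rel_h * max(abs(par[j]), 1e-3)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (grad_fn(up) - grad_fn(dn)) / (2 * h)
  }
  H
}

#' @export
coef.dce_mixl <- function(object, ...) object$coefficients

#' @export
vcov.dce_mixl <- function(object, ...) object$vcov

#' @export
logLik.dce_mixl <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + length(object$sd),
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.dce_mixl <- function(x, ...) {
  cat("Panel mixed logit (", x$n_obs, " paired tasks, ", x$n_respondents,
      " respondents, ", x$n_draws, " ", x$draw_type, " draws)\n", sep = "")
  if (identical(x$source, "published"))
    cat("  (published reference estimates)\n")
  if (isFALSE(x$converged)) cat("  ** did not converge **\n")
  sd_full <- setNames(rep(NA_real_, length(x$coefficients)),
                      names(x$coefficients))
  sd_full[names(x$sd)] <- x$sd
  print(round(cbind(mean = x$coefficients, se = x$se, sd = sd_full), 6),
        na.print = "")
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}
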