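# Latent-class conditional logit by EM. Each respondent belongs to one of C
# unobserved preference classes; the E-step computes posterior class
# probabilities from the current shares and per-class panel likelihoods,
# the M-step refits a weighted conditional logit per class and updates the
# shares, so the mixture log-likelihood is non-decreasing.

# per-respondent log panel likelihood under each class: n_resp x C
lcm_class_loglik <- function(betas, D, y, resp_idx) {
  s <- ifelse(y == 1, 1, -1)
  Ds <- D * s
  vapply(betas, function(b) rowsum(log_plogis(drop(Ds %*% b)), resp_idx)[, 1],
         numeric(max(resp_idx)))
}

# mixture log-likelihood given per-class panel log-likelihoods and shares
lcm_mixture_loglik <- function(class_ll, shares) {
  A <- sweep(class_ll, 2, log(shares), "+")
  m <- apply(A, 1, max)
  sum(m + log(rowSums(exp(A - m))))
}

#' Fit a latent-class conditional logit
#'
#' EM with multiple seeded restarts. Restarts initialise each class at the
#' pooled conditional-logit estimate plus noise and the shares near
#' uniform; the best final log-likelihood is kept. A restart whose smallest
#' share collapses below `share_floor` is abandoned and replaced. Classes
#' are relabelled deterministically (descending salary coefficient, ties by
#' descending share) so class numbering is reproducible. Standard errors
#' come from the inverse observed information of the mixture
#' log-likelihood over all parameters (class coefficients and share
#' logits), computed by central differences of the analytic score.
#'
#' @param data A long-format choice dataset.
#' @param schema A [dce_schema].
#' @param C Number of latent classes (>= 1).
#' @param n_starts EM restarts (default 5).
#' @param seed Integer seed for the restarts.
#' @param max_iter EM iteration cap per restart.
#' @param tol Absolute mixture log-likelihood improvement declaring
#'   convergence.
#' @param share_floor Smallest admissible class share: a restart whose
#'   smallest share drops below it is treated as degenerate. The default
#'   0.05 follows common mixture-modelling practice (a class smaller than
#'   a few percent of respondents is uninterpretable and typically a
#'   likelihood artifact); lower it towards 0 to admit arbitrarily small
#'   classes.
#' @return An object of class `dce_lcm`: `n_classes`, `coefficients` (list
#'   per class), `se`, `shares`, `loglik`, `aic`
#'   (`2k - 2LL`, `k = 6C + (C-1)` for the six-attribute schema),
#'   `posterior` (respondents x classes), `trace` (mixture log-likelihood
#'   per EM iteration of the winning restart), `converged`.
#' @examples
#' sim <- simulate_study(dgp_preset("latent_class"), n_respondents = 80,
#'                       seed = 1, n_iter = 200)
#' fit <- fit_lcm(sim$data, job_schema(), C = 2, n_starts = 2)
#' glance(fit)
#' @export
fit_lcm <- function(data, schema, C, n_starts = 5, seed = 1, max_iter = 400,
                    tol = 1e-7, share_floor = 0.05) {
  if (C < 1) abort("C must be >= 1")
  enc <- encode_pair_differences(data, schema)
  D <- enc$D
  y <- enc$y
  resp_idx <- match(enc$respondent, sort(unique(enc$respondent)))
  n_resp <- max(resp_idx)
  k <- ncol(D)
  pooled <- newton_clogit(D, y)

  if (C == 1L) {
    vc <- tryCatch(solve(-pooled$hessian),
                   error = function(e) matrix(NA_real_, k, k))
    out <- list(
      n_classes = 1L,
      coefficients = list(class_1 = setNames(pooled$beta, colnames(D))),
      se = list(class_1 = setNames(sqrt(pmax(diag(vc), 0)), colnames(D))),
      shares = c(class_1 = 1),
      loglik = pooled$loglik,
      aic = 2 * k - 2 * pooled$loglik,
      posterior = matrix(1, n_resp, 1),
      trace = pooled$loglik,
      converged = pooled$converged,
      source = "fitted")
    class(out) <- "dce_lcm"
    return(out)
  }

  run_em <- function(start_seed) {
    withr_seed(start_seed, {
      betas <- lapply(seq_len(C), function(c)
        pooled$beta * (1 + rnorm(k, 0, 0.5)) + rnorm(k, 0, 0.25) *
          pmax(abs(pooled$beta), 1e-4))
      shares <- rep(1 / C, C) + runif(C, -0.05, 0.05)
      shares <- shares / sum(shares)
    })
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      cll <- lcm_class_loglik(betas, D, y, resp_idx)
      ll <- lcm_mixture_loglik(cll, shares)
      trace <- c(trace, ll)
      # E-step: posterior class membership
      A <- sweep(cll, 2, log(shares), "+")
      A <- A - apply(A, 1, max)
      W <- exp(A)
      W <- W / rowSums(W)
      shares_new <- colMeans(W)
      if (min(shares_new) < share_floor) {
        degenerate <- TRUE
        break
      }
      # M-step: weighted clogit per class, warm-started
      betas <- lapply(seq_len(C), function(c)
        newton_clogit(D, y, weights = W[resp_idx, c], beta0 = betas[[c]],
                      tol = 1e-8)$beta)
      shares <- shares_new
      if (it > 1 && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(betas = betas, shares = shares, loglik = ll, trace = trace,
         posterior = W, converged = converged, degenerate = degenerate)
  }

  fits <- list()
  attempt <- 0L
  while (length(fits) < n_starts && attempt < 3L * n_starts) {
    attempt <- attempt + 1L
    f <- run_em(child_seed(seed, attempt))
    if (!f$degenerate) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    # every restart collapsed a class: return the degenerate best, flagged
    f <- run_em(child_seed(seed, 1L))
    fits <- list(f)
  }
  best <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]

  # deterministic labels: descending salary coefficient, then share
  salary_col <- if ("salary" %in% colnames(D)) "salary" else colnames(D)[1]
  key1 <- purrr::map_dbl(best$betas, ~ .x[match(salary_col, colnames(D))])
  ord <- order(-key1, -best$shares)
  betas <- best$betas[ord]
  shares <- best$shares[ord]
  posterior <- best$posterior[, ord, drop = FALSE]

  npar <- C * k + (C - 1)
  se <- lcm_standard_errors(betas, shares, D, y, resp_idx)
  cls <- paste0("class_", seq_len(C))
  out <- list(
    n_classes = as.integer(C),
    coefficients = setNames(lapply(betas, setNames, colnames(D)), cls),
    se = setNames(lapply(seq_len(C), function(c)
      setNames(se$beta_se[[c]], colnames(D))), cls),
    shares = setNames(shares, cls),
    share_se = setNames(se$share_se, cls),
    loglik = best$loglik,
    aic = 2 * npar - 2 * best$loglik,
    posterior = posterior,
    trace = best$trace,
    converged = best$converged && !best$degenerate,
    source = "fitted")
  class(out) <- "dce_lcm"
  out
}

# observed information of the mixture over (betas, share logits)
lcm_standard_errors <- function(betas, shares, D, y, resp_idx) {
  C <- length(betas)
  k <- ncol(D)
  s <- ifelse(y == 1, 1, -1)
  Ds <- D * s
  pack <- c(unlist(betas), log(shares[-C] / shares[C]))
  score <- function(par) {
    bl <- lapply(seq_len(C), function(c) par[((c - 1) * k + 1):(c * k)])
    ga <- par[(C * k + 1):(C * k + C - 1)]
    sh <- exp(c(ga, 0)) / sum(exp(c(ga, 0)))
    cll <- lcm_class_loglik(bl, D, y, resp_idx)
    A <- sweep(cll, 2, log(sh), "+")
    A <- A - apply(A, 1, max)
    W <- exp(A); W <- W / rowSums(W)
    g_beta <- unlist(lapply(seq_len(C), function(c) {
      eta <- drop(Ds %*% bl[[c]])
      drop(crossprod(Ds, W[resp_idx, c] * plogis(-eta)))
    }))
    wbar <- colSums(W)
    g_gamma <- (wbar - nrow(W) * sh)[-C]
    c(g_beta, g_gamma)
  }
  H <- numeric_hessian(score, pack, rel_h = 1e-5)
  vc <- tryCatch(solve(-(H + t(H)) / 2), error = function(e)
    matrix(NA_real_, length(pack), length(pack)))
  beta_se <- lapply(seq_len(C), function(c)
    sqrt(pmax(diag(vc)[((c - 1) * k + 1):(c * k)], 0)))
  # delta method for the shares from the share logits
  share_se <- rep(NA_real_, C)
  gi <- (C * k + 1):(C * k + C - 1)
  if (!anyNA(vc)) {
    Vg <- vc[gi, gi, drop = FALSE]
    J <- matrix(0, C, C - 1)
    for (c in seq_len(C)) for (j in seq_len(C - 1))
      J[c, j] <- shares[c] * ((c == j) - shares[j])
    share_se <- sqrt(pmax(diag(J %*% Vg %*% t(J)), 0))
  }
  list(beta_se = beta_se, share_se = share_se)
}

#' Select the number of latent classes by AIC
#'
#' Fits [fit_lcm()] for each candidate class count and picks the AIC
#' minimiser (`AIC = 2k - 2LL`).
#'
#' @param data,schema,seed,n_starts As in [fit_lcm()].
#' @param C_range Integer vector of candidate class counts.
#' @param ... Passed on to [fit_lcm()].
#' @return A list: `table` (tibble `C`, `loglik`, `aic`, `converged`),
#'   `chosen` (the AIC-minimising C), `fits` (named list of `dce_lcm`).
#' @export
select_classes <- function(data, schema, C_range = 1:4, seed = 1,
                           n_starts = 5, ...) {
  if (!length(C_range)) abort("C_range must be non-empty")
  fits <- lapply(C_range, function(C)
    fit_lcm(data, schema, C = C, n_starts = n_starts,
            seed = child_seed(seed, C), ...))
  tab <- tibble::tibble(
    C = as.integer(C_range),
    loglik = purrr::map_dbl(fits, "loglik"),
    aic = purrr::map_dbl(fits, "aic"),
    converged = purrr::map_lgl(fits, "converged"))
  # degenerate (non-converged) fits are reported but not eligible winners
  eligible <- if (any(tab$converged)) which(tab$converged) else
    seq_len(nrow(tab))
  list(table = tab, chosen = tab$C[eligible[which.min(tab$aic[eligible])]],
       fits = setNames(fits, paste0("C", C_range)))
}

#' @export
coef.dce_lcm <- function(object, ...) object$coefficients

#' @export
logLik.dce_lcm <- function(object, ...) {
  k <- length(object$coefficients[[1]])
  structure(object$loglik,
            df = object$n_classes * k + object$n_classes - 1,
            class = "logLik")
}

#' @export
print.dce_lcm <- function(x, ...) {
  cat(x$n_classes, "-class latent class logit\n", sep = "")
  if (identical(x$source, "published"))
    cat("  (published reference estimates)\n")
  if (isFALSE(x$converged)) cat("  ** did not converge **\n")
  cat("class shares:",
      paste(sprintf("%s %.1f%%", names(x$shares), 100 * x$shares),
            collapse = ", "), "\n")
  for (cl in names(x$coefficients)) {
    cat(cl, ":\n")
    print(round(cbind(estimate = x$coefficients[[cl]],
                      std.error = x$se[[cl]]), 6))
  }
  if (is.finite(x$loglik))
    cat(sprintf("log-likelihood: %.4f  AIC: %.2f\n", x$loglik, x$aic))
  invisible(x)
}
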