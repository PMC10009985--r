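#' Halton low-discrepancy sequence
#'
#' Radical-inverse Halton sequence in a prime base: element `i` reverses the
#' base-`base` digits of `i` around the radix point, giving a deterministic
#' sequence that fills (0, 1) far more evenly than pseudo-random draws.
#' Used to simulate the mixed-logit likelihood.
#'
#' @param n Number of elements to return.
#' @param base Prime base (2, 3, 5, ...).
#' @param burn Number of initial elements to discard (they cluster near 0).
#' @return Numeric vector of length `n` with values in (0, 1).
#' @examples
#' halton(3, base = 2)  # 0.5 0.25 0.75
#' halton(3, base = 3)  # 1/3 2/3 1/9
#' @export
halton <- function(n, base = 2, burn = 0) {
  is_prime <- length(base) == 1 && base == round(base) && base >= 2 &&
    (base < 4 || all(base %% 2:floor(sqrt(base)) != 0))
  if (!is_prime) abort("base must be a prime number")
  if (burn < 0) abort("burn must be >= 0")
  idx <- seq_len(n + burn)
  out <- numeric(n + burn)
  f <- 1
  while (any(idx > 0)) {
    f <- f / base
    out <- out + f * (idx %% base)
    idx <- idx %/% base
  }
  out[(burn + 1):(burn + n)]
}

# first k primes, Halton dimension bases
first_primes <- function(k) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  if (k > length(primes)) abort("too many Halton dimensions requested")
  primes[seq_len(k)]
}

# respondent-partitioned standard-normal Halton draws:
# array [n_respondents x R x k]; dimension j uses the j-th prime base,
# the first `burn` points are dropped, and respondent i takes rows
# ((i-1)R + 1) : (iR) of the remaining sequence.
halton_normal_draws <- function(n_respondents, R, k, burn = 50,
                                scramble = FALSE, seed = 1) {
  if (R <= 0) abort("R must be positive")
  bases <- first_primes(k)
  total <- n_respondents * R
  arr <- array(0, c(n_respondents, R, k))
  shifts <- if (scramble) withr_seed(seed, runif(k)) else rep(0, k)
  for (j in seq_len(k)) {
    u <- halton(total, base = bases[j], burn = burn)
    if (scramble) u <- (u + shifts[j]) %% 1
    u <- pmin(pmax(u, 1e-10), 1 - 1e-10)
    arr[, , j] <- matrix(qnorm(u), n_respondents, R, byrow = TRUE)
  }
  arr
}
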