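# Blocked orthogonal main-effects paired-choice design via seeded random-swap
# search. The generator that produced the original study's design is not
# recoverable; only its criteria are (orthogonality, level balance, minimum
# overlap, utility balance), so we minimise a weighted penalty over those
# four criteria directly.

#' Build a blocked paired-choice design
#'
#' Constructs `n_tasks` two-alternative choice tasks from the full factorial
#' of `schema` by seeded random-swap search: starting from a random set of
#' profile pairs, single-profile replacement moves are accepted whenever they
#' strictly reduce a weighted penalty combining (i) level imbalance, (ii)
#' mean absolute pairwise correlation between encoded attribute columns,
#' (iii) within-task attribute overlap and (iv) deviation of each task's
#' choice probability from 1/2 under a prior coefficient vector. Tasks are
#' then partitioned into `n_blocks` blocks by greedy level-balancing and
#' shuffled within block. The same `(schema, seed)` always yields the same
#' design.
#'
#' @param schema A [dce_schema].
#' @param n_tasks Number of paired tasks (must be divisible by `n_blocks`).
#' @param n_blocks Number of blocks.
#' @param prior Numeric prior coefficient vector of length
#'   `length(coef_names(schema))` used for the utility-balance criterion.
#'   Default all zeros (every task then has choice probability exactly 1/2).
#' @param seed Integer seed; identical seeds give bitwise-identical designs.
#' @param n_iter Number of candidate swap moves to evaluate.
#' @param weights Length-4 numeric penalty weights for (balance,
#'   orthogonality, overlap, utility imbalance). Default equal.
#'
#' @return A tibble of class `dce_design` with columns `task_id`, `block`,
#'   `alt` (`"A"`/`"B"`) and one level-label column per attribute
#'   (2 rows per task), carrying attributes `n_blocks`, `penalty_trace`
#'   and `diagnostics` (a [diagnose_design()] result).
#' @examples
#' des <- build_paired_design(job_schema(), n_tasks = 24, n_blocks = 3,
#'                            seed = 1, n_iter = 400)
#' dplyr::count(des, block) # 3 blocks x 8 tasks x 2 alternatives
#' @export
build_paired_design <- function(schema, n_tasks = 24, n_blocks = 3,
                                prior = NULL, seed = 1, n_iter = 2000,
                                weights = c(1, 1, 1, 1)) {
  profiles <- enumerate_profiles(schema)
  P <- nrow(profiles)
  if (n_tasks %% n_blocks != 0L)
    abort("n_tasks must be divisible by n_blocks")
  if (n_tasks > P * (P - 1) / 2)
    abort("n_tasks exceeds the number of distinct profile pairs")
  k <- length(coef_names(schema))
  if (is.null(prior)) prior <- rep(0, k)
  if (length(prior) != k)
    abort(sprintf("prior must have length %d (one per encoded column)", k))
  E <- as.matrix(encode_profiles(profiles, schema))
  # standardized copy for the correlation criterion
  Es <- scale(E)
  # level-index matrix of the enumeration (profiles x attributes)
  L <- vapply(seq_len(nrow(schema)),
              function(i) as.integer(profile_level_index(seq_len(P), schema, i)),
              integer(P))

  withr_seed(seed, {
    state <- init_pairs(P, n_tasks)
    pen <- design_penalty(state, E, Es, L, schema, prior, weights)
    trace <- numeric(n_iter + 1L)
    trace[1L] <- pen
    for (it in seq_len(n_iter)) {
      slot <- sample.int(2L * n_tasks, 1L)
      task <- (slot + 1L) %/% 2L
      side <- 2L - slot %% 2L
      partner <- state[task, 3L - side]
      cand <- sample.int(P, 1L)
      if (cand == partner || cand == state[task, side]) {
        trace[it + 1L] <- pen
        next
      }
      prop <- state
      prop[task, side] <- cand
      ppen <- design_penalty(prop, E, Es, L, schema, prior, weights)
      if (ppen < pen) {
        state <- prop
        pen <- ppen
      }
      trace[it + 1L] <- pen
    }
    # canonical task order: lexicographic on (min index, max index)
    key <- cbind(pmin(state[, 1], state[, 2]), pmax(state[, 1], state[, 2]))
    ord <- order(key[, 1], key[, 2])
    state <- state[ord, , drop = FALSE]
    blocks <- greedy_blocks(state, E, n_blocks)
    # seeded shuffle of task order within each block
    shuffled <- unlist(lapply(seq_len(n_blocks), function(b) {
      ids <- which(blocks == b)
      ids[sample.int(length(ids))]
    }))
    state <- state[shuffled, , drop = FALSE]
    blocks <- blocks[shuffled]
    design <- tibble::tibble(
      task_id = rep(seq_len(n_tasks), each = 2L),
      block = rep(blocks, each = 2L),
      alt = rep(c("A", "B"), n_tasks)
    )
    design <- dplyr::bind_cols(design, profiles[as.vector(t(state)), ])
    class(design) <- c("dce_design", class(design))
    attr(design, "n_blocks") <- n_blocks
    attr(design, "penalty_trace") <- trace
    attr(design, "diagnostics") <- diagnose_design(design, schema, prior)
    design
  })
}

# random distinct pairs, no self-pairing
init_pairs <- function(P, n_tasks) {
  a <- sample.int(P, n_tasks, replace = TRUE)
  b <- sample.int(P - 1L, n_tasks, replace = TRUE)
  b <- ifelse(b >= a, b + 1L, b)
  cbind(a, b, deparse.level = 0)
}

# the four-criteria penalty; state is an n_tasks x 2 matrix of profile rows,
# L the precomputed profiles x attributes level-index matrix
design_penalty <- function(state, E, Es, L, schema, prior, weights) {
  idx <- as.vector(t(state))
  n <- length(idx)
  # (1) level imbalance: mean absolute deviation of level frequencies from
  # uniform, per attribute, averaged (scale-free, 0 = perfect balance)
  Lsel <- L[idx, , drop = FALSE]
  sizes <- lengths(schema$levels)
  bal <- mean(vapply(seq_along(sizes), function(i) {
    counts <- tabulate(Lsel[, i], nbins = sizes[i])
    mean(abs(counts - n / sizes[i])) / n
  }, numeric(1)))
  # (2) orthogonality: mean absolute off-diagonal correlation of encoded cols
  cc <- suppressWarnings(cor(Es[idx, , drop = FALSE]))
  cc[!is.finite(cc)] <- 1 # degenerate (constant) column: worst case
  k <- ncol(cc)
  orth <- (sum(abs(cc)) - k) / (k * (k - 1))
  # (3) overlap: mean per-task share of attributes with identical levels
  ov <- mean(L[state[, 1], , drop = FALSE] == L[state[, 2], , drop = FALSE])
  # (4) utility imbalance: mean |P(A) - 1/2|, rescaled to [0, 1]
  dU <- (E[state[, 1], , drop = FALSE] - E[state[, 2], , drop = FALSE]) %*% prior
  ub <- mean(abs(plogis(dU) - 0.5)) * 2
  sum(weights * c(bal, orth, ov, ub))
}

# level index of profiles (by row number in the enumeration) for attribute i:
# expand_grid varies the last attribute fastest
profile_level_index <- function(rows, schema, i) {
  sizes <- lengths(schema$levels)
  after <- if (i < length(sizes)) prod(sizes[(i + 1):length(sizes)]) else 1L
  ((rows - 1L) %/% after) %% sizes[i] + 1L
}

# greedy level-balanced assignment of tasks to blocks of equal size
greedy_blocks <- function(state, E, n_blocks) {
  n_tasks <- nrow(state)
  per <- n_tasks / n_blocks
  blocks <- integer(n_tasks)
  # running sum of encoded columns per block; assign each task to the
  # non-full block whose column sums stay closest to proportional
  tot <- (E[state[, 1], , drop = FALSE] + E[state[, 2], , drop = FALSE])
  target <- colSums(tot) / n_blocks
  acc <- matrix(0, n_blocks, ncol(E))
  sizes <- integer(n_blocks)
  for (t in seq_len(n_tasks)) {
    open <- which(sizes < per)
    cost <- purrr::map_dbl(open, function(b) {
      sum(abs(acc[b, ] + tot[t, ] - target * (sizes[b] + 1) / per))
    })
    b <- open[which.min(cost)]
    blocks[t] <- b
    acc[b, ] <- acc[b, ] + tot[t, ]
    sizes[b] <- sizes[b] + 1L
  }
  blocks
}

#' Diagnose a paired-choice design
#'
#' Computes the four classical design criteria for a paired design: level
#' balance (per-attribute level frequencies over all profiles),
#' orthogonality (pairwise correlations between encoded attribute columns),
#' within-task attribute overlap, and utility balance (each task's choice
#' probability for alternative A under a prior coefficient vector).
#'
#' @param design A `dce_design` (or any tibble with `task_id`, `alt` and
#'   attribute columns, two rows per task).
#' @param schema The [dce_schema] the design was built from.
#' @param prior Prior coefficient vector for utility balance (default zero,
#'   under which every probability is exactly 1/2).
#' @return A list of class `dce_diagnostics`: `level_balance` (tibble
#'   `attribute`, `level`, `n`), `orthogonality` (list `max_abs_cor`,
#'   `cor_matrix`), `overlap` (tibble `task_id`, `n_same` plus attribute
#'   `mean`), `utility_balance` (tibble `task_id`, `p_A` plus attribute
#'   `max_dev`).
#' @export
diagnose_design <- function(design, schema, prior = NULL) {
  k <- length(coef_names(schema))
  if (is.null(prior)) prior <- rep(0, k)
  E <- as.matrix(encode_profiles(design, schema))
  lb <- tidyr::pivot_longer(design[, schema$attribute],
                            dplyr::everything(),
                            names_to = "attribute", values_to = "level") |>
    dplyr::count(.data$attribute, .data$level) |>
    dplyr::arrange(match(.data$attribute, schema$attribute))
  cc <- suppressWarnings(cor(E))
  diag(cc) <- 0
  cc[!is.finite(cc)] <- NA
  a_rows <- design$alt == "A"
  XA <- E[a_rows, , drop = FALSE]
  XB <- E[!a_rows, , drop = FALSE]
  labA <- design[a_rows, schema$attribute]
  labB <- design[!a_rows, schema$attribute]
  n_same <- rowSums(as.matrix(labA) == as.matrix(labB))
  ov <- tibble::tibble(task_id = unique(design$task_id), n_same = n_same)
  attr(ov, "mean") <- mean(n_same)
  pA <- as.vector(plogis((XA - XB) %*% prior))
  ub <- tibble::tibble(task_id = unique(design$task_id), p_A = pA)
  attr(ub, "max_dev") <- max(abs(pA - 0.5))
  out <- list(
    level_balance = lb,
    orthogonality = list(max_abs_cor = max(abs(cc), na.rm = TRUE),
                         cor_matrix = cc),
    overlap = ov,
    utility_balance = ub
  )
  class(out) <- "dce_diagnostics"
  out
}

#' @export
print.dce_diagnostics <- function(x, ...) {
  cat("Paired-design diagnostics\n")
  cat(sprintf("  max |cor| between encoded columns: %.4f\n",
              x$orthogonality$max_abs_cor))
  cat(sprintf("  mean within-task attribute overlap: %.3f\n",
              attr(x$overlap, "mean")))
  cat(sprintf("  max |P(A) - 0.5| under prior: %.4f\n",
              attr(x$utility_balance, "max_dev")))
  cat("  level counts:\n")
  print(as.data.frame(x$level_balance), row.names = FALSE)
  invisible(x)
}

#' Assign blocks to respondents
#'
#' Each respondent receives a uniformly random ordered draw of
#' `blocks_per_respondent` distinct blocks, so that the tasks a respondent
#' answers are `blocks_per_respondent` times the tasks per block.
#'
#' @param design A `dce_design` built by [build_paired_design()].
#' @param n_respondents Number of respondents.
#' @param blocks_per_respondent Blocks each respondent answers (default 2).
#' @param seed Integer seed.
#' @return A tibble `respondent_id`, `position`, `block` with
#'   `blocks_per_respondent` rows per respondent.
#' @examples
#' des <- build_paired_design(job_schema(), seed = 1, n_iter = 200)
#' asg <- assign_blocks(des, n_respondents = 352, seed = 1)
#' nrow(asg) / 352  # 2 blocks each -> 16 tasks each
#' @export
assign_blocks <- function(design, n_respondents, blocks_per_respondent = 2,
                          seed = 1) {
  n_blocks <- attr(design, "n_blocks") %||% length(unique(design$block))
  if (blocks_per_respondent > n_blocks)
    abort("blocks_per_respondent cannot exceed the number of blocks")
  withr_seed(seed, {
    draws <- purrr::map(seq_len(n_respondents),
                        ~ sample.int(n_blocks, blocks_per_respondent))
    tibble::tibble(
      respondent_id = rep(seq_len(n_respondents), each = blocks_per_respondent),
      position = rep(seq_len(blocks_per_respondent), n_respondents),
      block = unlist(draws)
    )
  })
}

#' Expand a block assignment into per-respondent tasks
#'
#' @param design A `dce_design`.
#' @param assignment Output of [assign_blocks()].
#' @return A long tibble: one row per respondent x task x alternative,
#'   with the design's attribute columns.
#' @export
respondent_tasks <- function(design, assignment) {
  dplyr::inner_join(assignment, tibble::as_tibble(design), by = "block",
                    relationship = "many-to-many") |>
    dplyr::arrange(.data$respondent_id, .data$position, .data$task_id) |>
    dplyr::select(-"position")
}

#' Write / read a paired design as CSV
#'
#' Plain long CSV with columns `task_id`, `block`, `alt` and one column per
#' attribute level label.
#'
#' @param design A `dce_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `dce_design` tibble.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(tibble::as_tibble(design), path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           task_id = "i", block = "i", alt = "c",
                           .default = "c"))
  class(out) <- c("dce_design", class(out))
  attr(out, "n_blocks") <- length(unique(out$block))
  out
}
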