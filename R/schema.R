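# Attribute schema: the contract shared by the design builder, the encoder,
# every estimator and all post-estimation. One row per attribute.

#' Construct an attribute schema
#'
#' An attribute schema lists the attributes of a paired choice experiment,
#' their levels, how each is coded in the design matrix (a single linear
#' column, or one dummy column per non-reference level) and, for linear
#' attributes, the numeric value of each level.
#'
#' @param attribute Character vector of attribute names.
#' @param levels List of character vectors, one per attribute, giving the
#'   level labels in display order. The first level of a categorical
#'   attribute is its reference unless `reference` says otherwise.
#' @param coding Character vector, `"linear"` or `"categorical"` per
#'   attribute.
#' @param reference Character vector of reference levels (ignored, and may be
#'   `NA`, for linear attributes).
#' @param values List of numeric vectors giving the numeric value of each
#'   level for linear attributes (`NULL`/`NA` entries for categorical ones).
#' @param codes List of character vectors naming the encoded column produced
#'   by each level. For a linear attribute a single name; for a categorical
#'   attribute one name per non-reference level. Defaults to
#'   `<attribute>` (linear) or `<attribute>_<level>` (categorical).
#'
#' @return A tibble of class `dce_schema` with columns `attribute`, `coding`,
#'   `reference`, `levels` (list), `values` (list), `codes` (list).
#' @seealso [job_schema()] for the rural-job schema used throughout the
#'   package's examples and simulations.
#' @export
dce_schema <- function(attribute, levels, coding, reference = NULL,
                       values = NULL, codes = NULL) {
  n <- length(attribute)
  if (n == 0L) abort("schema must contain at least one attribute")
  stopifnot(length(levels) == n, length(coding) == n)
  coding <- match.arg(coding, c("linear", "categorical"), several.ok = TRUE)
  if (length(coding) == 1L) coding <- rep(coding, n)
  if (is.null(reference)) {
    reference <- purrr::map2_chr(levels, coding,
                                 ~ if (.y == "categorical") .x[[1]] else NA_character_)
  }
  if (is.null(values)) values <- rep(list(NULL), n)
  if (is.null(codes)) {
    codes <- purrr::pmap(list(attribute, levels, coding, reference), function(a, l, c, r) {
      if (c == "linear") a else paste(a, setdiff(l, r), sep = "_")
    })
  }
  for (i in seq_len(n)) {
    if (length(levels[[i]]) < 2L)
      abort(sprintf("attribute '%s' needs at least 2 levels", attribute[[i]]))
    if (coding[[i]] == "categorical" && !reference[[i]] %in% levels[[i]])
      abort(sprintf("reference level '%s' not among the levels of '%s'",
                    reference[[i]], attribute[[i]]))
    if (coding[[i]] == "linear") {
      if (is.null(values[[i]]) || length(values[[i]]) != length(levels[[i]]))
        abort(sprintf("linear attribute '%s' needs one numeric value per level",
                      attribute[[i]]))
    }
  }
  out <- tibble::tibble(attribute = attribute, coding = coding,
                        reference = reference, levels = levels,
                        values = values, codes = codes)
  class(out) <- c("dce_schema", class(out))
  out
}

#' The rural-job attribute schema
#'
#' Six job attributes of the motivating rural-job preference study among
#' graduating Ethiopian medical students: monthly salary (four levels, 9,056
#' to 15,848 ETB, coded linearly in ETB/month) and five binary attributes
#' (housing, drug/equipment supply, mandatory service years before study
#' leave, management support, workload), each dummy-coded against the less
#' attractive reference level (basic housing, inadequate supply, two years,
#' unsupportive management, heavy workload).
#'
#' The full factorial of this schema has \eqn{4 \times 2^5 = 128} profiles.
#'
#' @return A `dce_schema` tibble with six rows.
#' @examples
#' job_schema()
#' nrow(enumerate_profiles(job_schema()))  # 128
#' @export
job_schema <- function() {
  dce_schema(
    attribute = c("salary", "housing", "drug_supply", "service_years",
                  "management", "workload"),
    levels = list(
      c("9056", "11320", "13584", "15848"),
      c("basic", "superior"),
      c("inadequate", "adequate"),
      c("two_years", "one_year"),
      c("unsupportive", "supportive"),
      c("heavy", "normal")
    ),
    coding = c("linear", rep("categorical", 5)),
    reference = c(NA, "basic", "inadequate", "two_years", "unsupportive",
                  "heavy"),
    values = list(c(9056, 11320, 13584, 15848), NULL, NULL, NULL, NULL, NULL),
    codes = list("salary", "house_superior", "drug_adequate", "serve_oneyear",
                 "management_support", "workload_normal")
  )
}

#' Encoded coefficient names of a schema
#'
#' The fixed column order of the encoded design matrix and of every
#' coefficient vector in the package. For [job_schema()] this is
#' `salary, house_superior, drug_adequate, serve_oneyear,
#' management_support, workload_normal`.
#'
#' @param schema A `dce_schema`.
#' @return Character vector of encoded column names.
#' @export
coef_names <- function(schema) unlist(schema$codes, use.names = FALSE)

#' Enumerate the full factorial of a schema
#'
#' Every distinct profile (one level per attribute), exactly once, in a
#' deterministic order (last attribute varying fastest).
#'
#' @param schema A `dce_schema`.
#' @return A tibble with one column per attribute (level labels) and one row
#'   per profile.
#' @export
enumerate_profiles <- function(schema) {
  if (!inherits(schema, "dce_schema") || nrow(schema) == 0L)
    abort("schema must be a non-empty dce_schema")
  grid <- rlang::exec(tidyr::expand_grid,
                      !!!rlang::set_names(schema$levels, schema$attribute))
  grid[, schema$attribute, drop = FALSE]
}

#' Encode profiles into a numeric design matrix
#'
#' Maps level labels to the numeric columns every estimator consumes: linear
#' attributes take their level's numeric value, categorical attributes one
#' 0/1 dummy per non-reference level (reference encodes to all zeros).
#'
#' @param data A data frame with one column per schema attribute holding
#'   level labels (extra columns are ignored).
#' @param schema A `dce_schema`.
#' @return A tibble of numeric columns named [coef_names()], row-aligned
#'   with `data`.
#' @examples
#' encode_profiles(
#'   tibble::tibble(salary = "15848", housing = "superior",
#'                  drug_supply = "adequate", service_years = "one_year",
#'                  management = "supportive", workload = "normal"),
#'   job_schema())
#' @export
encode_profiles <- function(data, schema) {
  missing_cols <- setdiff(schema$attribute, names(data))
  if (length(missing_cols))
    abort(paste0("data lacks attribute column(s): ",
                 paste(missing_cols, collapse = ", ")))
  cols <- purrr::pmap(schema, function(attribute, coding, reference, levels,
                                       values, codes) {
    lab <- as.character(data[[attribute]])
    bad <- which(!lab %in% levels)
    if (length(bad))
      abort(sprintf("unknown level '%s' for attribute '%s' (first at row %d)",
                    lab[bad[1]], attribute, bad[1]))
    if (coding == "linear") {
      out <- tibble::tibble(values[match(lab, levels)])
    } else {
      nonref <- setdiff(levels, reference)
      out <- tibble::as_tibble(
        purrr::map(nonref, ~ as.numeric(lab == .x)), .name_repair = "minimal")
    }
    rlang::set_names(out, codes)
  })
  dplyr::bind_cols(cols)
}

#' Decode an encoded design matrix back to level labels
#'
#' Inverse of [encode_profiles()] on valid encodings.
#'
#' @param encoded A data frame with the columns of [coef_names()].
#' @param schema A `dce_schema`.
#' @return A tibble of level labels, one column per attribute.
#' @export
decode_profiles <- function(encoded, schema) {
  cols <- purrr::pmap(schema, function(attribute, coding, reference, levels,
                                       values, codes) {
    if (coding == "linear") {
      idx <- match(encoded[[codes]], values)
      if (anyNA(idx)) abort(sprintf("unencodable value in column '%s'", codes))
      lab <- levels[idx]
    } else {
      nonref <- setdiff(levels, reference)
      dummies <- as.matrix(encoded[, codes, drop = FALSE])
      hits <- drop(dummies %*% seq_along(nonref))
      if (any(rowSums(dummies) > 1))
        abort(sprintf("attribute '%s': more than one dummy set", attribute))
      lab <- ifelse(hits == 0, reference, nonref[pmax(hits, 1)])
    }
    tibble::tibble(!!attribute := lab)
  })
  dplyr::bind_cols(cols)
}

# level -> numeric value of a linear attribute (or dummy contrast value of a
# categorical level); used by uptake_change and the design utilities
level_delta <- function(schema, attribute, from, to) {
  row <- schema[schema$attribute == attribute, ]
  if (nrow(row) != 1L) abort(sprintf("unknown attribute '%s'", attribute))
  lv <- row$levels[[1]]
  if (!from %in% lv || !to %in% lv)
    abort(sprintf("levels '%s' and '%s' must both belong to attribute '%s'",
                  from, to, attribute))
  if (row$coding == "linear") {
    vals <- row$values[[1]]
    list(code = row$codes[[1]],
         delta = vals[match(to, lv)] - vals[match(from, lv)])
  } else {
    ref <- row$reference
    nonref <- setdiff(lv, ref)
    dummy <- function(l) as.numeric(nonref == l)
    d <- dummy(to) - dummy(from)
    list(code = row$codes[[1]], delta = d)
  }
}
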