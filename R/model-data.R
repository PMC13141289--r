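#' Assemble a model frame for CPM-based causal estimation
#'
#' Validates and packages a rectangular dataset into the pieces the fitting
#' routines need: the encoded outcome, a numeric covariate matrix (factor and
#' character covariates are expanded to treatment-contrast indicators with the
#' lexicographically first level as reference), and a strictly binary 0/1
#' treatment vector. A two-level non-numeric treatment column is mapped with
#' the lexically larger level coded 1 unless `treatment_positive` names the
#' level to code as 1.
#'
#' @param data A data frame.
#' @param outcome,treatment Column names (length-1 character).
#' @param covariates Character vector of covariate column names (may be
#'   `NULL` for an unadjusted model).
#' @param treatment_positive Optional level of the treatment column to code
#'   as 1.
#' @return An object of class `mw_model_data`: list with `encoded`
#'   (see [encode_outcome()]), `x` (n-by-p numeric matrix), `a` (0/1 integer
#'   vector), `y` (original outcome) and bookkeeping fields.
#' @export
model_data <- function(data, outcome, treatment, covariates = NULL,
                       treatment_positive = NULL) {
  if (inherits(data, "mw_model_data")) return(data)
  stopifnot(is.data.frame(data))
  cols <- c(outcome, treatment, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0("column(s) not found: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mwcpm_missing_column")
  }
  if (outcome == treatment) {
    rlang::abort("outcome and treatment columns must be distinct",
                 class = "mwcpm_config_error")
  }
  if (anyNA(data[cols])) {
    rlang::abort(
      "missing values in used columns; use read_dataset() for complete-case handling",
      class = "mwcpm_na_error")
  }
  a <- encode_treatment(data[[treatment]], treatment_positive)
  enc <- encode_outcome(data[[outcome]])
  x <- build_covariate_matrix(data, covariates)
  structure(list(
    encoded = enc,
    x = x,
    a = a,
    y = data[[outcome]],
    outcome = outcome,
    treatment = treatment,
    covariates = covariates %||% character(0)
  ), class = "mw_model_data")
}

encode_treatment <- function(a_raw, treatment_positive = NULL) {
  lev <- sort(unique(as.character(a_raw)))
  if (length(lev) != 2) {
    rlang::abort(paste0("treatment must have exactly 2 levels, found ",
                        length(lev), ": ", paste(lev, collapse = ", ")),
                 class = "mwcpm_treatment_levels")
  }
  if (is.numeric(a_raw) && setequal(unique(a_raw), c(0, 1))) {
    return(as.integer(a_raw))
  }
  pos <- treatment_positive %||% lev[2] # lexically larger level is "treated"
  if (!pos %in% lev) {
    rlang::abort(paste0("treatment_positive level '", pos, "' not present"),
                 class = "mwcpm_config_error")
  }
  as.integer(as.character(a_raw) == pos)
}

build_covariate_matrix <- function(data, covariates) {
  if (is.null(covariates) || length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  df <- as.data.frame(data[covariates], stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) || is.logical(df[[j]])) {
      df[[j]] <- factor(df[[j]], levels = sort(unique(as.character(df[[j]]))))
    }
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mw_model_data <- function(x, ...) {
  cat("<mw_model_data> n =", length(x$a),
      " K =", length(x$encoded$distinct_values),
      " p =", ncol(x$x),
      " treated =", sum(x$a), "\n")
  invisible(x)
}
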