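#' Encode an orderable outcome as ranks over its distinct values
#'
#' The cumulative probability model carries one intercept per distinct outcome
#' value, so fitting begins by collapsing the outcome to the sorted grid
#' \eqn{y_{(1)} < \dots < y_{(K)}} and recording each observation's position on
#' it. Ties collapse to a shared rank, which is how the cumulative-link
#' likelihood accommodates ordinal and mixed outcomes.
#'
#' @param y A numeric (or otherwise orderable) vector, length at least 2,
#'   with at least two distinct values and no missing entries.
#' @return An object of class `mw_encoded`: a list with `distinct_values`
#'   (strictly increasing, length `K`), `rank_index` (integer in `1..K` per
#'   observation) and `counts` (observations per distinct value).
#' @examples
#' enc <- encode_outcome(c(3, 1, 3, 2))
#' enc$distinct_values  # 1 2 3
#' enc$rank_index       # 3 1 3 2
#' @export
encode_outcome <- function(y) {
  if (anyNA(y)) {
    rlang::abort("outcome contains missing values", class = "mwcpm_na_error")
  }
  if (length(y) < 2) {
    rlang::abort("need at least 2 observations", class = "mwcpm_data_error")
  }
  vals <- sort(unique(y))
  if (length(vals) < 2) {
    rlang::abort(
      "outcome is constant: no cumulative probability model can be fit",
      class = "mwcpm_degenerate_outcome")
  }
  r <- match(y, vals)
  structure(list(
    distinct_values = vals,
    rank_index = as.integer(r),
    counts = tabulate(r, nbins = length(vals))
  ), class = "mw_encoded")
}

#' @export
print.mw_encoded <- function(x, ...) {
  cat("<mw_encoded> n =", length(x$rank_index),
      " distinct values K =", length(x$distinct_values), "\n")
  invisible(x)
}
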