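#' Read a rectangular dataset for estimation
#'
#' Reads a CSV (header required), keeps only the columns the analysis uses,
#' drops rows with missing values in those columns (complete-case analysis;
#' the count is reported), expands factor/character covariates to indicator
#' columns with the lexicographically first level as reference, and maps the
#' treatment column to 0/1.
#'
#' @param path CSV file path.
#' @param outcome,treatment,covariates Column names.
#' @param treatment_positive Optional treatment level to code as 1 (default:
#'   the lexically larger level).
#' @param quiet Suppress the dropped-rows message?
#' @return An [model_data()] object; the number of dropped rows is attached
#'   as attribute `dropped`.
#' @export
read_dataset <- function(path, outcome, treatment, covariates = NULL,
                         treatment_positive = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "mwcpm_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- c(outcome, treatment, covariates)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("column(s) not found in ", path, ": ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mwcpm_missing_column")
  }
  used <- raw[cols]
  keep <- stats::complete.cases(used)
  dropped <- sum(!keep)
  if (dropped > 0 && !quiet) {
    message("dropped ", dropped, " row(s) with missing values (complete-case)")
  }
  md <- model_data(used[keep, ], outcome, treatment, covariates,
                   treatment_positive = treatment_positive)
  attr(md, "dropped") <- dropped
  md
}

#' Command-line entry points
#'
#' Thin argument-parsing wrappers around the package's estimation, simulation
#' and fixture functions, used by the `mwcpm` script in
#' `inst/cli/mwcpm.R` (`Rscript $(Rscript -e
#' 'cat(system.file("cli/mwcpm.R", package="mwcpm"))') <command> ...`).
#' Each returns an integer exit code (0 on success) and writes its report to
#' the chosen output.
#'
#' `run_estimate_command` flags: `--data`, `--outcome`, `--treatment`,
#' `--covariates` (comma-separated), `--link` (probit/logit/loglog/cloglog),
#' `--all-links`, `--method` (cpm/nlm), `--transform`
#' (identity/log/sqrt, nlm only), `--boot`, `--seed`, `--stratified`,
#' `--ci` (normal/percentile), `--out` (JSON path, default stdout).
#'
#' `run_simulate_command` flags: `--beta`, `--tau`, `--n` (comma lists),
#' `--estimator` (comma list of tags), `--nsim`, `--nboot`, `--seed`,
#' `--out` (CSV path), `--json` (optional JSON summary path).
#'
#' `run_fixture_command` flags: `--kind`, `--seed`, `--out`.
#'
#' @param args Character vector of command-line arguments (excluding the
#'   subcommand name).
#' @return Integer exit code, invisibly.
#' @name cli
NULL

num_list <- function(x) as.numeric(strsplit(x, ",")[[1]])
chr_list <- function(x) {
  if (is.null(x) || !nzchar(x)) return(NULL)
  trimws(strsplit(x, ",")[[1]])
}

report_json <- function(x, out) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(out)) cat(js, "\n") else writeLines(js, out)
}

cli_fail <- function(e) {
  message("error: ", conditionMessage(e))
  invisible(1L)
}

#' @rdname cli
#' @export
run_estimate_command <- function(args = character(0)) {
  spec <- list(
    optparse::make_option("--data", type = "character"),
    optparse::make_option("--outcome", type = "character"),
    optparse::make_option("--treatment", type = "character"),
    optparse::make_option("--covariates", type = "character", default = ""),
    optparse::make_option("--link", type = "character", default = "probit"),
    optparse::make_option("--all-links", action = "store_true",
                          default = FALSE, dest = "all_links"),
    optparse::make_option("--method", type = "character", default = "cpm"),
    optparse::make_option("--transform", type = "character",
                          default = "identity"),
    optparse::make_option("--boot", type = "integer", default = 200L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--stratified", action = "store_true",
                          default = FALSE),
    optparse::make_option("--ci", type = "character", default = "normal"),
    optparse::make_option("--out", type = "character", default = NULL)
  )
  tryCatch({
    opt <- optparse::parse_args(
      optparse::OptionParser(option_list = spec), args = args)
    if (is.null(opt$data) || is.null(opt$outcome) || is.null(opt$treatment)) {
      rlang::abort("--data, --outcome and --treatment are required",
                   class = "mwcpm_config_error")
    }
    covs <- chr_list(opt$covariates)
    md <- read_dataset(opt$data, opt$outcome, opt$treatment, covs)
    df <- as_frame(md)
    one_cpm <- function(link) {
      est <- bootstrap_theta(df, outcome = ".y", treatment = ".a",
                             covariates = colnames(md$x),
                             link = link, B = opt$boot, seed = opt$seed,
                             stratified = opt$stratified, ci_type = opt$ci)
      list(link = link, theta = est$theta, se = est$se,
           ci = c(est$ci_low, est$ci_high), loglik = est$loglik,
           converged = est$converged, n = est$n, K = est$K,
           n_boot_used = est$n_boot_used)
    }
    report <- if (opt$method == "nlm") {
      fit <- fit_transformed_nlm(df, ".y", ".a", colnames(md$x),
                                 transform = opt$transform)
      nboot <- nlm_boot(df, colnames(md$x), opt$transform, opt$boot, opt$seed)
      list(schema = 1L, method = "nlm", transform = opt$transform,
           theta = theta_from_nlm(fit), se = nboot$se, ci = nboot$ci,
           n = fit$n, n_boot_used = nboot$used, seed = opt$seed)
    } else if (opt$all_links) {
      fits <- lapply(c("probit", "logit", "loglog"), one_cpm)
      lls <- vapply(fits, function(f) f$loglik, numeric(1))
      list(schema = 1L, method = "cpm", fits = fits,
           best_link = fits[[which.max(lls)]]$link, seed = opt$seed)
    } else {
      c(list(schema = 1L, method = "cpm"), one_cpm(opt$link),
        list(seed = opt$seed))
    }
    report_json(report, opt$out)
    invisible(0L)
  }, error = cli_fail)
}

as_frame <- function(md) {
  df <- tibble::as_tibble(as.data.frame(md$x))
  df$.y <- md$y
  df$.a <- md$a
  df
}

nlm_boot <- function(df, covs, transform, B, seed) {
  point <- theta_from_nlm(fit_transformed_nlm(df, ".y", ".a", covs,
                                              transform = transform))
  n <- nrow(df)
  set.seed(seed)
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    d <- df[sample.int(n, n, replace = TRUE), ]
    if (length(unique(d$.a)) < 2) next
    boot[b] <- tryCatch(
      theta_from_nlm(fit_transformed_nlm(d, ".y", ".a", covs,
                                         transform = transform)),
      error = function(e) NA_real_)
  }
  ok <- boot[!is.na(boot)]
  se <- stats::sd(ok)
  list(se = se, ci = point + c(-1.96, 1.96) * se, used = length(ok))
}

#' @rdname cli
#' @export
run_simulate_command <- function(args = character(0)) {
  spec <- list(
    optparse::make_option("--beta", type = "character", default = "0,0.5,2"),
    optparse::make_option("--tau", type = "character", default = "0,0.5,2"),
    optparse::make_option("--n", type = "character", default = "50,200,500"),
    optparse::make_option("--estimator", type = "character",
                          default = "cpm-probit"),
    optparse::make_option("--nsim", type = "integer", default = 100L),
    optparse::make_option("--nboot", type = "integer", default = 50L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--json", type = "character", default = NULL)
  )
  tryCatch({
    opt <- optparse::parse_args(
      optparse::OptionParser(option_list = spec), args = args)
    grid <- scenario_grid(beta = num_list(opt$beta), tau = num_list(opt$tau),
                          n = as.integer(num_list(opt$n)),
                          estimator = chr_list(opt$estimator),
                          nsim = opt$nsim, nboot = opt$nboot)
    res <- run_grid(grid, seed = opt$seed)
    if (!is.null(opt$out)) readr::write_csv(res, opt$out)
    else print(res, n = Inf)
    if (!is.null(opt$json)) {
      report_json(list(schema = 1L, seed = opt$seed,
                       n_scenarios = nrow(res),
                       results = res), opt$json)
    }
    invisible(0L)
  }, error = cli_fail)
}

#' @rdname cli
#' @export
run_fixture_command <- function(args = character(0)) {
  spec <- list(
    optparse::make_option("--kind", type = "character", default = "tiny"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character")
  )
  tryCatch({
    opt <- optparse::parse_args(
      optparse::OptionParser(option_list = spec), args = args)
    if (is.null(opt$out)) {
      rlang::abort("--out is required", class = "mwcpm_config_error")
    }
    make_fixture(opt$kind, seed = opt$seed, path = opt$out)
    invisible(0L)
  }, error = cli_fail)
}
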