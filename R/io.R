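#' Read a modelling dataset from a delimited text file
#'
#' Reads a CSV or TSV file (dialect chosen by extension: `.tsv` / `.tab`
#' use tabs, anything else commas) with a header row, and assembles the
#' design matrix and response.  Rows containing missing values are rejected
#' with their indices reported.
#'
#' @param path file path.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names; NULL uses
#'   every non-response column, in file order.
#' @param intercept prepend a column of ones (default TRUE).
#' @return list with `X` (numeric matrix, row order preserved) and `y`.
#' @export
read_dataset <- function(path, response, covariates = NULL, intercept = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!response %in% names(df))
    stop("response column '", response, "' not found in ", path)
  if (is.null(covariates)) covariates <- setdiff(names(df), response)
  missing_cols <- setdiff(covariates, names(df))
  if (length(missing_cols))
    stop("covariate column(s) not found: ", paste(missing_cols, collapse = ", "))
  cols <- df[, c(response, covariates), drop = FALSE]
  for (nm in names(cols)) {
    if (!is.numeric(cols[[nm]]))
      stop("column '", nm, "' is not numeric")
  }
  bad <- which(!stats::complete.cases(cols))
  if (length(bad))
    stop("missing values in row(s): ", paste(bad, collapse = ", "))
  X <- as.matrix(cols[, covariates, drop = FALSE])
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) < ncol(X) + 1)
    stop("fewer than p + 1 complete rows (n = ", nrow(X),
         ", p = ", ncol(X), ")")
  list(X = X, y = as.numeric(cols[[response]]))
}

#' Read a linear-hypothesis specification from a YAML config
#'
#' The config holds either an explicit hypothesis (`H`: list of rows of the
#' p x q matrix, `b`: p-vector) or the shorthand `test: all` with `b`,
#' meaning `H = I`.
#'
#' @param path YAML file path.
#' @return a `"linear_hypothesis"`.
#' @export
read_hypothesis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$b)) stop("hypothesis config must provide 'b'")
  b <- as.numeric(cfg$b)
  if (!is.null(cfg$test) && identical(cfg$test, "all"))
    return(linear_hypothesis(diag(length(b)), b))
  if (is.null(cfg$H)) stop("hypothesis config must provide 'H' or 'test: all'")
  H <- do.call(rbind, lapply(cfg$H, as.numeric))
  linear_hypothesis(H, b)
}

#' Write a test result or simulation report to disk
#'
#' JSON output round-trips all numeric fields at full precision; CSV output
#' (simulation reports only) writes the report columns in their documented
#' order.
#'
#' @param result an `"m_test"` or `"sim_report"` object.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return invisibly, the path.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    if (inherits(result, "m_test")) {
      payload <- list(
        M_n = result$M_n, lambda_hat = result$lambda_hat,
        sigma2_hat = result$sigma2_hat, h = result$h, d_n = result$d_n,
        statistic = result$statistic, df = result$df, alpha = result$alpha,
        region = result$region, lower_crit = result$lower_crit,
        upper_crit = result$upper_crit, p_value = result$p_value,
        reject = result$reject, loss = result$loss$name,
        coef_unrestricted = as.numeric(stats::coef(result$fit_unrestricted)),
        coef_restricted = as.numeric(stats::coef(result$fit_restricted)))
      if (!is.null(result$noncentrality)) {
        payload$noncentrality <- result$noncentrality
        payload$power_theoretical <- result$power_theoretical
      }
    } else if (inherits(result, "sim_report")) {
      cfg <- attr(result, "config")
      payload <- list(report = as.data.frame(result),
                      settings = cfg[c("n", "reps", "design", "losses",
                                       "beta_true", "alpha_levels", "seed")])
    } else stop("unsupported result type: ", class(result)[1])
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    if (!inherits(result, "sim_report"))
      stop("csv output is supported for simulation reports only")
    utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  }
  invisible(path)
}
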