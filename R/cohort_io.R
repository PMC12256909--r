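#' Construct a cohort table
#'
#' The screening input: one row per individual with a continuous phenotype,
#' a polygenic score (PGS), and zero or more adjustment covariates.
#' Covariate columns with zero variance are dropped with a warning --
#' intercepts are implicit in every downstream fit and are never stored.
#'
#' @param phenotype numeric vector of trait values.
#' @param pgs numeric vector of polygenic scores.
#' @param covariates numeric matrix (or NULL) with named columns, one per
#'   adjustment covariate.
#' @param sample_id optional character vector of per-row identifiers.
#' @param exposure optional binary vector carried along for stratification
#'   experiments; not used as a covariate unless named in `covariates`.
#' @return an object of class `cohort_table`.
#' @export
cohort_table <- function(phenotype, pgs, covariates = NULL, sample_id = NULL,
                         exposure = NULL) {
  phenotype <- as.numeric(phenotype)
  pgs <- as.numeric(pgs)
  n <- length(phenotype)
  if (n < 1L) stop("cohort must contain at least one row")
  if (length(pgs) != n) stop("phenotype and pgs lengths differ")
  if (anyNA(phenotype) || anyNA(pgs)) {
    stop("missing values in phenotype or pgs; filter rows before construction")
  }
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  if (length(sample_id) != n) stop("sample_id length mismatch")

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate row count differs from phenotype")
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    storage.mode(covariates) <- "double"
    if (anyNA(covariates) || any(!is.finite(covariates))) {
      stop("covariates must be finite with no missing values")
    }
    keep <- apply(covariates, 2L, function(x) stats::var(x) > 0)
    if (!all(keep)) {
      warning(
        "dropping constant covariate column(s): ",
        paste(colnames(covariates)[!keep], collapse = ", ")
      )
      covariates <- covariates[, keep, drop = FALSE]
    }
    if (ncol(covariates) == 0L) covariates <- NULL
  }

  structure(
    list(
      sample_id = as.character(sample_id),
      phenotype = phenotype,
      pgs = pgs,
      covariates = covariates,
      exposure = if (!is.null(exposure)) as.numeric(exposure) else NULL,
      n = n
    ),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  k <- if (is.null(x$covariates)) 0L else ncol(x$covariates)
  cat(
    "<cohort_table> n =", x$n, "individuals,", k, "covariate(s)",
    if (!is.null(x$exposure)) "(+ exposure column)" else "", "\n"
  )
  invisible(x)
}

#' Read a cohort table from delimited text
#'
#' Reads a TSV or CSV file (header required; dialect auto-detected from the
#' file extension unless `sep` is given), selects the columns named in
#' `column_spec`, and keeps only rows complete in all selected columns.
#' The number of dropped rows is logged with [message()].
#'
#' @param path file path to a delimited text file with a header row.
#' @param column_spec named list with entries `phenotype`, `pgs` (single
#'   column names), optionally `covariates` (character vector), `id` and
#'   `exposure` (single column names).
#' @param sep field separator; `NULL` (default) auto-detects `","` for
#'   `.csv` and `"\t"` otherwise.
#' @param quiet suppress the dropped-row log message.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, column_spec, sep = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.null(column_spec$phenotype) || is.null(column_spec$pgs)) {
    stop("column_spec must name 'phenotype' and 'pgs' columns")
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  dt <- data.table::fread(
    path,
    sep = sep, header = TRUE, data.table = FALSE,
    na.strings = c("", "NA", "NaN"), showProgress = FALSE
  )
  covar_names <- column_spec$covariates %||% character(0)
  wanted <- c(
    column_spec$phenotype, column_spec$pgs, covar_names,
    column_spec$id, column_spec$exposure
  )
  missing_cols <- setdiff(wanted, names(dt))
  if (length(missing_cols) > 0L) {
    stop("column(s) absent from ", path, ": ", paste(missing_cols, collapse = ", "))
  }

  numeric_cols <- c(column_spec$phenotype, column_spec$pgs, covar_names)
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(dt[[cn]]))
    if (all(is.na(v)) && nrow(dt) > 0L) {
      stop("column '", cn, "' contains no numeric values")
    }
    dt[[cn]] <- v
  }

  complete <- stats::complete.cases(dt[, numeric_cols, drop = FALSE])
  n_dropped <- sum(!complete)
  if (!quiet) {
    message("read_cohort: ", sum(complete), " rows kept, ", n_dropped, " dropped")
  }
  if (sum(complete) == 0L) stop("zero complete rows in ", path)
  dt <- dt[complete, , drop = FALSE]

  cohort_table(
    phenotype = dt[[column_spec$phenotype]],
    pgs = dt[[column_spec$pgs]],
    covariates = if (length(covar_names) > 0L) {
      as.matrix(dt[, covar_names, drop = FALSE])
    } else {
      NULL
    },
    sample_id = if (!is.null(column_spec$id)) {
      as.character(dt[[column_spec$id]])
    } else {
      NULL
    },
    exposure = if (!is.null(column_spec$exposure)) {
      as.numeric(dt[[column_spec$exposure]])
    } else {
      NULL
    }
  )
}

#' Diagnose trait suitability for quantile-regression screening
#'
#' Quantile regression of a residualized trait is uninformative for binary
#' outcomes and unreliable for heavily tied or few-valued traits: most
#' quantile-specific slopes are then driven by the spacing of isolated
#' modes rather than by score-trait association.  The verdict never aborts
#' the pipeline; it annotates the report.
#'
#' @param cohort a [cohort_table()] or a numeric phenotype vector.
#' @param max_distinct traits with between 3 and this many distinct values
#'   are flagged `warn_discrete` (default 20).
#' @param max_tie_fraction modal-value share above which `warn_discrete` is
#'   raised (default 0.10).
#' @return list with `n_distinct`, `max_tie_fraction`, `verdict` (one of
#'   `"ok"`, `"warn_discrete"`, `"warn_binary"`).
#' @export
check_trait_suitability <- function(cohort, max_distinct = 20,
                                    max_tie_fraction = 0.10) {
  y <- if (inherits(cohort, "cohort_table")) cohort$phenotype else as.numeric(cohort)
  tab <- table(y)
  n_distinct <- length(tab)
  tie_frac <- max(tab) / length(y)
  verdict <- if (n_distinct == 2L) {
    "warn_binary"
  } else if (n_distinct > 2L && n_distinct <= max_distinct ||
    tie_frac > max_tie_fraction) {
    "warn_discrete"
  } else {
    "ok"
  }
  structure(
    list(
      n_distinct = n_distinct,
      max_tie_fraction = as.numeric(tie_frac),
      verdict = verdict
    ),
    class = "suitability_diagnostic"
  )
}

#' Write a screening report to JSON and TSV
#'
#' Writes `<path_prefix>.json` (the full machine-readable report including
#' a metadata block) and `<path_prefix>.tsv` (one row per quantile: tau,
#' beta_tau, se, ci_low, ci_high, ratio, ratio_ci_low, ratio_ci_high,
#' flagged at the report's primary lambda).  Numeric fields round-trip at
#' 12 significant digits.
#'
#' @param report a `screen_report` from [screen_cohort()].
#' @param path_prefix output path prefix (directories must exist).
#' @return invisibly, the two file paths.
#' @export
write_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "screen_report"))
  json_path <- paste0(path_prefix, ".json")
  tsv_path <- paste0(path_prefix, ".tsv")

  jsonlite::write_json(
    report_as_list(report), json_path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
  )

  tab <- report_quantile_table(report)
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "flagged"
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.table(
    tab, tsv_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Read back a JSON screening report
#'
#' @param path path to a `.json` file written by [write_report()].
#' @return the report as a plain nested list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# flat per-quantile view of a screen_report (flags at the primary lambda)
report_quantile_table <- function(report) {
  prof <- report$profile
  primary <- report$noneq[[as.character(report$config$lambda)]]
  z <- ci_z(report$config$alpha)
  beta_se <- report$boot$beta_se[-1L]
  data.frame(
    tau = prof$grid$taus,
    beta_tau = prof$beta_tau,
    se = beta_se,
    ci_low = prof$beta_tau - z * beta_se,
    ci_high = prof$beta_tau + z * beta_se,
    ratio = primary$ratios,
    ratio_ci_low = primary$ci_low,
    ratio_ci_high = primary$ci_high,
    flagged = primary$flags
  )
}

report_as_list <- function(report) {
  list(
    metadata = list(
      tool = "pgsqr",
      version = as.character(utils::packageVersion("pgsqr")),
      seed = report$config$seed,
      config = report$config[setdiff(names(report$config), "taus")],
      taus = report$profile$grid$taus
    ),
    n = report$n,
    suitability = unclass(report$suitability),
    profile = list(
      taus = report$profile$grid$taus,
      beta_ols = report$profile$beta_ols,
      r2_ols = report$profile$r2_ols,
      beta_tau = report$profile$beta_tau,
      intercept_tau = report$profile$intercept_tau,
      r2_tau = report$profile$r2_tau,
      unstable_tau = report$profile$unstable_tau
    ),
    bootstrap = list(
      m = report$boot$m, n = report$boot$n, B = report$boot$B,
      seed = report$boot$seed,
      beta_se = report$boot$beta_se,
      ratio_se = report$boot$ratio_se,
      ratio_mean = report$boot$ratio_mean,
      n_dropped_ratio = report$boot$n_dropped_ratio
    ),
    ratios = report$ratios,
    noneq = lapply(report$noneq, unclass),
    flag_table = report$flag_table,
    trend = unclass(report$trend),
    crossing = report$crossing
  )
}
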