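#' Person-level cost-effectiveness dataset
#'
#' Container for person-level trial data: one record per patient carrying a
#' binary treatment indicator (`tx`, 1 = new treatment, 0 = usual care), a
#' cost in currency units, an effect (typically QALYs), and any number of
#' covariates (numeric or categorical).  All downstream analyses — the cost,
#' effect and net benefit regressions, WTP sweeps, CEACs and subgroup models —
#' consume this container.
#'
#' Categorical covariates are stored with a deterministic level order
#' (first appearance in the data), which fixes the reference level used for
#' dummy coding in adjusted fits.
#'
#' @param tx integer/numeric vector of 0/1 treatment indicators.
#' @param cost numeric vector of per-patient costs (non-negative unless
#'   `allow_negative_cost = TRUE`).
#' @param effect numeric vector of per-patient effects (QALYs).
#' @param id optional character vector of patient identifiers; generated
#'   (`"P0001"`, ...) when omitted.
#' @param covariates optional data.frame of per-patient covariates (numeric
#'   or character/factor columns), same row count as `tx`.
#' @param units named character vector labelling the cost and effect scales;
#'   labels are carried for reporting only, the arithmetic is unit-agnostic.
#' @param allow_negative_cost allow negative per-patient costs (credits).
#'   Off by default so that likely data errors fail loudly.
#'
#' @return An object of class `ce_dataset`.
#' @examples
#' ds <- ce_dataset(tx = c(0, 0, 1, 1),
#'                  cost = c(50, 150, 100, 200),
#'                  effect = c(0.5, 1.5, 1.0, 2.0))
#' arm_summaries(ds)
#' @export
ce_dataset <- function(tx, cost, effect, id = NULL, covariates = NULL,
                       units = c(cost = "dollars", effect = "QALYs"),
                       allow_negative_cost = FALSE) {
  n <- length(tx)
  if (is.null(id)) id <- sprintf("P%04d", seq_len(n))
  id <- as.character(id)
  tx <- as.numeric(tx)
  cost <- as.numeric(cost)
  effect <- as.numeric(effect)
  if (length(cost) != n || length(effect) != n || length(id) != n)
    stop("tx, cost, effect and id must have equal length", call. = FALSE)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_len(n))
  } else {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != n)
      stop("covariates must have one row per patient", call. = FALSE)
  }
  schema <- infer_covariate_schema(covariates)
  # freeze categorical columns as factors with first-appearance level order
  for (nm in names(schema)) {
    if (schema[[nm]]$type == "categorical") {
      covariates[[nm]] <- factor(as.character(covariates[[nm]]),
                                 levels = schema[[nm]]$levels)
    }
  }
  ds <- structure(
    list(id = id, tx = tx, cost = cost, effect = effect,
         covariates = covariates, covariate_schema = schema,
         units = units),
    class = "ce_dataset"
  )
  validate_ce_dataset(ds, allow_negative_cost = allow_negative_cost)
  ds
}

infer_covariate_schema <- function(covariates) {
  schema <- list()
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.numeric(x)) {
      schema[[nm]] <- list(type = "numeric")
    } else {
      lev <- if (is.factor(x)) levels(droplevels(x)) else unique(as.character(x))
      schema[[nm]] <- list(type = "categorical", levels = lev)
    }
  }
  schema
}

validate_ce_dataset <- function(ds, allow_negative_cost = FALSE) {
  if (anyNA(ds$tx) || !all(ds$tx %in% c(0, 1)))
    stop("treatment indicator must be 0 or 1 for every record", call. = FALSE)
  bad <- !is.finite(ds$cost)
  if (any(bad))
    stop("missing or non-finite cost at row(s) ", paste(which(bad), collapse = ", "),
         "; complete cases are required (no imputation is performed)", call. = FALSE)
  bad <- !is.finite(ds$effect)
  if (any(bad))
    stop("missing or non-finite effect at row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  if (!allow_negative_cost && any(ds$cost < 0))
    stop("negative cost at row(s) ", paste(which(ds$cost < 0), collapse = ", "),
         "; pass allow_negative_cost = TRUE if credits are genuine", call. = FALSE)
  n_arm <- table(factor(ds$tx, levels = c(0, 1)))
  if (any(n_arm < 2))
    stop("each arm (tx = 0 and tx = 1) needs at least 2 records; got ",
         n_arm[["0"]], " control and ", n_arm[["1"]], " treated", call. = FALSE)
  if (anyNA(ds$covariates))
    stop("missing covariate values are not allowed", call. = FALSE)
  invisible(ds)
}

#' Read a person-level cost-effectiveness dataset from delimited text
#'
#' Reads a header-bearing delimited file (CSV by default) and maps its columns
#' onto the `ce_dataset` fields.  Rows are kept in file order; categorical
#' covariates receive first-appearance level ordering.  Parsing is strict:
#' a missing mapped column is a schema error, a non-numeric or empty cost or
#' effect cell is a parse error naming the offending row, and a treatment
#' value outside \{0, 1\} is a validation error.  No rows are silently
#' dropped or imputed.
#'
#' @param path file path.
#' @param schema named list mapping dataset fields to column names; entries
#'   `tx`, `cost`, `effect` are required, `id` and `covariates` (character
#'   vector of column names) optional.
#' @param delim single-character field delimiter.
#' @inheritParams ce_dataset
#' @return A validated [ce_dataset].
#' @export
read_ce_csv <- function(path,
                        schema = list(tx = "tx", cost = "cost", effect = "effect"),
                        delim = ",", allow_negative_cost = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = FALSE,
                           stringsAsFactors = FALSE)
  need <- c(tx = schema$tx %||% "tx", cost = schema$cost %||% "cost",
            effect = schema$effect %||% "effect")
  missing_cols <- setdiff(unname(need), names(raw))
  covs <- schema$covariates %||% character()
  missing_cols <- c(missing_cols, setdiff(covs, names(raw)))
  if (!is.null(schema$id)) missing_cols <- c(missing_cols, setdiff(schema$id, names(raw)))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  cost <- parse_numeric_column(raw[[need[["cost"]]]], need[["cost"]])
  effect <- parse_numeric_column(raw[[need[["effect"]]]], need[["effect"]])
  tx_chr <- trimws(raw[[need[["tx"]]]])
  tx <- suppressWarnings(as.numeric(tx_chr))
  if (anyNA(tx) || !all(tx %in% c(0, 1)))
    stop("treatment column '", need[["tx"]], "' must contain only 0 or 1; ",
         "offending row(s): ",
         paste(which(is.na(tx) | !(tx %in% c(0, 1))), collapse = ", "),
         call. = FALSE)

  covariates <- NULL
  if (length(covs)) {
    covariates <- raw[covs]
    for (nm in covs) {
      x <- suppressWarnings(as.numeric(covariates[[nm]]))
      looks_numeric <- !anyNA(x) && all(trimws(covariates[[nm]]) != "")
      covariates[[nm]] <- if (looks_numeric) x else covariates[[nm]]
    }
  }
  id <- if (!is.null(schema$id)) raw[[schema$id]] else NULL
  ce_dataset(tx = tx, cost = cost, effect = effect, id = id,
             covariates = covariates, allow_negative_cost = allow_negative_cost)
}

parse_numeric_column <- function(x, name) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | x == "")
  if (length(bad))
    stop("could not parse numeric '", name, "' at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cost-effectiveness dataset to delimited text
#'
#' Numeric fields are written with 17 significant digits so that a write/read
#' round trip reproduces every value exactly.
#'
#' @param ds a [ce_dataset].
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_ce_csv <- function(ds, path, delim = ",") {
  df <- data.frame(id = ds$id,
                   tx = format_full(ds$tx),
                   cost = format_full(ds$cost),
                   effect = format_full(ds$effect),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(ds$covariates)) {
    x <- ds$covariates[[nm]]
    df[[nm]] <- if (is.numeric(x)) format_full(x) else as.character(x)
  }
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = TRUE)
  invisible(path)
}

format_full <- function(x) sprintf("%.17g", x)

#' Per-arm counts and means
#'
#' Arithmetic means of cost and effect by treatment arm; the building blocks
#' of the incremental estimates (an unadjusted regression on the treatment
#' indicator recovers exactly these mean differences).
#'
#' @param ds a [ce_dataset].
#' @return A tibble with one row per arm: `arm`, `n`, `mean_cost`,
#'   `mean_effect`.
#' @export
arm_summaries <- function(ds) {
  stopifnot(inherits(ds, "ce_dataset"))
  out <- lapply(c(0, 1), function(a) {
    sel <- ds$tx == a
    tibble::tibble(arm = a, n = sum(sel),
                   mean_cost = mean(ds$cost[sel]),
                   mean_effect = mean(ds$effect[sel]))
  })
  do.call(rbind, out)
}

#' Dataset metadata as JSON
#'
#' @param ds a [ce_dataset].
#' @return JSON string with per-arm counts, units and the covariate schema.
#' @export
ce_meta_json <- function(ds) {
  stopifnot(inherits(ds, "ce_dataset"))
  arms <- arm_summaries(ds)
  meta <- list(
    n = length(ds$tx),
    n_per_arm = list("0" = arms$n[arms$arm == 0], "1" = arms$n[arms$arm == 1]),
    units = as.list(ds$units),
    covariate_schema = ds$covariate_schema
  )
  jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
}

#' @export
print.ce_dataset <- function(x, ...) {
  arms <- arm_summaries(x)
  cat("<ce_dataset> ", length(x$tx), " patients (",
      arms$n[1], " control, ", arms$n[2], " treated)\n", sep = "")
  cat("  cost [", x$units[["cost"]], "]  mean by arm: ",
      sprintf("%.2f / %.2f", arms$mean_cost[1], arms$mean_cost[2]), "\n", sep = "")
  cat("  effect [", x$units[["effect"]], "] mean by arm: ",
      sprintf("%.4f / %.4f", arms$mean_effect[1], arms$mean_effect[2]), "\n", sep = "")
  if (length(x$covariate_schema))
    cat("  covariates:", paste(names(x$covariate_schema), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ce_dataset <- function(x, ...) {
  df <- data.frame(id = x$id, tx = x$tx, cost = x$cost, effect = x$effect,
                   stringsAsFactors = FALSE)
  cbind(df, x$covariates)
}

# subset rows, preserving schema (levels stay frozen)
subset_ce <- function(ds, keep) {
  covs <- ds$covariates[keep, , drop = FALSE]
  out <- structure(
    list(id = ds$id[keep], tx = ds$tx[keep], cost = ds$cost[keep],
         effect = ds$effect[keep], covariates = covs,
         covariate_schema = ds$covariate_schema, units = ds$units),
    class = "ce_dataset"
  )
  validate_ce_dataset(out, allow_negative_cost = TRUE)
  out
}
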