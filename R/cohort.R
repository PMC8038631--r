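#' Cohort measurement columns, in reporting order
#'
#' Column order used throughout the package for descriptive tables:
#' the six covariates followed by the MUAC response.
#' @keywords internal
cohort_columns <- function() {
  c("age", "height", "weight", "hemoglobin", "protein", "albumen", "muac")
}

#' Construct a validated cohort table
#'
#' A cohort table holds one row per child: age (years), height (cm),
#' weight (kg), hemoglobin, total protein and albumen (clinical
#' concentrations as reported), and the MUAC response (cm). All values must
#' be strictly positive and finite; rows containing missing values are
#' dropped with a message stating how many were removed.
#'
#' @param data a data.frame containing at least the columns
#'   `age`, `height`, `weight`, `hemoglobin`, `protein`, `albumen`, `muac`.
#' @return a `cohort_table` (a data.frame with columns in reporting order).
#' @examples
#' cohort_table(data.frame(age = 2, height = 80, weight = 10,
#'                         hemoglobin = 10, protein = 65, albumen = 36,
#'                         muac = 13))
#' @export
cohort_table <- function(data) {
  if (!is.data.frame(data)) {
    stop("cohort_table: `data` must be a data.frame", call. = FALSE)
  }
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[cols]
  for (cl in cols) {
    if (!is.numeric(data[[cl]])) {
      stop("cohort_table: column '", cl, "' is not numeric", call. = FALSE)
    }
  }
  if (nrow(data) > 0) {
    complete <- stats::complete.cases(data)
    if (any(!complete)) {
      message(sprintf("cohort_table: dropped %d row(s) with missing values",
                      sum(!complete)))
      data <- data[complete, , drop = FALSE]
    }
    for (cl in cols) {
      v <- data[[cl]]
      if (any(!is.finite(v)) || any(v <= 0)) {
        stop("cohort_table: column '", cl,
             "' contains non-positive or non-finite values", call. = FALSE)
      }
    }
  }
  rownames(data) <- NULL
  class(data) <- c("cohort_table", "data.frame")
  data
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d children, %d measurements per child\n",
              nrow(x), ncol(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' Expects a UTF-8 CSV with a header row naming exactly the columns
#' `age, height, weight, hemoglobin, protein, albumen, muac` (any order,
#' "." as decimal separator). Duplicate headers are rejected. MUAC recorded
#' in millimetres can be converted on ingestion.
#'
#' @param path path to the CSV file.
#' @param muac_unit unit of the `muac` column in the file; `"mm"` converts
#'   to centimetres on ingestion. Default `"cm"` (no conversion).
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path, muac_unit = c("cm", "mm")) {
  muac_unit <- match.arg(muac_unit)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header)) {
    stop("read_cohort: duplicate column header(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  data <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (muac_unit == "mm" && "muac" %in% names(data)) {
    data$muac <- data$muac / 10
  }
  cohort_table(data)
}

#' Write a cohort table to CSV at full precision
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces every double exactly.
#'
#' @param table a [cohort_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  out <- as.data.frame(lapply(table, function(v) {
    sprintf("%.17g", v)
  }), stringsAsFactors = FALSE)
  names(out) <- names(table)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics for a cohort
#'
#' One row per measurement (covariates then MUAC, in reporting order) with
#' minimum, maximum, mean, median, standard deviation (n - 1 denominator)
#' and count.
#'
#' @param table a [cohort_table()] with at least one row.
#' @return a data.frame with columns
#'   `variable, minimum, maximum, mean, median, sd, n`.
#' @export
describe_cohort <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) == 0) {
    stop("describe_cohort: empty cohort table", call. = FALSE)
  }
  rows <- lapply(cohort_columns(), function(cl) {
    v <- table[[cl]]
    data.frame(variable = cl, minimum = min(v), maximum = max(v),
               mean = mean(v), median = stats::median(v),
               sd = stats::sd(v), n = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations with significance flags
#'
#' Computes the Pearson correlation matrix over all cohort columns, with
#' two-sided p-values from the t transform `t = r * sqrt(n - 2) /
#' sqrt(1 - r^2)` on `n - 2` degrees of freedom, and significance flags
#' `"*"` (p < 0.05) and `"**"` (p < 0.01). Diagonal p-values are `NA`.
#'
#' @param table a [cohort_table()] with at least 3 rows and no constant
#'   column.
#' @return an object of class `cohort_correlations`: a list with `labels`,
#'   `r`, `p`, `flags` and `n`.
#' @export
cohort_correlations <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  n <- nrow(table)
  if (n < 3) stop("cohort_correlations: need at least 3 rows", call. = FALSE)
  labels <- cohort_columns()
  for (cl in labels) {
    if (stats::sd(table[[cl]]) == 0) {
      stop("cohort_correlations: column '", cl, "' is constant",
           call. = FALSE)
    }
  }
  m <- as.matrix(as.data.frame(table)[labels])
  r <- stats::cor(m)
  # clamp tiny numerical overshoot before the t transform
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.finite(tstat)] <- 0
  diag(p) <- NA_real_
  flags <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  flags[!is.na(p) & p < 0.05] <- "*"
  flags[!is.na(p) & p < 0.01] <- "**"
  structure(list(labels = labels, r = r, p = p, flags = flags, n = n),
            class = "cohort_correlations")
}

#' @export
print.cohort_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations (n = %d)\n", x$n))
  shown <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                         ifelse(x$flags == "", "", " "), x$flags),
                  nrow(x$r), dimnames = dimnames(x$r))
  shown[upper.tri(shown)] <- ""
  print(shown, quote = FALSE)
  cat("*  p < 0.05, ** p < 0.01 (two-sided)\n")
  invisible(x)
}
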