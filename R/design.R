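#' Default model terms
#'
#' The ten-coefficient term list used for both the mean and the dispersion
#' submodels: the six covariates plus the three pairwise interactions among
#' the anthropometric measurements, in the fixed reporting order (intercept
#' implicit and always first).
#'
#' @return character vector of nine term labels (the intercept is implicit).
#' @export
default_terms <- function() {
  c("age", "weight", "height", "hemoglobin", "protein", "albumen",
    "weight:height", "age:weight", "age:height")
}

# split "a:b" into its parent covariate names; a main effect returns itself
term_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Build a design matrix from a term list
#'
#' Columns are the intercept (all ones) followed by one column per term in
#' the given order. A term is either a covariate name or `a:b`, the
#' elementwise product of two covariate columns. Term labels must be unique
#' and reference existing cohort columns.
#'
#' @param table a [cohort_table()] with at least one row.
#' @param terms character vector of term labels; `character(0)` gives an
#'   intercept-only design.
#' @return an n x (1 + length(terms)) numeric matrix with column labels
#'   `"(Intercept)"` followed by `terms`.
#' @examples
#' tab <- cohort_table(data.frame(age = c(1, 2), height = c(70, 80),
#'   weight = c(8, 10), hemoglobin = c(10, 11), protein = c(60, 65),
#'   albumen = c(30, 35), muac = c(12, 14)))
#' build_design(tab, c("weight", "weight:height"))
#' @export
build_design <- function(table, terms = default_terms()) {
  stopifnot(inherits(table, "cohort_table"))
  n <- nrow(table)
  if (n < 1) stop("build_design: empty cohort table", call. = FALSE)
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    stop("build_design: duplicate term label(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "),
         call. = FALSE)
  }
  covariates <- setdiff(cohort_columns(), "muac")
  cols <- lapply(terms, function(tm) {
    parents <- term_parents(tm)
    unknown <- setdiff(parents, covariates)
    if (length(unknown) > 0) {
      stop("build_design: unknown covariate '", unknown[1],
           "' in term '", tm, "'", call. = FALSE)
    }
    if (length(parents) == 1) {
      table[[parents]]
    } else if (length(parents) == 2) {
      table[[parents[1]]] * table[[parents[2]]]
    } else {
      stop("build_design: term '", tm,
           "' has more than two factors; only pairwise interactions are supported",
           call. = FALSE)
    }
  })
  if (length(terms) == 0) {
    X <- matrix(1, n, 1)
  } else {
    X <- cbind(1, do.call(cbind, cols))
  }
  colnames(X) <- c("(Intercept)", terms)
  X
}
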