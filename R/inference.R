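# Wald coefficient tables, the backward-elimination screen, and
# model-criteria comparison.

star_rule <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Wald coefficient table
#'
#' One row per coefficient with the Wald statistic `t = estimate / se`, a
#' two-sided p-value from the standard normal (the large-sample Z
#' approximation; pass a finite `df` for a t reference instead), and
#' significance stars `***` (p < 0.001), `**` (p < 0.01), `*` (p < 0.05).
#'
#' @param estimate coefficient estimates (names used as term labels when
#'   `labels` is missing).
#' @param se strictly positive standard errors, same length.
#' @param labels term labels.
#' @param df degrees of freedom for the reference distribution; `Inf`
#'   (default) uses the standard normal.
#' @return a data.frame of class `wald_table` with columns
#'   `term, estimate, se, t, p, stars`.
#' @examples
#' wald_table(c(weight = 1.194023), c(0.127182))  # t = 9.388
#' @export
wald_table <- function(estimate, se, labels = names(estimate), df = Inf) {
  if (length(estimate) != length(se)) {
    stop("wald_table: estimate and se have different lengths", call. = FALSE)
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("wald_table: standard errors must be strictly positive and finite",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("b", seq_along(estimate))
  t <- estimate / se
  p <- if (is.infinite(df)) 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df = df)
  out <- data.frame(term = labels, estimate = unname(estimate),
                    se = unname(se), t = unname(t), p = unname(p),
                    stars = star_rule(unname(p)), stringsAsFactors = FALSE)
  class(out) <- c("wald_table", "data.frame")
  out
}

#' @export
print.wald_table <- function(x, digits = 4, ...) {
  shown <- data.frame(term = x$term,
                      estimate = formatC(x$estimate, digits = 6, format = "g"),
                      se = formatC(x$se, digits = 6, format = "g"),
                      t = formatC(x$t, digits = digits, format = "f"),
                      p = formatC(x$p, digits = 4, format = "g"),
                      ` ` = x$stars, check.names = FALSE)
  print.data.frame(shown, row.names = FALSE, right = TRUE)
  invisible(x)
}

#' Refitters for the backward-elimination screen
#'
#' `refit_glm(table, terms)` fits the constant-dispersion Gaussian GLM
#' (intercept-only dispersion) and returns its mean-model [wald_table()];
#' `refit_joint_with(disp_terms, method)` returns such a refitter for the
#' joint model with a fixed dispersion term list.
#'
#' @param table a [cohort_table()].
#' @param terms mean-model term labels.
#' @return a [wald_table()] for the mean coefficients.
#' @export
refit_glm <- function(table, terms) {
  fit <- fit_joint(table, mean_terms = terms, disp_terms = character(0),
                   method = "ML")
  wald_table(fit$mean_fit$beta, fit$mean_fit$se)
}

#' @rdname refit_glm
#' @param disp_terms dispersion term labels held fixed across refits.
#' @param method passed to [fit_joint()].
#' @export
refit_joint_with <- function(disp_terms = default_terms(),
                             method = "REML") {
  force(disp_terms); force(method)
  function(table, terms) {
    fit <- fit_joint(table, mean_terms = terms, disp_terms = disp_terms,
                     method = method)
    wald_table(fit$mean_fit$beta, fit$mean_fit$se)
  }
}

#' Backward-elimination term screen
#'
#' Iteratively refits and removes the single least significant term whose
#' p-value is at or above the retention threshold, stopping when every
#' remaining term has p below it. The intercept is never dropped, and a
#' main effect is protected while any of its interactions survives. Ties on
#' p are broken by the lexicographically smaller label; the outcome is
#' independent of candidate ordering.
#'
#' @param table a [cohort_table()].
#' @param candidates candidate term labels (non-empty).
#' @param threshold retention p-value in (0, 1); terms with `p >= threshold`
#'   are eligible for removal (default 0.2).
#' @param refit a function `(table, terms) ->` data.frame with columns
#'   `term` and `p` (a [wald_table()] qualifies). Default [refit_glm()].
#' @return the surviving term labels, in their original order.
#' @export
backward_eliminate <- function(table, candidates, threshold = 0.2,
                               refit = refit_glm) {
  if (is.null(candidates)) {
    stop("backward_eliminate: candidates must not be NULL", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("backward_eliminate: threshold must be in (0, 1)", call. = FALSE)
  }
  # an intercept-only candidate list has nothing eliminable
  if (length(candidates) == 0) return(character(0))
  terms <- sort(as.character(candidates))
  original <- as.character(candidates)
  repeat {
    if (length(terms) == 0) break
    wt <- tryCatch(refit(table, terms), error = function(e) {
      stop(errorCondition(
        paste0("backward_eliminate: refit failed: ", conditionMessage(e)),
        surviving_terms = original[original %in% terms],
        class = c("muacjglm_refit_error", "error", "condition")))
    })
    wt <- wt[wt$term != "(Intercept)", , drop = FALSE]
    interactions <- terms[grepl(":", terms, fixed = TRUE)]
    protected <- unique(unlist(lapply(interactions, term_parents)))
    eligible <- wt[wt$p >= threshold &
                     !(wt$term %in% protected & !grepl(":", wt$term)), ,
                   drop = FALSE]
    if (nrow(eligible) == 0) break
    # worst p first; ties broken by lexicographically smaller label
    ord <- order(-eligible$p, eligible$term)
    drop_term <- eligible$term[ord[1]]
    terms <- setdiff(terms, drop_term)
  }
  original[original %in% terms]
}

#' Compare fitted models on the selection criteria
#'
#' One row per criterion (-2h, -2 p_beta(h), cAIC, AIC, BIC) with the value
#' for each fit and the per-criterion winner (lowest value; ties reported
#' explicitly with no winner). When the criteria disagree the overall winner
#' is the model with the lowest AIC.
#'
#' @param fits a list of two or more [fit_joint()] results on the same data.
#' @param labels model labels (default `model1, model2, ...`).
#' @return an object of class `model_comparison`: list with `table` (a
#'   data.frame criterion x model), `best` (winner per criterion, `NA` on
#'   ties) and `overall` (lowest-AIC model, `NA` on an AIC tie).
#' @export
compare_models <- function(fits, labels = NULL) {
  if (!is.list(fits) || length(fits) < 2) {
    stop("compare_models: need at least two fits", call. = FALSE)
  }
  if (!all(vapply(fits, inherits, logical(1), "joint_glm"))) {
    stop("compare_models: all fits must be joint_glm objects", call. = FALSE)
  }
  ns <- vapply(fits, function(f) length(f$y), integer(1))
  if (length(unique(ns)) != 1) {
    stop("compare_models: fits are on different sample sizes", call. = FALSE)
  }
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(f$y, fits[[1]]$y))) {
      stop("compare_models: fits are not on identical response data",
           call. = FALSE)
    }
  }
  if (is.null(labels)) labels <- paste0("model", seq_along(fits))
  crit_names <- c("minus2h", "minus2pbeta", "caic", "aic", "bic")
  pretty <- c("-2h", "-2 p_beta(h)", "cAIC", "AIC", "BIC")
  values <- sapply(fits, function(f) unlist(f$criteria[crit_names]))
  colnames(values) <- labels
  rownames(values) <- pretty
  best <- apply(values, 1, function(v) {
    winners <- which(v == min(v))
    if (length(winners) > 1) NA_character_ else labels[winners]
  })
  tab <- data.frame(criterion = pretty, values, best = unname(best),
                    check.names = FALSE, row.names = NULL)
  structure(list(table = tab, best = best, overall = unname(best["AIC"]),
                 labels = labels),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (lower is better):\n")
  print(x$table, row.names = FALSE, digits = 6)
  if (is.na(x$overall)) {
    cat("Overall: tie on AIC; no winner declared\n")
  } else {
    cat(sprintf("Overall winner (lowest AIC): %s\n", x$overall))
  }
  invisible(x)
}
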