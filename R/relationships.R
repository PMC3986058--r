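#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations with two-sided t-test p-values.
#' A zero-variance variable yields `NA` entries and a warning rather than
#' an error, so one degenerate column cannot sink a whole survey summary.
#'
#' @param data Data frame.
#' @param variables Columns to correlate (default: all numeric columns).
#' @return Object of class `cor_matrix`: list of matrices `r`, `p`, `n`.
#' @export
pearson_matrix <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      xi <- data[[variables[i]]]; xj <- data[[variables[j]]]
      ok <- is.finite(xi) & is.finite(xj)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
        warning(sprintf("zero variance in '%s' or '%s': correlation undefined",
                        variables[i], variables[j]), call. = FALSE)
        next
      }
      ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(n) <- vapply(variables, function(v) sum(is.finite(data[[v]])), numeric(1))
  structure(list(r = r, p = p, n = n), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlations (upper: r, lower: p):\n")
  m <- round(x$r, digits)
  m[lower.tri(m)] <- round(x$p, digits)[lower.tri(m)]
  print(m)
  invisible(x)
}

#' Forward stepwise regression with explained-variance partitioning
#'
#' Forward selection with backward elimination on partial-F p-values: at
#' each step the candidate with the smallest partial-F p-value enters if
#' that p-value is at most `alpha_in`; any included variable whose
#' partial-F p-value rises above `alpha_out` is then removed; the loop
#' stops when nothing changes. Candidates whose entry would make the model
#' matrix ill-conditioned (condition number above `kappa_max`) are skipped
#' with a warning.
#'
#' Explained variance is reported as the sequential R-squared increment of
#' each surviving variable in its entry order (in percent); the increments
#' sum to 100 times the final unadjusted R-squared.
#'
#' @param data Data frame containing response and candidates.
#' @param response Response column name (default `"soc"`).
#' @param candidates Candidate predictor column names.
#' @param alpha_in Entry threshold on the partial-F p-value.
#' @param alpha_out Removal threshold.
#' @param kappa_max Condition-number ceiling for collinearity screening.
#' @return Object of class `stepwise_lm`: list with `variables` (entry
#'   order), `coefficients` (including intercept), `explained_variance`
#'   (%), `r_squared`, `adj_r_squared`, `mse`, `p_values`, and `fit` (the
#'   final `lm`).
#' @export
stepwise_soc <- function(data, response = "soc",
                         candidates = c("stones", "sand", "silt", "clay", "bd"),
                         alpha_in = 0.05, alpha_out = 0.10,
                         kappa_max = 1e8) {
  cols <- c(response, candidates)
  d <- data[, cols, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(candidates) + 2L) {
    stop("too few complete cases for stepwise selection", call. = FALSE)
  }
  included <- character(0)
  skipped <- character(0)
  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, c(included, skipped))
    if (length(pool) > 0L) {
      fit0 <- stats::lm(stats::reformulate(if (length(included)) included else "1",
                                           response), data = d)
      pvals <- rep(NA_real_, length(pool)); names(pvals) <- pool
      for (v in pool) {
        X <- stats::model.matrix(
          stats::reformulate(c(included, v), response), data = d)
        if (kappa(X, exact = TRUE) > kappa_max) {
          warning("candidate '", v, "' skipped: collinear with included variables",
                  call. = FALSE)
          skipped <- c(skipped, v)
          next
        }
        fit1 <- stats::lm(stats::reformulate(c(included, v), response), data = d)
        a <- stats::anova(fit0, fit1) # partial F for adding v
        pvals[v] <- a[["Pr(>F)"]][2]
      }
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) > 0L && min(pvals) <= alpha_in) {
        included <- c(included, names(which.min(pvals)))
        changed <- TRUE
      }
    }
    # backward step
    if (length(included) > 1L) {
      fit <- stats::lm(stats::reformulate(included, response), data = d)
      dr <- stats::drop1(fit, test = "F")
      pv <- stats::setNames(dr[["Pr(>F)"]][-1], rownames(dr)[-1])
      if (length(pv) > 0L && max(pv) > alpha_out) {
        included <- setdiff(included, names(which.max(pv)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(included) == 0L) {
    fit <- stats::lm(stats::reformulate("1", response), data = d)
    return(structure(
      list(variables = character(0),
           coefficients = stats::coef(fit),
           explained_variance = numeric(0),
           r_squared = 0, adj_r_squared = 0,
           mse = stats::deviance(fit) / stats::df.residual(fit),
           p_values = numeric(0), n = n, fit = fit),
      class = "stepwise_lm"
    ))
  }
  fit <- stats::lm(stats::reformulate(included, response), data = d)
  sfit <- summary(fit)
  # sequential R^2 increments in entry order
  sst <- sum((d[[response]] - mean(d[[response]]))^2)
  an <- stats::anova(fit)
  incr <- 100 * an[["Sum Sq"]][seq_along(included)] / sst
  names(incr) <- included
  dr <- stats::drop1(fit, test = "F")
  pv <- stats::setNames(dr[["Pr(>F)"]][-1], rownames(dr)[-1])
  structure(
    list(variables = included,
         coefficients = stats::coef(fit),
         explained_variance = incr,
         r_squared = sfit$r.squared,
         adj_r_squared = sfit$adj.r.squared,
         mse = stats::deviance(fit) / stats::df.residual(fit),
         p_values = pv[included], n = n, fit = fit),
    class = "stepwise_lm"
  )
}

#' @export
print.stepwise_lm <- function(x, ...) {
  if (length(x$variables) == 0L) {
    cat("Stepwise regression: no variable met the entry criterion\n")
    return(invisible(x))
  }
  cat("Stepwise regression (entry order):\n")
  tab <- data.frame(
    variable = x$variables,
    coefficient = unname(x$coefficients[x$variables]),
    explained_variance_pct = unname(x$explained_variance),
    p = unname(x$p_values)
  )
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Intercept %.4g; adjusted R^2 = %.3f; MSE = %.4g; n = %d\n",
              x$coefficients[1], x$adj_r_squared, x$mse, x$n))
  invisible(x)
}

#' @export
coef.stepwise_lm <- function(object, ...) object$coefficients

#' @export
predict.stepwise_lm <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}
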