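#' Descriptive summary of one layer's values
#'
#' Minimum, maximum, mean, median, SD (n - 1 denominator), CV in percent,
#' small-sample-adjusted skewness and excess kurtosis (the type-2 formulas
#' of \code{\link[e1071]{skewness}} used by mainstream statistics
#' packages), and the one-sample Kolmogorov-Smirnov normality test. The
#' `log_transform` flag applies the rule used throughout the pipeline:
#' transform when the raw-scale K-S test rejects normality at 0.05 but the
#' ln-scale test does not.
#'
#' Constant samples get skewness and kurtosis 0 by convention and no K-S
#' test (the test is undefined for a degenerate distribution).
#'
#' @param x Numeric vector, finite, length >= 2.
#' @return One-row data frame with columns `n`, `min`, `max`, `mean`,
#'   `median`, `sd`, `cv` (%), `skewness`, `kurtosis`, `ks_D`, `ks_p`,
#'   `log_transform`.
#' @export
#' @examples
#' summarize_layer(c(1, 2, 3)) # mean 2, sd 1, cv 50
summarize_layer <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  constant <- s == 0
  skew <- if (constant) 0 else if (n >= 3L) e1071::skewness(x, type = 2) else NA_real_
  kurt <- if (constant) 0 else if (n >= 4L) e1071::kurtosis(x, type = 2) else NA_real_
  if (!constant && n >= 5L) {
    ks <- ks_normality(x)
    ks_ln <- if (all(x > 0)) ks_normality(log(x)) else list(p = NA_real_)
    logt <- isTRUE(ks$p <= 0.05 && !is.na(ks_ln$p) && ks_ln$p > 0.05)
  } else {
    ks <- list(D = NA_real_, p = NA_real_)
    logt <- FALSE
  }
  data.frame(
    n = n, min = min(x), max = max(x), mean = m, median = stats::median(x),
    sd = s, cv = 100 * s / m, skewness = skew, kurtosis = kurt,
    ks_D = ks$D, ks_p = ks$p, log_transform = logt
  )
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' `D` is the supremum distance between the empirical CDF and the normal
#' CDF with mean and SD estimated from the sample; `p` comes from the
#' asymptotic Kolmogorov distribution. Estimating the parameters from the
#' data makes this anticonservative (the Lilliefors issue); set
#' `lilliefors = TRUE` for the corrected test
#' (\code{\link[nortest]{lillie.test}}).
#'
#' @param x Numeric vector, length >= 5, non-degenerate.
#' @param lilliefors Use the Lilliefors-corrected p-value.
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop("need at least 5 values for the K-S test", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate distribution: zero variance", call. = FALSE)
  if (lilliefors) {
    t <- nortest::lillie.test(x)
    return(list(D = unname(t$statistic), p = unname(t$p.value)))
  }
  t <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x), exact = FALSE))
  list(D = unname(t$statistic), p = unname(t$p.value))
}

# insert-and-absorb compact letter display from a logical "significantly
# different" matrix; groups ordered as given (assumed sorted by mean desc)
.cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (s in seq_along(sets)) {
        if (all(c(i, j) %in% sets[[s]])) {
          a <- setdiff(sets[[s]], i)
          b <- setdiff(sets[[s]], j)
          sets[[s]] <- a
          sets[[length(sets) + 1L]] <- b
        }
      }
      # absorb: drop sets contained in another
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] &&
              all(sets[[s]] %in% sets[[t]]) &&
              (length(sets[[s]]) < length(sets[[t]]) || s > t)) {
            keep[s] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  # order letters by the best-ranked member of each set
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- character(k)
  for (s in seq_along(sets)) {
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  }
  letters_out
}

#' One-way ANOVA with LSD mean separation and compact letter display
#'
#' Fisher's protected-style least-significant-difference comparison: a
#' one-way ANOVA provides the pooled mean squared error, every pair of
#' groups is compared with an unadjusted t-test on that pooled MSE, and
#' letters are assigned by the insert-and-absorb compact-letter-display
#' algorithm with means sorted descending. Groups sharing any letter are
#' not significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `anova_lsd`: data frame `means` (group, n,
#'   mean, letters, in descending mean order) plus `F`, `p`, `mse`, `df`,
#'   `alpha`.
#' @export
#' @examples
#' anova_lsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12)))
anova_lsd <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  fit <- stats::aov(y ~ f)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2]
  df <- an[["Df"]][2]
  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, numeric(1))
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  sig <- matrix(FALSE, k, k)
  if (mse > 0) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        lsd <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
        sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd
      }
    }
  } else {
    sig[] <- outer(means, means, "!=")
  }
  structure(
    list(means = data.frame(group = names(means), n = ns, mean = means,
                            letters = .cld_insert_absorb(sig),
                            row.names = NULL, stringsAsFactors = FALSE),
         F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
         mse = mse, df = df, alpha = alpha),
    class = "anova_lsd"
  )
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g (pooled MSE %.4g, df %d)\n",
              x$F, x$p, x$mse, x$df))
  cat(sprintf("LSD mean separation at alpha = %g:\n", x$alpha))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Layer-wise descriptive table for a survey
#'
#' Applies [summarize_layer()] to each variable within each depth layer
#' and, for each variable, runs [anova_lsd()] across layers to attach the
#' compact letter display, mirroring the standard summary tables of grid
#' soil surveys.
#'
#' @param samples Sample data frame (see [read_samples()]).
#' @param variables Character vector of numeric columns to summarize.
#' @param alpha Significance level for the LSD letters.
#' @return Data frame, one row per layer x variable, summary columns plus
#'   `lsd_letters`.
#' @export
describe_survey <- function(samples,
                            variables = c("soc", "stones", "sand", "silt",
                                          "clay", "bd"),
                            alpha = 0.05) {
  layers <- intersect(soc_layers(), unique(samples$layer))
  out <- list()
  for (v in variables) {
    groups <- lapply(layers, function(l) samples[[v]][samples$layer == l])
    names(groups) <- layers
    groups <- Filter(function(g) sum(!is.na(g)) >= 2, groups)
    lets <- tryCatch({
      a <- anova_lsd(groups, alpha = alpha)
      stats::setNames(a$means$letters, a$means$group)
    }, error = function(e) stats::setNames(rep(NA_character_, length(groups)),
                                           names(groups)))
    for (l in names(groups)) {
      row <- summarize_layer(groups[[l]])
      row <- cbind(data.frame(variable = v, layer = l,
                              stringsAsFactors = FALSE),
                   row, lsd_letters = unname(lets[l]))
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
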