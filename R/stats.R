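#' Compare one or two samples
#'
#' The comparison machinery behind all cohort analyses. With
#' `test = "auto"`, each sample is first screened for normality
#' (Anderson-Darling for n >= 8, Shapiro-Wilk below) and the comparison is
#' routed to a t-type test when all samples look normal, otherwise to the
#' matching rank test. Any specific test can be pinned instead. Wilcoxon
#' procedures use the exact distribution for n <= 25 and the normal
#' approximation with continuity correction above.
#'
#' @param a Numeric sample.
#' @param b Second sample, or `NULL` for a one-sample comparison of `a`
#'   against `mu`.
#' @param paired Treat `a` and `b` as paired (requires equal lengths).
#' @param test One of `"auto"`, `"paired-t"`, `"unpaired-t"`,
#'   `"one-sample-t"`, `"wilcoxon-signed-rank"`, `"wilcoxon-rank-sum"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (alternatives are about `a` relative to `b`/`mu`).
#' @param mu Null value for one-sample comparisons (default 0).
#' @return A one-row tibble: `test_name`, `sidedness`, `alternative`,
#'   `statistic`, `p`, `n_a`, `n_b`, `routed` (whether auto-routing picked the
#'   test).
#' @examples
#' compare_samples(c(1, 2, 3, 4, 5, 7), c(2, 3, 4, 6, 7, 9), paired = TRUE,
#'                 test = "wilcoxon-signed-rank")
#' @export
compare_samples <- function(a, b = NULL, paired = FALSE, test = "auto",
                            alternative = c("two.sided", "greater", "less"),
                            mu = 0) {
  alternative <- match.arg(alternative)
  tests <- c("auto", "paired-t", "unpaired-t", "one-sample-t",
             "wilcoxon-signed-rank", "wilcoxon-rank-sum")
  if (!test %in% tests) {
    abort(paste0("unknown test '", test, "'"))
  }
  if (paired) {
    if (is.null(b) || length(a) != length(b)) {
      abort("paired comparison needs two samples of equal length")
    }
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]
    b <- b[keep]
  } else {
    a <- a[!is.na(a)]
    if (!is.null(b)) b <- b[!is.na(b)]
  }
  if (length(a) < 2 || (!is.null(b) && length(b) < 2)) {
    abort("insufficient data: each sample needs n >= 2")
  }
  routed <- test == "auto"
  if (routed) {
    normal <- is_normal(a) && (is.null(b) || paired || is_normal(b))
    if (paired) normal <- is_normal(a - b)
    test <- if (is.null(b)) {
      if (normal) "one-sample-t" else "wilcoxon-signed-rank"
    } else if (paired) {
      if (normal) "paired-t" else "wilcoxon-signed-rank"
    } else {
      if (normal) "unpaired-t" else "wilcoxon-rank-sum"
    }
  }
  # degenerate zero-variance inputs: identical paired samples give the null
  # result rather than an error from t.test()
  degenerate <- switch(
    test,
    "one-sample-t" = sd(a - mu) == 0,
    "paired-t" = sd(a - b) == 0,
    "unpaired-t" = sd(c(a - mean(a), b - mean(b))) == 0,
    FALSE
  )
  if (degenerate) {
    delta <- switch(test,
                    "one-sample-t" = mean(a) - mu,
                    "paired-t" = mean(a - b),
                    "unpaired-t" = mean(a) - mean(b))
    pval <- if (delta == 0) 1
            else switch(alternative,
                        two.sided = 0,
                        greater = as.numeric(delta < 0),
                        less = as.numeric(delta > 0))
    res <- list(statistic = if (delta == 0) 0 else Inf * sign(delta),
                p.value = pval)
    return(tibble(test_name = test,
                  sidedness = if (alternative == "two.sided") "two" else "one",
                  alternative = alternative,
                  statistic = res$statistic, p = res$p.value,
                  n_a = length(a),
                  n_b = if (is.null(b)) NA_integer_ else length(b),
                  routed = routed))
  }
  res <- switch(
    test,
    "one-sample-t" = t.test(a, mu = mu, alternative = alternative),
    "paired-t" = t.test(a, b, paired = TRUE, alternative = alternative),
    "unpaired-t" = t.test(a, b, alternative = alternative),
    "wilcoxon-signed-rank" = wilcoxon(a, b, paired = TRUE, mu = mu,
                                      alternative = alternative),
    "wilcoxon-rank-sum" = wilcoxon(a, b, paired = FALSE, mu = mu,
                                   alternative = alternative)
  )
  tibble(
    test_name = test,
    sidedness = if (alternative == "two.sided") "two" else "one",
    alternative = alternative,
    statistic = unname(res$statistic),
    p = min(1, res$p.value),
    n_a = length(a),
    n_b = if (is.null(b)) NA_integer_ else length(b),
    routed = routed
  )
}

is_normal <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (sd(x) == 0) return(FALSE)
  p <- if (length(x) >= 8) nortest::ad.test(x)$p.value
       else shapiro.test(x)$p.value
  p > alpha
}

# wilcox.test wrapper: exact for n <= 25, normal approximation with continuity
# correction above; degenerate all-zero difference vectors get the maximal p.
wilcoxon <- function(a, b, paired, mu, alternative) {
  if (paired && !is.null(b)) { a <- a - b; b <- NULL }
  if (is.null(b)) {
    d <- a - mu
    if (all(d == 0)) return(list(statistic = 0, p.value = 1))
    exact <- sum(d != 0) <= 25 && !any(duplicated(abs(d[d != 0])))
    suppressWarnings(
      wilcox.test(a, mu = mu, alternative = alternative, exact = exact,
                  correct = TRUE))
  } else {
    exact <- length(a) <= 25 && length(b) <= 25 &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      wilcox.test(a, b, mu = mu, alternative = alternative, exact = exact,
                  correct = TRUE))
  }
}

#' Per-animal correlation
#'
#' Computes a correlation per animal and summarizes across animals as
#' mean +/- SEM, matching how cohort correlations are reported (each animal
#' contributes one value). `"pearson-R2"` is the squared Pearson correlation of
#' a linear fit; `"spearman"` is the rank correlation. Incomplete pairs are
#' dropped per animal; animals with fewer than `min_n` complete pairs, or
#' constant input, yield `NA` with a flag.
#'
#' @param data Tibble with one row per (animal, unit) holding the two paired
#'   variables.
#' @param x,y Column names (character) of the paired variables.
#' @param by Grouping column, default `"animal_id"`.
#' @param method `"pearson-R2"` or `"spearman"`.
#' @param min_n Minimum complete pairs per animal (default 3).
#' @return A `correlation_result`: list with `per_animal` (tibble `animal_id`,
#'   `value`, `p`, `n`, `degenerate`), `method`, `mean`, `sem`.
#' @export
correlate <- function(data, x, y, by = "animal_id",
                      method = c("pearson-R2", "spearman"), min_n = 3) {
  method <- match.arg(method)
  per_animal <- data |>
    rename(.x = dplyr::all_of(x), .y = dplyr::all_of(y)) |>
    group_by(.data[[by]]) |>
    summarise(res = list(correlate_one(.data$.x, .data$.y, .env$method,
                                       .env$min_n)),
              .groups = "drop") |>
    tidyr::unnest_wider("res")
  out <- list(per_animal = per_animal, method = method,
              mean = mean_na(per_animal$value), sem = sem_na(per_animal$value))
  class(out) <- "correlation_result"
  out
}

correlate_one <- function(x, y, method, min_n) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  degenerate <- length(x) < min_n || sd(x) == 0 || sd(y) == 0
  if (degenerate) {
    return(list(value = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  }
  if (method == "pearson-R2") {
    ct <- cor.test(x, y, method = "pearson")
    list(value = unname(ct$estimate)^2, p = ct$p.value, n = length(x),
         degenerate = FALSE)
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    list(value = unname(ct$estimate), p = ct$p.value, n = length(x),
         degenerate = FALSE)
  }
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result>", x$method, "| mean =",
      formatC(x$mean, digits = 3, format = "f"), "+/- ",
      formatC(x$sem, digits = 3, format = "f"), "SEM (n =",
      nrow(x$per_animal), "animals)\n")
  invisible(x)
}

#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  mutate(x$per_animal, method = x$method)
}

#' @method glance correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  tibble(method = x$method, mean = x$mean, sem = x$sem,
         n_animals = sum(!is.na(x$per_animal$value)))
}

#' Bonferroni correction
#'
#' Adjusts p-values for `m` comparisons: `p_adj = min(1, p * m)`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @param m Family size; defaults to the number of non-missing p-values.
#' @return Adjusted p-values, never below the raw ones.
#' @examples
#' bonferroni_adjust(c(0.01, 0.5), m = 5)
#' @export
bonferroni_adjust <- function(p, m = sum(!is.na(p))) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  if (m < 1) m <- 1
  pmin(1, p * m)
}

#' One-way ANOVA with Tukey-Kramer comparisons
#'
#' Omnibus one-way ANOVA plus all pairwise comparisons adjusted with the
#' Tukey-Kramer (studentized range, unequal-n) procedure.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @return A list with `omnibus` (tibble `statistic` (F), `df1`, `df2`, `p`)
#'   and `pairwise` (tibble `group1`, `group2`, `diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    abort(paste0("degenerate group (n < 2): ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- aov(values ~ groups, data = data.frame(values = values,
                                                groups = groups))
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  list(
    omnibus = tibble(statistic = an[["F value"]][1], df1 = an[["Df"]][1],
                     df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1]),
    pairwise = tibble(group1 = pairs[, 1], group2 = pairs[, 2],
                      diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
                      upr = unname(tk[, "upr"]),
                      p_adj = unname(tk[, "p adj"]))
  )
}
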