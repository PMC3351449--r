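#' Exact two-tailed Mann-Whitney U test with ties
#'
#' Rank-based two-sample test of whether two groups of ordinal phenotype
#' values (grades or raw scores) are equally severe. U is computed from
#' mid-ranks. For `n1 + n2 <= exact_limit` the two-tailed p value is exact:
#' the complete permutation distribution of U over all
#' `choose(n1 + n2, n1)` group assignments of the observed (possibly tied)
#' values is enumerated and
#' `p = P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|)`. Above the limit, a
#' normal approximation with tie-corrected variance and continuity
#' correction is used; the `method` field records which path ran.
#'
#' @param a,b numeric vectors (non-empty); ties within and across groups are
#'   allowed.
#' @param exact_limit largest `n1 + n2` for which the permutation
#'   distribution is fully enumerated.
#' @return Object of class `axq_test` with `statistic` (U of the first
#'   sample), `U_a`, `U_b`, `p.value`, `method` and sample sizes.
#' @export
mann_whitney_exact <- function(a, b, exact_limit = 20L) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  v <- c(a, b)
  r <- rank(v)  # mid-ranks for ties
  U_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U_b <- n1 * n2 - U_a
  mu <- n1 * n2 / 2
  if (N <= exact_limit) {
    idx <- utils::combn(N, n1)
    ua <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(ua - mu) >= abs(U_a - mu) - 1e-9)
    method <- "exact (complete permutation enumeration)"
    exact <- TRUE
  } else {
    t_ <- table(v)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(t_^3 - t_) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U_a - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation, tie-corrected, continuity-corrected"
    exact <- FALSE
  }
  structure(list(test = "Mann-Whitney U",
                 statistic = c(U = U_a), U_a = U_a, U_b = U_b,
                 df = NA_real_, p.value = p, method = method, exact = exact,
                 n = c(n1 = n1, n2 = n2)),
            class = "axq_test")
}

#' One-way ANOVA on replicate penetrances with Tukey post hoc
#'
#' Fixed-effects one-way ANOVA across treatment groups of per-replicate
#' penetrance values (percent), with Tukey HSD pairwise comparisons and
#' group means and standard deviations.
#'
#' @param groups named list of numeric vectors, one per treatment; at least
#'   two groups with at least two replicates each.
#' @return Object of class `axq_test` with `statistic` (F), `df`
#'   (`c(between, within)`), `p.value`, a `posthoc` data.frame
#'   (`comparison`, `diff`, `lwr`, `upr`, `p_adj`) and a `group_stats`
#'   data.frame of means and SDs.
#' @export
anova_penetrance <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least two replicates")
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups), sizes)))
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit)$group
  posthoc <- data.frame(comparison = rownames(hsd),
                        diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                        upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                        row.names = NULL, stringsAsFactors = FALSE)
  gs <- data.frame(group = names(groups),
                   mean = vapply(groups, mean, numeric(1)),
                   sd = vapply(groups, stats::sd, numeric(1)),
                   n = as.integer(sizes), row.names = NULL)
  structure(list(test = "one-way ANOVA",
                 statistic = c(F = tab[["F value"]][1]),
                 df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
                 p.value = tab[["Pr(>F)"]][1],
                 method = "fixed-effects one-way ANOVA + Tukey HSD",
                 posthoc = posthoc, group_stats = gs),
            class = "axq_test")
}

#' @export
print.axq_test <- function(x, ...) {
  cat(x$test, "\n")
  if (!all(is.na(x$df)))
    cat(sprintf("  %s = %.4g, df = (%g, %g), p = %.4g\n",
                names(x$statistic), x$statistic, x$df[1], x$df[2], x$p.value))
  else
    cat(sprintf("  %s = %.4g, p = %.4g\n",
                names(x$statistic), x$statistic, x$p.value))
  cat("  method:", x$method, "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Tukey HSD):\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}
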