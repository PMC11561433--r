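#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for a fixed number of raters assigning one of
#' several categories to each item: kappa = (Pbar - Pe) / (1 - Pe), where
#' Pbar is the mean per-item observed agreement and Pe the chance agreement
#' implied by the marginal category proportions.
#'
#' @param ratings An items x categories matrix of counts; each row must sum
#'   to the number of raters.
#' @param n_raters Number of raters; inferred from the row sums when missing.
#' @return A list of class `fleiss_kappa`: `kappa`, `n_items`, `n_raters`,
#'   `n_categories`, `p_bar`, `p_e`.
#' @examples
#' m <- rbind(c(3, 0), c(0, 3), c(2, 1))  # 3 raters, 2 categories
#' fleiss_kappa(m)$kappa
#' @export
fleiss_kappa <- function(ratings, n_raters = NULL) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2) stop("need at least 2 items")
  rs <- rowSums(ratings)
  if (is.null(n_raters)) n_raters <- rs[1]
  if (n_raters < 2) stop("need at least 2 raters")
  if (any(rs != n_raters))
    stop("each item's category counts must sum to n_raters")
  n <- nrow(ratings)
  p_i <- (rowSums(ratings^2) - n_raters) / (n_raters * (n_raters - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(ratings) / (n * n_raters)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps^0.5)
    stop(errorCondition("degenerate agreement: all ratings in one category",
                        class = "telefocus_degenerate"))
  structure(list(kappa = (p_bar - p_e) / (1 - p_e), n_items = n,
                 n_raters = as.integer(n_raters),
                 n_categories = ncol(ratings), p_bar = p_bar, p_e = p_e),
            class = "fleiss_kappa")
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf("Fleiss' kappa = %.3f (%d items, %d raters, %d categories)\n",
              x$kappa, x$n_items, x$n_raters, x$n_categories))
  invisible(x)
}

#' Two-group comparison by OLS with cluster-robust standard errors
#'
#' Regresses the outcome on an intercept and a binary group indicator, so the
#' slope equals the difference of group means. The variance of the slope is
#' estimated with the CR1 cluster sandwich: the meat sums X'uu'X over
#' clusters and is scaled by the small-sample factor
#' G/(G-1) x (N-1)/(N-K); p-values and 95\% confidence intervals use the t
#' distribution with G - 1 degrees of freedom, G being the number of
#' clusters. Observations from the same cluster may fall in both groups.
#'
#' @param outcome Numeric outcome vector.
#' @param group Binary group indicator (logical, 0/1, or a two-level factor);
#'   the estimate is mean(group == 1) minus mean(group == 0).
#' @param cluster Cluster identifiers (e.g. patient ids), same length.
#' @param outcome_name Optional label carried into the result.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `cluster_ols` with `estimate`, `se_clustered`,
#'   `ci_low`, `ci_high`, `p_value`, `df`, `group_means`, `group_sds`,
#'   `group_medians`, `group_iqrs`, `n_per_group`, `n_clusters`, and the
#'   full coefficient vector.
#' @export
ols_cluster_robust <- function(outcome, group, cluster,
                               outcome_name = deparse(substitute(outcome)),
                               conf_level = 0.95) {
  y <- as.numeric(outcome)
  g <- as.integer(as.logical(if (is.factor(group)) group == levels(group)[2]
                             else group))
  stopifnot(length(y) == length(g), length(y) == length(cluster))
  if (length(unique(g)) < 2) stop("both groups must be non-empty")
  n <- length(y)
  X <- cbind(1, g)
  K <- ncol(X)
  XtX_inv <- solve(crossprod(X))
  beta <- drop(XtX_inv %*% crossprod(X, y))
  u <- y - drop(X %*% beta)
  G <- length(unique(cluster))

  est <- unname(beta[2])
  grp_stats <- function(v) c(mean(v), stats::sd(v))
  m1 <- y[g == 1]; m0 <- y[g == 0]
  res <- list(outcome_name = outcome_name, estimate = est,
              coefficients = c(`(Intercept)` = beta[1], group = beta[2]),
              group_means = c(not_focused = mean(m0), focused = mean(m1)),
              group_sds = c(not_focused = stats::sd(m0), focused = stats::sd(m1)),
              group_medians = c(not_focused = stats::median(m0),
                                focused = stats::median(m1)),
              group_iqrs = rbind(not_focused = stats::quantile(m0, c(.25, .75)),
                                 focused = stats::quantile(m1, c(.25, .75))),
              n_per_group = c(not_focused = sum(g == 0), focused = sum(g == 1)),
              n_clusters = G, residuals = u)
  if (G < 2) {
    warning("fewer than 2 clusters: estimate returned without inference")
    res <- c(res, list(se_clustered = NA_real_, df = NA_real_,
                       p_value = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_))
    class(res) <- "cluster_ols"
    return(res)
  }
  meat <- matrix(0, K, K)
  for (cl in split(seq_len(n), cluster)) {
    Xg <- X[cl, , drop = FALSE]
    ug <- u[cl]
    s <- crossprod(Xg, ug)
    meat <- meat + s %*% t(s)
  }
  adj <- (G / (G - 1)) * ((n - 1) / (n - K))
  V <- adj * XtX_inv %*% meat %*% XtX_inv
  se <- sqrt(V[2, 2])
  df <- G - 1
  tval <- if (se > 0) est / se else ifelse(est == 0, 0, Inf * sign(est))
  p <- 2 * stats::pt(-abs(tval), df = df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  res <- c(res, list(se_clustered = se, df = df, p_value = p,
                     ci_low = est - crit * se, ci_high = est + crit * se,
                     vcov = V))
  class(res) <- "cluster_ols"
  res
}

#' @export
print.cluster_ols <- function(x, digits = 3, ...) {
  cat("Two-group OLS with cluster-robust (CR1) SEs —", x$outcome_name, "\n")
  cat(sprintf("  estimate %.*f (SE %.*f), 95%% CI [%.*f, %.*f], t(%d), p = %.4g\n",
              digits, x$estimate, digits, x$se_clustered, digits, x$ci_low,
              digits, x$ci_high, as.integer(x$df), x$p_value))
  cat(sprintf("  group means: %.*f (n=%d) vs %.*f (n=%d), %d clusters\n",
              digits, x$group_means["focused"], x$n_per_group["focused"],
              digits, x$group_means["not_focused"], x$n_per_group["not_focused"],
              x$n_clusters))
  invisible(x)
}

#' @export
coef.cluster_ols <- function(object, ...) object$coefficients

#' @export
confint.cluster_ols <- function(object, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("group", c("lower", "upper")))
}

#' Holm-Bonferroni step-down adjustment of p-values
#'
#' Sorts the m p-values ascending, multiplies the k-th smallest by
#' (m - k + 1), enforces monotone non-decrease along the sorted sequence,
#' caps at 1, and restores the input order. Controls the family-wise error
#' rate and is uniformly more powerful than Bonferroni.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return A list with `raw` and `adjusted` vectors in input order.
#' @examples
#' holm_bonferroni(c(0.01, 0.02, 0.04))$adjusted  # 0.03 0.04 0.04
#' @export
holm_bonferroni <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(list(raw = numeric(), adjusted = numeric()))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(raw = p, adjusted = adjusted)
}

#' Spearman rank correlation with midrank ties and t approximation
#'
#' Computes rho as the Pearson correlation of midranks (average ranks for
#' ties) and a two-sided p-value from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A list of class `spearman_test`: `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop(errorCondition("undefined correlation: a variable has constant ranks",
                        class = "telefocus_degenerate"))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "spearman_test")
}

#' @export
print.spearman_test <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.4g (n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Cohen's d with pooled standard deviation
#'
#' d = (mean(a) - mean(b)) / s_pooled, with the pooled variance
#' ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2). No small-sample
#' (Hedges) correction is applied.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list of class `cohens_d`: `d`, `group_means`, `group_sds`,
#'   `group_ns`.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop(errorCondition("effect size undefined: a group has fewer than 2 values",
                        class = "telefocus_degenerate"))
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  diff <- mean(a) - mean(b)
  d <- if (sp2 > 0) diff / sqrt(sp2) else if (diff == 0) 0 else
    stop(errorCondition("infinite effect: zero pooled SD with unequal means",
                        class = "telefocus_degenerate"))
  structure(list(d = d, group_means = c(mean(a), mean(b)),
                 group_sds = c(stats::sd(a), stats::sd(b)),
                 group_ns = c(na, nb)),
            class = "cohens_d")
}

#' @export
print.cohens_d <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (means %.2f vs %.2f, n = %d vs %d)\n",
              x$d, x$group_means[1], x$group_means[2],
              x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

#' Proportion of calls mentioning given attributes
#'
#' For a group of calls, the fraction of calls containing at least one
#' utterance carrying any of the listed attributes (e.g. the symptom
#' attributes: location, frequency, extent, time, activity). Reported per
#' attribute and pooled; descriptive only.
#'
#' @param cohort A `telecare_cohort`.
#' @param call_ids Identifiers of the calls forming the group.
#' @param attribute_set Character vector of attribute labels; defaults to the
#'   symptom attributes of the cohort's vocabulary.
#' @return A data frame with one row per attribute plus a pooled `any` row:
#'   `attribute`, `n_calls`, `n_mentioning`, `proportion`.
#' @export
proportion_with_attribute <- function(cohort, call_ids,
                                      attribute_set = symptom_attributes(cohort$vocab)) {
  stopifnot(inherits(cohort, "telecare_cohort"), length(call_ids) > 0)
  u <- cohort$utterances[cohort$utterances$call_id %in% call_ids, , drop = FALSE]
  attr_lists <- split_labels(u$attributes)
  n <- length(call_ids)
  rows <- lapply(attribute_set, function(a) {
    hits <- unique(u$call_id[vapply(attr_lists, function(v) a %in% v, logical(1))])
    data.frame(attribute = a, n_calls = n, n_mentioning = length(hits),
               proportion = length(hits) / n)
  })
  any_hit <- unique(u$call_id[vapply(attr_lists, function(v)
    any(attribute_set %in% v), logical(1))])
  rows <- c(rows, list(data.frame(attribute = "any", n_calls = n,
                                  n_mentioning = length(any_hit),
                                  proportion = length(any_hit) / n)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
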