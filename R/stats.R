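# Self-contained statistics battery. Each test is written out from its
# defining formula (tie handling included) rather than wrapping the base R
# equivalents, which serve as independent oracles in the test suite.

.check_groups <- function(groups, min_n = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lens <- vapply(groups, length, integer(1))
  if (any(lens < min_n)) {
    stop("every group needs at least ", min_n, " value(s)")
  }
  lapply(groups, function(g) {
    stopifnot(is.numeric(g), all(is.finite(g)))
    as.numeric(g)
  })
}

# tie-correction sum over the pooled sample: sum(t^3 - t) over tie groups
.tie_sum <- function(x) {
  t <- table(x)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test
#'
#' Joint mid-ranking of all values; the statistic
#' \eqn{H = \frac{12}{N(N+1)} \sum n_i (\bar R_i - \frac{N+1}{2})^2}
#' is divided by the tie correction
#' \eqn{C = 1 - \sum(t^3 - t)/(N^3 - N)} and referred to a chi-square
#' distribution with k-1 degrees of freedom. When all pooled values are
#' identical, p = 1 by convention.
#'
#' @param groups named list of numeric vectors.
#' @return list with \code{statistic} (H), \code{df}, \code{p_value},
#'   \code{mean_ranks}, \code{n}.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  stopifnot(N >= 3L)
  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                mean_ranks = rep((N + 1) / 2, length(groups)), n = N))
  }
  r <- rank(x)  # mid-ranks for ties
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  rbar <- tapply(r, factor(g, levels = names(groups)), mean)
  ni <- tapply(r, factor(g, levels = names(groups)), length)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  C <- 1 - .tie_sum(x) / (N^3 - N)
  H <- H / C
  df <- length(groups) - 1L
  list(statistic = H, df = df,
       p_value = stats::pchisq(H, df, lower.tail = FALSE),
       mean_ranks = as.numeric(rbar), n = N)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For each group pair, \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sigma_{ij}}
#' with \eqn{\sigma_{ij}^2 = (\frac{N(N+1)}{12} -
#' \frac{\sum(t^3-t)}{12(N-1)}) (1/n_i + 1/n_j)} on the joint mid-ranks,
#' two-sided normal p-values, Benjamini-Hochberg adjusted across all
#' k(k-1)/2 pairs.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with columns \code{group_i, group_j, z, p_raw,
#'   p_adjusted}.
#' @export
dunn_posthoc <- function(groups) {
  groups <- .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  labs <- names(groups)
  if (length(unique(x)) == 1L) {
    pairs <- utils::combn(labs, 2L)
    return(data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                      z = 0, p_raw = 1, p_adjusted = 1,
                      stringsAsFactors = FALSE))
  }
  r <- rank(x)
  g <- factor(rep(labs, vapply(groups, length, integer(1))), levels = labs)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  var_term <- N * (N + 1) / 12 - .tie_sum(x) / (12 * (N - 1))
  pairs <- utils::combn(labs, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(var_term * (1 / ni[[i]] + 1 / ni[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(abs(z[k]), lower.tail = FALSE)
  }
  data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ], z = z,
             p_raw = p, p_adjusted = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sort ascending; \eqn{adj_{(i)} = \min_{j \ge i} (m/j) p_{(j)}}, capped at
#' 1, returned in the original order.
#'
#' @param pvals numeric vector in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m <= 1L) return(pvals)
  o <- order(pvals)
  scaled <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))     # enforce min over j >= i
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way ANOVA
#'
#' Standard between/within sum-of-squares decomposition; F with
#' (k-1, N-k) degrees of freedom.
#'
#' @param groups named list of numeric vectors.
#' @return list with \code{statistic} (F), \code{df} (length-2), and
#'   \code{p_value}. F = 0, p = 1 when all values are identical; an error if
#'   within-group variance is zero while group means differ.
#' @export
anova_oneway <- function(groups) {
  groups <- .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  ni <- vapply(groups, length, integer(1))
  N <- length(x)
  k <- length(groups)
  stopifnot(N > k)
  gm <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ni * (means - gm)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(list(statistic = 0, df = c(k - 1L, N - k), p_value = 1))
    }
    stop("zero within-group variance with unequal means: F undefined")
  }
  Fstat <- (ss_between / (k - 1)) / (ss_within / (N - k))
  list(statistic = Fstat, df = c(k - 1L, N - k),
       p_value = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

#' Pairwise two-sample t tests with Bonferroni correction
#'
#' Pooled-variance two-sample t per pair; raw p multiplied by the number of
#' pairs, capped at 1.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @return data.frame with columns \code{group_i, group_j, t, df, p_raw,
#'   p_adjusted}.
#' @export
pairwise_t_bonferroni <- function(groups) {
  groups <- .check_groups(groups, min_n = 2L)
  labs <- names(groups)
  pairs <- utils::combn(labs, 2L)
  m <- ncol(pairs)
  t <- df <- p <- numeric(m)
  for (k in seq_len(m)) {
    a <- groups[[pairs[1L, k]]]; b <- groups[[pairs[2L, k]]]
    df[k] <- length(a) + length(b) - 2L
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df[k]
    if (sp2 == 0) {
      t[k] <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
      p[k] <- if (mean(a) == mean(b)) 1 else 0
      next
    }
    t[k] <- (mean(a) - mean(b)) /
      sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    p[k] <- 2 * stats::pt(abs(t[k]), df[k], lower.tail = FALSE)
  }
  data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ], t = t, df = df,
             p_raw = p, p_adjusted = pmin(p * m, 1),
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares regression of y on x
#'
#' Closed-form simple OLS with the regression F test
#' \eqn{F = r^2 (n-2) / (1 - r^2)} on (1, n-2) degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, var(x) > 0).
#' @param log10p1 transform both variables by log10(v + 1) first (an option
#'   for heavy-tailed expression scales).
#' @return list with \code{slope}, \code{intercept}, \code{r},
#'   \code{statistic} (F), \code{df}, \code{p_value}, \code{n}.
#' @export
linreg <- function(x, y, log10p1 = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L, all(is.finite(x)), all(is.finite(y)))
  if (log10p1) {
    x <- log10(x + 1); y <- log10(y + 1)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("var(x) = 0: slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  n <- length(x)
  if (syy == 0) {
    # y constant: perfect horizontal fit, correlation undefined -> 0
    return(list(slope = slope, intercept = intercept, r = 0,
                statistic = 0, df = c(1L, n - 2L), p_value = 1, n = n))
  }
  r <- sxy / sqrt(sxx * syy)
  Fstat <- r^2 * (n - 2) / max(1 - r^2, .Machine$double.eps)
  list(slope = slope, intercept = intercept, r = r, statistic = Fstat,
       df = c(1L, n - 2L),
       p_value = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE), n = n)
}
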