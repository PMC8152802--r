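# Rank-based tests used for the morphometric group contrasts and the
# covariate screens. Ties always receive average ranks.

#' One-tailed Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test of whether values in `x` (e.g. widths of
#' diapausing, group-D eggs) are stochastically larger than values in `y`
#' (non-diapausing, group-ND eggs). The statistic is the Mann-Whitney W
#' (rank sum of `x` minus `nx (nx + 1) / 2`, average ranks for ties). The
#' p-value is exact by enumeration of all group labelings when
#' `length(x) + length(y) <= 12`, and a normal approximation with tie
#' correction otherwise.
#'
#' @param x numeric values of the first group (tested as the larger one
#'   under `alternative = "greater"`).
#' @param y numeric values of the second group.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return a `rank_test` list: `test_name`, `statistic` (W), `p_value`,
#'   `effect_pct` (percent difference of group means, relative to `y`),
#'   `n_x`, `n_y`, `exact`, `degenerate`.
#' @examples
#' wilcoxon_one_tailed(c(3, 4), c(1, 2))$p_value # exactly 1/6
#' @export
wilcoxon_one_tailed <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  degenerate <- length(unique(pooled)) == 1L

  w_stat <- function(idx_x) {
    r <- rank(pooled)
    sum(r[idx_x]) - nx * (nx + 1) / 2
  }
  w_obs <- w_stat(seq_len(nx))

  exact <- n <= 12
  if (degenerate) {
    p <- 1
  } else if (exact) {
    r <- rank(pooled)
    combos <- combn(n, nx)
    w_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- if (alternative == "greater") {
      mean(w_all >= w_obs - eps)
    } else {
      mean(w_all <= w_obs + eps)
    }
  } else {
    r <- rank(pooled)
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (w_obs - mu) / sqrt(sigma2)
    p <- if (alternative == "greater") {
      pnorm(z, lower.tail = FALSE)
    } else {
      pnorm(z, lower.tail = TRUE)
    }
  }

  structure(
    list(
      test_name = "wilcoxon_one_tailed",
      alternative = alternative,
      statistic = w_obs,
      p_value = p,
      effect_pct = 100 * (mean(x) - mean(y)) / mean(y),
      n_x = nx,
      n_y = ny,
      exact = exact && !degenerate,
      degenerate = degenerate
    ),
    class = "rank_test"
  )
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H over two or more groups,
#' \eqn{H = [12/(N(N+1)) \sum R_j^2/n_j - 3(N+1)] / C} with
#' \eqn{C = 1 - \sum (t^3 - t) / (N^3 - N)}, and a chi-square p-value on
#' k - 1 degrees of freedom. Used to confirm that weeks pooled into one
#' diapause group behave as a homogeneous group.
#'
#' @param groups a list of two or more non-empty numeric vectors.
#' @return a `rank_test` list: `test_name`, `statistic` (H), `p_value`,
#'   `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least two groups")
  }
  if (any(lengths(groups) == 0)) abort("all groups must be non-empty")
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  gi <- rep(seq_len(k), lengths(groups))
  rank_sums <- tapply(r, gi, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(r)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) {
    # every observation tied: no rank information
    h <- 0
  } else {
    h <- h / correction
  }
  structure(
    list(
      test_name = "kruskal_wallis",
      statistic = h,
      p_value = pchisq(h, df = k - 1, lower.tail = FALSE),
      df = k - 1,
      n = n
    ),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

# all permutations of 1..n as an (n! x n) matrix, by insertion
.permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  if (n == 1) return(p)
  for (k in 2:n) {
    nr <- nrow(p)
    out <- matrix(0L, nr * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * nr + seq_len(nr)
      if (pos == 1) {
        out[rows, ] <- cbind(k, p)
      } else if (pos == k) {
        out[rows, ] <- cbind(p, k)
      } else {
        out[rows, ] <- cbind(p[, seq_len(pos - 1), drop = FALSE], k,
                             p[, pos:(k - 1), drop = FALSE])
      }
    }
    p <- out
  }
  p
}

#' Spearman rank correlation
#'
#' Rank correlation between two paired series (average ranks for ties):
#' the Pearson correlation of the rank vectors. The p-value is two-sided,
#' from exact permutation of one rank vector when `n < 10` (weekly series
#' are short) and from the t-approximation with n - 2 degrees of freedom
#' otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @param var_x,var_y labels carried into the result.
#' @return a one-row tibble: `var_x`, `var_y`, `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y, var_x = deparse(substitute(x)),
                     var_y = deparse(substitute(y))) {
  # capture labels before the arguments are modified
  force(var_x); force(var_y)
  var_x <- paste(var_x, collapse = "")
  var_y <- paste(var_y, collapse = "")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must be paired")
  n <- length(x)
  if (n < 3) abort("need at least 3 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("zero variance in one variable: rank correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- .permutations(n)
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    rho_all <- apply(ry_perm, 1, function(p) stats::cor(rx, p))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(var_x = var_x, var_y = var_y, rho = rho, p_value = p, n = n)
}
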