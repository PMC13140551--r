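# Generic statistics used by several stages: correlations with p-values,
# multiple-testing corrections, Kruskal-Wallis and Dunn's post hoc test
# with a compact letter display.

#' Correlation test (Pearson or Spearman)
#'
#' Pearson's product-moment correlation with a two-sided p-value from the
#' t-distribution on n-2 degrees of freedom, or Spearman's rank correlation
#' computed as Pearson on mid-ranks with the same t-approximation for the
#' p-value (the convention of `scipy.stats.spearmanr`, which differs from
#' `stats::cor.test`'s small-sample exact p). For Spearman with n <= 8 an
#' exact permutation p-value is available via `exact = TRUE`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @param method `"pearson"` or `"spearman"`.
#' @param exact Spearman only: compute the permutation p-value over all
#'   `n!` orderings (n <= 8).
#' @return List with `coefficient`, `p_value`, `n`, `method`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman"),
                             exact = FALSE) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_gs("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_gs("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_gs("correlation is undefined for constant input")
  }
  if (method == "spearman") {
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (exact) {
      if (n > 8L) stop_gs("exact permutation p only supported for n <= 8")
      perms <- permutations(n)
      rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
      p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    } else {
      p <- t_cor_pvalue(rho, n)
    }
    return(list(coefficient = rho, p_value = p, n = n, method = "spearman"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(coefficient = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = "pearson")
}

t_cor_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# All permutations of seq_len(n) as rows (n <= 8 => at most 40320 rows).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-pos]
      out[row, ] <- c(pos, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Holm step-down adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Holm-adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "holm")
}

check_pvalues <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_gs("p-values must be numeric and in [0, 1]")
  }
  invisible(p)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on g-1 degrees of
#' freedom. The degenerate case where every value is identical returns
#' H = 0, p = 1 rather than failing, which keeps fully tied synthetic
#' datasets usable.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, one per observation; at least two non-empty
#'   groups are required.
#' @return List with `H`, `p_value`, `sizes` (named group sizes).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop_gs("values and groups must have equal length")
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) stop_gs("need at least 2 groups")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p_value = 1,
                sizes = stats::setNames(as.integer(sizes), names(sizes))))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p_value = kt$p.value,
       sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Dunn's post hoc test with Holm correction and letter display
#'
#' Pairwise z statistics from mean-rank differences with the tie-corrected
#' pooled variance, two-sided normal p-values, Holm adjustment across all
#' g(g-1)/2 pairs, and a compact letter display in which groups sharing a
#' letter are not significantly different at `alpha`.
#'
#' By convention the omnibus Kruskal-Wallis test must be significant at
#' `alpha` before post hoc comparisons are interpreted; set `force = TRUE`
#' to run them regardless.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level for both the omnibus gate and the
#'   letter display (default 0.05).
#' @param force Run even when the omnibus test is not significant.
#' @return List with `omnibus` (the [kruskal_wallis()] result), `pairwise`
#'   (data frame: `group_a`, `group_b`, `z`, `p_raw`, `p_holm`) and
#'   `letters` (named character vector).
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05, force = FALSE) {
  groups <- as.character(groups)
  omnibus <- kruskal_wallis(values, groups)
  if (!force && omnibus$p_value > alpha) {
    stop_gs("omnibus Kruskal-Wallis test is not significant (p = ",
            format(omnibus$p_value, digits = 3),
            "); use force = TRUE to run post hoc comparisons anyway",
            class = "gillsym_precondition")
  }
  N <- length(values)
  r <- rank(values)
  lev <- names(sort(tapply(r, groups, mean)))  # by ascending mean rank
  rbar <- tapply(r, groups, mean)[lev]
  ni <- table(groups)[lev]
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(lev, 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(sigma2 * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    p_raw[j] <- if (se == 0) 1 else 2 * stats::pnorm(-abs(z[j]))
  }
  p_holm <- holm_adjust(p_raw)
  pw <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                   z = z, p_raw = p_raw, p_holm = p_holm,
                   stringsAsFactors = FALSE)
  letters <- compact_letters(pw, lev, alpha = alpha)
  list(omnibus = omnibus, pairwise = pw, letters = letters)
}

#' Compact letter display from pairwise comparisons
#'
#' Greedy insertion in the supplied group order (typically ascending mean
#' rank): each group joins every existing letter class it is compatible
#' with (no Holm-significant difference with any member); a group
#' compatible with none opens a new class. Groups sharing a letter are not
#' significantly different.
#'
#' @param pairwise Data frame with columns `group_a`, `group_b`, `p_holm`.
#' @param level_order Character vector of group labels, insertion order.
#' @param alpha Significance level.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(pairwise, level_order, alpha = 0.05) {
  sig <- function(a, b) {
    hit <- (pairwise$group_a == a & pairwise$group_b == b) |
      (pairwise$group_a == b & pairwise$group_b == a)
    any(pairwise$p_holm[hit] <= alpha)
  }
  classes <- list()
  for (g in level_order) {
    joined <- FALSE
    for (i in seq_along(classes)) {
      if (!any(vapply(classes[[i]], sig, logical(1L), b = g))) {
        classes[[i]] <- c(classes[[i]], g)
        joined <- TRUE
      }
    }
    if (!joined) classes[[length(classes) + 1L]] <- g
  }
  out <- stats::setNames(rep("", length(level_order)), level_order)
  for (i in seq_along(classes)) {
    for (g in classes[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
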