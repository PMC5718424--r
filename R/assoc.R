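# Contingency-table association suite, implemented from the formulas:
# Pearson chi-squared (no continuity correction), Cramer's V, Haberman
# adjusted-residual post-hoc with Bonferroni correction, and the
# Mann-Whitney U rank test with tie-corrected normal approximation and exact
# enumeration for small untied samples.

drop_zero_marginals <- function(tab) {
  rz <- rowSums(tab) == 0
  cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " zero row(s) and ", sum(cz),
            " zero column(s) from the contingency table", call. = FALSE)
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  tab
}

#' Pearson chi-squared test of association
#'
#' Expected counts E_ij = row_i * col_j / N; the statistic is
#' sum((O - E)^2 / E) over cells with E > 0, referred to the chi-squared
#' distribution with (r - 1)(c - 1) degrees of freedom. No continuity
#' correction. Zero row/column marginals are dropped with a warning and the
#' degrees of freedom recomputed.
#'
#' @param tab matrix of non-negative observed counts (rows = actor,
#'   columns = category), with dimnames.
#' @return object of class \code{assoc_chisq}: \code{statistic}, \code{df},
#'   \code{p.value}, \code{cramers_v}, \code{N}, \code{observed},
#'   \code{expected}.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(is.na(tab))) stop("counts must be non-negative")
  tab <- drop_zero_marginals(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("chi-squared test needs at least 2 rows and 2 columns with ",
         "positive marginals")
  N <- sum(tab)
  if (N <= 0) stop("contingency table has no observations")
  E <- outer(rowSums(tab), colSums(tab)) / N
  stat <- sum(((tab - E)^2 / E)[E > 0])
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 cramers_v = cramers_v(stat, N, nrow(tab), ncol(tab)),
                 N = N, observed = tab, expected = E),
            class = "assoc_chisq")
}

#' @export
print.assoc_chisq <- function(x, ...) {
  cat(sprintf("Chi-squared test of association: X^2 = %.2f, df = %d, %s; Cramer's V = %.3f (N = %d)\n",
              x$statistic, x$df, format_p(x$p.value), x$cramers_v, x$N))
  invisible(x)
}

format_p <- function(p) {
  if (p < 0.001) "p < 0.001" else sprintf("p = %.3f", p)
}

#' Cramer's V effect size
#'
#' V = sqrt(chi2 / (N * (min(r, c) - 1))), in [0, 1].
#'
#' @param chi2 chi-squared statistic (>= 0).
#' @param n total count N (>= 1).
#' @param r,c table dimensions.
#' @return V.
#' @export
cramers_v <- function(chi2, n, r, c) {
  if (chi2 < 0) stop("chi2 must be non-negative")
  if (n < 1) stop("N must be at least 1")
  if (min(r, c) < 2) stop("Cramer's V needs at least a 2 x 2 table")
  sqrt(chi2 / (n * (min(r, c) - 1)))
}

#' Adjusted-residual post-hoc test
#'
#' Per-cell adjusted (standardized) residuals
#' z_ij = (O_ij - E_ij) / sqrt(E_ij (1 - row_i/N) (1 - col_j/N)),
#' approximately standard normal under independence; two-sided raw p-values
#' with Bonferroni correction by the number of cells (r * c by default).
#'
#' @param tab observed count matrix (zero marginals dropped as in
#'   \code{\link{chi_square}}).
#' @param alpha significance level for the flags (default 0.05).
#' @param bonferroni_factor correction factor; defaults to the number of
#'   cells of the (possibly reduced) table.
#' @return object of class \code{assoc_posthoc}: matrices \code{z},
#'   \code{p_raw}, \code{p_adj} and logical \code{significant}, plus
#'   \code{alpha} and \code{bonferroni_factor}.
#' @export
adjusted_residuals <- function(tab, alpha = 0.05, bonferroni_factor = NULL) {
  tab <- as.matrix(tab)
  tab <- drop_zero_marginals(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("post-hoc test needs at least a 2 x 2 table")
  N <- sum(tab)
  rp <- rowSums(tab) / N
  cp <- colSums(tab) / N
  E <- outer(rowSums(tab), colSums(tab)) / N
  denom <- sqrt(E * outer(1 - rp, 1 - cp))
  z <- (tab - E) / denom
  z[denom == 0] <- 0
  p_raw <- 2 * stats::pnorm(-abs(z))
  if (is.null(bonferroni_factor)) bonferroni_factor <- length(tab)
  p_adj <- p_raw * bonferroni_factor
  p_adj[p_adj > 1] <- 1
  structure(list(z = z, p_raw = p_raw, p_adj = p_adj,
                 significant = p_adj < alpha, alpha = alpha,
                 bonferroni_factor = bonferroni_factor, observed = tab),
            class = "assoc_posthoc")
}

#' @export
print.assoc_posthoc <- function(x, ...) {
  cat("Adjusted-residual post-hoc (Bonferroni x", x$bonferroni_factor,
      ", alpha =", x$alpha, ")\n")
  cat("z:\n"); print(round(x$z, 2))
  sig <- which(x$significant, arr.ind = TRUE)
  if (nrow(sig) > 0L) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  [%s, %s]: z = %.2f, adj. %s\n",
                  rownames(x$z)[sig[i, 1]] %||% sig[i, 1],
                  colnames(x$z)[sig[i, 2]] %||% sig[i, 2],
                  x$z[sig[i, 1], sig[i, 2]],
                  format_p(x$p_adj[sig[i, 1], sig[i, 2]])))
    }
  } else cat("  no cell significant after correction\n")
  invisible(x)
}

#' Mann-Whitney U rank test
#'
#' Midranks over the pooled sample; U1 = n1 n2 + n1(n1 + 1)/2 - R1; the
#' reported U is min(U1, U2). The p-value uses the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction, or exact
#' enumeration when n1 + n2 <= 12 and there are no ties (the default
#' \code{exact = NULL} picks automatically).
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact force (\code{TRUE}) or suppress (\code{FALSE}) exact
#'   enumeration; \code{NULL} decides by the rule above.
#' @return object of class \code{rank_test}: \code{U}, \code{U1}, \code{U2},
#'   \code{n1}, \code{n2}, \code{z}, \code{p.value}, \code{method},
#'   \code{median1}, \code{median2}.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  R1 <- sum(rk[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  # continuity-corrected z, as in the reference rank-test implementations
  z <- if (sigma2 > 0)
    (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2) else 0
  use_exact <- if (is.null(exact)) (n <= 12L && !has_ties) else isTRUE(exact)
  if (use_exact && has_ties) {
    warning("exact enumeration is not defined with ties; using the normal ",
            "approximation", call. = FALSE)
    use_exact <- FALSE
  }
  if (use_exact) {
    p <- mw_exact_p(U1, rk, n1)
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(U = U, U1 = U1, U2 = U2, n1 = n1, n2 = n2, z = z,
                 p.value = p, method = method,
                 median1 = stats::median(x), median2 = stats::median(y)),
            class = "rank_test")
}

# Exact two-sided p by full enumeration of the choose(n, n1) group
# assignments: p = 2 * min(P(U1 <= u), P(U1 >= u)), capped at 1.
mw_exact_p <- function(U1_obs, ranks, n1) {
  n <- length(ranks)
  combos <- utils::combn(n, n1)
  R1_all <- colSums(matrix(ranks[combos], nrow = n1))
  U1_all <- n1 * (n - n1) + n1 * (n1 + 1) / 2 - R1_all
  eps <- 1e-9
  p <- 2 * min(mean(U1_all <= U1_obs + eps), mean(U1_all >= U1_obs - eps))
  min(1, p)
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, n1 = %d, n2 = %d, %s (%s)\n",
              x$U, x$n1, x$n2, format_p(x$p.value), x$method))
  cat(sprintf("  group medians: %.3g vs %.3g\n", x$median1, x$median2))
  invisible(x)
}

#' Build a labelled contingency table from two classification vectors
#'
#' @param rows,cols parallel classification vectors (e.g. actor and
#'   category).
#' @param col_levels optional explicit column level order.
#' @return integer matrix of counts with dimnames.
#' @export
contingency_table <- function(rows, cols, col_levels = NULL) {
  if (!is.null(col_levels)) cols <- factor(cols, levels = col_levels)
  tab <- table(rows, cols)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}
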