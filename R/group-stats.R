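# Nonparametric statistical layer: Kruskal-Wallis omnibus with Dunn's
# pairwise post-hoc z tests, compact letter displays, Wilcoxon signed-rank
# paired tests and Spearman correlations.

#' Dunn's pairwise post-hoc test on mean ranks
#'
#' For each pair of groups, z = (Rbar_i - Rbar_j) / sigma_ij with the pooled
#' tie-corrected variance
#' sigma_ij^2 = (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j),
#' ranks taken over all observations jointly. Two-sided normal p values,
#' optionally adjusted.
#'
#' @param values Numeric vector.
#' @param groups Grouping labels, same length.
#' @param adjust `"holm"`, `"bonferroni"` or `"none"`.
#' @return Data frame with `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(values, groups, adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) < 1)) stop("every group needs at least 1 observation")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    sig2 <- (N * (N + 1) / 12 - tie_term) * (1 / n[[pr[1]]] + 1 / n[[pr[2]]])
    if (sig2 <= 0) return(NA_real_)
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / sqrt(sig2)
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_raw = p_raw, p_adj = stats::p.adjust(p_raw, method = adjust))
}

#' Kruskal-Wallis test with Dunn's post hoc and compact letters
#'
#' The standard nonparametric group-comparison chain for non-normal field
#' data: tie-corrected Kruskal-Wallis omnibus test, Dunn's pairwise z tests,
#' p-value adjustment, and a compact letter display in which groups sharing
#' no letter differ significantly at `alpha`. When all values are tied
#' across all groups the omnibus H is undefined; p is set to 1 and flagged.
#'
#' @param values Numeric response vector.
#' @param groups Grouping labels (surface classes).
#' @param alpha Significance level for the letter display (default 0.05).
#' @param adjust Adjustment for the Dunn p values: `"holm"` (default),
#'   `"bonferroni"` or `"none"` (some analyses report unadjusted pairwise p).
#' @return A list of class `"comparison_result"`: `omnibus_stat`, `omnibus_p`,
#'   `omnibus_df`, `pairwise` (Dunn table), `letters` (named character),
#'   `alpha`, `adjust`, `degenerate`.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05,
                         adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  degenerate <- length(unique(values)) == 1
  if (degenerate) {
    stat <- NA_real_
    p <- 1
    pw <- data.frame(group1 = utils::combn(levels(groups), 2)[1, ],
                     group2 = utils::combn(levels(groups), 2)[2, ],
                     z = 0, p_raw = 1, p_adj = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
    stat <- unname(kw$statistic)
    p <- kw$p.value
    pw <- dunn_test(values, groups, adjust = adjust)
  }
  lev <- levels(groups)
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(pw))) {
    s <- !is.na(pw$p_adj[i]) && pw$p_adj[i] < alpha
    sig[pw$group1[i], pw$group2[i]] <- s
    sig[pw$group2[i], pw$group1[i]] <- s
  }
  structure(list(omnibus_stat = stat, omnibus_p = p,
                 omnibus_df = nlevels(groups) - 1,
                 pairwise = pw, letters = compact_letters(sig),
                 alpha = alpha, adjust = adjust, degenerate = degenerate),
            class = "comparison_result")
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: start with all groups sharing one letter;
#' for each significantly different pair found together in a letter column,
#' split the column into two (one without each member); finally absorb
#' columns whose group set is contained in another. The result satisfies the
#' two letter-display axioms: a significant pair shares no letter, and a
#' non-significant pair shares at least one.
#'
#' @param sig Symmetric logical matrix; `TRUE` = the pair differs
#'   significantly. Row/column names are the group labels.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(sig) {
  if (!is.matrix(sig) || nrow(sig) != ncol(sig)) stop("`sig` must be square")
  if (!isTRUE(all(sig == t(sig)))) stop("`sig` must be symmetric")
  g <- rownames(sig)
  if (is.null(g)) g <- as.character(seq_len(nrow(sig)))
  cols <- list(g)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- g[pairs[k, 1]]
    b <- g[pairs[k, 2]]
    newcols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) {
      for (j in seq_along(newcols)) {
        if (i != j && keep[j] &&
            all(newcols[[i]] %in% newcols[[j]]) &&
            !(length(newcols[[i]]) == length(newcols[[j]]) && i < j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- newcols[keep]
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(g)), g)
  # order columns by their first group so letter 'a' goes to the first group
  first_idx <- vapply(cols, function(col) min(match(col, g)), numeric(1))
  cols <- cols[order(first_idx)]
  for (i in seq_along(cols)) {
    for (m in cols[[i]]) out[m] <- paste0(out[m], letters_pool[i])
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on matched observations (e.g. the same soils
#' under two incubation treatments). Zero differences are dropped; the exact
#' distribution is used for n <= 25 without ties, the normal approximation
#' with continuity correction otherwise. A degenerate all-zero-difference
#' input is flagged rather than tested.
#'
#' @param x,y Matched numeric vectors.
#' @return A list with `statistic` (V), `p`, `n` (non-zero differences),
#'   `degenerate`.
#' @export
paired_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be matched (equal length)")
  d <- x - y
  d <- d[d != 0]
  if (length(d) < 1) {
    return(list(statistic = NA_real_, p = NA_real_, n = 0, degenerate = TRUE))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(d),
       degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A list with `R` (rho) and `p` (exact for n <= 9 without ties,
#'   t/AS89 approximation otherwise).
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("constant vector: correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 9 && !any(duplicated(x)) &&
                      !any(duplicated(y)))
  )
  list(R = unname(ct$estimate), p = ct$p.value)
}
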