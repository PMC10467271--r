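#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality is checked in each group; if both pass (p >= 0.05)
#' a two-sample Student t-test is used, otherwise the Kruskal-Wallis rank
#' test (equivalent to a two-sided rank-sum test for two groups). With
#' `tails = "one"` the tested direction is taken from the sample-mean
#' ordering and reported explicitly; a one-tail request under non-normality
#' falls back to the two-sided rank test with a warning. Note that a
#' data-driven one-tail test has twice the nominal level of a two-sided one;
#' the package default for calibrated screening is `tails = "two"`.
#'
#' @param a,b Numeric vectors (>= 3 values each).
#' @param tails `"two"` or `"one"`.
#' @param alpha Significance level recorded in the result.
#' @param name Label carried into the record.
#' @param shapiro_alpha Normality gate level.
#' @return One-row data frame: `name`, `test`, `statistic`, `p`,
#'   `direction` (`"A>B"`/`"B>A"`), `normality_p_a`, `normality_p_b`,
#'   `significant`, `degenerate`.
#' @export
compare_groups <- function(a, b, tails = c("two", "one"), alpha = 0.05,
                           name = "", shapiro_alpha = 0.05) {
  tails <- match.arg(tails)
  stopifnot(length(a) >= 3, length(b) >= 3)
  direction <- if (mean(a) >= mean(b)) "A>B" else "B>A"

  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(data.frame(name = name, test = "degenerate", statistic = 0,
                      p = 1, direction = direction,
                      normality_p_a = NA_real_, normality_p_b = NA_real_,
                      significant = FALSE, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  sw <- function(x) {
    if (stats::sd(x) == 0) return(0)   # constant sample: treat as non-normal
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  pa <- sw(a); pb <- sw(b)
  normal <- pa >= shapiro_alpha && pb >= shapiro_alpha

  if (normal) {
    alt <- if (tails == "two") "two.sided" else
      if (direction == "A>B") "greater" else "less"
    tt <- stats::t.test(a, b, alternative = alt, var.equal = TRUE)
    test <- if (tails == "two") "t_two_tail" else "t_one_tail"
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    if (tails == "one")
      warning("non-normal samples: reporting two-sided Kruskal-Wallis ",
              "instead of the requested one-tail test")
    kw <- stats::kruskal.test(list(a, b))
    test <- "kruskal_wallis"
    stat <- unname(kw$statistic); p <- kw$p.value
  }
  data.frame(name = name, test = test, statistic = stat, p = p,
             direction = direction, normality_p_a = pa, normality_p_b = pb,
             significant = is.finite(p) && p < alpha, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Edge-wise group comparison of connectivity matrices
#'
#' Compares the Fisher-z connectivity entry-by-entry between two groups of
#' subjects: one test per unordered channel pair (91 tests for 14 channels),
#' significance at uncorrected `p < alpha` by default, optionally
#' Benjamini-Hochberg adjusted.
#'
#' @param group_a,group_b Lists of `connectivity_matrix` objects (one per
#'   subject) of the same channel count.
#' @param alpha Significance level.
#' @param tails Passed to [compare_groups()].
#' @param fdr If `TRUE`, significance is decided on BH-adjusted p-values.
#' @return List with `p_matrix` (symmetric, `NA` diagonal), `records` (one
#'   row per pair) and `significant` (subset of records).
#' @export
compare_connectivity_edges <- function(group_a, group_b, alpha = 0.05,
                                       tails = "two", fdr = FALSE) {
  za <- simplify2array(lapply(group_a, unclass))  # n x n x subjects
  zb <- simplify2array(lapply(group_b, unclass))
  if (dim(za)[1] != dim(zb)[1]) stop("channel counts differ between groups")
  n <- dim(za)[1]
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  recs <- vector("list", nrow(ut))
  p_matrix <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    rec <- compare_groups(za[i, j, ], zb[i, j, ], tails = tails,
                          alpha = alpha,
                          name = sprintf("ch%02d-ch%02d", i, j))
    rec$ch_i <- i; rec$ch_j <- j
    recs[[k]] <- rec
    p_matrix[i, j] <- p_matrix[j, i] <- rec$p
  }
  records <- do.call(rbind, recs)
  if (fdr) {
    records$p_adj <- stats::p.adjust(records$p, method = "BH")
    records$significant <- records$p_adj < alpha
  }
  list(p_matrix = p_matrix, records = records,
       significant = records[records$significant, , drop = FALSE])
}

#' Demographic comparisons between two groups
#'
#' For every shared column of the two tables: continuous variables are
#' compared with the two-tail two-sample t-test, categorical variables
#' (factor/character/logical) with Fisher's exact test on the contingency
#' table. Empty category levels are dropped with a warning.
#'
#' @param table_a,table_b Data frames of per-subject fields, one row per
#'   subject.
#' @param alpha Significance level recorded per row.
#' @return Data frame with one record per variable: `name`, `test`,
#'   `statistic` (t statistic or `NA` for Fisher), `p`, `significant`.
#' @export
compare_demographics <- function(table_a, table_b, alpha = 0.05) {
  vars <- intersect(names(table_a), names(table_b))
  if (!length(vars)) stop("no shared columns to compare")
  out <- lapply(vars, function(v) {
    xa <- table_a[[v]]; xb <- table_b[[v]]
    if (is.numeric(xa) && is.numeric(xb)) {
      tt <- stats::t.test(xa, xb, alternative = "two.sided", var.equal = TRUE)
      data.frame(name = v, test = "t_two_tail",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 significant = tt$p.value < alpha, stringsAsFactors = FALSE)
    } else {
      f <- factor(c(as.character(xa), as.character(xb)))
      g <- factor(rep(c("A", "B"), c(length(xa), length(xb))))
      tab <- table(f, g)
      keep <- rowSums(tab) > 0
      if (!all(keep)) {
        warning("variable ", v, ": dropping empty level(s) ",
                paste(rownames(tab)[!keep], collapse = ", "))
        tab <- tab[keep, , drop = FALSE]
      }
      ft <- stats::fisher.test(tab)
      data.frame(name = v, test = "fisher_exact", statistic = NA_real_,
                 p = ft$p.value, significant = ft$p.value < alpha,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Spearman correlation between a network metric and HAMD scores
#'
#' Values from both groups are pooled into a single set and rank-correlated
#' (midranks for ties) with the pooled HAMD scores; two-sided p-value.
#'
#' @param values Pooled metric values (>= 5).
#' @param hamd Pooled HAMD scores, same length.
#' @return List with `rho` and `p` (`NA` when the metric is constant).
#' @export
spearman_vs_hamd <- function(values, hamd) {
  stopifnot(length(values) == length(hamd))
  ok <- is.finite(values) & is.finite(hamd)
  values <- values[ok]; hamd <- hamd[ok]
  if (length(values) < 5) stop("need at least 5 complete pairs")
  if (stats::sd(values) == 0) return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(values, hamd, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
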