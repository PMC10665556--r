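#' Pearson chi-squared test for a 2x2 table
#'
#' Baseline-table comparison of a dichotomous trait between two groups:
#' Pearson chi-squared on the 2x2 counts **without** continuity
#' correction, df = 1, two-sided. This is the variant that reproduces
#' printed baseline-table p-values from printed counts.
#'
#' @param a,b counts for group 1 (trait yes / trait no).
#' @param c_,d counts for group 2 (trait yes / trait no).
#' @return list `chi2`, `p`, `table`.
#' @export
#' @examples
#' chisq_2x2(59, 113, 35, 62)$p  # ~0.769
chisq_2x2 <- function(a, b, c_, d) {
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(group = c("g1", "g2"),
                                trait = c("yes", "no")))
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-squared test undefined")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Two-sample t-test from printed summary statistics
#'
#' Reconstructs the two-sided t-test from group means, SDs and sizes as
#' printed in a baseline table, in Welch (unequal-variance, default) or
#' pooled-variance form. Two zero-SD groups with equal means give t = 0,
#' p = 1.
#'
#' @param mean_a,sd_a,n_a group A summaries (sd >= 0, n >= 2).
#' @param mean_b,sd_b,n_b group B summaries.
#' @param mode `"welch"` or `"pooled"`.
#' @return list `t`, `df`, `p`.
#' @export
#' @examples
#' t_from_summaries(58.5, 12.6, 97, 51.8, 12.9, 62)$p  # rounds to 0.002
t_from_summaries <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                             mode = c("welch", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2)
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) return(list(t = 0, df = n_a + n_b - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  if (mode == "welch") {
    se2 <- sd_a^2 / n_a + sd_b^2 / n_b
    t <- (mean_a - mean_b) / sqrt(se2)
    df <- se2^2 / ((sd_a^2 / n_a)^2 / (n_a - 1) +
                     (sd_b^2 / n_b)^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Fisher's exact test for a 2x2 table (utility)
#'
#' Provided for sparse tables where the chi-squared approximation is
#' unreliable; not the default baseline-table test.
#'
#' @inheritParams chisq_2x2
#' @return list `p`, `odds_ratio`.
#' @export
fisher_2x2 <- function(a, b, c_, d) {
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Baseline-table comparisons from a labeled input table
#'
#' Runs [chisq_2x2()] on rows of type `"dichotomous"` (columns `a`, `b`,
#' `c_`, `d`) and [t_from_summaries()] on rows of type `"continuous"`
#' (columns `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`), returning
#' one p-value per labeled row.
#'
#' @param tab data frame with columns `label`, `type` and the columns
#'   required by the row's type.
#' @param mode t-test variant for continuous rows.
#' @return data frame `label`, `type`, `statistic`, `p`.
#' @export
table1_compare <- function(tab, mode = "welch") {
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (r$type == "dichotomous") {
      res <- chisq_2x2(r$a, r$b, r$c_, r$d)
      data.frame(label = r$label, type = r$type, statistic = res$chi2,
                 p = res$p, stringsAsFactors = FALSE)
    } else if (r$type == "continuous") {
      res <- t_from_summaries(r$mean_a, r$sd_a, r$n_a,
                              r$mean_b, r$sd_b, r$n_b, mode = mode)
      data.frame(label = r$label, type = r$type, statistic = res$t,
                 p = res$p, stringsAsFactors = FALSE)
    } else stop("unknown row type: ", r$type)
  }))
  rownames(out) <- NULL
  out
}
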