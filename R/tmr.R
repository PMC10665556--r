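#' Tetramer-positive T-cell frequency per million CD4
#'
#' Frequency statistic for magnetically enriched tetramer-stained samples
#' in which 1% of the cells were reserved before enrichment to estimate
#' the total CD4+ count:
#' `F = (1e6 * tmr_events) / (100 * cd4_pre)`,
#' i.e. tetramer-positive events per million CD4+ T cells.
#'
#' @param tmr_events non-negative integer(s): tetramer-positive events
#'   recovered from the enriched fraction.
#' @param cd4_pre positive integer(s): CD4+ cells counted in the reserved
#'   1% pre-enrichment fraction.
#' @return numeric frequency per million (vectorised).
#' @export
#' @examples
#' tmr_frequency(5, 2000)  # 25 per million
tmr_frequency <- function(tmr_events, cd4_pre) {
  stopifnot(all(tmr_events >= 0))
  if (any(cd4_pre <= 0))
    stop("cd4_pre must be positive: frequency undefined otherwise")
  (1e6 * tmr_events) / (100 * cd4_pre)
}

#' Combined citrullinated-antigen frequency for one subject
#'
#' Sums the per-antigen frequencies over the four citrullinated
#' specificities, excluding the influenza control. All four must be
#' present (a missing antigen is an error naming it); `combine = "mean"`
#' is available for the averaged variant.
#'
#' @param freqs named numeric vector of per-antigen frequencies.
#' @param cit_antigens names of the citrullinated antigens to combine.
#' @param combine `"sum"` (default) or `"mean"`.
#' @return single combined frequency.
#' @export
#' @examples
#' combine_cit(c("cit-aggrecan" = 1, "cit-CILP" = 2,
#'               "cit-vimentin/fibrinogen" = 3, "cit-alpha-enolase" = 4,
#'               "influenza" = 50))
combine_cit <- function(freqs,
                        cit_antigens = c("cit-aggrecan", "cit-CILP",
                                         "cit-vimentin/fibrinogen",
                                         "cit-alpha-enolase"),
                        combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  miss <- setdiff(cit_antigens, names(freqs))
  if (length(miss))
    stop("missing cit antigen(s): ", paste(miss, collapse = ", "))
  v <- freqs[cit_antigens]
  if (combine == "sum") sum(v) else mean(v)
}

#' Per-subject tetramer frequency table
#'
#' Convenience wrapper turning a long table of tetramer counts into
#' per-subject per-antigen frequencies plus the combined citrullinated
#' frequency. Subjects with a non-positive pre-enrichment CD4 count are
#' excluded (frequency undefined) with a message.
#'
#' @param counts data frame with `subject`, `group`, `antigen`,
#'   `tmr_events`, `cd4_pre`.
#' @param cit_antigens,combine passed to [combine_cit()].
#' @return data frame, one row per subject: `subject`, `group`, one column
#'   per antigen, and `combined_cit`.
#' @export
tmr_frequency_table <- function(counts,
                                cit_antigens = c("cit-aggrecan", "cit-CILP",
                                                 "cit-vimentin/fibrinogen",
                                                 "cit-alpha-enolase"),
                                combine = "sum") {
  bad <- counts$cd4_pre <= 0
  if (any(bad)) {
    message(length(unique(counts$subject[bad])),
            " subject(s) excluded: non-positive pre-enrichment CD4 count")
    counts <- counts[!counts$subject %in% counts$subject[bad], ,
                     drop = FALSE]
  }
  counts$freq <- tmr_frequency(counts$tmr_events, counts$cd4_pre)
  wide <- stats::reshape(
    counts[, c("subject", "group", "antigen", "freq")],
    idvar = c("subject", "group"), timevar = "antigen",
    direction = "wide")
  names(wide) <- sub("^freq\\.", "", names(wide))
  wide$combined_cit <- apply(wide[, setdiff(names(wide),
                                            c("subject", "group")),
                                  drop = FALSE], 1, function(r)
    combine_cit(unlist(r), cit_antigens, combine))
  rownames(wide) <- NULL
  wide
}

#' Wilcoxon rank-sum comparison of per-subject values between groups
#'
#' Two-sided unpaired Wilcoxon (Mann-Whitney) test for each requested
#' group pair; exact p for small untied samples, normal approximation
#' with tie correction otherwise (the [stats::wilcox.test()] policy).
#' All-tied input yields p = 1 with a warning rather than an error.
#'
#' @param values numeric vector of per-subject statistics.
#' @param groups factor/character of group labels, same length.
#' @param pairs list of group pairs to compare; default control vs
#'   at-risk and at-risk vs early RA.
#' @return data frame of class `group_comparison` with `comparison`,
#'   `estimate` (difference of group medians), `p`, `n_a`, `n_b`.
#' @export
compare_tmr_groups <- function(values, groups,
                               pairs = list(c("ctrl", "at_risk"),
                                            c("at_risk", "early_ra"))) {
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    if (length(a) < 2 || length(b) < 2)
      stop("need >=2 subjects per group for ", paste(pr, collapse = " vs "))
    if (length(unique(c(a, b))) == 1) {
      warning("all values tied for ", paste(pr, collapse = " vs "),
              "; p set to 1")
      p <- 1
    } else {
      p <- suppressWarnings(wilcox.test(a, b)$p.value)
    }
    data.frame(comparison = paste(pr, collapse = "_vs_"),
               estimate = stats::median(b) - stats::median(a),
               p = p, n_a = length(a), n_b = length(b),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("group_comparison", class(out))
  out
}
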