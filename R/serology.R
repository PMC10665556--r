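#' Call antibody positivity against control-derived thresholds
#'
#' An antibody is positive for a subject when its MFI is at or above
#' `mean + sd_mult * SD` of the control-group MFI for that antigen
#' (default 3 SD; the boundary is inclusive). Antigens with zero control
#' variance fall back to the control mean as threshold, with a warning.
#'
#' @param arr a [serum_array()].
#' @param ctrl_group control group label (default `"ctrl"`).
#' @param sd_mult SD multiplier (default 3).
#' @return list of class `positivity_calls`: `calls` (logical subjects x
#'   antigens), `thresholds` (named numeric).
#' @export
call_positivity <- function(arr, ctrl_group = "ctrl", sd_mult = 3) {
  stopifnot(inherits(arr, "serum_array"))
  ctrl <- arr$covariates$group == ctrl_group
  if (sum(ctrl) < 2)
    stop("need at least 2 control subjects to set thresholds")
  mu <- colMeans(arr$mfi[ctrl, , drop = FALSE])
  sdv <- apply(arr$mfi[ctrl, , drop = FALSE], 2, sd)
  if (any(sdv == 0))
    warning("zero control variance for antigen(s): ",
            paste(colnames(arr$mfi)[sdv == 0], collapse = ", "),
            "; threshold set to control mean")
  thr <- mu + sd_mult * sdv
  calls <- sweep(arr$mfi, 2, thr, ">=")
  structure(list(calls = calls, thresholds = thr), class = "positivity_calls")
}

#' Summed antigen-group levels and positivity counts
#'
#' Aggregates similar peptides by summing MFI within each antigen summing
#' group, and counts positive antibodies per subject, overall and per
#' group. The total count always equals the sum of group counts plus
#' ungrouped positives.
#'
#' @param arr a [serum_array()].
#' @param calls a `positivity_calls` object from [call_positivity()].
#' @return list: `group_sums` (subjects x antigen groups MFI sums),
#'   `group_counts` (subjects x antigen groups positive counts),
#'   `total_count` (named integer vector), `ungrouped_count`.
#' @export
summarize_antigen_groups <- function(arr, calls) {
  stopifnot(inherits(arr, "serum_array"),
            inherits(calls, "positivity_calls"))
  grp <- arr$antigen_meta$antigen_group
  groups <- sort(unique(grp[!is.na(grp)]))
  n <- nrow(arr$mfi)
  agg <- function(m) {
    out <- matrix(numeric(0), n, 0,
                  dimnames = list(rownames(arr$mfi), NULL))
    if (length(groups))
      out <- vapply(groups, function(g)
        rowSums(m[, which(grp == g), drop = FALSE]), numeric(n))
    out
  }
  group_sums <- agg(arr$mfi)
  group_counts <- agg(calls$calls)
  list(group_sums = group_sums,
       group_counts = group_counts,
       total_count = rowSums(calls$calls),
       ungrouped_count = rowSums(calls$calls[, is.na(grp), drop = FALSE]))
}

# Fit one covariate-adjusted two-group model. family: gaussian for levels,
# binomial for single-antigen positivity, poisson for positivity counts.
# Returns the group coefficient (pair[2] relative to pair[1]), its
# two-sided p, and a separation flag for logistic fits. On separation the
# estimate is refit with a small ridge penalty (glmnet) and p is NA.
fit_one_model <- function(y, covars, pair, family = "gaussian",
                          adjust = c("age", "sex", "smoking_ever")) {
  keep <- covars$group %in% pair
  dat <- data.frame(y = y[keep], covars[keep, c("group", adjust),
                                        drop = FALSE])
  cc <- complete.cases(dat)
  if (!all(cc)) message(sum(!cc), " row(s) with missing covariates dropped")
  dat <- dat[cc, , drop = FALSE]
  dat$group <- factor(dat$group, levels = pair)
  fam <- switch(family, gaussian = stats::gaussian(),
                binomial = binomial(), poisson = poisson())
  form <- stats::reformulate(c("group", adjust), response = "y")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = dat, family = fam),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg))
        sep <<- TRUE
      # sparse-outcome fitting noise is expected for rare positives;
      # the separation flag and NA p carry the information instead
      if (grepl("fitted (probabilities|rates) numerically|did not converge",
                msg))
        invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  row <- paste0("group", pair[2])
  est <- if (row %in% rownames(co)) co[row, 1] else NA_real_
  p <- if (row %in% rownames(co)) co[row, 4] else NA_real_
  disp <- NA_real_
  if (family == "poisson")
    disp <- sum(stats::residuals(fit, type = "pearson")^2) /
      stats::df.residual(fit)
  if (sep && family == "binomial") {
    # penalized (ridge) fallback: stabilises the estimate; no valid Wald p
    if (length(table(dat$y)) == 2 && all(table(dat$y) >= 8) &&
        requireNamespace("glmnet", quietly = TRUE)) {
      x <- stats::model.matrix(form, dat)[, -1, drop = FALSE]
      pf <- glmnet::glmnet(x, dat$y, family = "binomial", alpha = 0,
                           lambda = 0.1)
      est <- coef(pf)[row, 1]
    }
    p <- NA_real_
  }
  list(estimate = est, p = p, separation = sep, dispersion = disp,
       n = nrow(dat))
}

#' Covariate-adjusted group comparisons for antibody-array outcomes
#'
#' For a pair of participant groups, models each target while adjusting
#' for age, sex and smoking status (ever/never):
#'
#' * `outcome = "level"`: linear regression of antibody level, per
#'   individual antigen and per summed antigen group. Levels are modeled
#'   as `log(MFI + 1)` by default (`log_mfi = FALSE` for raw).
#' * `outcome = "positivity"`: logistic regression of the per-antigen
#'   positive/negative call.
#' * `outcome = "count"`: Poisson regression of positivity counts (total
#'   and per antigen group), with the Pearson dispersion statistic
#'   reported.
#'
#' The group-coefficient two-sided p-values are Benjamini-Hochberg
#' adjusted within the call (one outcome type x one pairwise comparison
#' is the FDR family).
#'
#' @param arr a [serum_array()].
#' @param outcome `"level"`, `"positivity"` or `"count"`.
#' @param pair character vector of two group labels, second vs first.
#' @param calls a `positivity_calls` object (required for positivity and
#'   count outcomes; computed from `arr` if omitted).
#' @param log_mfi model levels on log(MFI + 1) (default TRUE).
#' @param adjust covariate columns to adjust for.
#' @return data frame of class `group_comparison`: `outcome`, `target`,
#'   `comparison`, `estimate`, `p`, `fdr`, `separation`, `dispersion`,
#'   `n`.
#' @export
fit_group_models <- function(arr, outcome = c("level", "positivity",
                                              "count"),
                             pair = c("ctrl", "at_risk"), calls = NULL,
                             log_mfi = TRUE,
                             adjust = c("age", "sex", "smoking_ever")) {
  stopifnot(inherits(arr, "serum_array"))
  outcome <- match.arg(outcome)
  if (outcome != "level" && is.null(calls)) calls <- call_positivity(arr)
  covars <- arr$covariates
  missing_groups <- setdiff(pair, covars$group)
  if (length(missing_groups))
    stop("group(s) absent: ", paste(missing_groups, collapse = ", "))

  targets <- switch(outcome,
    level = {
      summ <- summarize_antigen_groups(arr, calls %||% call_positivity(arr))
      tr <- function(v) if (log_mfi) log(v + 1) else v
      c(lapply(setNames(colnames(arr$mfi), colnames(arr$mfi)),
               function(a) list(y = tr(arr$mfi[, a]), fam = "gaussian")),
        local({
          gs <- colnames(summ$group_sums) %||% character(0)
          nm <- if (length(gs)) paste0("sum:", gs) else character(0)
          lapply(setNames(gs, nm),
                 function(g) list(y = tr(summ$group_sums[, g]),
                                  fam = "gaussian"))
        }))
    },
    positivity = lapply(setNames(colnames(calls$calls),
                                 colnames(calls$calls)),
                        function(a) list(y = as.numeric(calls$calls[, a]),
                                         fam = "binomial")),
    count = {
      summ <- summarize_antigen_groups(arr, calls)
      c(list(total = list(y = summ$total_count, fam = "poisson")),
        local({
          gc_ <- colnames(summ$group_counts) %||% character(0)
          nm <- if (length(gc_)) paste0("count:", gc_) else character(0)
          lapply(setNames(gc_, nm),
                 function(g) list(y = summ$group_counts[, g],
                                  fam = "poisson"))
        }))
    })

  res <- do.call(rbind, lapply(names(targets), function(tn) {
    tg <- targets[[tn]]
    fit <- fit_one_model(tg$y, covars, pair, family = tg$fam,
                         adjust = adjust)
    data.frame(outcome = outcome, target = tn,
               comparison = paste(pair, collapse = "_vs_"),
               estimate = fit$estimate, p = fit$p,
               separation = fit$separation, dispersion = fit$dispersion,
               n = fit$n, stringsAsFactors = FALSE)
  }))
  res$fdr <- fdr_adjust(res$p)
  res <- res[, c("outcome", "target", "comparison", "estimate", "p",
                 "fdr", "separation", "dispersion", "n")]
  class(res) <- c("group_comparison", class(res))
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; monotone and never below the raw p. Missing
#' p-values are passed through untouched and do not count towards the
#' family size.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.04))  # 0.02, 0.04
fdr_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Group comparisons stratified by *04:01 carriage
#'
#' Re-fits [fit_group_models()] separately within the *04:01-positive and
#' *04:01-negative strata, with the same covariates. Strata with fewer
#' than `min_n` subjects in either group are skipped with a message.
#'
#' @param arr a [serum_array()].
#' @param outcome,pair,calls,log_mfi,adjust passed to
#'   [fit_group_models()].
#' @param min_n minimum subjects per group per stratum (default 5).
#' @return data frame like [fit_group_models()] with an extra `stratum`
#'   column (`"0401_pos"` / `"0401_neg"`).
#' @export
stratify_by_allele <- function(arr, outcome = "level",
                               pair = c("ctrl", "at_risk"), calls = NULL,
                               log_mfi = TRUE,
                               adjust = c("age", "sex", "smoking_ever"),
                               min_n = 5) {
  out <- list()
  for (pos in c(TRUE, FALSE)) {
    sel <- arr$covariates$hla0401 == pos
    lab <- if (pos) "0401_pos" else "0401_neg"
    tab <- table(factor(arr$covariates$group[sel], levels = pair))
    if (any(tab < min_n)) {
      message("stratum ", lab, " skipped: fewer than ", min_n,
              " subjects in a group")
      next
    }
    sub <- serum_array(arr$mfi[sel, , drop = FALSE],
                       arr$covariates[sel, , drop = FALSE],
                       arr$antigen_meta)
    sub_calls <- if (is.null(calls)) NULL else
      structure(list(calls = calls$calls[sel, , drop = FALSE],
                     thresholds = calls$thresholds),
                class = "positivity_calls")
    r <- fit_group_models(sub, outcome, pair, calls = sub_calls,
                          log_mfi = log_mfi, adjust = adjust)
    r$stratum <- lab
    out[[lab]] <- r
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

#' Spearman correlation between T-cell frequencies and antibody levels
#'
#' Two-sided Spearman rank correlation on paired per-subject values
#' (e.g. CILP-reactive T-cell frequency vs anti-CILP antibody level).
#' A constant vector makes the correlation undefined; the result is
#' flagged rather than raising.
#'
#' @param tcell_freq,ab_level paired numeric vectors, length >= 3.
#' @return list `rho`, `p`, `n`, `undefined`.
#' @export
tcell_ab_correlation <- function(tcell_freq, ab_level) {
  keep <- complete.cases(tcell_freq, ab_level)
  x <- tcell_freq[keep]; y <- ab_level[keep]
  if (length(x) < 3) stop("need at least 3 paired subjects")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                undefined = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       undefined = FALSE)
}
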