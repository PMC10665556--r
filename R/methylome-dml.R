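#' Remove blacklisted probes from a beta matrix
#'
#' Generic probe-level filter standing in for array QC steps such as
#' SNP-overlapping or cross-reactive probe removal: any probe on the
#' supplied blacklist is dropped, and probe order is otherwise preserved.
#'
#' @param beta a [beta_matrix()].
#' @param blacklist character vector of probe ids to remove.
#' @return a filtered [beta_matrix()].
#' @export
#' @examples
#' out <- make_beta_matrix(synth_config(n_probes = 20, n_planted_dml = 0,
#'                                      cell_types = "Tmem"))
#' filter_probes(out$beta, rownames(out$beta$values)[1:2])
filter_probes <- function(beta, blacklist) {
  stopifnot(inherits(beta, "beta_matrix"))
  hit <- rownames(beta$values) %in% blacklist
  if (length(blacklist) && !any(hit))
    warning("blacklist does not overlap the probe set; nothing removed")
  keep <- !hit
  if (!any(keep)) stop("all probes removed by blacklist")
  subset_beta(beta, probes = keep)
}

#' Convert beta fractions to M-values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into
#' \[clip, 1 - clip\] so the transform stays finite at fully
#' methylated/unmethylated probes.
#'
#' @param beta a [beta_matrix()] or a bare numeric matrix/vector.
#' @param clip clipping fraction in (0, 0.5).
#' @return an object of class `m_matrix` (list with `values`,
#'   `sample_meta`) for a beta_matrix input, otherwise a numeric object of
#'   the input shape.
#' @export
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0 and 2
beta_to_m <- function(beta, clip = 1e-3) {
  stopifnot(clip > 0, clip < 0.5)
  f <- function(v) log2(pmin(pmax(v, clip), 1 - clip) /
                          (1 - pmin(pmax(v, clip), 1 - clip)))
  if (inherits(beta, "beta_matrix"))
    structure(list(values = f(beta$values), sample_meta = beta$sample_meta),
              class = "m_matrix")
  else f(beta)
}

#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, the per-locus test used by the differential-methylation caller.
#' Degenerate input (fewer than two non-missing values per group, or zero
#' pooled standard error) yields a missing p-value with a `degenerate`
#' flag rather than an error, so matrix-wide callers can log and skip.
#'
#' @param x,y numeric vectors (missing values dropped).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                degenerate = TRUE))
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / length(x) + v2 / length(y)
  if (se2 == 0) {
    return(list(t = 0, df = NA_real_,
                p = if (mean(x) == mean(y)) 1 else NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

# Vectorised row-wise Welch test: rows of `vals`, columns split by idx_a /
# idx_b. Pairwise-complete: NAs are dropped per row and group. This is the
# performance path behind call_dml(); tests compare it against a per-locus
# t.test() loop.
row_welch <- function(vals, idx_a, idx_b) {
  a <- vals[, idx_a, drop = FALSE]
  b <- vals[, idx_b, drop = FALSE]
  na_ <- rowSums(!is.na(a)); nb_ <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na_ - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb_ - 1, 1)
  se2 <- va / na_ + vb / nb_
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / pmax(na_ - 1, 1) +
                   (vb / nb_)^2 / pmax(nb_ - 1, 1))
  p <- 2 * pt(-abs(t), df)
  degen <- na_ < 2 | nb_ < 2 | se2 == 0
  p[degen] <- NA_real_
  data.frame(mean_a = ma, mean_b = mb, delta_beta = ma - mb,
             t = t, df = df, p = p, degenerate = degen)
}

#' Call differentially methylated loci
#'
#' Per cohort and cell type, each probe is tested between two participant
#' groups with Welch's t-test on beta values, and called a DML when
#' `p < alpha` **and** `|delta beta| > delta_beta` (no multiple-testing
#' correction; the unadjusted-p rule is deliberate and matches common
#' practice for this two-gate definition). With three groups, mode
#' `"any_pair"` runs all three pairwise comparisons and a probe is a DML
#' if any pair passes both gates; mode `"pairwise"` requires an explicit
#' `comparison` pair.
#'
#' @param beta a [beta_matrix()].
#' @param comparison character vector of two group labels, or of three or
#'   more labels with `mode = "any_pair"`.
#' @param alpha p-value gate (default 0.05).
#' @param delta_beta absolute mean beta-difference gate (default 0.1).
#' @param mode `"pairwise"` or `"any_pair"`.
#' @return a data frame of class `dml_result`, one row per probe x pair x
#'   cohort x cell type, with columns `cohort`, `cell_type`, `comparison`,
#'   `probe_id`, `mean_a`, `mean_b`, `delta_beta`, `t`, `df`, `p`,
#'   `called`. Probes with degenerate variance carry `p = NA` and are
#'   never called; their count is reported via `message()`.
#' @export
call_dml <- function(beta, comparison, alpha = 0.05, delta_beta = 0.1,
                     mode = c("pairwise", "any_pair")) {
  stopifnot(inherits(beta, "beta_matrix"))
  mode <- match.arg(mode)
  meta <- beta$sample_meta
  missing_groups <- setdiff(comparison, meta$group)
  if (length(missing_groups))
    stop("group(s) not present in sample metadata: ",
         paste(missing_groups, collapse = ", "))
  if (mode == "pairwise" && length(comparison) != 2)
    stop("pairwise mode needs exactly two groups")
  pairs <- if (mode == "pairwise") list(comparison) else
    utils::combn(comparison, 2, simplify = FALSE)

  out <- list()
  for (co in unique(meta$cohort)) {
    for (ct in unique(meta$cell_type)) {
      sel <- meta$cohort == co & meta$cell_type == ct
      for (pr in pairs) {
        ia <- which(sel & meta$group == pr[1])
        ib <- which(sel & meta$group == pr[2])
        if (!length(ia) || !length(ib)) next
        res <- row_welch(beta$values, ia, ib)
        res <- cbind(data.frame(cohort = co, cell_type = ct,
                                comparison = paste(pr, collapse = "_vs_"),
                                probe_id = rownames(beta$values),
                                stringsAsFactors = FALSE),
                     res)
        out[[length(out) + 1]] <- res
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$called <- !is.na(res$p) & res$p < alpha &
    abs(res$delta_beta) > delta_beta
  n_degen <- sum(res$degenerate)
  if (n_degen) message(n_degen, " probe tests had degenerate variance ",
                       "and were excluded from calling")
  class(res) <- c("dml_result", class(res))
  res
}

#' Extract the called DML probe set
#'
#' Collapses a [call_dml()] result to the unique probe ids called in a
#' given cohort/cell type (any passing pair counts under `any_pair` mode).
#'
#' @param dml a `dml_result` data frame.
#' @param cohort,cell_type optional filters.
#' @return character vector of probe ids.
#' @export
dml_set <- function(dml, cohort = NULL, cell_type = NULL) {
  keep <- dml$called
  if (!is.null(cohort)) keep <- keep & dml$cohort %in% cohort
  if (!is.null(cell_type)) keep <- keep & dml$cell_type %in% cell_type
  unique(dml$probe_id[keep])
}

#' Cross-cohort replication of DML sets
#'
#' Tests whether the overlap between the DML sets of two independent
#' cohorts exceeds chance with an exact upper-tail hypergeometric test on
#' the filtered-probe universe, and returns the union set that downstream
#' gene mapping consumes.
#'
#' @param dml1,dml2 character vectors of called probe ids per cohort.
#' @param universe integer, number of filtered loci tested in both
#'   cohorts.
#' @return object of class `overlap_test`: list with `n_universe`, `k1`,
#'   `k2`, `overlap`, `p`, `union`, `intersection`.
#' @export
#' @examples
#' cross_cohort(letters[1:5], letters[2:5], universe = 10)$p
cross_cohort <- function(dml1, dml2, universe) {
  dml1 <- unique(dml1); dml2 <- unique(dml2)
  un <- union(dml1, dml2)
  if (universe < length(un))
    stop("universe (", universe, ") smaller than |union| (", length(un), ")")
  m <- length(intersect(dml1, dml2))
  K <- length(dml1); n <- length(dml2)
  p <- phyper(m - 1, K, universe - K, n, lower.tail = FALSE)
  structure(list(n_universe = universe, k1 = K, k2 = n, overlap = m,
                 p = p, union = un, intersection = intersect(dml1, dml2)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Cross-cohort overlap:", x$overlap, "of", x$k1, "and", x$k2,
      "DML on a universe of", x$n_universe, "loci\n")
  cat("  hypergeometric upper-tail p =", format(x$p, digits = 4), "\n")
  cat("  |union| =", length(x$union), "\n")
  invisible(x)
}
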