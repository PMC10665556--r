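make_test_array <- function(mfi, groups, age = NULL, panel = NULL) {
  n <- nrow(mfi)
  if (is.null(panel))
    panel <- data.frame(antigen = colnames(mfi), citrullinated = TRUE,
                        antigen_group = NA_character_)
  cov <- data.frame(subject = rownames(mfi), group = groups,
                    age = age %||% rnorm(n, 55, 10),
                    sex = sample(c("F", "M"), n, TRUE),
                    smoking_ever = sample(c(TRUE, FALSE), n, TRUE),
                    hla0401 = sample(c(TRUE, FALSE), n, TRUE))
  serum_array(mfi, cov, panel)
}

test_that("positivity calls follow the 3-SD rule with inclusive boundary", {
  set.seed(1)
  n_ctrl <- 40
  mfi <- matrix(rnorm(n_ctrl + 2, 100, 10), ncol = 1,
                dimnames = list(sprintf("s%02d", 1:(n_ctrl + 2)), "ag1"))
  groups <- c(rep("ctrl", n_ctrl), "at_risk", "at_risk")
  arr <- make_test_array(abs(mfi), groups)
  thr <- call_positivity(arr)$thresholds
  # plant values just above/below the threshold
  arr$mfi[n_ctrl + 1, 1] <- thr + 1   # above: positive
  arr$mfi[n_ctrl + 2, 1] <- thr - 1   # below: negative
  calls <- call_positivity(arr)
  expect_true(calls$calls[n_ctrl + 1, 1])
  expect_false(calls$calls[n_ctrl + 2, 1])
  # boundary inclusive
  arr$mfi[n_ctrl + 2, 1] <- calls$thresholds
  expect_true(call_positivity(arr)$calls[n_ctrl + 2, 1])
  # zero control variance: warn, threshold = mean
  arr$mfi[1:n_ctrl, 1] <- 100
  expect_warning(cz <- call_positivity(arr), "zero control variance")
  expect_equal(unname(cz$thresholds), 100)
  expect_error(call_positivity(make_test_array(abs(mfi),
                                               rep("at_risk", n_ctrl + 2))),
               "2 control subjects")
})

test_that("positivity thresholds track the control distribution", {
  set.seed(2)
  mfi <- matrix(rlnorm(60, 5, 0.4), ncol = 2,
                dimnames = list(sprintf("s%02d", 1:30),
                                c("ag1", "ag2")))
  arr <- make_test_array(mfi, rep(c("ctrl", "at_risk"), each = 15))
  c1 <- call_positivity(arr)
  # shifting everyone (controls included) leaves the calls unchanged
  arr2 <- arr; arr2$mfi <- arr$mfi + 500
  expect_identical(call_positivity(arr2)$calls, c1$calls)
  # shifting only non-controls changes calls
  arr3 <- arr
  arr3$mfi[16:30, ] <- arr3$mfi[16:30, ] * 10
  expect_false(identical(call_positivity(arr3)$calls, c1$calls))
})

test_that("null control positivity rate matches the 3-SD normal tail", {
  set.seed(3)
  # normal null: P(X >= mu + 3 sd-hat) ~ pnorm(-3) ~ 0.00135
  mfi <- matrix(abs(rnorm(200 * 50, 500, 40)), 200,
                dimnames = list(sprintf("s%03d", 1:200),
                                sprintf("ag%02d", 1:50)))
  arr <- make_test_array(mfi, rep("ctrl", 200))
  rate <- mean(call_positivity(arr)$calls)
  expect_lt(rate, 0.004)
  expect_gt(rate, 0.0002)
})

test_that("antigen-group summaries conserve counts and sums", {
  set.seed(4)
  panel <- data.frame(antigen = paste0("ag", 1:6),
                      citrullinated = TRUE,
                      antigen_group = c("gA", "gA", "gA", "gA", "gB", NA))
  mfi <- matrix(rlnorm(20 * 6, 5, 0.5), 20,
                dimnames = list(sprintf("s%02d", 1:20), panel$antigen))
  arr <- make_test_array(mfi, rep(c("ctrl", "at_risk"), each = 10),
                         panel = panel)
  calls <- call_positivity(arr)
  summ <- summarize_antigen_groups(arr, calls)
  expect_equal(summ$group_sums[, "gA"], rowSums(mfi[, 1:4]))
  expect_equal(summ$total_count,
               rowSums(summ$group_counts) + summ$ungrouped_count)
  # a subject positive for 3 of 4 gA antigens has group count 3
  i <- which(rowSums(calls$calls[, 1:4]) == 3)
  if (length(i))
    expect_equal(unname(summ$group_counts[i[1], "gA"]), 3)
  # all-zero MFI edge
  arr0 <- arr; arr0$mfi[] <- 0
  expect_warning(calls0 <- call_positivity(arr0))
  summ0 <- summarize_antigen_groups(arr0, calls0)
  expect_true(all(summ0$group_sums == 0))
})

test_that("group model coefficients match an independent IRLS oracle", {
  set.seed(5)
  n <- 40
  cov <- data.frame(group = rep(c("ctrl", "at_risk"), each = n / 2),
                    age = rnorm(n, 55, 10),
                    sex = sample(c("F", "M"), n, TRUE),
                    smoking_ever = sample(c(TRUE, FALSE), n, TRUE))
  X <- cbind(1, cov$group == "at_risk", cov$age, cov$sex == "M",
             cov$smoking_ever)
  irls <- function(y, family) {
    b <- rep(0, ncol(X))
    if (family == "gaussian") return(solve(crossprod(X), crossprod(X, y)))
    for (it in 1:50) {
      eta <- X %*% b
      mu <- if (family == "binomial") 1 / (1 + exp(-eta)) else exp(eta)
      w <- if (family == "binomial") mu * (1 - mu) else mu
      z <- eta + (y - mu) / w
      b_new <- solve(crossprod(X * sqrt(as.numeric(w))),
                     crossprod(X * as.numeric(w), z))
      if (max(abs(b_new - b)) < 1e-10) break
      b <- b_new
    }
    b
  }
  for (fam in c("gaussian", "binomial", "poisson")) {
    y <- switch(fam, gaussian = rnorm(n, 5 + (cov$group == "at_risk")),
                binomial = rbinom(n, 1, 0.3 +
                                    0.3 * (cov$group == "at_risk")),
                poisson = rpois(n, exp(0.5 + 0.4 *
                                         (cov$group == "at_risk"))))
    fit <- atriskimmune:::fit_one_model(y, cov, c("ctrl", "at_risk"),
                                        family = fam)
    expect_equal(fit$estimate, irls(y, fam)[2], tolerance = 1e-6)
  }
})

test_that("fit_group_models recovers a planted level shift with FDR control", {
  cfg <- tiny_cfg(seed = 6,
                  n_serum = c(ctrl = 80, at_risk = 60, early_ra = 20),
                  antigen_effects = list(at_risk = c("cit-clusterin" = 2.5)))
  arr <- make_serum_array(cfg)
  res <- fit_group_models(arr, "level", c("ctrl", "at_risk"))
  sig <- res$target[res$fdr < 0.05]
  expect_true("sum:cit-clusterin" %in% sig)
  # untargeted sums stay quiet
  expect_false("sum:cit-fibrinogen" %in% sig)
  expect_true(all(res$fdr >= res$p, na.rm = TRUE))
})

test_that("positivity and count outcomes run with sane output schema", {
  cfg <- tiny_cfg(seed = 7,
                  n_serum = c(ctrl = 60, at_risk = 50, early_ra = 30))
  arr <- make_serum_array(cfg)
  calls <- call_positivity(arr)
  pos <- fit_group_models(arr, "positivity", c("at_risk", "early_ra"),
                          calls = calls)
  cnt <- fit_group_models(arr, "count", c("at_risk", "early_ra"),
                          calls = calls)
  expect_equal(nrow(pos), ncol(arr$mfi))
  expect_true("total" %in% cnt$target)
  expect_true(all(is.finite(cnt$dispersion)))  # dispersion reported
  expect_identical(names(pos), names(cnt))
  expect_error(fit_group_models(arr, "level", c("ctrl", "missing")),
               "absent")
})

test_that("BH adjustment is monotone and never below raw p", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    q <- fdr_adjust(p)
    expect_true(all(q >= p))
    # definitional step-up oracle
    m <- length(p); o <- order(p)
    want <- rev(cummin(rev(p[o] * m / seq_len(m))))
    expect_equal(q[o], pmin(want, 1))
  }
})

test_that("allele stratification refits within strata and skips small ones", {
  cfg <- tiny_cfg(seed = 9,
                  n_serum = c(ctrl = 70, at_risk = 60, early_ra = 20))
  arr <- make_serum_array(cfg)
  res <- stratify_by_allele(arr, "level", c("ctrl", "at_risk"))
  expect_setequal(unique(res$stratum), c("0401_pos", "0401_neg"))
  # same schema as the pooled fit (plus stratum)
  pooled <- fit_group_models(arr, "level", c("ctrl", "at_risk"))
  expect_identical(setdiff(names(res), "stratum"), names(pooled))
  # tiny strata are skipped with a message
  arr2 <- arr
  arr2$covariates$hla0401 <- FALSE
  arr2$covariates$hla0401[1:2] <- TRUE
  expect_message(r2 <- stratify_by_allele(arr2, "level",
                                          c("ctrl", "at_risk")),
                 "skipped")
  expect_false("0401_pos" %in% r2$stratum)
})

test_that("Spearman correlation matches exact permutation and flags constants", {
  expect_equal(tcell_ab_correlation(1:6, (1:6)^2)$rho, 1)
  expect_true(tcell_ab_correlation(rep(1, 5), rnorm(5))$undefined)
  expect_error(tcell_ab_correlation(1:2, 1:2), "3 paired")
  set.seed(10)
  x <- rnorm(6); y <- rnorm(6)
  got <- tcell_ab_correlation(x, y)
  # exact permutation null over all 720 orderings
  rho_obs <- cor(rank(x), rank(y))
  all_rho <- vapply(all_permutations(6), function(idx)
    cor(rank(x), rank(y[idx])), numeric(1))
  p_perm <- mean(abs(all_rho) >= abs(rho_obs) - 1e-12)
  expect_equal(got$p, p_perm, tolerance = 0.02)
})
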