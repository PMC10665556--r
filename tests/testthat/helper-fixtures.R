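# Small shared fixtures and independent oracles used across test files.

# compact synthetic-study config for fast tests
tiny_cfg <- function(seed = 1, ...) {
  defaults <- list(
    n_per_group_per_cohort = rbind(cohort1 = c(ctrl = 6, at_risk = 6,
                                               early_ra = 5),
                                   cohort2 = c(ctrl = 6, at_risk = 6,
                                               early_ra = 5)),
    n_probes = 300, n_planted_dml = 15, delta_beta_effect = 0.25,
    beta_noise_sd = 0.03, cell_types = "Tmem",
    n_subjects_flow = c(ctrl = 3, at_risk = 3, early_ra = 3),
    n_events_flow = 300,
    n_serum = c(ctrl = 25, at_risk = 20, early_ra = 15),
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# textbook Welch t-test: independent of the package's vectorised path
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force per-locus DML caller: loop + stats::t.test
oracle_call_dml <- function(vals, ia, ib, alpha = 0.05, delta = 0.1) {
  called <- logical(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    a <- vals[i, ia]; b <- vals[i, ib]
    if (var(a) == 0 && var(b) == 0) next
    tt <- t.test(a, b)
    called[i] <- tt$p.value < alpha && abs(mean(a) - mean(b)) > delta
  }
  called
}

# upper-tail hypergeometric by explicit pmf summation over choose()
oracle_hyper_p <- function(N, K, n, m) {
  hi <- min(K, n)
  if (m > hi) return(0)
  sum(vapply(m:hi, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
}

# O(n^3) Ward linkage via the Lance-Williams update; returns cutree-style
# labels for k groups. Independent of stats::hclust.
oracle_ward_cut <- function(x, k) {
  n <- nrow(x)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d2 <- as.matrix(dist(x))^2  # ward merge cost on squared distances
  diag(d2) <- Inf
  while (length(active) > k) {
    idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- vapply(seq_along(active), function(l) {
      if (l == i || l == j) return(Inf)
      nl <- sizes[l]
      ((ni + nl) * d2[i, l] + (nj + nl) * d2[j, l] - nl * d2[i, j]) /
        (ni + nj + nl)
    }, numeric(1))
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    d2[i, ] <- new_d; d2[, i] <- new_d
    d2[i, i] <- Inf
    active[[j]] <- NULL
    sizes <- sizes[-j]
    d2 <- d2[-j, -j, drop = FALSE]
  }
  labels <- integer(n)
  for (g in seq_along(active)) labels[active[[g]]] <- g
  labels
}

# adjusted Rand index between two labelings (via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# two-group rank-sum p by full enumeration of group assignments (small n)
oracle_ranksum_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals); na_ <- length(a)
  obs <- sum(rank(vals)[seq_len(na_)])
  combs <- utils::combn(n, na_)
  stat <- apply(combs, 2, function(idx) sum(rank(vals)[idx]))
  mu <- na_ * (n + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

# all permutations of 1:n as a list (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}
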