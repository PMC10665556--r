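test_that("beta to M-value transform matches closed forms", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(1, clip = 1e-3), log2(999))
  expect_equal(beta_to_m(0, clip = 1e-3), -log2(999))
  expect_error(beta_to_m(0.5, clip = 0.6))
})

test_that("welch_t agrees with the textbook formula and handles edge cases", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(4 + i); y <- rnorm(7, 1, 2)
    got <- welch_t(x, y); want <- oracle_welch(x, y)
    expect_equal(got$t, want$t)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p)
  }
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  sep <- welch_t(c(0, 0, 0, 0) + rnorm(4, 0, 1e-6), c(1, 1, 1, 1))
  expect_lt(sep$p, 1e-6)
  degen <- welch_t(c(1, 1, 1), c(2, 2, 2))
  expect_true(degen$degenerate)
})

test_that("filter_probes removes exactly the blacklist", {
  out <- make_beta_matrix(tiny_cfg(n_probes = 10, n_planted_dml = 0))
  bm <- out$beta
  ids <- rownames(bm$values)
  expect_identical(filter_probes(bm, character())$values, bm$values)
  kept <- filter_probes(bm, ids[1:2])
  expect_identical(rownames(kept$values), ids[-(1:2)])
  expect_warning(filter_probes(bm, "cg_nonexistent"), "does not overlap")
  expect_error(filter_probes(bm, ids), "all probes removed")
})

test_that("call_dml equals the brute-force per-locus oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    vals <- matrix(runif(30 * 2 * n), 30,
                   dimnames = list(sprintf("cg%02d", 1:30), NULL))
    meta <- data.frame(sample_id = paste0("s", 1:(2 * n)),
                       subject = paste0("s", 1:(2 * n)),
                       group = rep(c("ctrl", "at_risk"), each = n),
                       cohort = "cohort1", cell_type = "Tmem")
    colnames(vals) <- meta$sample_id
    bm <- beta_matrix(vals, meta)
    got <- call_dml(bm, c("ctrl", "at_risk"))
    want <- oracle_call_dml(vals, 1:n, n + 1:n)
    expect_identical(got$called, want)
  }
})

test_that("the delta-beta gate blocks significant but small effects", {
  set.seed(1)
  n <- 50
  vals <- rbind(small = c(rnorm(n, 0.50, 0.01), rnorm(n, 0.55, 0.01)),
                big = c(rnorm(n, 0.30, 0.01), rnorm(n, 0.60, 0.01)),
                flat = rep(0.4, 2 * n))
  meta <- data.frame(sample_id = paste0("s", 1:(2 * n)),
                     subject = paste0("s", 1:(2 * n)),
                     group = rep(c("ctrl", "at_risk"), each = n),
                     cohort = "cohort1", cell_type = "B")
  colnames(vals) <- meta$sample_id
  res <- suppressMessages(call_dml(beta_matrix(vals, meta),
                                   c("ctrl", "at_risk")))
  expect_lt(res$p[res$probe_id == "small"], 0.05)  # significant...
  expect_false(res$called[res$probe_id == "small"])  # ...but gated out
  expect_true(res$called[res$probe_id == "big"])
  expect_true(is.na(res$p[res$probe_id == "flat"]))  # zero variance
  expect_false(res$called[res$probe_id == "flat"])
})

test_that("DML calls are invariant to sample column order", {
  out <- make_beta_matrix(tiny_cfg(seed = 13))
  bm <- out$beta
  res1 <- call_dml(bm, c("ctrl", "at_risk"))
  perm <- sample(ncol(bm$values))
  res2 <- call_dml(subset_beta(bm, perm), c("ctrl", "at_risk"))
  expect_setequal(dml_set(res1), dml_set(res2))
})

test_that("call_dml names a missing group and validates mode", {
  bm <- make_beta_matrix(tiny_cfg())$beta
  expect_error(call_dml(bm, c("ctrl", "nope")), "nope")
  expect_error(call_dml(bm, c("ctrl", "at_risk", "early_ra"),
                        mode = "pairwise"), "exactly two")
})

test_that("any-pair mode is the union of the pairwise calls", {
  bm <- make_beta_matrix(tiny_cfg(seed = 17))$beta
  all3 <- call_dml(bm, c("ctrl", "at_risk", "early_ra"), mode = "any_pair")
  pairwise <- unique(unlist(lapply(
    list(c("ctrl", "at_risk"), c("ctrl", "early_ra"),
         c("at_risk", "early_ra")),
    function(pr) dml_set(call_dml(bm, pr)))))
  expect_setequal(dml_set(all3), pairwise)
})

test_that("cross_cohort reproduces exact hypergeometric cases", {
  # N=10, K=5, n=4, m=4: C(5,4)C(5,0)/C(10,4) = 5/210
  r <- cross_cohort(letters[1:5], letters[2:5], universe = 10)
  expect_equal(r$overlap, 4)
  expect_equal(r$p, 5 / 210)
  # no overlap: p = 1
  r0 <- cross_cohort(c("a", "b"), c("c", "d"), universe = 10)
  expect_equal(r0$p, 1)
  expect_equal(length(r0$union), r0$k1 + r0$k2 - r0$overlap)
  expect_error(cross_cohort(letters[1:5], letters[6:10], universe = 8),
               "universe")
})

test_that("map_dmg applies the strand-oriented promoter window", {
  ann <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    chrom = "chr1",
    pos = c(9000, 7499, 10500, 11000, 8000, 90000),
    strand = c("+", "+", "+", "-", "-", "+"),
    gene = c("G1", "G1", "G1", "G2", "G2", "G1"),
    tss = c(10000, 10000, 10000, 11500, 11500, 10000),
    gene_start = c(10000, 10000, 10000, 5000, 5000, 10000),
    gene_end = c(20000, 20000, 20000, 11500, 11500, 20000))
  res <- suppressMessages(map_dmg(ann$probe_id, ann))
  get <- function(p) res$region[res$probe_id == p]
  expect_equal(get("p1"), "promoter")        # +, TSS-1000
  expect_length(get("p2"), 0)                # +, TSS-2501: outside (closed)
  expect_equal(get("p3"), "promoter")        # +, TSS+500 boundary
  expect_equal(get("p4"), "promoter")        # -, 500 bp 3' of TSS in genome
  expect_equal(get("p5"), "body")            # -, in gene, outside window
  expect_length(get("p6"), 0)                # far downstream of everything
})

test_that("minus-strand promoter windows are reflected in genomic space", {
  # gene on -, TSS at 11500; probe 1000 bp downstream in genomic
  # coordinates (pos 12500) is upstream in transcription direction
  ann <- data.frame(probe_id = "pm", chrom = "chr1", pos = 12500,
                    strand = "-", gene = "G", tss = 11500,
                    gene_start = 5000, gene_end = 11500)
  expect_equal(map_dmg("pm", ann)$region, "promoter")
  # and 2501 bp downstream falls outside the closed window
  ann$pos <- 11500 + 2501
  expect_equal(nrow(suppressMessages(map_dmg("pm", ann))), 0)
})

test_that("pathway enrichment matches exact enumeration and hand BH", {
  bg <- sprintf("G%02d", 1:20)
  dmg <- bg[1:5]
  # set identical to the DMG: p = C(5,5)C(15,0)/C(20,5)
  res <- pathway_enrichment(dmg, list(hit = dmg), bg)
  expect_equal(res$p, 1 / choose(20, 5))
  # disjoint set: p = 1
  res2 <- pathway_enrichment(dmg, list(none = bg[6:10]), bg)
  expect_equal(res2$p, 1)
  # BH on (0.01, 0.04) -> (0.02, 0.04) [construct sets giving those p]
  expect_equal(fdr_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # generic agreement with the pmf-sum oracle
  set.seed(3)
  for (i in 1:10) {
    s <- sample(bg, sample(3:12, 1))
    r <- pathway_enrichment(dmg, list(s = s), bg)
    expect_equal(r$p, oracle_hyper_p(20, 5, length(s),
                                     length(intersect(dmg, s))))
  }
  expect_error(pathway_enrichment(c(dmg, "NOT_IN_BG"), list(s = dmg), bg),
               "background")
  expect_message(pathway_enrichment(dmg, list(empty = "ZZZ"), bg),
                 "empty")
})

test_that("embeddings preserve geometry and match the eigen oracle", {
  # three collinear samples stay collinear under MDS
  vals <- cbind(a = rep(0, 10), b = rep(1, 10), c = rep(2, 10)) +
    matrix(0, 10, 3)
  rownames(vals) <- paste0("cg", 1:10)
  xy <- embed_samples(vals, "mds", k = 2)
  expect_equal(unname(abs(diff(xy[, 1]))), rep(sqrt(10), 2))
  expect_lt(max(abs(xy[, 2])), 1e-6)

  # PCA coordinates reproduce the covariance eigen-decomposition
  set.seed(8)
  m <- matrix(rnorm(20 * 6), 20, dimnames = list(paste0("cg", 1:20),
                                                 paste0("s", 1:6)))
  pc <- embed_samples(m, "pca", k = 2)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))
  want <- x %*% ev$vectors[, 1:2]
  for (j in 1:2)  # eigenvectors defined up to sign
    expect_equal(abs(unname(pc[, j])), abs(unname(want[, j])))
  expect_error(embed_samples(m[, 1:2], "pca"), "3 samples")
})

test_that("two planted sample blocks separate in the embedding", {
  set.seed(21)
  block <- rep(c(0, 3), each = 5)
  vals <- sapply(block, function(b) rnorm(40, b, 0.5))
  rownames(vals) <- paste0("cg", 1:40)
  colnames(vals) <- paste0("s", 1:10)
  xy <- embed_samples(vals, "mds")
  within <- c(dist(xy[1:5, 1]), dist(xy[6:10, 1]))
  between <- abs(mean(xy[1:5, 1]) - mean(xy[6:10, 1]))
  expect_gt(between, max(within))
})

test_that("hierarchical clustering behaves on duplicates and blocks", {
  set.seed(5)
  base <- matrix(rnorm(30 * 4), 30,
                 dimnames = list(paste0("cg", 1:30), paste0("s", 1:4)))
  dup <- cbind(base, s5 = base[, 1])
  hc <- hier_cluster(dup, rownames(dup))
  coph <- as.matrix(stats::cophenetic(hc$hclust))
  expect_equal(coph["s1", "s5"], 0)
  expect_identical(hc$linkage, "complete")

  block_vals <- sapply(rep(c(0, 4), each = 4), function(b)
    rnorm(30, b, 0.3))
  colnames(block_vals) <- paste0("s", 1:8)
  rownames(block_vals) <- paste0("cg", 1:30)
  hb <- hier_cluster(block_vals, rownames(block_vals))
  expect_equal(unname(cutree(hb$hclust, 2)), rep(1:2, each = 4))
  expect_error(hier_cluster(base[, 1, drop = FALSE], rownames(base)),
               "2 samples")
  expect_error(hier_cluster(base, character()), "non-empty")
})

test_that("classifier is deterministic and near chance on permuted labels", {
  set.seed(77)
  n <- 30
  vals <- rbind(matrix(rnorm(10 * 2 * n, rep(c(0, 1), each = n), 0.4),
                       10, byrow = TRUE),
                matrix(rnorm(20 * 2 * n), 20))
  rownames(vals) <- paste0("cg", 1:30)
  colnames(vals) <- paste0("s", 1:(2 * n))
  meta <- data.frame(sample_id = colnames(vals),
                     group = rep(c("ctrl", "at_risk"), each = n))
  r1 <- classify_one_vs_one(vals, meta, rownames(vals),
                            c("ctrl", "at_risk"), seed = 5)
  r2 <- classify_one_vs_one(vals, meta, rownames(vals),
                            c("ctrl", "at_risk"), seed = 5)
  expect_identical(r1[c("best", "cv_accuracy", "test_accuracy",
                        "top_features")],
                   r2[c("best", "cv_accuracy", "test_accuracy",
                        "top_features")])
  expect_gt(r1$test_accuracy, 0.8)  # separable features present
  expect_length(r1$top_features, 3)  # ceiling(10% of 30)

  perm_meta <- meta
  set.seed(123)
  perm_meta$group <- sample(perm_meta$group)
  accs <- vapply(1:5, function(s)
    classify_one_vs_one(vals, perm_meta, rownames(vals),
                        c("ctrl", "at_risk"), seed = s)$test_accuracy,
    numeric(1))
  expect_lt(mean(accs), 0.75)  # chance band for n_test = 18
  expect_error(classify_one_vs_one(vals, meta[1:10, ], rownames(vals),
                                   c("ctrl", "at_risk")), "at least")
})
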