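#' Arcsinh transform for cytometry intensities
#'
#' `y = asinh(a + b * x)`, the standard variance-stabilising transform for
#' flow/mass cytometry; defaults `a = 0`, `b = 1/150` (cofactor 150).
#'
#' @param x numeric vector/matrix of raw intensities.
#' @param a additive shift (default 0).
#' @param b positive scale (default 1/150).
#' @return transformed values, same shape as `x`.
#' @export
#' @examples
#' arcsinh_transform(150)  # asinh(1) = 0.8814
arcsinh_transform <- function(x, a = 0, b = 1 / 150) {
  stopifnot(b > 0)
  asinh(a + b * x)
}

landscape_markers <- function() {
  c("CD45RA", "CD38", "CCR4", "CCR6", "CXCR3", "CCR7")
}

#' Cluster one subject's events into individual clusters
#'
#' Phenograph-family clustering: a k-nearest-neighbour graph is built on
#' the transformed marker space and partitioned by Louvain modularity
#' community detection. Deterministic given `seed`. For very small event
#' tables a k-means fallback mode is available.
#'
#' @param x numeric matrix events x markers (transformed space).
#' @param k_neighbors neighbours per event for the kNN graph (default 30).
#' @param resolution Louvain resolution; values below 1 favour coarser
#'   communities (default 1, phenograph-like granularity).
#' @param seed integer seed.
#' @param method `"knn_louvain"` (default) or `"kmeans"`.
#' @param kmeans_centers centers for the fallback mode (default 8, capped
#'   at n/3).
#' @return integer vector of cluster labels (1-based), one per event.
#' @export
cluster_sample <- function(x, k_neighbors = 30, seed = 1L,
                           method = c("knn_louvain", "kmeans"),
                           kmeans_centers = 8, resolution = 1) {
  method <- match.arg(method)
  n <- nrow(x)
  set.seed(seed)
  if (method == "kmeans") {
    centers <- min(kmeans_centers, max(1, n %/% 3))
    return(kmeans(x, centers = centers, nstart = 5)$cluster)
  }
  if (n < k_neighbors + 1)
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1, " events")
  d <- as.matrix(dist(x))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[2:(k_neighbors + 1)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

#' Per-cluster z-score profiles with an abundance floor
#'
#' For each individual cluster, its per-marker mean expression is
#' expressed as a z-score against the subject's total CD4+ events
#' (`z = (cluster mean - subject mean) / subject SD`, computed in
#' transformed space); clusters at or below the frequency floor
#' (default 1%) are dropped from alignment. A marker with zero
#' subject-level SD yields z = 0 with a message.
#'
#' @param x numeric matrix events x markers (transformed space).
#' @param labels integer cluster labels from [cluster_sample()].
#' @param subject subject id recorded in the output.
#' @param min_frac abundance floor; clusters with frequency <= this are
#'   flagged not-kept (default 0.01).
#' @return data frame: `subject`, `cluster`, `freq`, `kept`, and one
#'   `z_<marker>` column per marker. Frequencies over all clusters sum
#'   to 1.
#' @export
profile_and_filter <- function(x, labels, subject = "s1",
                               min_frac = 0.01) {
  stopifnot(nrow(x) == length(labels))
  mu <- colMeans(x); sdv <- apply(x, 2, sd)
  if (any(sdv == 0)) {
    message("marker(s) with zero subject SD: ",
            paste(colnames(x)[sdv == 0], collapse = ", "),
            "; z set to 0")
  }
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    sel <- labels == cl
    z <- (colMeans(x[sel, , drop = FALSE]) - mu) / sdv
    z[sdv == 0] <- 0
    df <- data.frame(subject = subject, cluster = cl,
                     freq = mean(sel), stringsAsFactors = FALSE)
    df[paste0("z_", colnames(x))] <- as.list(z)
    df
  }))
  out$kept <- out$freq > min_frac
  rownames(out) <- NULL
  out
}

#' Metacluster individual-cluster profiles into aligned clusters
#'
#' Hierarchical metaclustering of the retained per-subject z-score
#' profiles with Euclidean distance and Ward's method, cut into exactly
#' `cut` aligned clusters (ACs). The mapping (subject, individual
#' cluster) -> AC is applied back to events by [ac_frequencies()].
#'
#' @param profiles row-bound output of [profile_and_filter()] across
#'   subjects; only rows with `kept = TRUE` are aligned.
#' @param cut number of aligned clusters (default 10).
#' @return list of class `aligned_cluster_model`: `assignments` (data
#'   frame `subject`, `cluster`, `ac`), `hclust`, `cut`.
#' @export
metacluster <- function(profiles, cut = 10) {
  prof <- profiles[profiles$kept, , drop = FALSE]
  if (nrow(prof) < cut)
    stop("cut (", cut, ") exceeds number of retained profiles (",
         nrow(prof), ")")
  zcols <- grep("^z_", names(prof), value = TRUE)
  zmat <- as.matrix(prof[, zcols])
  rownames(zmat) <- paste(prof$subject, prof$cluster, sep = ":")
  hc <- hclust(dist(zmat), method = "ward.D2")
  ac <- cutree(hc, k = cut)
  structure(list(assignments = data.frame(subject = prof$subject,
                                          cluster = prof$cluster,
                                          ac = unname(ac),
                                          stringsAsFactors = FALSE),
                 hclust = hc, cut = cut),
            class = "aligned_cluster_model")
}

#' Per-subject aligned-cluster frequencies for total CD4 and tetramer classes
#'
#' Counts each subject's events per aligned cluster, separately for the
#' total-CD4 class (non-tetramer events) and for each tetramer antigen,
#' and converts to fractions of that class's event total. Events whose
#' individual cluster fell below the abundance floor stay unassigned, so
#' assigned fractions sum to at most 1. Subjects with fewer than
#' `min_tmr_events` total events for an antigen are excluded from that
#' antigen's statistics.
#'
#' @param model an `aligned_cluster_model` from [metacluster()].
#' @param events list of per-subject event data frames carrying `tmr`,
#'   `antigen` and an appended `cluster` column of individual-cluster
#'   labels.
#' @param min_tmr_events minimum antigen-specific events per subject for
#'   inclusion in antigen-specific statistics (default 8).
#' @return data frame: `subject`, `group`, `class` (`"total"` or antigen
#'   name), `ac`, `n_class`, `frac`.
#' @export
ac_frequencies <- function(model, events, min_tmr_events = 8) {
  acs <- sort(unique(model$assignments$ac))
  out <- list()
  for (subj in names(events)) {
    ev <- events[[subj]]
    map <- model$assignments[model$assignments$subject == subj, ]
    ev$ac <- map$ac[match(ev$cluster, map$cluster)]
    classes <- c("total",
                 unique(ev$antigen[ev$tmr & !is.na(ev$antigen)]))
    for (cls in classes) {
      sel <- if (cls == "total") !ev$tmr else ev$tmr & ev$antigen == cls
      n_cls <- sum(sel)
      if (cls != "total" && n_cls < min_tmr_events) next
      if (n_cls == 0) next
      cnt <- table(factor(ev$ac[sel], levels = acs))
      out[[length(out) + 1]] <- data.frame(
        subject = subj, group = ev$group[1], class = cls, ac = acs,
        n_class = n_cls, frac = as.numeric(cnt) / n_cls,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Wilcoxon comparison of aligned-cluster proportions between groups
#'
#' Two-sided rank-sum test per aligned cluster per group pair on the
#' per-subject AC fractions of one event class. Pairs with an empty group
#' are skipped with a message.
#'
#' @param ac_freq output of [ac_frequencies()].
#' @param class event class to compare (`"total"` or an antigen name).
#' @param pairs list of group pairs.
#' @return data frame `class`, `ac`, `comparison`, `estimate`, `p`,
#'   `n_a`, `n_b`.
#' @export
compare_ac <- function(ac_freq, class = "total",
                       pairs = list(c("ctrl", "at_risk"),
                                    c("at_risk", "early_ra"))) {
  dat <- ac_freq[ac_freq$class == class, , drop = FALSE]
  out <- list()
  for (a in sort(unique(dat$ac))) {
    sub <- dat[dat$ac == a, ]
    for (pr in pairs) {
      va <- sub$frac[sub$group == pr[1]]
      vb <- sub$frac[sub$group == pr[2]]
      if (length(va) < 2 || length(vb) < 2) {
        message("skipping AC", a, " ", paste(pr, collapse = " vs "),
                ": fewer than 2 subjects in a group")
        next
      }
      p <- if (length(unique(c(va, vb))) == 1) 1 else
        suppressWarnings(wilcox.test(va, vb)$p.value)
      out[[length(out) + 1]] <- data.frame(
        class = class, ac = a, comparison = paste(pr, collapse = "_vs_"),
        estimate = stats::median(vb) - stats::median(va), p = p,
        n_a = length(va), n_b = length(vb), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

#' Run the full CD4 landscape pipeline on event tables
#'
#' Transform -> per-subject clustering -> z-score profiling with the
#' abundance floor -> cross-subject metaclustering into aligned clusters
#' -> per-subject AC frequencies. Tetramer-positive events participate in
#' clustering (they are part of the concatenated table) and, by default,
#' in the subject mean/SD reference used for z-scores.
#'
#' @param tables list with `events` (per-subject data frames carrying the
#'   six markers, `tmr`, `antigen`), e.g. from [make_event_tables()] or
#'   [read_event_tables()].
#' @param markers marker columns to use (default the six phenotyping
#'   markers).
#' @param a,b arcsinh parameters (defaults 0, 1/150).
#' @param k_neighbors,cluster_method,kmeans_centers,resolution passed to
#'   [cluster_sample()].
#' @param min_cluster_frac abundance floor for profile retention.
#' @param cut number of aligned clusters.
#' @param min_tmr_events antigen-specific inclusion threshold.
#' @param exclude_tmr_from_reference if `TRUE`, the subject mean/SD used
#'   for z-scores is computed on non-tetramer events only.
#' @param seed integer seed (per-subject child seeds are derived from it).
#' @return list of class `landscape_result`: `profiles`, `model`,
#'   `ac_freq`, `events` (with appended `cluster` labels), `params`.
#' @export
run_landscape <- function(tables, markers = landscape_markers(),
                          a = 0, b = 1 / 150, k_neighbors = 30,
                          cluster_method = "knn_louvain",
                          kmeans_centers = 8, resolution = 1,
                          min_cluster_frac = 0.01, cut = 10,
                          min_tmr_events = 8,
                          exclude_tmr_from_reference = FALSE,
                          seed = 1L) {
  events <- tables$events
  profiles <- list()
  for (i in seq_along(events)) {
    subj <- names(events)[i]
    ev <- events[[subj]]
    y <- arcsinh_transform(as.matrix(ev[, markers]), a = a, b = b)
    labels <- cluster_sample(y, k_neighbors = k_neighbors,
                             seed = stage_seed(seed, subj),
                             method = cluster_method,
                             kmeans_centers = kmeans_centers,
                             resolution = resolution)
    ev$cluster <- labels
    events[[subj]] <- ev
    ref <- if (exclude_tmr_from_reference) y[!ev$tmr, , drop = FALSE]
           else y
    mu <- colMeans(ref); sdv <- apply(ref, 2, sd)
    prof <- profile_and_filter(y, labels, subject = subj,
                               min_frac = min_cluster_frac)
    if (exclude_tmr_from_reference) {
      # recompute z against the tmr-free reference
      zc <- paste0("z_", markers)
      for (r in seq_len(nrow(prof))) {
        sel <- labels == prof$cluster[r]
        z <- (colMeans(y[sel, , drop = FALSE]) - mu) / sdv
        z[sdv == 0] <- 0
        prof[r, zc] <- as.list(z)
      }
    }
    profiles[[subj]] <- prof
  }
  profiles <- do.call(rbind, profiles)
  rownames(profiles) <- NULL
  model <- metacluster(profiles, cut = cut)
  freq <- ac_frequencies(model, events, min_tmr_events = min_tmr_events)
  structure(list(profiles = profiles, model = model, ac_freq = freq,
                 events = events,
                 params = list(markers = markers, a = a, b = b,
                               k_neighbors = k_neighbors,
                               min_cluster_frac = min_cluster_frac,
                               cut = cut, min_tmr_events = min_tmr_events,
                               seed = seed)),
            class = "landscape_result")
}
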