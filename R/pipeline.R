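#' Build a validated pipeline run configuration
#'
#' Collects every per-arm parameter (all defaulting to the standard values
#' of the analysis: alpha 0.05, delta-beta 0.1, promoter window -2500/+500,
#' arcsinh cofactor 150, 1% cluster floor, 10 aligned clusters, 8-event
#' tetramer threshold, 3-SD positivity rule, age/sex/smoking adjustment)
#' together with the synthetic-study settings and a single global seed
#' from which each stage derives its own child seed.
#'
#' @param synth a [synth_config()]; its seed is overridden by `seed`.
#' @param alpha,delta_beta DML gates.
#' @param dml_mode `"any_pair"` (three-group rule, default) or
#'   `"pairwise"`.
#' @param promoter_upstream,promoter_downstream promoter window (bp).
#' @param arcsinh_b,k_neighbors,min_cluster_frac,cut,min_tmr_events
#'   landscape parameters.
#' @param cluster_method `"knn_louvain"` or `"kmeans"`.
#' @param sd_mult serology positivity SD multiplier.
#' @param adjust serology adjustment covariates.
#' @param seed global integer seed.
#' @param out_dir output directory, or `NULL` for no file output.
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = synth_config(),
                       alpha = 0.05, delta_beta = 0.1,
                       dml_mode = "any_pair",
                       promoter_upstream = 2500, promoter_downstream = 500,
                       arcsinh_b = 1 / 150, k_neighbors = 30,
                       cluster_method = "knn_louvain",
                       min_cluster_frac = 0.01, cut = 10,
                       min_tmr_events = 8, sd_mult = 3,
                       adjust = c("age", "sex", "smoking_ever"),
                       seed = 1L, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, delta_beta >= 0,
            dml_mode %in% c("any_pair", "pairwise"),
            promoter_upstream >= 0, promoter_downstream >= 0,
            arcsinh_b > 0, min_cluster_frac >= 0, cut >= 1,
            min_tmr_events >= 0, sd_mult > 0)
  synth$seed <- as.integer(seed)
  structure(list(synth = synth, alpha = alpha, delta_beta = delta_beta,
                 dml_mode = dml_mode,
                 promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 arcsinh_b = arcsinh_b, k_neighbors = k_neighbors,
                 cluster_method = cluster_method,
                 min_cluster_frac = min_cluster_frac, cut = cut,
                 min_tmr_events = min_tmr_events, sd_mult = sd_mult,
                 adjust = adjust, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] may be set in a YAML file; unknown
#' fields raise an error naming them. Nested synthetic-generator scalars
#' go under a `synth:` block.
#'
#' @param file path to a YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  synth_args <- y$synth %||% list()
  known_synth <- names(formals(synth_config))
  bad <- setdiff(names(synth_args), known_synth)
  if (length(bad)) stop("unknown synth config field(s): ",
                        paste(bad, collapse = ", "))
  y$synth <- NULL
  known <- setdiff(names(formals(run_config)), "synth")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  do.call(run_config, c(list(synth = do.call(synth_config, synth_args)), y))
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes every analysis arm on freshly generated synthetic data:
#' methylome (per-cohort DML calling, cross-cohort replication, gene
#' mapping, pathway enrichment, one-vs-one classification), tetramer
#' frequencies with group comparisons, the aligned-cluster landscape,
#' serology (positivity, level/positivity/count models for both group
#' pairs) and baseline cohort statistics on the synthetic covariates.
#' When `cfg$out_dir` is set, each stage writes TSV/JSON outputs under
#' `out_dir/<stage>/` and a run manifest (seed, parameter hash, stage
#' summary) is written to `out_dir/manifest.json`.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress (default TRUE).
#' @return list of class `run_result` with elements `methylome`, `tmr`,
#'   `landscape`, `serology`, `cohortstats`, `manifest`.
#' @export
run_all <- function(cfg = run_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message("[", format(Sys.time(),
                                                        "%H:%M:%S"),
                                            "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  groups <- colnames(cfg$synth$n_per_group_per_cohort)

  say("synth: generating inputs")
  synth_out <- stage("synth", {
    list(beta = make_beta_matrix(cfg$synth),
         flow = make_event_tables(cfg$synth),
         serum = make_serum_array(cfg$synth))
  })

  say("methylome: DML calling and classification")
  methylome <- stage("methylome", {
    beta <- synth_out$beta$beta
    dml <- call_dml(beta, groups, alpha = cfg$alpha,
                    delta_beta = cfg$delta_beta, mode = cfg$dml_mode)
    cohorts <- unique(beta$sample_meta$cohort)
    reps <- lapply(setNames(nm = unique(beta$sample_meta$cell_type)),
                   function(ct)
      cross_cohort(dml_set(dml, cohorts[1], ct),
                   dml_set(dml, cohorts[2], ct),
                   universe = nrow(beta$values)))
    ann <- make_probe_annotation(rownames(beta$values), seed = cfg$seed)
    union_all <- unique(unlist(lapply(reps, function(r) r$union)))
    dmg <- map_dmg(union_all, ann, upstream = cfg$promoter_upstream,
                   downstream = cfg$promoter_downstream)
    sets <- make_gene_sets(unique(ann$gene), planted = NULL,
                           seed = cfg$seed)
    enr <- if (length(unique(dmg$gene)))
      pathway_enrichment(unique(dmg$gene), sets, unique(ann$gene))
    else NULL
    m <- beta_to_m(beta)
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    classifiers <- lapply(pairs, function(pr) {
      lab <- paste(pr, collapse = "_vs_")
      feats <- unique(dml$probe_id[dml$called & dml$comparison == lab])
      if (length(feats) < 2) return(NULL)
      classify_one_vs_one(m, beta$sample_meta, feats, pr,
                          seed = stage_seed(cfg$seed, "classify"))
    })
    names(classifiers) <- vapply(pairs, paste, "", collapse = "_vs_")
    list(dml = dml, replication = reps, dmg = dmg, enrichment = enr,
         classifiers = classifiers)
  })

  say("tmr: tetramer frequencies")
  tmr <- stage("tmr", {
    ev <- synth_out$flow
    counts <- do.call(rbind, lapply(names(ev$events), function(s) {
      e <- ev$events[[s]]
      ags <- rownames(cfg$synth$tmr_enrichment)
      data.frame(subject = s, group = e$group[1], antigen = ags,
                 tmr_events = vapply(ags, function(a)
                   sum(e$tmr & e$antigen == a), numeric(1)),
                 cd4_pre = ev$cd4_pre[[s]], stringsAsFactors = FALSE)
    }))
    freq <- tmr_frequency_table(counts)
    list(counts = counts, freq = freq,
         combined = compare_tmr_groups(freq$combined_cit, freq$group),
         cilp = compare_tmr_groups(freq[["cit-CILP"]], freq$group))
  })

  say("landscape: clustering and aligned clusters")
  landscape <- stage("landscape", {
    ls <- run_landscape(synth_out$flow, b = cfg$arcsinh_b,
                        k_neighbors = cfg$k_neighbors,
                        cluster_method = cfg$cluster_method,
                        min_cluster_frac = cfg$min_cluster_frac,
                        cut = cfg$cut,
                        min_tmr_events = cfg$min_tmr_events,
                        seed = stage_seed(cfg$seed, "landscape"))
    list(result = ls,
         total_comparisons = compare_ac(ls$ac_freq, "total"),
         cilp_comparisons = compare_ac(ls$ac_freq, "cit-CILP"))
  })

  say("serology: positivity and group models")
  serology <- stage("serology", {
    arr <- synth_out$serum
    calls <- call_positivity(arr, sd_mult = cfg$sd_mult)
    pairs <- list(c("ctrl", "at_risk"), c("at_risk", "early_ra"))
    models <- do.call(rbind, lapply(pairs, function(pr)
      do.call(rbind, lapply(c("level", "positivity", "count"),
                            function(oc)
        fit_group_models(arr, oc, pr, calls = calls,
                         adjust = cfg$adjust)))))
    list(calls = calls, models = models,
         summary = summarize_antigen_groups(arr, calls))
  })

  say("cohortstats: baseline comparisons")
  cohortstats <- stage("cohortstats", {
    cov <- synth_out$serum$covariates
    rows <- list()
    for (pr in list(c("ctrl", "at_risk"), c("at_risk", "early_ra"))) {
      a <- cov[cov$group == pr[1], ]; b <- cov[cov$group == pr[2], ]
      lab <- paste(pr, collapse = "_vs_")
      rows[[paste0(lab, ":age")]] <- data.frame(
        label = paste0(lab, ":age"), type = "continuous",
        p = t_from_summaries(mean(a$age), sd(a$age), nrow(a),
                             mean(b$age), sd(b$age), nrow(b))$p)
      for (v in c("sex", "smoking_ever", "hla0401")) {
        ya <- if (v == "sex") a[[v]] == "F" else a[[v]]
        yb <- if (v == "sex") b[[v]] == "F" else b[[v]]
        rows[[paste0(lab, ":", v)]] <- data.frame(
          label = paste0(lab, ":", v), type = "dichotomous",
          p = chisq_2x2(sum(ya), sum(!ya), sum(yb), sum(!yb))$p)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  manifest <- list(
    seed = cfg$seed,
    param_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(
      methylome = list(n_dml_union = length(dml_set(methylome$dml)),
                       replication_p = vapply(methylome$replication,
                                              function(r) r$p, numeric(1)),
                       n_dmg = length(unique(methylome$dmg$gene))),
      tmr = list(combined_p = methylome_safe(tmr$combined$p)),
      landscape = list(n_ac = cfg$cut),
      serology = list(n_models = nrow(serology$models))))

  if (!is.null(cfg$out_dir)) {
    say("writing outputs to ", cfg$out_dir)
    write_run_outputs(cfg$out_dir, synth_out, methylome, tmr, landscape,
                      serology, cohortstats, manifest)
  }
  structure(list(synth = synth_out, methylome = methylome, tmr = tmr,
                 landscape = landscape, serology = serology,
                 cohortstats = cohortstats, manifest = manifest),
            class = "run_result")
}

methylome_safe <- function(x) if (is.null(x)) NA_real_ else x

write_run_outputs <- function(dir, synth_out, methylome, tmr, landscape,
                              serology, cohortstats, manifest) {
  sub <- function(s) {
    d <- file.path(dir, s)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    d
  }
  wt <- function(x, f) write.table(x, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  write_beta_matrix(synth_out$beta$beta, sub("synth"))
  jsonlite::write_json(synth_out$beta$truth,
                       file.path(sub("synth"), "beta_truth.json"))
  wt(methylome$dml[methylome$dml$called, ],
     file.path(sub("methylome"), "dml.tsv"))
  wt(methylome$dmg, file.path(sub("methylome"), "dmg.tsv"))
  if (!is.null(methylome$enrichment))
    wt(methylome$enrichment, file.path(sub("methylome"), "pathways.tsv"))
  wt(tmr$freq, file.path(sub("tmr"), "frequencies.tsv"))
  wt(rbind(tmr$combined, tmr$cilp),
     file.path(sub("tmr"), "comparisons.tsv"))
  wt(landscape$result$ac_freq,
     file.path(sub("landscape"), "ac_frequencies.tsv"))
  wt(landscape$result$profiles,
     file.path(sub("landscape"), "profiles.tsv"))
  wt(serology$models, file.path(sub("serology"), "models.tsv"))
  wt(cohortstats, file.path(sub("cohortstats"), "table1.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_result <- function(x, ...) {
  cat("pipeline run (seed", x$manifest$seed, ")\n")
  cat("  DML union:", x$manifest$stages$methylome$n_dml_union,
      "| DMG:", x$manifest$stages$methylome$n_dmg, "\n")
  cat("  tmr combined-cit comparisons:\n")
  print(x$tmr$combined)
  cat("  serology models fit:", nrow(x$serology$models), "\n")
  invisible(x)
}
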