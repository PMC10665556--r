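#' Configuration for the synthetic study generator
#'
#' Builds a validated configuration describing a synthetic cross-sectional
#' study with the structure of a three-group (ACPA-negative control,
#' ACPA-positive at-risk, early RA) immune-profiling design: a two-cohort
#' sorted-cell methylation arm, a tetramer/flow-cytometry arm restricted to
#' DRB1*04:01-positive subjects, and a serum antibody-array arm on the full
#' cohort. Defaults mirror the published study sizes (cohort 1: 21/20/5
#' female subjects per group; cohort 2: 31/36/17; tetramer arm 30/24/17;
#' serology arm 172/97/62) with the probe count and per-subject event count
#' scaled down so the full pipeline runs in seconds.
#'
#' @param n_per_group_per_cohort integer matrix, 2 cohorts x 3 groups
#'   (columns `ctrl`, `at_risk`, `early_ra`): methylation subjects.
#' @param n_probes number of methylation probes to simulate.
#' @param n_planted_dml number of probes per cohort given a planted group
#'   effect.
#' @param delta_beta_effect planted methylation difference, in beta units.
#' @param beta_noise_sd per-probe within-group biological noise on the beta
#'   scale; applied as logit-normal noise so values stay in (0, 1).
#' @param replication_rate fraction of planted loci shared between the two
#'   cohorts, in \[0, 1\].
#' @param planted_group participant group receiving the planted beta shift.
#' @param cell_types sorted cell populations to simulate per subject.
#' @param n_subjects_flow named integer vector, tetramer-arm subjects per
#'   group.
#' @param n_events_flow total CD4+ events per subject in the cytometry arm.
#' @param cluster_spec list with `means` (components x 6 markers, arcsinh
#'   space), `props` (mixing proportions summing to 1) and `sd` (per-marker
#'   noise in arcsinh space). The default has five phenotype archetypes
#'   (naive-like, Th1-like, Th2-like, Th17-like, Th17.1-like).
#' @param arcsinh_b cofactor of the arcsinh transform used to map the
#'   mixture back to raw intensities; default 1/150.
#' @param prop_concentration Dirichlet concentration controlling
#'   subject-to-subject variation of component proportions.
#' @param tmr_enrichment matrix antigens x groups of expected
#'   tetramer-positive frequencies per million CD4+ cells.
#' @param tmr_skew optional list of records `list(antigen=, group=,
#'   weights=)` overriding the phenotype mixture for tetramer-positive
#'   events of one antigen in one group (the planted phenotype effect).
#' @param cd4_pre_mean expected CD4+ count in the reserved 1%
#'   pre-enrichment fraction.
#' @param n_serum named integer vector, serology subjects per group.
#' @param antigen_effects named list: participant group -> named numeric
#'   vector of multiplicative MFI shifts keyed by antigen summing group.
#' @param mfi_log_sd log-scale SD of the log-normal MFI noise.
#' @param seed integer seed; all generators derive stage seeds from it.
#' @return an object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_probes = 200, seed = 7)
#' cfg$n_planted_dml
synth_config <- function(n_per_group_per_cohort = rbind(
                           cohort1 = c(ctrl = 21, at_risk = 20, early_ra = 5),
                           cohort2 = c(ctrl = 31, at_risk = 36, early_ra = 17)),
                         n_probes = 5000,
                         n_planted_dml = 100,
                         delta_beta_effect = 0.2,
                         beta_noise_sd = 0.03,
                         replication_rate = 0.5,
                         planted_group = "at_risk",
                         cell_types = c("B", "Tmem", "Tnaive"),
                         n_subjects_flow = c(ctrl = 30, at_risk = 24,
                                             early_ra = 17),
                         n_events_flow = 2000,
                         cluster_spec = default_cluster_spec(),
                         arcsinh_b = 1 / 150,
                         prop_concentration = 200,
                         tmr_enrichment = default_tmr_enrichment(),
                         tmr_skew = default_tmr_skew(),
                         cd4_pre_mean = 1.5e5,
                         n_serum = c(ctrl = 172, at_risk = 97, early_ra = 62),
                         antigen_effects = default_antigen_effects(),
                         mfi_log_sd = 0.5,
                         seed = 1L) {
  cfg <- list(
    n_per_group_per_cohort = n_per_group_per_cohort,
    n_probes = n_probes, n_planted_dml = n_planted_dml,
    delta_beta_effect = delta_beta_effect, beta_noise_sd = beta_noise_sd,
    replication_rate = replication_rate, planted_group = planted_group,
    cell_types = cell_types, n_subjects_flow = n_subjects_flow,
    n_events_flow = n_events_flow, cluster_spec = cluster_spec,
    arcsinh_b = arcsinh_b, prop_concentration = prop_concentration,
    tmr_enrichment = tmr_enrichment, tmr_skew = tmr_skew,
    cd4_pre_mean = cd4_pre_mean, n_serum = n_serum,
    antigen_effects = antigen_effects, mfi_log_sd = mfi_log_sd,
    seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(
    is.matrix(cfg$n_per_group_per_cohort),
    ncol(cfg$n_per_group_per_cohort) == 3,
    all(cfg$n_per_group_per_cohort > 0),
    cfg$n_probes >= 1, cfg$n_planted_dml >= 0,
    cfg$replication_rate >= 0, cfg$replication_rate <= 1,
    cfg$beta_noise_sd > 0, cfg$delta_beta_effect >= 0,
    cfg$planted_group %in% colnames(cfg$n_per_group_per_cohort),
    all(cfg$n_subjects_flow > 0), cfg$n_events_flow > 0,
    cfg$arcsinh_b > 0, cfg$cd4_pre_mean > 0,
    all(cfg$n_serum > 0), cfg$mfi_log_sd > 0,
    all(cfg$tmr_enrichment >= 0),
    all(names(cfg$n_subjects_flow) %in% colnames(cfg$tmr_enrichment)))
  if (cfg$n_planted_dml > cfg$n_probes)
    stop("n_planted_dml (", cfg$n_planted_dml,
         ") exceeds n_probes (", cfg$n_probes, ")")
  sp <- cfg$cluster_spec
  if (!length(sp$props) || nrow(sp$means) != length(sp$props))
    stop("cluster_spec means/props mismatch")
  if (abs(sum(sp$props) - 1) > 1e-8)
    stop("cluster_spec proportions must sum to 1")
  invisible(cfg)
}

#' Default cytometry mixture: five CD4+ phenotype archetypes
#'
#' Component means are in arcsinh-transformed space over the six markers
#' CD45RA, CD38, CCR4, CCR6, CXCR3, CCR7, sketching naive-like, Th1-like,
#' Th2-like, Th17-like and Th17.1-like surface phenotypes.
#'
#' @return list with `means`, `props`, `sd`.
#' @export
default_cluster_spec <- function() {
  markers <- c("CD45RA", "CD38", "CCR4", "CCR6", "CXCR3", "CCR7")
  means <- rbind(
    naive  = c(5.0, 1.0, 1.0, 1.0, 1.0, 5.0),
    th1    = c(1.0, 2.0, 1.0, 1.0, 5.0, 3.0),
    th2    = c(1.0, 2.0, 5.0, 1.0, 1.0, 3.0),
    th17   = c(1.0, 2.0, 4.0, 5.0, 1.0, 3.0),
    th17_1 = c(1.0, 2.0, 1.0, 5.0, 5.0, 2.0))
  colnames(means) <- markers
  list(means = means,
       props = c(0.40, 0.20, 0.15, 0.15, 0.10),
       sd = 0.35)
}

#' Default expected tetramer-positive frequencies (per million CD4)
#'
#' Rows are the five tetramer antigens (four citrullinated specificities
#' plus an influenza control), columns the three participant groups. The
#' citrullinated CILP specificity carries the dominant at-risk expansion;
#' influenza is flat across groups.
#'
#' @return numeric matrix antigens x groups.
#' @export
default_tmr_enrichment <- function() {
  m <- rbind(
    "cit-aggrecan"            = c(1.0, 1.5, 1.5),
    "cit-CILP"                = c(1.0, 5.0, 3.0),
    "cit-vimentin/fibrinogen" = c(1.0, 1.5, 2.0),
    "cit-alpha-enolase"       = c(1.0, 1.5, 1.5),
    "influenza"               = c(20, 20, 20))
  colnames(m) <- c("ctrl", "at_risk", "early_ra")
  m
}

#' Default planted tetramer phenotype skew
#'
#' Citrullinated-CILP-specific events in the at-risk group are drawn
#' preferentially from the Th17.1-like component, emulating an
#' antigen-specific phenotype shift recoverable by the aligned-cluster
#' comparison.
#'
#' @return list of skew records.
#' @export
default_tmr_skew <- function() {
  list(list(antigen = "cit-CILP", group = "at_risk",
            weights = c(0.05, 0.05, 0.05, 0.05, 0.80)))
}

#' Default antibody-array group effects
#'
#' Multiplicative MFI shifts per antigen summing group, per participant
#' group: modest cit-clusterin / cit-fibrinogen / cit-histone-H4 elevation
#' in the at-risk group and larger, broader elevations (including
#' citrullinated CILP) in early RA.
#'
#' @return named list of named numeric vectors.
#' @export
default_antigen_effects <- function() {
  list(
    at_risk = c("cit-clusterin" = 1.5, "cit-fibrinogen" = 1.3,
                "cit-histone-H4" = 1.4),
    early_ra = c("cit-clusterin" = 2.0, "cit-fibrinogen" = 2.0,
                 "cit-histone-H4" = 2.0, "cit-CILP" = 2.0,
                 "cit-fillagrin" = 1.5))
}

group_levels <- function() c("ctrl", "at_risk", "early_ra")

#' Generate a synthetic methylation beta matrix with planted DML
#'
#' Per-probe baseline methylation fractions are drawn from a U-shaped beta
#' distribution (mimicking the bimodal methylated/unmethylated landscape of
#' array data); within-group noise is logit-normal with a beta-scale SD of
#' `cfg$beta_noise_sd`, which keeps every value strictly inside (0, 1).
#' `cfg$n_planted_dml` probes per cohort receive a `cfg$delta_beta_effect`
#' shift (towards 0.5, so the shift never leaves the unit interval) in the
#' `cfg$planted_group` samples of that cohort; a fraction
#' `cfg$replication_rate` of planted probes is shared between cohorts. The
#' same planted loci are applied to every simulated cell type.
#'
#' @param cfg a [synth_config()].
#' @return list with `beta` (a [beta_matrix()]) and `truth`, a data frame
#'   of planted loci (`probe_id`, `cohort`, `group`, `delta`) where `delta`
#'   is the signed planted beta shift.
#' @export
#' @examples
#' out <- make_beta_matrix(synth_config(n_probes = 100, n_planted_dml = 5,
#'                                      cell_types = "Tmem", seed = 1))
#' dim(out$beta$values)
#' head(out$truth)
make_beta_matrix <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(stage_seed(cfg$seed, "beta"))
  probes <- sprintf("cg%07d", seq_len(cfg$n_probes))
  groups <- colnames(cfg$n_per_group_per_cohort)
  cohorts <- rownames(cfg$n_per_group_per_cohort) %||% c("cohort1", "cohort2")

  # shared + cohort-specific planted loci
  n_shared <- round(cfg$replication_rate * cfg$n_planted_dml)
  n_extra <- cfg$n_planted_dml - n_shared
  if (n_shared + 2 * n_extra > cfg$n_probes)
    stop("not enough probes for ", cfg$n_planted_dml, " planted DML at ",
         "replication rate ", cfg$replication_rate,
         " (needs ", n_shared + 2 * n_extra, ", have ", cfg$n_probes, ")")
  pool <- sample(probes, n_shared + 2 * n_extra)
  shared <- pool[seq_len(n_shared)]
  extra1 <- pool[n_shared + seq_len(n_extra)]
  extra2 <- pool[n_shared + n_extra + seq_len(n_extra)]
  planted <- list(c(shared, extra1), c(shared, extra2))
  names(planted) <- cohorts

  mu <- 0.05 + 0.90 * rbeta(cfg$n_probes, 0.4, 0.4)
  names(mu) <- probes
  # planted shift moves the mean towards 0.5 so it stays in range
  shift_dir <- ifelse(mu <= 0.5, 1, -1)

  meta <- do.call(rbind, lapply(cohorts, function(co) {
    do.call(rbind, lapply(groups, function(g) {
      n <- cfg$n_per_group_per_cohort[co, g]
      subj <- sprintf("%s_%s_%02d", co, g, seq_len(n))
      expand_meta <- expand.grid(subject = subj, cell_type = cfg$cell_types,
                                 stringsAsFactors = FALSE)
      data.frame(sample_id = paste(expand_meta$subject,
                                   expand_meta$cell_type, sep = "."),
                 subject = expand_meta$subject, group = g, cohort = co,
                 cell_type = expand_meta$cell_type,
                 stringsAsFactors = FALSE)
    }))
  }))

  vals <- matrix(NA_real_, cfg$n_probes, nrow(meta),
                 dimnames = list(probes, meta$sample_id))
  for (i in seq_len(nrow(meta))) {
    m_i <- mu
    if (meta$group[i] == cfg$planted_group) {
      pl <- planted[[meta$cohort[i]]]
      m_i[pl] <- pmin(pmax(mu[pl] + shift_dir[pl] * cfg$delta_beta_effect,
                           0.02), 0.98)
    }
    sd_logit <- cfg$beta_noise_sd / (m_i * (1 - m_i))
    vals[, i] <- plogis(rnorm(cfg$n_probes, qlogis(m_i), sd_logit))
  }

  truth <- do.call(rbind, lapply(cohorts, function(co) {
    pl <- planted[[co]]
    if (!length(pl) || cfg$delta_beta_effect == 0) return(NULL)
    data.frame(probe_id = pl, cohort = co, group = cfg$planted_group,
               delta = shift_dir[pl] * cfg$delta_beta_effect,
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(probe_id = character(), cohort = character(),
                        group = character(), delta = numeric())
  list(beta = beta_matrix(vals, meta), truth = truth)
}

#' Generate synthetic per-subject cytometry event tables
#'
#' Total CD4+ events are drawn from the Gaussian mixture in
#' `cfg$cluster_spec` in arcsinh space, mapped back to raw intensities with
#' `sinh(y)/b`, and tetramer-positive events for each antigen are appended
#' to the subject's table (mirroring the concatenated-FCS layout used in
#' tetramer landscape analyses). Tetramer counts are Poisson with mean
#' implied by the configured per-million enrichment frequency and the
#' subject's pre-enrichment CD4 count; `cfg$tmr_skew` redirects the
#' phenotype mixture of selected antigen/group combinations. Per-subject
#' component proportions get Dirichlet jitter around the configured
#' mixture proportions.
#'
#' @param cfg a [synth_config()].
#' @return list with `events` (list of per-subject data frames carrying the
#'   six marker intensities, `tmr`, `antigen` and the ground-truth
#'   `component` column), `cd4_pre` (named pre-enrichment CD4 counts) and
#'   `truth_props` (subjects x components matrix of true proportions).
#' @export
make_event_tables <- function(cfg) {
  validate_synth_config(cfg)
  if (cfg$n_events_flow <= 0) stop("zero events requested")
  set.seed(stage_seed(cfg$seed, "flow"))
  sp <- cfg$cluster_spec
  k <- length(sp$props)
  markers <- colnames(sp$means)
  groups <- names(cfg$n_subjects_flow)

  draw_events <- function(n, weights) {
    comp <- sample.int(k, n, replace = TRUE, prob = weights)
    y <- sp$means[comp, , drop = FALSE] +
      matrix(rnorm(n * length(markers), 0, sp$sd), n)
    raw <- sinh(y) / cfg$arcsinh_b
    colnames(raw) <- markers
    list(raw = raw, comp = comp)
  }

  events <- list(); cd4_pre <- numeric(); props_true <- list()
  for (g in groups) {
    for (s in seq_len(cfg$n_subjects_flow[[g]])) {
      subj <- sprintf("flow_%s_%02d", g, s)
      w <- rgamma(k, shape = sp$props * cfg$prop_concentration)
      w <- w / sum(w)
      props_true[[subj]] <- w
      tot <- draw_events(cfg$n_events_flow, w)
      df <- data.frame(subject = subj, group = g, tot$raw,
                       tmr = FALSE, antigen = NA_character_,
                       component = tot$comp, stringsAsFactors = FALSE,
                       check.names = FALSE)
      pre <- rpois(1, cfg$cd4_pre_mean)
      cd4_pre[subj] <- pre
      for (ag in rownames(cfg$tmr_enrichment)) {
        lam <- cfg$tmr_enrichment[ag, g] * 100 * pre / 1e6
        n_tmr <- rpois(1, lam)
        if (n_tmr == 0) next
        w_ag <- w
        for (sk in cfg$tmr_skew)
          if (sk$antigen == ag && sk$group == g) w_ag <- sk$weights
        tm <- draw_events(n_tmr, w_ag)
        df <- rbind(df, data.frame(subject = subj, group = g, tm$raw,
                                   tmr = TRUE, antigen = ag,
                                   component = tm$comp,
                                   stringsAsFactors = FALSE,
                                   check.names = FALSE))
      }
      events[[subj]] <- df
    }
  }
  list(events = events, cd4_pre = cd4_pre,
       truth_props = do.call(rbind, props_true))
}

#' Build the default synthetic antibody-array antigen panel
#'
#' 41 antigens (27 citrullinated, 14 native) organised into the summing
#' groups reported for this assay family: cit-clusterin, cit-fibrinogen,
#' cit-fillagrin, cit-histone-H4, and ten CILP peptides (five citrullinated,
#' five native). The peptide identities are synthetic placeholders; the
#' group structure is what the serology arm consumes.
#'
#' @return data frame with `antigen`, `citrullinated`, `antigen_group`.
#' @export
default_antigen_panel <- function() {
  mk <- function(stem, n, cit, grp)
    data.frame(antigen = sprintf("%s_%d", stem, seq_len(n)),
               citrullinated = cit,
               antigen_group = grp, stringsAsFactors = FALSE)
  panel <- rbind(
    mk("cit-clusterin", 3, TRUE, "cit-clusterin"),
    mk("cit-fibrinogen", 4, TRUE, "cit-fibrinogen"),
    mk("cit-fillagrin", 2, TRUE, "cit-fillagrin"),
    mk("cit-histoneH4", 3, TRUE, "cit-histone-H4"),
    mk("cit-CILP", 5, TRUE, "cit-CILP"),
    mk("CILP", 5, FALSE, "CILP-native"),
    mk("cit-vimentin", 4, TRUE, NA_character_),
    mk("cit-enolase", 3, TRUE, NA_character_),
    mk("cit-apolipoprotein", 3, TRUE, NA_character_),
    mk("fibrinogen", 3, FALSE, NA_character_),
    mk("vimentin", 3, FALSE, NA_character_),
    mk("histoneH4", 3, FALSE, NA_character_))
  stopifnot(nrow(panel) == 41, sum(panel$citrullinated) == 27)
  panel
}

#' Generate a synthetic serum antibody-array dataset
#'
#' Control-group MFI values are log-normal per antigen; subjects in
#' affected groups have their MFI multiplied by the configured
#' antigen-group effect. Covariates (age, sex, smoking ever/never,
#' DRB1*04:01 carriage) are drawn with the group imbalances observed in
#' the study's baseline table, which makes covariate adjustment in the
#' serology models meaningful.
#'
#' @param cfg a [synth_config()].
#' @param panel antigen panel data frame; defaults to
#'   [default_antigen_panel()].
#' @return a [serum_array()] with a `truth` attribute naming the antigen
#'   groups carrying planted effects per participant group.
#' @export
make_serum_array <- function(cfg, panel = default_antigen_panel()) {
  validate_synth_config(cfg)
  set.seed(stage_seed(cfg$seed, "serum"))
  groups <- names(cfg$n_serum)
  cov_tab <- list( # baseline-table means/rates per group
    age_mean = c(ctrl = 57.8, at_risk = 58.5, early_ra = 51.8),
    age_sd = c(ctrl = 12.6, at_risk = 12.6, early_ra = 12.9),
    p_female = c(ctrl = 0.680, at_risk = 0.649, early_ra = 0.661),
    p_smoke = c(ctrl = 0.343, at_risk = 0.361, early_ra = 0.532),
    p_0401 = c(ctrl = 0.192, at_risk = 0.268, early_ra = 0.387))

  covars <- do.call(rbind, lapply(groups, function(g) {
    n <- cfg$n_serum[[g]]
    data.frame(
      subject = sprintf("serum_%s_%03d", g, seq_len(n)), group = g,
      age = rnorm(n, cov_tab$age_mean[[g]], cov_tab$age_sd[[g]]),
      sex = ifelse(rbinom(n, 1, cov_tab$p_female[[g]]) == 1, "F", "M"),
      smoking_ever = rbinom(n, 1, cov_tab$p_smoke[[g]]) == 1,
      hla0401 = rbinom(n, 1, cov_tab$p_0401[[g]]) == 1,
      stringsAsFactors = FALSE)
  }))

  base_meanlog <- runif(nrow(panel), log(200), log(2000))
  names(base_meanlog) <- panel$antigen
  mfi <- matrix(NA_real_, nrow(covars), nrow(panel),
                dimnames = list(covars$subject, panel$antigen))
  for (j in seq_len(nrow(panel))) {
    eff <- vapply(covars$group, function(g) {
      e <- cfg$antigen_effects[[g]]
      grp <- panel$antigen_group[j]
      if (!is.null(e) && !is.na(grp) && grp %in% names(e)) e[[grp]] else 1
    }, numeric(1))
    mfi[, j] <- rlnorm(nrow(covars), base_meanlog[j] + log(eff),
                       cfg$mfi_log_sd)
  }
  arr <- serum_array(mfi, covars, panel)
  attr(arr, "truth") <- cfg$antigen_effects
  arr
}

#' Generate a synthetic probe annotation table
#'
#' Distributes probes over `n_genes` genes on a toy genome: each gene gets
#' a TSS, a strand and a body interval, and its probes are placed either
#' inside the strand-oriented promoter window, inside the gene body, or
#' just outside both (so gene mapping has all three cases to resolve).
#'
#' @param probe_ids character vector of probe ids to annotate.
#' @param n_genes number of genes (default ~1 gene per 4 probes).
#' @param seed integer seed.
#' @return annotation data frame in the [read_probe_annotation()] schema.
#' @export
make_probe_annotation <- function(probe_ids,
                                  n_genes = max(1, length(probe_ids) %/% 4),
                                  seed = 1L) {
  set.seed(stage_seed(seed, "annotation"))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  tss <- sort(sample(seq(1e4, 1e8, by = 1e4), n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- sample(2e3:5e4, n_genes, replace = TRUE)
  gene_start <- ifelse(strand == "+", tss, tss - glen)
  gene_end <- ifelse(strand == "+", tss + glen, tss)
  gi <- sample(seq_len(n_genes), length(probe_ids), replace = TRUE)
  zone <- sample(c("promoter", "body", "outside"), length(probe_ids),
                 replace = TRUE, prob = c(0.4, 0.4, 0.2))
  dirn <- ifelse(strand[gi] == "+", 1, -1)
  off <- integer(length(probe_ids))
  off[zone == "promoter"] <- sample(-2500:500,
                                    sum(zone == "promoter"), TRUE)
  off[zone == "body"] <- sample(600:1900, sum(zone == "body"), TRUE)
  off[zone == "outside"] <- sample(60000:90000,
                                   sum(zone == "outside"), TRUE)
  pos <- tss[gi] + dirn * off
  data.frame(probe_id = probe_ids,
             chrom = paste0("chr", 1 + (gi %% 22)),
             pos = pos, strand = strand[gi], gene = genes[gi],
             tss = tss[gi], gene_start = gene_start[gi],
             gene_end = gene_end[gi], stringsAsFactors = FALSE)
}

#' Generate synthetic gene sets
#'
#' Random gene sets over a gene universe, optionally with one set
#' enriched for a supplied target list (a planted pathway).
#'
#' @param genes character vector, the gene universe.
#' @param n_sets number of random sets.
#' @param set_size size of each set.
#' @param planted optional character vector of genes; when given, an
#'   extra set named `"planted_pathway"` containing them is appended.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
make_gene_sets <- function(genes, n_sets = 20, set_size = 15,
                           planted = NULL, seed = 1L) {
  set.seed(stage_seed(seed, "genesets"))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, min(set_size, length(genes))))
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  if (!is.null(planted)) sets$planted_pathway <- planted
  sets
}
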