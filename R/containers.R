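#' Methylation beta matrix with sample metadata
#'
#' Couples a probes x samples matrix of methylation fractions with the
#' per-sample metadata (group, cohort, cell type, subject) every methylome
#' operation needs. Values must lie in \[0, 1\] or be missing; probe ids
#' (rownames) must be unique; sample ids must match between the matrix
#' columns and the metadata.
#'
#' @param values numeric matrix, probes x samples, rownames = probe ids,
#'   colnames = sample ids.
#' @param sample_meta data frame with columns `sample_id`, `subject`,
#'   `group`, `cohort`, `cell_type`.
#' @return an object of class `beta_matrix`.
#' @export
#' @examples
#' v <- matrix(runif(6), 3, 2, dimnames = list(paste0("cg", 1:3), c("a", "b")))
#' m <- data.frame(sample_id = c("a", "b"), subject = c("s1", "s2"),
#'                 group = c("ctrl", "at_risk"), cohort = "cohort1",
#'                 cell_type = "Tmem")
#' beta_matrix(v, m)
beta_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.data.frame(sample_meta))
  req <- c("sample_id", "subject", "group", "cohort", "cell_type")
  missing_cols <- setdiff(req, names(sample_meta))
  if (length(missing_cols))
    stop("sample_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique probe id rownames")
  if (!identical(colnames(values), sample_meta$sample_id))
    stop("column order of values must match sample_meta$sample_id")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]")
  structure(list(values = values, sample_meta = sample_meta),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples\n")
  cat("  groups:   ", paste(names(table(x$sample_meta$group)),
                            table(x$sample_meta$group),
                            sep = "=", collapse = ", "), "\n")
  cat("  cohorts:  ", paste(unique(x$sample_meta$cohort), collapse = ", "),
      "\n")
  cat("  cell types:", paste(unique(x$sample_meta$cell_type),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Subset a beta matrix by sample or probe
#'
#' @param beta a [beta_matrix()].
#' @param samples logical/integer/character index into samples.
#' @param probes logical/integer/character index into probes.
#' @return a [beta_matrix()].
#' @export
subset_beta <- function(beta, samples = NULL, probes = NULL) {
  stopifnot(inherits(beta, "beta_matrix"))
  v <- beta$values; m <- beta$sample_meta
  if (!is.null(probes)) v <- v[probes, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    m <- m[samples, , drop = FALSE]
  }
  beta_matrix(v, m)
}

#' Serum antibody-array container
#'
#' Subjects x antigens mean-fluorescence matrix plus subject covariates and
#' antigen metadata (citrullination flag and summing group). Every antigen
#' belongs to at most one summing group.
#'
#' @param mfi numeric matrix, subjects x antigens, non-negative;
#'   dimnames required.
#' @param covariates data frame with `subject`, `group`, `age`, `sex`,
#'   `smoking_ever`, `hla0401`.
#' @param antigen_meta data frame with `antigen`, `citrullinated`,
#'   `antigen_group` (NA = ungrouped).
#' @return an object of class `serum_array`.
#' @export
serum_array <- function(mfi, covariates, antigen_meta) {
  stopifnot(is.matrix(mfi), all(mfi >= 0, na.rm = TRUE))
  req <- c("subject", "group", "age", "sex", "smoking_ever", "hla0401")
  if (length(setdiff(req, names(covariates))))
    stop("covariates lack columns: ",
         paste(setdiff(req, names(covariates)), collapse = ", "))
  if (!identical(rownames(mfi), covariates$subject))
    stop("mfi rownames must match covariates$subject")
  if (!identical(colnames(mfi), antigen_meta$antigen))
    stop("mfi colnames must match antigen_meta$antigen")
  structure(list(mfi = mfi, covariates = covariates,
                 antigen_meta = antigen_meta),
            class = "serum_array")
}

#' @export
print.serum_array <- function(x, ...) {
  cat("serum_array:", nrow(x$mfi), "subjects x", ncol(x$mfi), "antigens (",
      sum(x$antigen_meta$citrullinated), "citrullinated )\n")
  print(table(x$covariates$group))
  invisible(x)
}
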