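#' Read / write methylation inputs
#'
#' The beta matrix travels as a TSV with probes as rows (first column
#' `probe_id`, remaining columns = sample ids) together with a sample-sheet
#' TSV (`sample_id`, `subject`, `group`, `cohort`, `cell_type`).
#'
#' @param matrix_file path to the beta TSV.
#' @param sheet_file path to the sample-sheet TSV.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(matrix_file, sheet_file) {
  tab <- read.delim(matrix_file, check.names = FALSE)
  meta <- read.delim(sheet_file, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  beta_matrix(vals, meta)
}

#' @rdname read_beta_matrix
#' @param beta a [beta_matrix()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return (writer) invisibly, the two file paths.
#' @export
write_beta_matrix <- function(beta, dir, prefix = "beta") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  sf <- file.path(dir, paste0(prefix, "_samples.tsv"))
  out <- data.frame(probe_id = rownames(beta$values), beta$values,
                    check.names = FALSE)
  write.table(out, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(beta$sample_meta, sf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix = mf, samples = sf))
}

#' Read a BED-like probe annotation table
#'
#' Expected tab-separated columns: `probe_id`, `chrom`, `pos` (1-based),
#' `strand` (+/-), `gene`, `tss`, `gene_start`, `gene_end`. Coordinates are
#' 1-based; promoter windows downstream are oriented by `strand`.
#' Malformed rows raise an error naming the offending line.
#'
#' @param file path to the annotation TSV.
#' @return a validated data frame.
#' @export
read_probe_annotation <- function(file) {
  ann <- read.delim(file, stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "pos", "strand", "gene", "tss",
           "gene_start", "gene_end")
  if (length(setdiff(req, names(ann))))
    stop("annotation lacks columns: ",
         paste(setdiff(req, names(ann)), collapse = ", "))
  bad <- which(!(ann$strand %in% c("+", "-")) | is.na(ann$pos) |
                 is.na(ann$tss) | ann$gene_start > ann$gene_end)
  if (length(bad))
    stop("malformed annotation row(s) at line ",
         paste(head(bad + 1, 5), collapse = ", "),
         " of ", file)
  ann
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT (set name, description, member genes...).
#' Parsing is delegated to \pkg{fgsea}.
#'
#' @param file path to a .gmt file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(file) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the fgsea package")
  fgsea::gmtPathways(file)
}

#' Write / read per-subject cytometry event tables
#'
#' One CSV per subject (columns: subject, group, the six marker
#' intensities, tmr, antigen) plus a CSV of pre-enrichment CD4 counts.
#'
#' @param tables result of [make_event_tables()] or a compatible list.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_event_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables$events), function(s) {
    f <- file.path(dir, paste0(s, ".csv"))
    write.csv(tables$events[[s]], f, row.names = FALSE)
    f
  }, character(1))
  cf <- file.path(dir, "cd4_pre.csv")
  write.csv(data.frame(subject = names(tables$cd4_pre),
                       cd4_pre = as.integer(tables$cd4_pre)),
            cf, row.names = FALSE)
  invisible(c(paths, cd4_pre = cf))
}

#' @rdname write_event_tables
#' @export
read_event_tables <- function(dir) {
  cf <- file.path(dir, "cd4_pre.csv")
  cd4 <- read.csv(cf, stringsAsFactors = FALSE)
  files <- setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                   cf)
  events <- lapply(files, read.csv, stringsAsFactors = FALSE)
  names(events) <- vapply(events, function(e) e$subject[1], character(1))
  list(events = events,
       cd4_pre = setNames(cd4$cd4_pre, cd4$subject))
}

#' Write / read a serum antibody array
#'
#' Three CSVs: the MFI matrix (`subject` + one column per antigen), the
#' covariates, and the antigen metadata.
#'
#' @param arr a [serum_array()].
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_serum_array <- function(arr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- file.path(dir, "mfi.csv")
  cf <- file.path(dir, "covariates.csv")
  af <- file.path(dir, "antigens.csv")
  write.csv(data.frame(subject = rownames(arr$mfi), arr$mfi,
                       check.names = FALSE), mf, row.names = FALSE)
  write.csv(arr$covariates, cf, row.names = FALSE)
  write.csv(arr$antigen_meta, af, row.names = FALSE)
  invisible(c(mfi = mf, covariates = cf, antigens = af))
}

#' @rdname write_serum_array
#' @export
read_serum_array <- function(dir) {
  mtab <- read.csv(file.path(dir, "mfi.csv"), check.names = FALSE)
  mfi <- as.matrix(mtab[, -1, drop = FALSE])
  rownames(mfi) <- mtab$subject
  covars <- read.csv(file.path(dir, "covariates.csv"),
                     stringsAsFactors = FALSE)
  ant <- read.csv(file.path(dir, "antigens.csv"), stringsAsFactors = FALSE)
  serum_array(mfi, covars, ant)
}
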