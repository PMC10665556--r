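#' Map DML to differentially methylated genes
#'
#' A probe supports a gene's promoter when its position falls inside the
#' strand-oriented window \[TSS - upstream, TSS + downstream\] (both ends
#' closed; for minus-strand genes the window is reflected in genomic
#' coordinates), and the gene body when it falls inside the annotated gene
#' interval. Promoter assignment wins when both apply. Coordinates are
#' 1-based. Probes without annotation are dropped with a message.
#'
#' @param probes character vector of DML probe ids (typically the
#'   cross-cohort union).
#' @param annotation data frame as returned by [read_probe_annotation()].
#' @param upstream,downstream promoter window extent in bp relative to the
#'   TSS, measured in transcription direction (defaults 2500 and 500).
#' @return a data frame of class `dmg_set` with columns `gene`, `region`
#'   (`promoter`/`body`), `probe_id`; one row per supporting probe. The
#'   unique gene set is available via `unique(x$gene)`.
#' @export
#' @examples
#' ann <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 900,
#'                   strand = "+", gene = "G1", tss = 1000,
#'                   gene_start = 1000, gene_end = 5000)
#' map_dmg("cg1", ann)  # 100 bp upstream of the TSS: promoter
map_dmg <- function(probes, annotation, upstream = 2500, downstream = 500) {
  ann <- annotation[annotation$probe_id %in% probes, , drop = FALSE]
  n_unann <- length(setdiff(probes, ann$probe_id))
  if (n_unann)
    message(n_unann, " probe(s) without annotation were dropped")
  if (!nrow(ann))
    return(structure(data.frame(gene = character(), region = character(),
                                probe_id = character()),
                     class = c("dmg_set", "data.frame")))
  plus <- ann$strand == "+"
  win_lo <- ifelse(plus, ann$tss - upstream, ann$tss - downstream)
  win_hi <- ifelse(plus, ann$tss + downstream, ann$tss + upstream)
  in_prom <- ann$pos >= win_lo & ann$pos <= win_hi
  in_body <- ann$pos >= ann$gene_start & ann$pos <= ann$gene_end
  region <- ifelse(in_prom, "promoter", ifelse(in_body, "body", NA))
  out <- data.frame(gene = ann$gene, region = region,
                    probe_id = ann$probe_id, stringsAsFactors = FALSE)
  out <- out[!is.na(out$region), , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("dmg_set", "data.frame")
  out
}

#' Pathway over-representation of a DMG set
#'
#' One-sided (upper-tail) hypergeometric test of each gene set against the
#' DMG list on a user-supplied background universe, with
#' Benjamini-Hochberg FDR across sets and a significance flag at the
#' stated FDR threshold (default 0.1). Gene sets are intersected with the
#' background first; sets that become empty are skipped with a message.
#'
#' @param genes character vector of differentially methylated genes.
#' @param genesets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background character vector, the gene universe. Must contain all
#'   DMG.
#' @param fdr_threshold flag threshold on the BH-adjusted p (default 0.1).
#' @return data frame with `set`, `set_size`, `overlap`, `p`, `fdr`,
#'   `significant`, ordered by p.
#' @export
pathway_enrichment <- function(genes, genesets, background,
                               fdr_threshold = 0.1) {
  genes <- unique(genes)
  if (length(setdiff(genes, background)))
    stop("background must contain every DMG; missing: ",
         paste(head(setdiff(genes, background), 5), collapse = ", "))
  genesets <- lapply(genesets, intersect, background)
  empty <- lengths(genesets) == 0
  if (any(empty)) {
    message(sum(empty), " gene set(s) empty after background ",
            "intersection; skipped")
    genesets <- genesets[!empty]
  }
  N <- length(unique(background)); K <- length(genes)
  res <- do.call(rbind, lapply(names(genesets), function(s) {
    members <- genesets[[s]]
    m <- length(intersect(genes, members))
    data.frame(set = s, set_size = length(members), overlap = m,
               p = phyper(m - 1, K, N - K, length(members),
                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), fdr = numeric(),
                      significant = logical()))
  res$fdr <- p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold
  res[order(res$p), , drop = FALSE]
}
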