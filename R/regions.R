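#' Classify circRNAs by genomic region
#'
#' Assigns each circRNA exactly one of four region classes against a set of
#' gene models: `exonic` (same-strand overlap with at least one exon),
#' `intronic` (same-strand containment in a gene body with no exon
#' overlap), `antisense` (overlap only with opposite-strand genes) and
#' `intergenic` (no gene overlap).  A `"."`/`"*"` circRNA strand matches
#' either strand for exonic/intronic calls but never produces an antisense
#' call.  The host gene is recorded for exonic and intronic circRNAs.
#'
#' @param circ BED-like data frame (`chrom`, `start` 0-based half-open,
#'   `end`, `strand`, `circ_id`).
#' @param gene_models GRanges with `type` (gene/exon) and `gene_id`
#'   metadata, e.g. from [generate_annotation()] or [read_gene_models()].
#' @return `circ` with `region_class` and `host_gene` columns.
#' @export
classify_region <- function(circ, gene_models) {
  stopifnot(is.data.frame(circ))
  if (nrow(circ) == 0L) {
    circ$region_class <- character(0)
    circ$host_gene <- character(0)
    return(circ)
  }
  if (any(circ$start >= circ$end))
    stop("malformed circRNA interval(s): start >= end for ",
         paste(circ$circ_id[circ$start >= circ$end], collapse = ", "))
  strand <- ifelse(circ$strand %in% c("+", "-"), circ$strand, "*")
  cgr <- GenomicRanges::GRanges(circ$chrom,
                                IRanges::IRanges(circ$start + 1L, circ$end),
                                strand = strand)
  exons <- gene_models[gene_models$type == "exon"]
  genes <- gene_models[gene_models$type == "gene"]
  if (!length(genes) && length(exons)) {
    spl <- split(exons, exons$gene_id)
    genes <- unlist(range(spl))
    genes$gene_id <- names(genes)
    genes$type <- "gene"
  }

  n <- nrow(circ)
  cls <- rep("intergenic", n)
  host <- rep(NA_character_, n)

  # same-strand ('*' matches either) exon overlap -> exonic
  ov_ex <- GenomicRanges::findOverlaps(cgr, exons, ignore.strand = FALSE)
  if (length(ov_ex)) {
    qh <- S4Vectors::queryHits(ov_ex)
    cls[unique(qh)] <- "exonic"
    first <- !duplicated(qh)
    host[qh[first]] <- exons$gene_id[S4Vectors::subjectHits(ov_ex)[first]]
  }

  # same-strand containment in a gene body without exon overlap -> intronic
  ov_in <- GenomicRanges::findOverlaps(cgr, genes, type = "within",
                                       ignore.strand = FALSE)
  if (length(ov_in)) {
    qh <- S4Vectors::queryHits(ov_in)
    take <- cls[qh] == "intergenic"
    cls[qh[take]] <- "intronic"
    first <- take & !duplicated(qh)
    host[qh[first]] <- genes$gene_id[S4Vectors::subjectHits(ov_in)[first]]
  }

  # remaining gene overlap: antisense only for stranded circRNAs whose every
  # overlapping gene lies on the opposite strand
  ov_any <- GenomicRanges::findOverlaps(cgr, genes, ignore.strand = TRUE)
  if (length(ov_any)) {
    qh <- S4Vectors::queryHits(ov_any)
    cand <- setdiff(unique(qh), which(cls != "intergenic"))
    for (i in cand) {
      if (strand[i] == "*") next
      gs <- as.character(GenomicRanges::strand(
        genes[S4Vectors::subjectHits(ov_any)[qh == i]]))
      if (all(gs %in% c("+", "-")) && all(gs != strand[i]))
        cls[i] <- "antisense"
    }
  }

  circ$region_class <- cls
  circ$host_gene <- host
  circ
}
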