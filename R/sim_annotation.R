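#' Generate gene models and circRNA intervals with known region classes
#'
#' Lays the configured genes head to tail on one chromosome (five 300-bp
#' exons separated by 700-bp introns, strands alternating) and places each
#' circRNA so that its genomic region class is guaranteed by construction:
#' exonic circRNAs inside an exon of their host gene on the same strand,
#' intronic circRNAs inside an intron, antisense circRNAs overlapping a gene
#' on the opposite strand, and intergenic circRNAs in the gaps between
#' genes.
#'
#' @param config A [sim_config()].
#' @return List with `circ_annotation` (BED-like data frame: `chrom`,
#'   `start` 0-based half-open, `end`, `strand`, `circ_id`, `host_gene`;
#'   host is `NA` for intergenic and antisense circRNAs) and `gene_models`
#'   (a [GenomicRanges::GRanges] with `type` gene/exon and `gene_id`,
#'   1-based closed coordinates as in GTF).
#' @seealso [classify_region()], [write_gtf()]
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  plan <- .feature_plan(config)
  n_gene <- config$n_gene
  n_exon <- 5L; exon_len <- 300L; intron_len <- 700L
  gene_len <- n_exon * exon_len + (n_exon - 1L) * intron_len
  spacing <- 3000L

  gene_rows <- list()
  gene_start <- integer(n_gene)  # 1-based gene start
  gene_strand <- character(n_gene)
  for (i in seq_len(n_gene)) {
    s <- (i - 1L) * (gene_len + spacing) + 1001L
    strand <- if (i %% 2L == 1L) "+" else "-"
    gene_start[i] <- s
    gene_strand[i] <- strand
    gid <- plan$gene_ids[i]
    gene_rows[[gid]] <- data.frame(
      start = c(s, s + (seq_len(n_exon) - 1L) * (exon_len + intron_len)),
      end = c(s + gene_len - 1L,
              s + (seq_len(n_exon) - 1L) * (exon_len + intron_len) + exon_len - 1L),
      type = c("gene", rep("exon", n_exon)),
      gene_id = gid, strand = strand, stringsAsFactors = FALSE)
  }
  gtab <- if (n_gene) do.call(rbind, c(gene_rows, list(make.row.names = FALSE)))
          else data.frame(start = integer(0), end = integer(0),
                          type = character(0), gene_id = character(0),
                          strand = character(0))
  gene_models <- GenomicRanges::GRanges(
    seqnames = rep("chr1", nrow(gtab)),
    ranges = IRanges::IRanges(start = gtab$start, end = gtab$end),
    strand = gtab$strand, type = gtab$type, gene_id = gtab$gene_id)
  names(gene_start) <- plan$gene_ids
  names(gene_strand) <- plan$gene_ids

  n_circ <- config$n_circ
  ann <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    strand = character(0), circ_id = character(0),
                    host_gene = character(0), stringsAsFactors = FALSE)
  if (n_circ) {
    ci <- which(plan$kind == "circ")
    rows <- vector("list", n_circ)
    n_intergenic_seen <- 0L
    for (j in seq_len(n_circ)) {
      i <- ci[j]
      cls <- plan$region[i]
      jit <- (j %% 3L) * 10L
      if (cls == "exonic") {
        s1 <- gene_start[plan$host[i]]
        start0 <- s1 + 1000L + 20L + jit - 1L      # inside exon 2 (0-based)
        end0 <- start0 + 200L
        strand <- gene_strand[plan$host[i]]
        host <- plan$host[i]
      } else if (cls == "intronic") {
        s1 <- gene_start[plan$host[i]]
        start0 <- s1 + 1300L + 100L + jit - 1L     # inside intron 2
        end0 <- start0 + 350L
        strand <- gene_strand[plan$host[i]]
        host <- plan$host[i]
      } else if (cls == "antisense") {
        s1 <- gene_start[plan$asense[i]]
        start0 <- s1 + 400L + jit - 1L
        end0 <- start0 + 800L
        strand <- if (gene_strand[plan$asense[i]] == "+") "-" else "+"
        host <- NA_character_
      } else {                                     # intergenic
        n_intergenic_seen <- n_intergenic_seen + 1L
        base <- if (n_gene) {
          g <- 1L + (n_intergenic_seen - 1L) %% n_gene
          gene_start[g] + gene_len - 1L
        } else 1000L * n_intergenic_seen
        start0 <- base + 500L + jit
        end0 <- start0 + 600L
        strand <- if (j %% 2L) "+" else "-"
        host <- NA_character_
      }
      rows[[j]] <- data.frame(chrom = "chr1", start = start0, end = end0,
                              strand = strand, circ_id = plan$feature_id[i],
                              host_gene = host, stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  list(circ_annotation = ann, gene_models = gene_models)
}

#' Write gene models as GTF
#'
#' @param gene_models GRanges as produced by [generate_annotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gene_models, path) {
  rtracklayer::export(gene_models, path, format = "gtf")
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports the file and keeps gene/exon records with their `gene_id`, the
#' form [classify_region()] expects.
#'
#' @param path GTF file (1-based closed coordinates).
#' @return A GRanges with `type` and `gene_id` metadata columns.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("gene", "exon")]
  GenomicRanges::GRanges(seqnames = GenomicRanges::seqnames(gr),
                         ranges = IRanges::ranges(gr),
                         strand = GenomicRanges::strand(gr),
                         type = as.character(gr$type), gene_id = gr$gene_id)
}

#' Write / read the BED-like circRNA annotation table
#'
#' Tab-separated, 0-based half-open `start`, columns `chrom`, `start`,
#' `end`, `strand`, `circ_id`, `host_gene`.
#'
#' @param annotation Data frame as produced by [generate_annotation()].
#' @param path File path.
#' @return `path` (writer) or the annotation data frame (reader).
#' @export
write_circ_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_circ_annotation
#' @export
read_circ_annotation <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
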