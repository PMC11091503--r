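#' circRNA-mRNA correlation edges within trait-significant modules
#'
#' Tests every circRNA x gene pair co-assigned to a module significantly
#' associated with feed efficiency (RFI or DFC at `p < sig_level`) and
#' stores an edge iff Spearman's `r > r_threshold` and `p < p_threshold`
#' ([spearman_test()]; exact permutation p for n <= 9).  Expression
#' matrices should already be subset to the tissue x cross samples under
#' study.
#'
#' @param circ_expr,gene_expr Expression matrices (features x samples,
#'   shared columns).
#' @param assignment Module assignment data frame (`feature_id`, `module`)
#'   covering both feature kinds.
#' @param trait_correlation Result of [module_trait_correlation()] for the
#'   same modules (module labels `ME<label>` or bare labels).
#' @param traits Traits that qualify a module (default RFI and DFC).
#' @param sig_level Module-trait significance gate (default 0.01).
#' @param r_threshold,p_threshold Edge thresholds (defaults 0.6, 0.05).
#' @param tissue,cross Labels carried into the edge table.
#' @return Data frame of stored edges: `circ_id`, `gene_id`, `spearman_r`,
#'   `p`, `module`, `tissue`, `cross`.
#' @export
correlate_pairs <- function(circ_expr, gene_expr, assignment,
                            trait_correlation,
                            traits = c("RFI", "DFC"), sig_level = 0.01,
                            r_threshold = 0.6, p_threshold = 0.05,
                            tissue = NA_character_, cross = NA_character_) {
  stopifnot(identical(colnames(circ_expr), colnames(gene_expr)))
  empty <- data.frame(circ_id = character(0), gene_id = character(0),
                      spearman_r = numeric(0), p = numeric(0),
                      module = character(0), tissue = character(0),
                      cross = character(0), stringsAsFactors = FALSE)
  tc <- trait_correlation
  tc$module <- sub("^ME", "", tc$module)
  qual <- unique(tc$module[tc$trait %in% traits & !is.na(tc$p) &
                             tc$p < sig_level])
  qual <- setdiff(qual, c("0", "grey"))
  if (!length(qual)) {
    message("no module significantly associated with ",
            paste(traits, collapse = "/"), "; empty network")
    return(empty)
  }
  mods <- .as_assignment(assignment)
  rows <- list()
  for (m in qual) {
    members <- names(mods)[mods == m]
    circs <- intersect(members, rownames(circ_expr))
    genes <- intersect(members, rownames(gene_expr))
    for (ci in circs) {
      x <- circ_expr[ci, ]
      if (sd(x) == 0) next
      for (gi in genes) {
        y <- gene_expr[gi, ]
        if (sd(y) == 0) next
        st <- spearman_test(x, y)
        if (st$r > r_threshold && st$p < p_threshold)
          rows[[length(rows) + 1L]] <-
            data.frame(circ_id = ci, gene_id = gi, spearman_r = st$r,
                       p = st$p, module = m, tissue = tissue, cross = cross,
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Candidate heterosis-associated circRNA-gene pairs
#'
#' Keeps the edges whose two endpoints are both nonadditive (dominant,
#' overdominant or underdominant) in the cross under study, and flags
#' whether the pair shares an identical pattern label (`same_pattern`) and
#' whether the circRNA's pattern differs between the two crosses
#' (`cross_divergent`, the criterion for consistency with divergent RFI
#' heterosis between the reciprocal crosses).
#'
#' @param edges Edge table from [correlate_pairs()].
#' @param pattern_calls Pattern calls covering both feature kinds, with
#'   columns `feature_id`, `cross`, `pattern`, `pattern_class` (for the
#'   relevant tissue).
#' @param cross Cross under study (`"WY"` or `"YW"`).
#' @return Subset of `edges` with `circ_pattern`, `gene_pattern`,
#'   `same_pattern`, `cross_divergent` columns.
#' @export
select_candidates <- function(edges, pattern_calls, cross) {
  if (!cross %in% CROSSES) stop("'cross' must be WY or YW")
  nonadd <- c("dominant", "overdominant", "underdominant")
  lk <- function(id, cr, what = "pattern") {
    hit <- pattern_calls$feature_id == id & pattern_calls$cross == cr
    if (!any(hit)) return(NA_character_)
    pattern_calls[[what]][which(hit)[1]]
  }
  keep <- list()
  for (i in seq_len(nrow(edges))) {
    cp <- lk(edges$circ_id[i], cross)
    gp <- lk(edges$gene_id[i], cross)
    if (is.na(cp) || is.na(gp)) {
      warning("no pattern call for edge ", edges$circ_id[i], " - ",
              edges$gene_id[i], "; skipped")
      next
    }
    if (!(pattern_class(cp) %in% nonadd) || !(pattern_class(gp) %in% nonadd))
      next
    other <- setdiff(CROSSES, cross)
    cp_other <- lk(edges$circ_id[i], other)
    row <- edges[i, , drop = FALSE]
    row$circ_pattern <- cp
    row$gene_pattern <- gp
    row$same_pattern <- identical(cp, gp)
    row$cross_divergent <- !is.na(cp_other) && cp_other != cp
    keep[[length(keep) + 1L]] <- row
  }
  if (!length(keep))
    return(cbind(edges[0, , drop = FALSE],
                 data.frame(circ_pattern = character(0),
                            gene_pattern = character(0),
                            same_pattern = logical(0),
                            cross_divergent = logical(0))))
  do.call(rbind, c(keep, list(make.row.names = FALSE)))
}

#' Export a circRNA-gene network as GraphML and SIF
#'
#' Writes `<prefix>.graphml` (node attributes: feature kind, pattern,
#' module; edge attributes: r, p) and `<prefix>.sif` (simple interaction
#' format, relation `corr`).  The SIF round-trips losslessly through
#' [read_sif()].
#'
#' @param edges Edge table from [correlate_pairs()] (optionally with the
#'   pattern columns from [select_candidates()]).
#' @param path_prefix Output path without extension.
#' @return Named character vector of the two written paths, invisibly.
#' @export
export_network <- function(edges, path_prefix) {
  gml <- paste0(path_prefix, ".graphml")
  sif <- paste0(path_prefix, ".sif")
  nodes <- data.frame(name = unique(c(edges$circ_id, edges$gene_id)),
                      stringsAsFactors = FALSE)
  if (nrow(nodes)) {
    nodes$kind <- ifelse(nodes$name %in% edges$circ_id, "circ", "gene")
    pat <- c(setNames(edges$circ_pattern %||% rep(NA_character_, nrow(edges)),
                      edges$circ_id),
             setNames(edges$gene_pattern %||% rep(NA_character_, nrow(edges)),
                      edges$gene_id))
    nodes$pattern <- ifelse(is.na(pat[nodes$name]), "", pat[nodes$name])
    mod <- c(setNames(edges$module, edges$circ_id),
             setNames(edges$module, edges$gene_id))
    nodes$module <- ifelse(is.na(mod[nodes$name]), "", mod[nodes$name])
  } else {
    nodes$kind <- character(0); nodes$pattern <- character(0)
    nodes$module <- character(0)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$circ_id, to = edges$gene_id,
               r = edges$spearman_r, p = edges$p,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  igraph::write_graph(g, gml, format = "graphml")
  sif_tab <- data.frame(source = edges$circ_id, relation = rep("corr",
                                                               nrow(edges)),
                        target = edges$gene_id, stringsAsFactors = FALSE)
  write.table(sif_tab, sif, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(graphml = gml, sif = sif))
}

#' @rdname export_network
#' @param path A `.sif` file written by [export_network()].
#' @return `read_sif()`: data frame `source`, `relation`, `target`.
#' @export
read_sif <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(source = character(0), relation = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  out <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("source", "relation", "target")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
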