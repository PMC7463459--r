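# Homology projection of a reference protein-protein interaction edge list
# onto the query family: each query maps to its closest reference by domain
# p-distance, and reference edges induce edges between the mapped queries.

#' Map each query to its best-matching reference by domain p-distance
#'
#' @param queries,references Named character vectors of aligned 55-column
#'   domains.
#' @return A homolog map data frame: `query_id`, `reference_id`, `distance`
#'   (ties broken by reference order).
#' @export
best_hits <- function(queries, references) {
  if (!length(references)) stop("reference set must be non-empty")
  hits <- assign_clades(queries, references,
                        ref_clades = names(references) %||%
                          paste0("ref", seq_along(references)))
  data.frame(query_id = hits$query_id, reference_id = hits$nearest_reference,
             distance = hits$distance, stringsAsFactors = FALSE)
}

#' Project reference interactions onto the query family
#'
#' For every reference edge (A, B), an edge (q1, q2) is emitted for every
#' query q1 mapping to A and q2 mapping to B with q1 != q2; duplicates are
#' collapsed and self-edges dropped.  A reference self-loop (homodimer)
#' projects to all distinct query pairs sharing that reference, and each such
#' query is annotated as a potential homodimer.
#'
#' @param map A [best_hits()] data frame (`query_id`, `reference_id`).
#' @param reference_edges Data frame with two columns of reference ids.
#' @param references Optional character vector of all valid reference ids;
#'   when given, an edge naming an id outside it is an error.
#' @return List with `edges` (data frame `from`, `to`, `via` - the inducing
#'   reference edge) and `homodimer_candidates` (character vector).
#' @export
project_network <- function(map, reference_edges, references = NULL) {
  ref_a <- as.character(reference_edges[[1]])
  ref_b <- as.character(reference_edges[[2]])
  if (!is.null(references)) {
    bad <- setdiff(c(ref_a, ref_b), references)
    if (length(bad)) stop("edge names unknown reference(s): ",
                          paste(bad, collapse = ", "))
  }
  edges <- list()
  homodimers <- character(0)
  for (i in seq_along(ref_a)) {
    qa <- map$query_id[map$reference_id == ref_a[i]]
    qb <- map$query_id[map$reference_id == ref_b[i]]
    if (!length(qa) || !length(qb)) next
    pairs <- expand.grid(from = qa, to = qb, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    if (ref_a[i] == ref_b[i]) homodimers <- union(homodimers, qa)
    if (nrow(pairs)) {
      # canonical undirected orientation
      lo <- pmin(pairs$from, pairs$to)
      hi <- pmax(pairs$from, pairs$to)
      edges[[length(edges) + 1L]] <- data.frame(
        from = lo, to = hi, via = paste(ref_a[i], ref_b[i], sep = "--"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(edges)) {
    return(list(edges = data.frame(from = character(0), to = character(0),
                                   via = character(0)),
                homodimer_candidates = homodimers))
  }
  all_edges <- do.call(rbind, edges)
  all_edges <- all_edges[!duplicated(all_edges[, c("from", "to")]), ,
                         drop = FALSE]
  rownames(all_edges) <- NULL
  list(edges = all_edges, homodimer_candidates = sort(homodimers))
}

#' The packaged reference interaction edge list
#'
#' A small Arabidopsis bHLH interaction set (PYE with UNE12, bHLH104, ILR3,
#' FMA, MUTE and SPCH; ICE1 with FMA, SPCH and MUTE; HEC2 with SPT) of the
#' kind produced by querying an interaction database for the family.
#'
#' @return Data frame with columns `ref_a`, `ref_b`.
#' @export
reference_edges <- function() {
  read_tsv(system.file("extdata", "reference_edges.tsv", package = "bhlhscan"))
}
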