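# Distance-based phylogeny over the 55-column domain alignment: p-distance
# matrices, Saitou-Nei neighbor joining with deterministic tie-breaks,
# bootstrap bipartition support, and nearest-reference clade assignment.
# Trees are carried as ape "phylo" objects.

msa_matrix <- function(msa) {
  nm <- names(msa)
  msa <- as.character(msa)
  names(msa) <- nm
  if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
  if (length(unique(nchar(msa))) != 1L) stop("alignment is ragged")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

pdist_from_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- !gap[i, ] & !gap[j, ]
      nc <- sum(keep)
      if (nc == 0) {
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j])
      }
      d[i, j] <- d[j, i] <- sum(m[i, keep] != m[j, keep]) / nc
    }
  }
  d
}

#' Pairwise p-distance matrix of an aligned sequence set
#'
#' p-distance = mismatches / compared columns, with pairwise deletion of
#' columns where either sequence carries a gap.
#'
#' @param msa Named character vector of equal-length aligned sequences
#'   (gaps as `-`).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  if (length(msa) < 2) stop("need at least two sequences")
  pdist_from_matrix(msa_matrix(msa))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-criterion; pendant branch lengths from
#' the standard two-point formulas, negative lengths clamped to zero (with a
#' log line).  Ties on Q are broken by the smallest (i, j) pair in current
#' label order, so the result is deterministic.
#'
#' @param D Symmetric distance matrix with labelled rows/columns.
#' @return An unrooted `phylo` tree (binary except for the final trifurcation
#'   at the join of the last three lineages).
#' @export
nj_tree <- function(D) {
  n <- nrow(D)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  # each active node is represented by its newick subtree string
  nodes <- labels
  d <- D
  clamped <- FALSE
  fmt <- function(x) sprintf("%.17g", x)
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima of Q
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0 || lj < 0) clamped <- TRUE
    li <- max(0, li); lj <- max(0, lj)
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], merged)
    dimnames(d2) <- list(NULL, NULL)
    d <- d2
  }
  # final three lineages: three-point formulas
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) clamped <- TRUE
  if (clamped && getOption("bhlhscan.verbose", TRUE)) {
    log_msg("INFO", "negative NJ branch length(s) clamped to 0")
  }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nodes[1], fmt(max(0, la)),
                    nodes[2], fmt(max(0, lb)),
                    nodes[3], fmt(max(0, lc)))
  ape::read.tree(text = newick)
}

#' Neighbor-joining tree with bootstrap bipartition support
#'
#' Alignment columns are resampled with replacement `n_replicates` times; the
#' support of each internal edge of the full-data tree is the fraction of
#' replicate trees containing the same leaf bipartition (counted with
#' [ape::boot.phylo()]).  Supports are stored in `$node.label`.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed (resampling is reproducible).
#' @return A `phylo` tree with node labels in `[0, 1]` (root label `NA`).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  m <- msa_matrix(msa)
  build <- function(x) nj_tree(pdist_from_matrix(x))
  tree <- build(m)
  old <- options(bhlhscan.verbose = FALSE)  # silence per-replicate clamp logs
  on.exit(options(old))
  counts <- with_seed(seed,
    ape::boot.phylo(tree, m, build, B = n_replicates,
                    quiet = TRUE, rooted = FALSE))
  support <- counts / n_replicates
  support[1] <- NA  # the root "bipartition" of an unrooted tree is not a split
  tree$node.label <- support
  tree
}

#' Assign query domains to clades by nearest labelled reference
#'
#' Each query receives the clade of its minimum-p-distance reference (ties
#' broken by reference order); the distance to that reference is reported.
#'
#' @param queries Named character vector of aligned 55-column domains.
#' @param references Named character vector of aligned reference domains.
#' @param ref_clades Clade label per reference (recycled names of
#'   `references` order).
#' @return Data frame: `query_id`, `clade`, `nearest_reference`, `distance`.
#' @export
assign_clades <- function(queries, references, ref_clades) {
  if (!length(references)) stop("reference set must be non-empty")
  stopifnot(length(ref_clades) == length(references))
  if (!length(queries)) {
    return(data.frame(query_id = character(0), clade = character(0),
                      nearest_reference = character(0), distance = numeric(0)))
  }
  qm <- msa_matrix(queries)
  rm_ <- msa_matrix(references)
  if (ncol(qm) != ncol(rm_)) stop("query/reference alignments differ in width")
  rows <- lapply(seq_len(nrow(qm)), function(qi) {
    dvec <- vapply(seq_len(nrow(rm_)), function(ri) {
      keep <- qm[qi, ] != "-" & rm_[ri, ] != "-"
      if (!sum(keep)) return(NA_real_)
      sum(qm[qi, keep] != rm_[ri, keep]) / sum(keep)
    }, numeric(1))
    if (all(is.na(dvec))) {
      stop("query ", rownames(qm)[qi], " has no comparable columns to any reference")
    }
    best <- which.min(dvec)  # first minimum = reference label order
    data.frame(query_id = rownames(qm)[qi],
               clade = ref_clades[best],
               nearest_reference = rownames(rm_)[best],
               distance = dvec[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a tree as newick through the package's writer
#' @param tree A `phylo` object (node labels, if any, are kept).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
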