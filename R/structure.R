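# Exon-intron structure by spliced exact matching of a CDS against its
# genomic sequence.  Matching is exact (CDS and genomic derive from the same
# assembly); gaps shorter than min_intron are rejected as artifacts.
#
# Search: iterative deepening on the intron count.  At each depth the
# splice-constrained search (every intron GT..AG) runs first, then the
# unconstrained one, so the decomposition with fewest introns wins and
# all-GT..AG solutions are preferred at equal count.  Exon start candidates
# are anchored on exact 8-mer seeds located with Biostrings, then tried left
# to right with the longest consistent exon first; internal exons shorter
# than the 8 nt anchor are not discoverable (documented limitation).

ANCHOR_LEN <- 8L

#' Build a gene model object
#' @param gene_id Gene id.
#' @param exons Integer matrix of 0-based half-open exon intervals.
#' @param genomic Genomic sequence the intervals refer to.
#' @param strand `"+"` or `"-"` (annotation only).
#' @return A `gene_model` with derived `introns` and per-intron
#'   `splice_flags` (starts `GT` and ends `AG`).
#' @export
gene_model <- function(gene_id, exons, genomic, strand = "+") {
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  colnames(exons) <- c("start", "end")
  n <- nrow(exons)
  introns <- if (n > 1) {
    cbind(start = exons[-n, 2], end = exons[-1, 1])
  } else {
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  }
  g <- toupper(as.character(genomic)[1])
  splice_flags <- vapply(seq_len(nrow(introns)), function(i) {
    s <- introns[i, 1]; e <- introns[i, 2]
    substr(g, s + 1, s + 2) == "GT" && substr(g, e - 1, e) == "AG"
  }, logical(1))
  structure(list(gene_id = gene_id, exons = exons, introns = introns,
                 splice_flags = splice_flags, strand = strand),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene model %s: %d exon(s), %d intron(s)%s\n",
              x$gene_id, nrow(x$exons), nrow(x$introns),
              if (nrow(x$introns) && all(x$splice_flags)) ", all GT..AG" else ""))
  invisible(x)
}

# Longest common extension of cds[ci..] and genomic chars from gi (1-based
# indices into character vectors).
common_extension <- function(cds_chars, gen_chars, ci, gi) {
  n <- min(length(cds_chars) - ci, length(gen_chars) - gi) + 1L
  if (n <= 0) return(0L)
  cmp <- cds_chars[ci:(ci + n - 1L)] != gen_chars[gi:(gi + n - 1L)]
  mm <- which(cmp)
  if (length(mm)) mm[1] - 1L else n
}

#' Infer exon-intron structure from a CDS and its genomic sequence
#'
#' Finds a decomposition of the CDS into exact genomic substrings (exons)
#' separated by gaps (introns) of at least `min_intron` nt.  Among valid
#' decompositions the search prefers (1) fewest introns, (2) all introns
#' GT..AG, (3) leftmost exon starts.
#'
#' @param cds,genomic Named DNA sequences (character); `names()` must agree
#'   when both are named.
#' @param min_intron Minimum intron length in nt (default 20).
#' @param max_introns Search depth cap.
#' @return A [gene_model()].  Errors when the CDS is not derivable from the
#'   genomic sequence.
#' @export
infer_structure <- function(cds, genomic, min_intron = 20L, max_introns = 25L) {
  id <- names(cds) %||% names(genomic) %||% "gene"
  cds_s <- toupper(as.character(cds)[1])
  gen_s <- toupper(as.character(genomic)[1])
  if (nchar(cds_s) > nchar(gen_s)) stop("CDS longer than genomic sequence")
  cds_chars <- strsplit(cds_s, "")[[1]]
  gen_chars <- strsplit(gen_s, "")[[1]]
  Lc <- length(cds_chars); Lg <- length(gen_chars)

  # k-mer index of the genomic sequence: rolling base-4 codes of every
  # ANCHOR_LEN window, bucketed by code, give O(1) candidate exon starts
  kmer_codes <- function(chars, w) {
    base <- match(chars, DNA_LETTERS) - 1L
    n <- length(base) - w + 1L
    if (n < 1L) return(numeric(0))
    code <- numeric(n)
    for (t in 0:(w - 1L)) {
      code <- code + base[(1 + t):(n + t)] * 4^(w - 1L - t)
    }
    code
  }
  gen_codes <- kmer_codes(gen_chars, ANCHOR_LEN)
  gen_index <- list2env(split(seq_along(gen_codes), gen_codes),
                        hash = TRUE, parent = emptyenv())
  cds_codes <- kmer_codes(cds_chars, ANCHOR_LEN)
  cds_keys <- as.character(cds_codes)
  gt_after <- c(gen_chars[-Lg] == "G" & gen_chars[-1] == "T", FALSE, FALSE)
  ag_before <- c(FALSE, FALSE,
                 gen_chars[seq_len(Lg - 2)] == "A" &
                   gen_chars[seq_len(Lg - 2) + 1L] == "G")

  starts_for <- function(ci) {
    if (ci <= length(cds_codes)) {
      hit <- get0(cds_keys[ci], gen_index, inherits = FALSE)
      if (is.null(hit)) integer(0) else hit
    } else {
      # remainder shorter than the anchor: brute-force character match
      w <- Lc - ci + 1L
      pat <- cds_chars[ci:Lc]
      cand <- which(gen_chars == pat[1])
      cand[vapply(cand, function(g) {
        g + w - 1L <= Lg && all(gen_chars[g:(g + w - 1L)] == pat)
      }, logical(1))]
    }
  }

  # failure memo: largest intron budget for which (ci, g-start, mode)
  # is known infeasible
  fail_env <- new.env(parent = emptyenv())

  # DFS with intron budget k.  gt_ag constrains intron boundaries.
  # Returns list of exon interval rows (1-based inclusive) or NULL.
  search <- function(ci, gmin, k, gt_ag) {
    cand <- starts_for(ci)
    cand <- cand[cand >= gmin]
    if (gt_ag && gmin > 1L) cand <- cand[ag_before[cand]]  # intron ends AG
    remaining <- Lc - ci + 1L
    for (g in cand) {
      key <- paste0(ci, ":", g, ":", gt_ag)
      memo <- get0(key, fail_env, inherits = FALSE)
      if (!is.null(memo) && memo >= k) next
      ext <- common_extension(cds_chars, gen_chars, ci, g)
      found <- NULL
      if (ext >= remaining) {
        # can finish here with a single final exon
        return(list(c(g, g + remaining - 1L)))
      }
      if (ext > 0L && k > 0L) {
        # choose an exon end; the following intron starts right after
        e_opts <- seq(ext, 1L)
        if (gt_ag) e_opts <- e_opts[gt_after[g + e_opts]]
        for (e in e_opts) {
          nxt <- search(ci + e, g + e + min_intron, k - 1L, gt_ag)
          if (!is.null(nxt)) {
            found <- c(list(c(g, g + e - 1L)), nxt)
            break
          }
        }
      }
      if (!is.null(found)) return(found)
      assign(key, k, fail_env)
    }
    NULL
  }

  for (k in 0:max_introns) {
    for (gt_ag in c(TRUE, FALSE)) {
      sol <- search(1L, 1L, k, gt_ag)
      if (!is.null(sol)) {
        ex <- do.call(rbind, sol)
        exons <- cbind(start = ex[, 1] - 1L, end = ex[, 2])  # to 0-based half-open
        model <- gene_model(id, exons, gen_s)
        # hard postcondition: exon concatenation reproduces the CDS
        rebuilt <- paste(vapply(seq_len(nrow(exons)), function(i) {
          substr(gen_s, exons[i, 1] + 1L, exons[i, 2])
        }, character(1)), collapse = "")
        stopifnot(identical(rebuilt, cds_s))
        return(model)
      }
    }
  }
  stop("CDS not derivable from genomic sequence for ", id)
}

#' Summary statistics over a collection of gene models
#'
#' @param models List of [gene_model()] objects.
#' @return List with `per_gene` (data frame gene_id, n_introns), `histogram`
#'   (named intron-count tabulation), and `intron_length`
#'   (min/mean/max; `NULL` when no gene has introns).
#' @export
intron_stats <- function(models) {
  if (!length(models)) stop("empty model collection")
  per_gene <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, n_introns = nrow(m$introns),
               stringsAsFactors = FALSE)
  }))
  counts <- table(factor(per_gene$n_introns,
                         levels = 0:max(per_gene$n_introns)))
  lens <- unlist(lapply(models, function(m) {
    if (nrow(m$introns)) m$introns[, 2] - m$introns[, 1] else numeric(0)
  }))
  list(per_gene = per_gene,
       histogram = counts,
       intron_length = if (length(lens)) {
         c(min = min(lens), mean = mean(lens), max = max(lens))
       } else NULL)
}
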