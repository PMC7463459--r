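# Promoter extraction and cis-regulatory element scanning.  Motifs are plain
# IUPAC consensi matched exactly on both strands; no PWM scoring.

#' The packaged default cis-element dictionary
#'
#' PlantCARE-style consensi for the elements most often tallied in plant TF
#' family surveys (G-box, ABRE, the CGTCA/TGACG MeJA pair, ERE, MBS, LTR,
#' ARE, CAT-box).  Elements whose exact consensus is tool-internal (TC-rich
#' repeats, WUN-motif, O2-site) are deliberately left to the user.
#'
#' @param path Optional motif dictionary TSV (columns `name`, `pattern`,
#'   `class`) replacing the packaged one.
#' @return Data frame with columns `name`, `pattern`, `class`.
#' @export
default_motif_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_library.tsv", package = "bhlhscan")
  }
  lib <- read_tsv(path)
  stopifnot(all(c("name", "pattern", "class") %in% names(lib)))
  lib$pattern <- toupper(lib$pattern)
  if (any(nchar(lib$pattern) < 4)) stop("motif patterns must be at least 4 nt")
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", lib$pattern)
  if (any(bad)) stop("non-IUPAC motif pattern(s): ",
                     paste(lib$name[bad], collapse = ", "))
  lib
}

# 0-based start positions where an IUPAC pattern matches the subject.
# Ambiguity codes are expanded in the pattern only; an ambiguous subject
# base (including N) matches nothing, so masked regions never inflate
# counts.  Vectorized sliding comparison: one logical AND per pattern
# column.
iupac_match_starts <- function(subject, pattern) {
  chars <- if (length(subject) > 1L) subject else strsplit(subject, "")[[1]]
  w <- nchar(pattern)
  L <- length(chars)
  if (L < w) return(integer(0))
  sets <- lapply(strsplit(toupper(pattern), "")[[1]], function(cd) {
    strsplit(IUPAC_EXPAND[[cd]], "")[[1]]
  })
  n <- L - w + 1L
  ok <- rep(TRUE, n)
  for (t in seq_len(w)) {
    ok <- ok & chars[t:(n + t - 1L)] %in% sets[[t]]
  }
  which(ok) - 1L
}

is_palindromic <- function(pattern) identical(revcomp(pattern), toupper(pattern))

#' Extract the upstream promoter window of a gene
#'
#' For a `+` strand gene the promoter is `contig[max(0, tss - window) .. tss)`
#' (0-based half-open); for a `-` strand gene it is the reverse complement of
#' `contig[tss + 1 .. tss + 1 + window)`.  Either way the returned sequence
#' reads 5' to 3' on the gene's coding strand.  When fewer than `window` bases
#' are available the record is flagged as truncated.
#'
#' @param contig Named DNA sequence (character).
#' @param tss 0-based transcription start position on the contig.
#' @param strand `"+"` or `"-"`.
#' @param window Window size in nt (default 2000).
#' @param gene_id Id for the promoter record.
#' @return A `promoter_record`: `gene_id`, `sequence`, `truncated_flag`,
#'   `window`.
#' @export
extract_promoter <- function(contig, tss, strand = c("+", "-"),
                             window = 2000L, gene_id = NULL) {
  strand <- match.arg(strand)
  seqc <- toupper(as.character(contig)[1])
  L <- nchar(seqc)
  if (tss < 0 || tss > L) stop("tss outside contig (0..", L, ")")
  if (strand == "+") {
    from <- max(0L, tss - window)
    s <- substr(seqc, from + 1L, tss)        # [from, tss)
  } else {
    from <- tss + 1L
    to <- min(L, tss + 1L + window)
    s <- revcomp(substr(seqc, from + 1L, to))  # [tss+1, tss+1+window)
  }
  structure(list(gene_id = gene_id %||% names(contig) %||% "promoter",
                 sequence = s, truncated_flag = nchar(s) < window,
                 window = window),
            class = "promoter_record")
}

#' Scan a promoter for cis-element occurrences on both strands
#'
#' All (overlapping) positions where each IUPAC pattern matches the forward
#' string are reported on strand `+`; matches of the reverse complement of
#' the pattern are reported on strand `-` at their forward-coordinate start.
#' A palindromic pattern is scanned on the forward strand only, so each site
#' is counted once (strand `+`).
#'
#' @param promoter A `promoter_record` or a bare DNA string.
#' @param library A motif dictionary data frame (see
#'   [default_motif_library()]).
#' @return Data frame of hits: `promoter_id`, `motif`, `position`
#'   (0-based forward start), `strand`.
#' @export
scan_motifs <- function(promoter, library = default_motif_library()) {
  if (!nrow(library)) stop("empty motif library")
  if (inherits(promoter, "promoter_record")) {
    id <- promoter$gene_id
    seqc <- promoter$sequence
  } else {
    id <- names(promoter) %||% "promoter"
    seqc <- toupper(as.character(promoter)[1])
  }
  if (!nzchar(seqc)) stop("empty promoter sequence")
  out <- list()
  for (i in seq_len(nrow(library))) {
    pat <- library$pattern[i]
    fw <- iupac_match_starts(seqc, pat)
    if (length(fw)) {
      out[[length(out) + 1L]] <- data.frame(
        promoter_id = id, motif = library$name[i],
        position = sort(fw), strand = "+", stringsAsFactors = FALSE)
    }
    if (!is_palindromic(pat)) {
      rv <- iupac_match_starts(seqc, revcomp(pat))
      if (length(rv)) {
        out[[length(out) + 1L]] <- data.frame(
          promoter_id = id, motif = library$name[i],
          position = sort(rv), strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(promoter_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

#' Summarize motif hits over a gene cohort
#'
#' @param hits Row-bound [scan_motifs()] output over all promoters.
#' @param genes Character vector of all gene/promoter ids surveyed (including
#'   those without hits).
#' @param library Motif dictionary (rows define the summary rows).
#' @return Data frame: `motif`, `genes_with_hit`, `total_occurrences`.
#' @export
summarize_motifs <- function(hits, genes, library = default_motif_library()) {
  if (!length(genes)) stop("gene list must be non-empty")
  if (nrow(hits) && any(!hits$promoter_id %in% genes)) {
    stop("hit references unknown gene: ",
         paste(setdiff(unique(hits$promoter_id), genes), collapse = ", "))
  }
  do.call(rbind, lapply(library$name, function(m) {
    h <- hits[hits$motif == m, , drop = FALSE]
    data.frame(motif = m,
               genes_with_hit = length(unique(h$promoter_id)),
               total_occurrences = nrow(h),
               stringsAsFactors = FALSE)
  }))
}
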