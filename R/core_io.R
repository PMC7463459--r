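#' @keywords internal
"_PACKAGE"

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_VALID <- c(AA_LETTERS, "X")
DNA_LETTERS <- c("A", "C", "G", "T")
# IUPAC nucleotide ambiguity codes
DNA_VALID <- c(DNA_LETTERS, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Emit a level-prefixed log line to standard error
#'
#' @param level One of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... Passed to [sprintf()] (first element is the format string).
#' @keywords internal
log_msg <- function(level = "INFO", ...) {
  message(sprintf("[%s] %s", level, sprintf(...)))
}

validate_sequences <- function(seqs, alphabet, stop_strip = TRUE) {
  valid <- if (alphabet == "protein") AA_VALID else DNA_VALID
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence record needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs[] <- toupper(seqs)
  if (alphabet == "protein" && stop_strip) {
    has_stop <- grepl("*", seqs, fixed = TRUE)
    if (any(has_stop)) {
      log_msg("WARN", "stripping '*' (stop) from %d protein record(s): %s",
              sum(has_stop), paste(ids[has_stop], collapse = ", "))
      seqs <- gsub("*", "", seqs, fixed = TRUE)
    }
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% valid)
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                   alphabet, chars[bad[1]], ids[i], bad[1]))
    }
  }
  seqs
}

#' Read a FASTA file into a named character vector
#'
#' Records are returned in file order as an upper-case named character vector;
#' line-wrapped sequences are concatenated.  Protein records containing a `*`
#' (stop) have it stripped with a warning.  The record id is the first
#' whitespace-delimited token of the header; the remainder is kept in the
#' `"descriptions"` attribute.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`; characters are checked against the
#'   declared alphabet plus ambiguity codes (`X` for protein, IUPAC for DNA).
#' @return Named character vector with attributes `alphabet` and
#'   `descriptions`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  names(seqs) <- ids
  seqs <- validate_sequences(seqs, alphabet)
  attr(seqs, "alphabet") <- alphabet
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(as.character(seqs))
  desc <- attr(seqs, "descriptions")
  nm <- names(seqs)
  if (!is.null(desc)) {
    extra <- desc[nm]
    nm <- ifelse(!is.na(extra) & nzchar(extra), paste(nm, extra), nm)
  }
  names(set) <- nm
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Internal coordinates are 0-based half-open; the GFF3 written here is
#' 1-based inclusive, with one `gene` feature spanning each model and one
#' `exon` feature per exon (sorted by start), on the model's strand.
#'
#' @param models A list of [gene_model] objects.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  grl <- lapply(models, function(m) {
    stopifnot(inherits(m, "gene_model"))
    ex <- m$exons[order(m$exons[, 1]), , drop = FALSE]
    n <- nrow(ex)
    GenomicRanges::GRanges(
      seqnames = m$gene_id,
      ranges = IRanges::IRanges(
        start = c(ex[1, 1], ex[, 1]) + 1L,        # 0-based -> 1-based
        end   = c(ex[n, 2], ex[, 2])),            # half-open -> inclusive
      strand = m$strand %||% "+",
      type = c("gene", rep("exon", n)),
      ID = c(m$gene_id, paste0(m$gene_id, ".exon", seq_len(n))),
      Parent = c(NA_character_, rep(m$gene_id, n)))
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene exon intervals back from a GFF3 file
#'
#' Returns, per gene, the exon intervals converted back to the package's
#' 0-based half-open convention.
#'
#' @param path A GFF3 file written by [write_gff3()].
#' @return Named list of integer matrices with columns `start`, `end`.
#' @export
read_gff3_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- as.character(unlist(ex$Parent))
  split_idx <- split(seq_along(ex), parent)
  out <- lapply(split_idx, function(i) {
    m <- cbind(start = GenomicRanges::start(ex)[i] - 1L,
               end = GenomicRanges::end(ex)[i])
    m[order(m[, 1]), , drop = FALSE]
  })
  out[unique(parent)]
}

#' Write a data frame as a TSV with optional comment header lines
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param header_lines Character vector of lines written verbatim (each
#'   prefixed `# `) before the column header, e.g. the run seed.
#' @export
write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data.frame (comment lines starting `#` skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a validated run configuration
#'
#' Central plumbing object: thresholds, resource paths, seed and output
#' directory for [run_pipeline()].  All randomized operations take their seed
#' from here; there is no hidden global random state.
#'
#' @param seed Integer seed recorded in every output header.
#' @param out_dir Output directory.
#' @param t_expr,t_low,t_mod FPKM tier thresholds (not expressed below
#'   `t_expr`; low below `t_low`; moderate below `t_mod`; abundant above).
#' @param domain_threshold Domain detection threshold in bits, or `NULL` to
#'   calibrate empirically (see [calibrate_threshold()]).
#' @param basic_cutoff Minimum number of basic residues for DNA binding.
#' @param basic_set Residues counted as basic.
#' @param motif_library Path to a motif dictionary TSV (default: packaged).
#' @param reference_set Path to a clade-labelled reference FASTA (optional).
#' @param stages Character vector of stage names to run.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("bhlhscan_"),
                       t_expr = 2, t_low = 10, t_mod = 50,
                       domain_threshold = NULL,
                       basic_cutoff = 6L, basic_set = c("R", "K", "H"),
                       motif_library = system.file("extdata", "motif_library.tsv",
                                                   package = "bhlhscan"),
                       reference_set = NULL,
                       stages = c("identify", "classify", "conserve",
                                  "promoters", "structure", "tree",
                                  "expression", "qpcr", "network", "report")) {
  thr <- c(t_expr = t_expr, t_low = t_low, t_mod = t_mod,
           basic_cutoff = basic_cutoff,
           domain_threshold = domain_threshold %||% NA_real_)
  if (any(!is.finite(thr[c("t_expr", "t_low", "t_mod", "basic_cutoff")]))) {
    stop("all thresholds must be finite")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 t_expr = t_expr, t_low = t_low, t_mod = t_mod,
                 domain_threshold = domain_threshold,
                 basic_cutoff = as.integer(basic_cutoff),
                 basic_set = basic_set,
                 motif_library = motif_library,
                 reference_set = reference_set,
                 stages = stages),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Reverse complement of a DNA string (IUPAC-aware)
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVBHDNtgcayrswmkvbhdn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
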