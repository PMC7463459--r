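# The bHLH domain is modelled as a fixed 55-column block partitioned into
# basic region (columns 1-17), helix 1 (18-32), loop (33-40) and helix 2
# (41-55).  Scanning is ungapped: gaps occur only where a window runs off the
# protein terminus.

DOMAIN_LEN <- 55L
REGION_BOUNDS <- list(basic = 1:17, helix1 = 18:32, loop = 33:40, helix2 = 41:55)

#' Build a position-specific scoring matrix from a gapless 55-column alignment
#'
#' Column weights are log-odds in bits:
#' `log2((count + pseudocount * background) / (n + pseudocount) / background)`.
#' The consensus is the per-column majority residue with alphabetical
#' tie-break.
#'
#' @param seed_alignment Character vector of aligned 55-residue sequences
#'   (no gaps), or a path handled by [read_fasta()].
#' @param pseudocount Positive smoothing constant.
#' @param background Named numeric of background amino-acid frequencies
#'   (default uniform 1/20).
#' @return A `domain_profile` with elements `weights` (20 x 55 matrix, bits),
#'   `probs`, `consensus`, `background`, `pseudocount`, `region_bounds`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = NULL) {
  if (length(seed_alignment) == 1L && file.exists(seed_alignment)) {
    seed_alignment <- read_fasta(seed_alignment, "protein")
  }
  rows <- toupper(as.character(seed_alignment))
  if (!length(rows)) stop("seed alignment needs at least one row")
  if (any(nchar(rows) != DOMAIN_LEN)) {
    stop("ragged alignment: all rows must have exactly ", DOMAIN_LEN, " columns")
  }
  m <- do.call(rbind, strsplit(rows, ""))
  if (any(!m %in% AA_LETTERS)) {
    stop("non-amino-acid characters in seed alignment: ",
         paste(unique(m[!m %in% AA_LETTERS]), collapse = ", "))
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_LETTERS)
  }
  background <- background[AA_LETTERS]
  n <- nrow(m)
  counts <- apply(m, 2, function(col) {
    tabulate(factor(col, levels = AA_LETTERS), nbins = 20L)
  })
  rownames(counts) <- AA_LETTERS
  probs <- sweep(counts + pseudocount * background, 2,
                 n + pseudocount, "/")
  weights <- log2(sweep(probs, 1, background, "/"))
  consensus <- apply(counts, 2, function(cnt) {
    AA_LETTERS[which.max(cnt)]  # which.max: first index wins; rows alphabetical
  })
  structure(list(weights = weights, probs = probs,
                 consensus = paste(consensus, collapse = ""),
                 background = background, pseudocount = pseudocount,
                 n_seed = n, region_bounds = REGION_BOUNDS),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("bHLH domain profile: %d columns, %d seed sequence(s), pseudocount %g\n",
              ncol(x$weights), x$n_seed, x$pseudocount))
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}

# Best-window scores of one protein against the profile; terminal windows are
# padded with '-' which scores each column's minimum weight.
window_scores <- function(chars, profile) {
  L <- length(chars)
  W <- profile$weights
  gap_min <- apply(W, 2, min)
  idx <- match(chars, AA_LETTERS)  # X / unknown -> NA
  scores <- numeric(L)
  for (i in seq_len(DOMAIN_LEN)) {
    col <- W[, i][idx]
    col[is.na(col)] <- gap_min[i]          # ambiguity scores like a gap
    full <- c(col, rep(gap_min[i], DOMAIN_LEN))
    scores <- scores + full[seq_len(L) + (i - 1L)]
  }
  scores
}

#' Scan a protein for its best-scoring bHLH domain window
#'
#' Every 55-residue window (0-based starts `0 .. L-1`; windows running past
#' the C-terminus are padded with `-`, and a gap column scores that column's
#' minimum weight) is scored against the profile; the best window is returned
#' if it reaches `threshold`, with ties broken by leftmost start.
#'
#' @param protein A single named sequence (character) or an element of a
#'   [read_fasta()] collection.
#' @param profile A [build_profile()] result.
#' @param threshold Detection threshold in bits (see [calibrate_threshold()]).
#' @param id Protein id (defaults to `names(protein)`).
#' @return A `domain_hit` (`protein_id`, `start`, `aligned55`, `score`,
#'   `regions`) or `NULL` when no window reaches the threshold.
#' @export
scan_domain <- function(protein, profile, threshold, id = NULL) {
  id <- id %||% names(protein) %||% "query"
  seqc <- toupper(as.character(protein)[1])
  chars <- strsplit(seqc, "")[[1]]
  if (length(chars) < 20L) stop("protein too short to scan (< 20 residues)")
  scores <- unname(window_scores(chars, profile))
  best <- which.max(scores)  # leftmost maximum
  if (scores[best] < threshold) return(NULL)
  start0 <- best - 1L
  window <- chars[best:min(length(chars), start0 + DOMAIN_LEN)]
  aligned55 <- paste(c(window, rep("-", DOMAIN_LEN - length(window))),
                     collapse = "")
  hit <- structure(list(protein_id = id, start = start0,
                        aligned55 = aligned55, score = scores[best]),
                   class = "domain_hit")
  hit$regions <- partition_regions(hit)
  hit
}

#' @export
print.domain_hit <- function(x, ...) {
  cat(sprintf("domain hit in %s: start %d (0-based), score %.2f bits\n",
              x$protein_id, x$start, x$score))
  cat(" ", x$aligned55, "\n")
  invisible(x)
}

#' Calibrate the domain detection threshold on random proteins
#'
#' The threshold is the `quantile` (default 99.9th percentile) of best-window
#' scores over i.i.d. random proteins drawn from the profile background.
#'
#' @param profile A [build_profile()] result.
#' @param n Number of random proteins.
#' @param length Length of each random protein.
#' @param probs Quantile to return.
#' @param seed Integer seed.
#' @return Threshold in bits.
#' @export
calibrate_threshold <- function(profile, n = 1000L, length = 500L,
                                probs = 0.999, seed = 1L) {
  rng <- new_rng(seed)
  best <- vapply(seq_len(n), function(i) {
    chars <- rng$sample(AA_LETTERS, length, replace = TRUE,
                        prob = profile$background)
    max(window_scores(chars, profile))
  }, numeric(1))
  unname(stats::quantile(best, probs))
}

#' Partition a 55-column domain into basic region, helices and loop
#'
#' Columns 1-17 form the basic region, 18-32 helix 1, 33-40 the loop and
#' 41-55 helix 2 (1-based, inclusive); their concatenation reproduces the
#' aligned window.
#'
#' @param hit A `domain_hit`, or a bare 55-character string.
#' @return Named list of region strings.
#' @export
partition_regions <- function(hit) {
  s <- if (inherits(hit, "domain_hit")) hit$aligned55 else as.character(hit)
  if (nchar(s) != DOMAIN_LEN) stop("aligned domain must have 55 columns")
  lapply(REGION_BOUNDS, function(ix) substr(s, min(ix), max(ix)))
}

#' Per-column conservation of a set of aligned domains
#'
#' Identity is the fraction of sequences carrying the column's top residue,
#' with gaps counted in the denominator; a column is flagged as consensus
#' when identity exceeds 0.5.  Ties are broken alphabetically.
#'
#' @param domains Character vector of aligned 55-character strings
#'   (may contain `-`).
#' @return Data frame with `column`, `region`, `top_residue`, `identity`,
#'   `consensus_flag`.
#' @export
conservation <- function(domains) {
  domains <- as.character(domains)
  if (!length(domains)) stop("need at least one domain")
  if (any(nchar(domains) != DOMAIN_LEN)) stop("ragged input: domains must be 55 columns")
  m <- do.call(rbind, strsplit(toupper(domains), ""))
  n <- nrow(m)
  region_of <- character(DOMAIN_LEN)
  for (r in names(REGION_BOUNDS)) region_of[REGION_BOUNDS[[r]]] <- r
  rows <- lapply(seq_len(DOMAIN_LEN), function(j) {
    col <- m[, j]
    cnt <- table(factor(col[col != "-"], levels = AA_LETTERS))
    top <- AA_LETTERS[which.max(cnt)]       # alphabetical tie-break
    ident <- as.integer(cnt[top]) / n       # gaps stay in the denominator
    data.frame(column = j, region = region_of[j], top_residue = top,
               identity = ident, consensus_flag = ident > 0.5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify the DNA-binding type of a bHLH domain from its basic region
#'
#' Decision tree on the 17-column basic region (positions 1-based within the
#' region):
#' 1. fewer than `basic_cutoff` residues from `basic_set`: non-DNA-binding;
#' 2. otherwise, Glu at position 13 and Arg at position 16: an E-box binder,
#'    refined to a G-box binder iff position 9 is His or Lys and position 17
#'    is Arg, else an E-box (non-G-box) binder;
#' 3. otherwise a non-E-box binder.
#'
#' A gap (`-`) at a rule position fails that position's test.  Note the two
#' published rules are applied literally: the E-box test reads position 16,
#' the G-box refinement position 17.
#'
#' @param hit A `domain_hit` or a 55-character aligned domain string.
#' @param basic_set Residues counted as basic (default Arg/Lys/His).
#' @param basic_cutoff Minimum basic-residue count for DNA binding (default 6).
#' @return A `binding_call` list: `category` (one of `non_DNA_binding`,
#'   `G_box`, `E_box_non_G_box`, `non_E_box`), `basic_count`,
#'   `rule_residues` (characters at positions 9, 13, 16, 17).
#' @export
classify_binding <- function(hit, basic_set = c("R", "K", "H"),
                             basic_cutoff = 6L) {
  basic <- if (inherits(hit, "domain_hit")) {
    hit$regions$basic
  } else {
    partition_regions(hit)$basic
  }
  chars <- strsplit(basic, "")[[1]]
  stopifnot(length(chars) == 17L)
  basic_count <- sum(chars %in% basic_set)
  rule <- chars[c(9L, 13L, 16L, 17L)]
  names(rule) <- c("p9", "p13", "p16", "p17")
  category <- if (basic_count < basic_cutoff) {
    "non_DNA_binding"
  } else if (rule[["p13"]] == "E" && rule[["p16"]] == "R") {
    if (rule[["p9"]] %in% c("H", "K") && rule[["p17"]] == "R") {
      "G_box"
    } else {
      "E_box_non_G_box"
    }
  } else {
    "non_E_box"
  }
  structure(list(category = category, basic_count = basic_count,
                 rule_residues = rule),
            class = "binding_call")
}

#' @export
print.binding_call <- function(x, ...) {
  cat(sprintf("binding call: %s (basic count %d; 9/13/16/17 = %s)\n",
              x$category, x$basic_count, paste(x$rule_residues, collapse = "/")))
  invisible(x)
}

# Expasy ProtParam average residue masses (Da)
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.0153

# Expasy pKa constants used by the bisection pI solver
PKA <- list(pos = c(Nterm = 7.5, H = 5.98, K = 10.0, R = 12.0),
            neg = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0))

# Henderson-Hasselbalch net charge of a peptide at a given pH
peptide_charge <- function(counts, ph) {
  pos <- c(Nterm = 1, counts[c("H", "K", "R")])
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  sum(pos / (1 + 10^(ph - PKA$pos))) - sum(neg / (1 + 10^(PKA$neg - ph)))
}

#' Molecular weight and isoelectric point of a protein
#'
#' MW is the sum of average residue masses plus one water (18.02 Da); `X`
#' contributes the mean residue mass.  pI is solved by bisection on the
#' Henderson-Hasselbalch net charge (N-/C-terminus plus D, E, C, Y, H, K, R,
#' Expasy pKa values) to |charge| < 1e-4 on pH in (0, 14).
#'
#' @param protein A single protein sequence (character).
#' @param id Optional id.
#' @return A `protein_properties` list: `length`, `mw` (Da), `pi`.
#' @export
protein_properties <- function(protein, id = NULL) {
  seqc <- toupper(as.character(protein)[1])
  chars <- strsplit(seqc, "")[[1]]
  if (!length(chars)) stop("empty sequence")
  bad <- setdiff(unique(chars), c(names(AA_MASS), "X"))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  mw <- sum(AA_MASS[chars], na.rm = TRUE) +
    sum(chars == "X") * mean(AA_MASS) + WATER_MASS
  counts <- vapply(c("H", "K", "R", "D", "E", "C", "Y"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- peptide_charge(counts, mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-10) break
    if (q > 0) lo <- mid else hi <- mid
  }
  structure(list(id = id %||% names(protein) %||% NA_character_,
                 length = length(chars), mw = mw, pi = mid),
            class = "protein_properties")
}

#' @export
print.protein_properties <- function(x, ...) {
  cat(sprintf("%s: %d aa, MW %.2f Da (%.2f kDa), pI %.2f\n",
              x$id, x$length, x$mw, x$mw / 1000, x$pi))
  invisible(x)
}
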