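# Seeded generators for every input the pipeline consumes.  Each generator
# returns both the artifact and a `truth` record of what was planted, so
# recovery is testable.  Identical seed + configuration gives byte-identical
# output; the caller's global random state is never touched.

DEFAULT_TISSUES <- c("column", "flower_buds", "lip", "sepal",
                     "leaf", "stem", "white_root", "green_root_tip")

TIER_BOUNDS <- list(not_expressed = c(0, 2), low = c(2, 10),
                    moderate = c(10, 50), abundant = c(50, 300))

BINDING_CATEGORIES <- c("non_DNA_binding", "G_box", "E_box_non_G_box", "non_E_box")

# Deterministic basic-region templates realizing each DNA-binding category.
# Rule positions (9, 13, 16, 17) and the basic-residue count are fixed by
# construction; these columns are exempt from mutation so the planted
# category is exact.
BASIC_TEMPLATES <- c(
  G_box           = "ADRRKAANHRERERRRR",  # p9 H, p13 E, p16 R, p17 R; 10 basics
  E_box_non_G_box = "ADRRKAANSRERERRRR",  # p9 S breaks the G-box refinement
  non_E_box       = "ADRRKAANHRERARRRR",  # p13 A breaks the E-box rule
  non_DNA_binding = "ADSNKAANSANAEASSA")  # 1 basic residue (< 6)

mutate_chars <- function(chars, rate, positions, rng) {
  if (rate <= 0 || !length(positions)) return(chars)
  hit <- positions[rng$runif(length(positions)) < rate]
  for (p in hit) {
    chars[p] <- rng$sample(setdiff(AA_LETTERS, chars[p]), 1L)
  }
  chars
}

#' Generate a synthetic bHLH protein family with planted domains
#'
#' Each protein carries exactly one planted 55-residue domain: a clade
#' ancestor (the packaged profile consensus diverged per clade) further
#' mutated per protein at `mutation_rate`, flanked by random non-domain
#' residues.  Mutations touch only columns 18-55, so the basic region -- and
#' with it the planted DNA-binding category -- is exact by construction, and
#' inter-clade divergence exceeds intra-clade divergence.
#'
#' @param n_proteins Family size.
#' @param clade_spec Named integer vector, clade label -> size (sizes must sum
#'   to `n_proteins`; each at least 2).
#' @param mutation_rate Per-site substitution rate within a clade (0 to 0.3).
#' @param seed Integer seed.
#' @param categories DNA-binding category per protein (recycled if length 1).
#' @param clade_divergence Per-site rate separating clade ancestors from the
#'   family consensus.
#' @param flank_range Min/max length of each random flank.
#' @param profile A [build_profile()] result supplying the consensus
#'   (default: the packaged synthetic seed alignment).
#' @return List with `proteins` (named character vector) and `truth`
#'   (`seed`, `members` data frame: id, clade, offset, domain55, basic
#'   region, category; `ancestors`: named vector of clade ancestor 55-mers).
#' @export
make_family <- function(n_proteins, clade_spec, mutation_rate = 0.05,
                        seed = 1L, categories = "G_box",
                        clade_divergence = 0.25, flank_range = c(10L, 80L),
                        profile = NULL) {
  if (mutation_rate < 0 || mutation_rate > 0.3) {
    stop("mutation_rate must be within [0, 0.3]")
  }
  if (sum(clade_spec) != n_proteins) {
    stop("clade sizes must sum to n_proteins")
  }
  if (any(clade_spec < 2)) stop("clade size < 2 is not allowed")
  if (is.null(names(clade_spec))) {
    names(clade_spec) <- paste0("clade", seq_along(clade_spec))
  }
  categories <- rep_len(categories, n_proteins)
  if (any(!categories %in% BINDING_CATEGORIES)) {
    stop("unknown binding category: ",
         paste(setdiff(categories, BINDING_CATEGORIES), collapse = ", "))
  }
  if (is.null(profile)) profile <- packaged_profile()
  consensus <- strsplit(profile$consensus, "")[[1]]
  mut_cols <- 18:55  # keep the basic region template-exact
  rng <- new_rng(seed)

  ancestors <- vapply(names(clade_spec), function(cl) {
    paste(mutate_chars(consensus, clade_divergence, mut_cols, rng),
          collapse = "")
  }, character(1))

  ids <- sprintf("synbHLH%02d", seq_len(n_proteins))
  clade_of <- rep(names(clade_spec), clade_spec)
  members <- vector("list", n_proteins)
  proteins <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    anc <- strsplit(ancestors[[clade_of[i]]], "")[[1]]
    dom <- mutate_chars(anc, mutation_rate, mut_cols, rng)
    dom[1:17] <- strsplit(BASIC_TEMPLATES[[categories[i]]], "")[[1]]
    dom55 <- paste(dom, collapse = "")
    nf <- rng$sample(seq(flank_range[1], flank_range[2]), 1L)
    cf <- rng$sample(seq(flank_range[1], flank_range[2]), 1L)
    flank_n <- paste(rng$sample(AA_LETTERS, nf, replace = TRUE), collapse = "")
    flank_c <- paste(rng$sample(AA_LETTERS, cf, replace = TRUE), collapse = "")
    proteins[i] <- paste0(flank_n, dom55, flank_c)
    members[[i]] <- data.frame(id = ids[i], clade = clade_of[i],
                               offset = nf, domain55 = dom55,
                               basic_region = substr(dom55, 1, 17),
                               category = categories[i],
                               stringsAsFactors = FALSE)
  }
  names(proteins) <- ids
  attr(proteins, "alphabet") <- "protein"
  list(proteins = proteins,
       truth = list(seed = as.integer(seed),
                    members = do.call(rbind, members),
                    ancestors = ancestors))
}

#' The family specification used by the packaged 98-member fixture
#'
#' Eighteen clades summing to 98 members, with per-member DNA-binding
#' categories in the proportions 61 G-box : 4 E-box(non-G) : 11 non-E-box :
#' 22 non-binder.
#'
#' @return List with `clade_spec` (named sizes) and `categories` (length 98).
#' @export
default_family_spec <- function() {
  sizes <- c(9, 3, 5, 4, 3, 9, 3, 4, 3, 8, 3, 4, 4, 13, 13, 2, 6, 2)
  names(sizes) <- paste0("clade", 1:18)
  categories <- rep(c("G_box", "E_box_non_G_box", "non_E_box",
                      "non_DNA_binding"), times = c(61, 4, 11, 22))
  list(clade_spec = sizes, categories = categories)
}

# Profile built from the packaged synthetic seed alignment (memoized).
packaged_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "bhlh_seed_alignment_synthetic.fasta",
                          package = "bhlhscan")
      cache <<- build_profile(path, pseudocount = 1)
    }
    cache
  }
})

random_dna <- function(n, gc, rng) {
  rng$sample(DNA_LETTERS, n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic gene (genomic + CDS pair) with GT..AG introns
#'
#' The genomic sequence interleaves random exons and introns; every intron
#' begins `GT` and ends `AG`; the CDS is the exon concatenation.
#'
#' @param n_introns Number of introns (>= 0).
#' @param exon_len_range,intron_len_range Length ranges (intron minimum
#'   at least 20 nt).
#' @param seed Integer seed.
#' @param gene_id Id shared by the genomic and CDS records.
#' @param gc Background GC fraction.
#' @return List with `genomic`, `cds` (named character vectors) and `truth`
#'   (`exons`, `introns`: 0-based half-open interval matrices on the genomic
#'   sequence).
#' @export
make_gene <- function(n_introns, exon_len_range = c(30L, 300L),
                      intron_len_range = c(44L, 2000L), seed = 1L,
                      gene_id = "syngene1", gc = 0.44) {
  stopifnot(n_introns >= 0)
  if (exon_len_range[1] > exon_len_range[2] ||
      intron_len_range[1] > intron_len_range[2]) {
    stop("length range is inverted")
  }
  if (intron_len_range[1] < 20) stop("minimum intron length must be >= 20")
  rng <- new_rng(seed)
  n_exons <- n_introns + 1L
  exon_len <- rng$sample(seq(exon_len_range[1], exon_len_range[2]),
                         n_exons, replace = TRUE)
  pieces <- character(0)
  exons <- matrix(0L, n_exons, 2, dimnames = list(NULL, c("start", "end")))
  introns <- if (n_introns > 0) {
    matrix(0L, n_introns, 2, dimnames = list(NULL, c("start", "end")))
  } else {
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  }
  pos <- 0L
  for (i in seq_len(n_exons)) {
    ex <- paste(random_dna(exon_len[i], gc, rng), collapse = "")
    pieces <- c(pieces, ex)
    exons[i, ] <- c(pos, pos + exon_len[i])
    pos <- pos + exon_len[i]
    if (i <= n_introns) {
      ilen <- rng$sample(seq(intron_len_range[1], intron_len_range[2]), 1L)
      intr <- paste0("GT", paste(random_dna(ilen - 4L, gc, rng), collapse = ""), "AG")
      pieces <- c(pieces, intr)
      introns[i, ] <- c(pos, pos + ilen)
      pos <- pos + ilen
    }
  }
  genomic <- stats::setNames(paste(pieces, collapse = ""), gene_id)
  cds <- stats::setNames(paste(vapply(seq_len(n_exons), function(i) {
    substr(genomic, exons[i, 1] + 1L, exons[i, 2])
  }, character(1)), collapse = ""), gene_id)
  attr(genomic, "alphabet") <- "dna"
  attr(cds, "alphabet") <- "dna"
  list(genomic = genomic, cds = cds,
       truth = list(seed = as.integer(seed), exons = exons, introns = introns))
}

# Concrete instance of an IUPAC pattern (each ambiguity code resolved at random)
instantiate_iupac <- function(pattern, rng) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(codes, function(cd) {
    opts <- strsplit(IUPAC_EXPAND[[cd]], "")[[1]]
    if (length(opts) == 1L) opts else rng$sample(opts, 1L)
  }, character(1)), collapse = "")
}

IUPAC_EXPAND <- list(A = "A", C = "C", G = "G", T = "T",
                     R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT",
                     M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                     N = "ACGT")

#' Generate synthetic promoters with planted cis-element instances
#'
#' Backgrounds are i.i.d. at the stated GC; planted instances (concrete
#' realizations of each motif's IUPAC pattern) are placed at non-overlapping
#' uniform positions on randomly chosen strands.  With
#' `background = "clean"` (the default), background positions are
#' re-randomized until scanning the library yields no match outside a planted
#' span, so planted counts are recoverable exactly; with `"iid"` chance
#' matches may remain (the truth still lists only planted instances).
#'
#' @param n Number of promoters.
#' @param length Promoter length in nt (default 2000, the upstream window).
#' @param plant Named integer vector, motif name -> copies per promoter.
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @param library Motif dictionary (see [default_motif_library()]); must
#'   contain every planted motif.
#' @param background `"clean"` or `"iid"`.
#' @return List with `promoters` (named character vector) and `truth`
#'   (data frame: promoter_id, motif, position, strand).
#' @export
make_promoters <- function(n, length = 2000L, plant = c(),
                           gc = 0.44, seed = 1L,
                           library = default_motif_library(),
                           background = c("clean", "iid")) {
  background <- match.arg(background)
  rng <- new_rng(seed)
  plant <- plant[plant > 0]
  if (length(plant)) {
    unknown <- setdiff(names(plant), library$name)
    if (length(unknown)) stop("motifs not in library: ", paste(unknown, collapse = ", "))
  }
  pat_of <- stats::setNames(library$pattern, library$name)
  ids <- sprintf("synprom%03d", seq_len(n))
  truth <- list()
  promoters <- character(n)
  for (p in seq_len(n)) {
    chars <- random_dna(length, gc, rng)
    spans <- matrix(integer(0), 0, 2)   # 0-based half-open planted spans
    rows <- list()
    for (m in names(plant)) {
      for (k in seq_len(plant[[m]])) {
        inst <- instantiate_iupac(pat_of[[m]], rng)
        w <- nchar(inst)
        strand <- rng$sample(c("+", "-"), 1L)
        placed <- if (strand == "-") revcomp(inst) else inst
        ok <- FALSE
        for (try in 1:1000) {
          start <- rng$sample(seq(0L, length - w), 1L)  # 0-based
          if (!nrow(spans) ||
              all(start + w <= spans[, 1] | start >= spans[, 2])) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("infeasible packing: cannot place motif ", m)
        chars[(start + 1):(start + w)] <- strsplit(placed, "")[[1]]
        spans <- rbind(spans, c(start, start + w))
        rows[[length(rows) + 1L]] <-
          data.frame(promoter_id = ids[p], motif = m, position = start,
                     strand = strand, stringsAsFactors = FALSE)
      }
    }
    if (background == "clean") {
      chars <- clean_background(chars, spans, library, gc, rng)
    }
    promoters[p] <- paste(chars, collapse = "")
    if (length(rows)) truth[[p]] <- do.call(rbind, rows)
  }
  names(promoters) <- ids
  attr(promoters, "alphabet") <- "dna"
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(promoter_id = character(0), motif = character(0),
               position = integer(0), strand = character(0))
  list(promoters = promoters,
       truth = list(seed = as.integer(seed), planted = truth_df))
}

# Re-randomize background positions until no library match lies outside a
# planted span (bounded iteration; chance matches are rare, so this
# converges almost immediately).
clean_background <- function(chars, spans, library, gc, rng) {
  in_span <- function(s, e) {
    nrow(spans) && any(s >= spans[, 1] & e <= spans[, 2])
  }
  for (iter in 1:100) {
    seqc <- paste(chars, collapse = "")
    offending <- integer(0)
    for (i in seq_len(nrow(library))) {
      pat <- library$pattern[i]
      w <- nchar(pat)
      starts <- c(iupac_match_starts(seqc, pat),
                  iupac_match_starts(seqc, revcomp(pat)))
      for (s in starts) {
        if (!in_span(s, s + w)) {
          pos <- setdiff(seq(s + 1L, s + w), which_span_positions(spans))
          offending <- union(offending, pos)
        }
      }
    }
    if (!length(offending)) return(chars)
    chars[offending] <- random_dna(length(offending), gc, rng)
  }
  stop("could not clean promoter background of chance motif matches")
}

which_span_positions <- function(spans) {
  if (!nrow(spans)) return(integer(0))
  unlist(lapply(seq_len(nrow(spans)), function(i) {
    seq(spans[i, 1] + 1L, spans[i, 2])
  }))
}

#' Generate a tissue-structured synthetic FPKM matrix
#'
#' Values are drawn uniformly within the tier bin requested for each
#' gene/tissue (not expressed `[0,2)`, low `[2,10)`, moderate `[10,50)`,
#' abundant `[50,300)`), then perturbed multiplicatively by
#' `1 + N(0, noise_sd)` and clipped at 0.
#'
#' @param n_genes Number of genes.
#' @param tissues Tissue names (default: the eight surveyed tissues).
#' @param group_spec List of groups, each
#'   `list(name=, size=, tiers = named character vector tissue -> tier)`;
#'   sizes must sum to `n_genes` (default: [default_group_spec()] scaled).
#' @param noise_sd Multiplicative noise SD.
#' @param seed Integer seed.
#' @return List with `fpkm` (genes x tissues matrix) and `truth` (`tiers`
#'   matrix, `groups` named vector).
#' @export
make_expression <- function(n_genes, tissues = DEFAULT_TISSUES,
                            group_spec = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (is.null(group_spec)) group_spec <- default_group_spec(n_genes, tissues)
  sizes <- vapply(group_spec, `[[`, numeric(1), "size")
  if (sum(sizes) != n_genes) stop("group sizes must sum to n_genes")
  rng <- new_rng(seed)
  ids <- sprintf("syngene%03d", seq_len(n_genes))
  fpkm <- matrix(0, n_genes, length(tissues), dimnames = list(ids, tissues))
  tiers <- matrix("", n_genes, length(tissues), dimnames = list(ids, tissues))
  groups <- character(n_genes)
  g <- 1L
  for (grp in group_spec) {
    if (any(!grp$tiers %in% names(TIER_BOUNDS))) {
      stop("unknown tier name in group '", grp$name, "'")
    }
    for (k in seq_len(grp$size)) {
      for (t in tissues) {
        tier <- grp$tiers[[t]]
        b <- TIER_BOUNDS[[tier]]
        v <- rng$runif(1, b[1], b[2])
        v <- max(0, v * (1 + rng$rnorm(1, 0, noise_sd)))
        fpkm[g, t] <- v
        tiers[g, t] <- tier
      }
      groups[g] <- grp$name
      g <- g + 1L
    }
  }
  names(groups) <- ids
  list(fpkm = fpkm, truth = list(seed = as.integer(seed),
                                 tiers = tiers, groups = groups))
}

#' Default five-group expression specification
#'
#' Emulates the tissue-restricted patterns of a plant TF family survey:
#' flower-specific, sporadic-low, root-specific, broadly moderate and
#' ubiquitously abundant groups.
#'
#' @param n_genes Total genes to split over the five groups.
#' @param tissues Tissue names (the eight defaults).
#' @return A `group_spec` list for [make_expression()].
#' @export
default_group_spec <- function(n_genes = 75L, tissues = DEFAULT_TISSUES) {
  stopifnot(identical(tissues, DEFAULT_TISSUES), n_genes >= 5)
  base <- c(I = 6, II = 13, III = 4, IV = 40, V = 12)  # sums to 75
  sizes <- pmax(round(base * n_genes / 75), 1)
  sizes[length(sizes)] <- n_genes - sum(sizes[-length(sizes)])
  tiers <- list(
    I   = c(column = "low", flower_buds = "abundant", lip = "low",
            sepal = "low", leaf = "not_expressed", stem = "not_expressed",
            white_root = "not_expressed", green_root_tip = "not_expressed"),
    II  = c(column = "not_expressed", flower_buds = "not_expressed",
            lip = "not_expressed", sepal = "not_expressed",
            leaf = "not_expressed", stem = "not_expressed",
            white_root = "low", green_root_tip = "not_expressed"),
    III = c(column = "not_expressed", flower_buds = "not_expressed",
            lip = "not_expressed", sepal = "not_expressed",
            leaf = "not_expressed", stem = "not_expressed",
            white_root = "abundant", green_root_tip = "moderate"),
    IV  = c(column = "moderate", flower_buds = "moderate", lip = "moderate",
            sepal = "moderate", leaf = "low", stem = "moderate",
            white_root = "moderate", green_root_tip = "moderate"),
    V   = c(column = "abundant", flower_buds = "abundant", lip = "abundant",
            sepal = "abundant", leaf = "abundant", stem = "abundant",
            white_root = "abundant", green_root_tip = "abundant"))
  lapply(names(sizes), function(nm) {
    list(name = nm, size = unname(sizes[[nm]]), tiers = tiers[[nm]])
  })
}

#' Generate a synthetic qPCR CT table with planted log2 fold changes
#'
#' Per technical replicate, `CT = baseline_ct - log2fc + N(0, ct_noise_sd)`;
#' the internal reference gene is generated with log2 fold change 0
#' everywhere, so the delta-delta-CT analysis recovers the planted values.
#'
#' @param genes Target gene ids (reference gene added automatically).
#' @param log2fc_spec Data frame `gene, condition, timepoint, log2fc` for
#'   non-baseline combinations (missing combinations default to 0).
#' @param ct_noise_sd Gaussian CT noise SD (cycles).
#' @param n_bio,n_tech Biological / technical replicates (`n_bio >= 2`).
#' @param seed Integer seed.
#' @param reference_gene Internal reference gene id.
#' @param conditions,timepoints Design levels; `conditions[1]` x
#'   `timepoints[1]` is the baseline.
#' @param baseline_ct,reference_ct Noise-free CT of targets at baseline and
#'   of the reference gene.
#' @return List with `table` (long data frame: gene, condition, timepoint,
#'   bio_rep, tech_rep, ct) and `truth` (planted log2fc per
#'   gene/condition/timepoint).
#' @export
make_qpcr <- function(genes, log2fc_spec = NULL, ct_noise_sd = 0,
                      n_bio = 3L, n_tech = 3L, seed = 1L,
                      reference_gene = "DoActin",
                      conditions = c("control", "MeJA", "ABA"),
                      timepoints = c("0h", "3h", "6h"),
                      baseline_ct = 24, reference_ct = 20) {
  if (n_bio < 2) stop("n_bio must be at least 2 (t-test impossible otherwise)")
  if (!is.null(log2fc_spec) && reference_gene %in% log2fc_spec$gene &&
      any(log2fc_spec$log2fc[log2fc_spec$gene == reference_gene] != 0)) {
    stop("the reference gene must have log2 fold change 0")
  }
  rng <- new_rng(seed)
  all_genes <- c(reference_gene, setdiff(genes, reference_gene))
  design <- expand.grid(gene = all_genes, condition = conditions,
                        timepoint = timepoints, stringsAsFactors = FALSE)
  design$log2fc <- 0
  lookup_fc <- function(g, cond, tp) {
    if (g == reference_gene) return(0)
    if (cond == conditions[1] && tp == timepoints[1]) return(0)
    if (is.null(log2fc_spec)) return(0)
    hit <- log2fc_spec$gene == g & log2fc_spec$condition == cond &
      log2fc_spec$timepoint == tp
    if (any(hit)) log2fc_spec$log2fc[hit][1] else 0
  }
  rows <- list()
  for (i in seq_len(nrow(design))) {
    g <- design$gene[i]; cond <- design$condition[i]; tp <- design$timepoint[i]
    fc <- lookup_fc(g, cond, tp)
    base <- if (g == reference_gene) reference_ct else baseline_ct
    for (b in seq_len(n_bio)) {
      ct <- base - fc + rng$rnorm(n_tech, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, condition = cond, timepoint = tp,
                   bio_rep = b, tech_rep = seq_len(n_tech), ct = ct,
                   stringsAsFactors = FALSE)
    }
    design$log2fc[i] <- fc
  }
  list(table = do.call(rbind, rows),
       truth = list(seed = as.integer(seed), log2fc = design))
}
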