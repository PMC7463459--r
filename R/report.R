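# Family-level summary tables and the end-to-end pipeline driver.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize DNA-binding calls into the family binding table
#'
#' Counts per category plus the derived rows E-box (= G-box + non-G-box
#' E-box binders) and DNA-binding total (= E-box + non-E-box); percentages
#' are count/total, rounded half-up to two decimals.
#'
#' @param calls List of `binding_call` objects, or a character vector of
#'   category names.
#' @return Data frame: `type`, `count`, `percent`.
#' @export
summarize_binding <- function(calls) {
  cats <- if (is.character(calls)) calls else
    vapply(calls, function(x) x$category, character(1))
  if (!length(cats)) stop("no binding calls to summarize")
  stopifnot(all(cats %in% BINDING_CATEGORIES))
  n <- length(cats)
  cnt <- function(x) sum(cats %in% x)
  counts <- c(
    E_box = cnt(c("G_box", "E_box_non_G_box")),
    G_box = cnt("G_box"),
    non_G_box = cnt("E_box_non_G_box"),
    non_E_box = cnt("non_E_box"),
    DNA_binding = cnt(c("G_box", "E_box_non_G_box", "non_E_box")),
    non_DNA_binding = cnt("non_DNA_binding"))
  data.frame(type = names(counts), count = unname(counts),
             percent = round_half_up(100 * unname(counts) / n),
             stringsAsFactors = FALSE)
}

#' Parse a family member table (gene name, id, accession, clade)
#'
#' Reads the packaged family roster by default and checks the basic
#' bookkeeping invariants (unique names, integer clade labels).
#'
#' @param path Member table TSV with columns `gene_name`, `gene_id`,
#'   `accession`, `clade`.
#' @return The table as a data.frame.
#' @export
read_member_table <- function(path = system.file("extdata",
                                                 "family_members.tsv",
                                                 package = "bhlhscan")) {
  tab <- read_tsv(path)
  stopifnot(all(c("gene_name", "gene_id", "accession", "clade") %in% names(tab)))
  if (anyDuplicated(tab$gene_name)) stop("duplicate gene names in member table")
  tab
}

#' Run the full family-characterization pipeline on synthetic inputs
#'
#' Generates the synthetic study set from the configured seed, runs the
#' enabled stages (identify, classify, conserve, promoters, structure, tree,
#' expression, qpcr, network, report) and writes one TSV per stage to the
#' output directory.  Every output carries `# seed=` and `# config_md5=`
#' header lines; a rerun with the same configuration is byte-identical.
#'
#' @param config A [run_config()].
#' @param n_genes_structure Number of synthetic genes for the structure stage.
#' @param n_promoters Number of synthetic promoters.
#' @return Invisibly, a list with the in-memory stage results and the output
#'   directory.
#' @export
run_pipeline <- function(config = run_config(), n_genes_structure = 20L,
                         n_promoters = 20L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(config), function(x) x), cfg_path)
  # hash excludes the output path so reruns elsewhere are byte-identical
  hash_path <- tempfile()
  hashable <- unclass(config)
  hashable$out_dir <- NULL
  yaml::write_yaml(hashable, hash_path)
  cfg_md5 <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  hdr <- c(paste0("seed=", config$seed), paste0("config_md5=", cfg_md5))
  out <- list(out_dir = config$out_dir)
  seed <- config$seed
  stage_on <- function(s) s %in% config$stages

  spec <- default_family_spec()
  fam <- make_family(98L, spec$clade_spec, mutation_rate = 0.05,
                     seed = seed, categories = spec$categories)
  profile <- packaged_profile()
  threshold <- config$domain_threshold %||%
    calibrate_threshold(profile, n = 200L, seed = seed)

  if (stage_on("identify")) {
    hits <- lapply(names(fam$proteins), function(id) {
      scan_domain(fam$proteins[[id]], profile, threshold, id = id)
    })
    names(hits) <- names(fam$proteins)
    found <- !vapply(hits, is.null, logical(1))
    out$hits <- hits[found]
    out$no_hit <- names(hits)[!found]
    props <- lapply(names(fam$proteins), function(id) {
      protein_properties(fam$proteins[[id]], id = id)
    })
    member_rows <- do.call(rbind, lapply(which(found), function(i) {
      h <- hits[[i]]; p <- props[[i]]
      data.frame(id = h$protein_id, clade = fam$truth$members$clade[i],
                 length = p$length, mw = round(p$mw, 2),
                 pi = round(p$pi, 2), domain_start = h$start,
                 score = round(h$score, 3), stringsAsFactors = FALSE)
    }))
    if (stage_on("classify")) {
      calls <- lapply(out$hits, classify_binding,
                      basic_set = config$basic_set,
                      basic_cutoff = config$basic_cutoff)
      out$calls <- calls
      member_rows$category <- vapply(calls, function(x) x$category, character(1))
      out$binding_summary <- summarize_binding(calls)
      write_tsv(out$binding_summary,
                file.path(config$out_dir, "binding_summary.tsv"), hdr)
    }
    out$members <- member_rows
    write_tsv(member_rows, file.path(config$out_dir, "members.tsv"), hdr)
    if (stage_on("conserve")) {
      doms <- vapply(out$hits, function(h) h$aligned55, character(1))
      out$conservation <- conservation(doms)
      write_tsv(out$conservation,
                file.path(config$out_dir, "conservation.tsv"), hdr)
    }
    if (stage_on("tree")) {
      doms <- vapply(out$hits, function(h) h$aligned55, character(1))
      tree <- nj_tree(p_distance_matrix(doms))
      out$tree <- tree
      write_newick(tree, file.path(config$out_dir, "family_tree.nwk"))
      out$clades <- assign_clades(doms, fam$truth$ancestors,
                                  names(fam$truth$ancestors))
      write_tsv(out$clades, file.path(config$out_dir, "clades.tsv"), hdr)
    }
    if (stage_on("network")) {
      doms <- vapply(out$hits, function(h) h$aligned55, character(1))
      refs <- fam$truth$ancestors
      map <- best_hits(doms, refs)
      ed <- reference_edges()
      # project along a ring over the reference ancestors for the synthetic run
      ring <- data.frame(ref_a = names(refs),
                         ref_b = c(names(refs)[-1], names(refs)[1]))
      net <- project_network(map, ring)
      out$network <- net
      write_tsv(net$edges, file.path(config$out_dir, "network_edges.tsv"), hdr)
    }
  }

  if (stage_on("promoters")) {
    lib <- default_motif_library(config$motif_library)
    prom <- make_promoters(n_promoters, plant = c(`G-box` = 2, MBS = 1),
                           seed = seed, library = lib)
    hits <- do.call(rbind, lapply(names(prom$promoters), function(id) {
      scan_motifs(stats::setNames(prom$promoters[id], id), lib)
    }))
    out$motif_summary <- summarize_motifs(hits, names(prom$promoters), lib)
    write_tsv(out$motif_summary,
              file.path(config$out_dir, "motif_summary.tsv"), hdr)
  }

  if (stage_on("structure")) {
    models <- lapply(seq_len(n_genes_structure), function(i) {
      g <- make_gene(n_introns = (i - 1L) %% 6L, seed = seed + i,
                     intron_len_range = c(44L, 400L),
                     gene_id = sprintf("syngene%03d", i))
      infer_structure(g$cds, g$genomic)
    })
    out$models <- models
    st <- intron_stats(models)
    write_tsv(st$per_gene, file.path(config$out_dir, "gene_structure.tsv"), hdr)
    write_gff3(models, file.path(config$out_dir, "gene_models.gff3"))
  }

  if (stage_on("expression")) {
    expr <- make_expression(75L, noise_sd = 0.1, seed = seed)
    calls <- call_expression(expr$fpkm, config$t_expr, config$t_low,
                             config$t_mod)
    grp <- heatmap_groups(expr$fpkm[calls$expressed, , drop = FALSE], k = 5L)
    out$expression <- list(calls = calls, groups = grp$groups)
    write_tsv(data.frame(gene = names(grp$groups), group = grp$groups),
              file.path(config$out_dir, "expression_groups.tsv"), hdr)
  }

  if (stage_on("qpcr")) {
    fc_spec <- expand.grid(gene = sprintf("target%d", 1:5),
                           condition = c("MeJA", "ABA"),
                           timepoint = c("3h", "6h"), stringsAsFactors = FALSE)
    fc_spec$log2fc <- rep_len(c(-2, -1, 0, 1, 2), nrow(fc_spec))
    qp <- make_qpcr(unique(fc_spec$gene), fc_spec, ct_noise_sd = 0.1,
                    seed = seed)
    out$qpcr <- ddct(qp$table)
    write_tsv(out$qpcr, file.path(config$out_dir, "qpcr_foldchange.tsv"), hdr)
  }

  invisible(out)
}
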