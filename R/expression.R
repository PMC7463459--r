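# Expression-tier calling on FPKM matrices, heatmap grouping on
# log2(FPKM + 0.01), and 2^-ddCT relative quantification with Student's
# t-tests.

#' Call expression tiers from an FPKM matrix
#'
#' Tiers by half-open bins: not expressed `[0, t_expr)`, low
#' `[t_expr, t_low)`, moderate `[t_low, t_mod)`, abundant `[t_mod, Inf)`.
#' A gene is flagged expressed when any tissue reaches `t_expr`.
#'
#' @param fpkm Genes x tissues numeric matrix (FPKM, non-negative).
#' @param t_expr,t_low,t_mod Tier thresholds (defaults 2, 10, 50).
#' @return List with `tiers` (character matrix), `expressed` (named logical),
#'   `thresholds`.
#' @export
call_expression <- function(fpkm, t_expr = 2, t_low = 10, t_mod = 50) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("negative FPKM values")
  tiers <- matrix(cut(fpkm, breaks = c(-Inf, t_expr, t_low, t_mod, Inf),
                      labels = c("not_expressed", "low", "moderate", "abundant"),
                      right = FALSE),
                  nrow(fpkm), ncol(fpkm), dimnames = dimnames(fpkm))
  expressed <- apply(fpkm, 1, function(x) any(x >= t_expr))
  list(tiers = tiers, expressed = expressed,
       thresholds = c(t_expr = t_expr, t_low = t_low, t_mod = t_mod))
}

#' Heatmap grouping of expressed genes on log2(FPKM + 0.01)
#'
#' The matrix restricted to expressed genes is transformed to
#' `log2(FPKM + 0.01)` and genes are clustered agglomeratively
#' (default: average linkage on Euclidean distances), then cut into exactly
#' `k` groups.  Deterministic; ties in merge order follow [stats::hclust()]'s
#' documented label-order behaviour.
#'
#' @param fpkm Genes x tissues FPKM matrix, already restricted to expressed
#'   genes.
#' @param k Number of groups (default 5).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @return List with `transformed` matrix, `tree` (hclust) and `groups`
#'   (named integer vector of group labels 1..k).
#' @export
heatmap_groups <- function(fpkm, k = 5L, linkage = "average",
                           metric = "euclidean") {
  fpkm <- as.matrix(fpkm)
  if (k < 1 || k > nrow(fpkm)) stop("k must be in 1..number of genes")
  lt <- log2(fpkm + 0.01)
  tree <- stats::hclust(stats::dist(lt, method = metric), method = linkage)
  groups <- stats::cutree(tree, k = k)
  list(transformed = lt, tree = tree, groups = groups)
}

#' Relative expression by the 2^-ddCT method with Student's t-tests
#'
#' Technical replicates are averaged to one CT per (gene, condition,
#' timepoint, biological replicate); `dCT = CT_gene - CT_reference` per
#' biological replicate; `ddCT = mean dCT_condition - mean dCT_baseline`;
#' `fold = 2^-ddCT`.  Significance per gene/condition/timepoint is a
#' two-sided pooled-variance Student's t-test comparing biological-replicate
#' dCT values against baseline, starred at p < 0.05 (`*`) and p < 0.01
#' (`**`); a Benjamini-Hochberg adjusted column is emitted alongside.
#'
#' @param table Long qPCR data frame: `gene`, `condition`, `timepoint`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param reference_gene Internal reference gene id.
#' @param baseline List/vector with `condition` and `timepoint` naming the
#'   calibrator sample (default control at 0h).
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return Data frame per gene/condition/timepoint (baseline rows excluded):
#'   `delta_ct`, `delta_delta_ct`, `fold`, `log2fc`, `t_statistic`,
#'   `p_value`, `p_adj`, `stars`.
#' @export
ddct <- function(table, reference_gene = "DoActin",
                 baseline = c(condition = "control", timepoint = "0h"),
                 welch = FALSE) {
  need <- c("gene", "condition", "timepoint", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(table)))
  if (!reference_gene %in% table$gene) {
    stop("reference gene '", reference_gene, "' absent from table")
  }
  bcond <- baseline[["condition"]]; btp <- baseline[["timepoint"]]
  if (!any(table$condition == bcond & table$timepoint == btp)) {
    stop("baseline (", bcond, ", ", btp, ") absent from table")
  }
  # average technical replicates
  agg <- stats::aggregate(ct ~ gene + condition + timepoint + bio_rep,
                          data = table, FUN = mean)
  ref <- agg[agg$gene == reference_gene, ]
  key <- function(df) paste(df$condition, df$timepoint, df$bio_rep)
  ref_ct <- stats::setNames(ref$ct, key(ref))
  tgt <- agg[agg$gene != reference_gene, ]
  tgt$ref_ct <- ref_ct[key(tgt)]
  if (any(is.na(tgt$ref_ct))) {
    stop("missing reference CT for some (condition, timepoint, bio_rep)")
  }
  tgt$dct <- tgt$ct - tgt$ref_ct
  rows <- list()
  for (g in unique(tgt$gene)) {
    sub <- tgt[tgt$gene == g, ]
    base_dct <- sub$dct[sub$condition == bcond & sub$timepoint == btp]
    if (length(base_dct) < 2) stop("fewer than 2 baseline replicates for ", g)
    for (cond in unique(sub$condition)) {
      for (tp in unique(sub$timepoint[sub$condition == cond])) {
        if (cond == bcond && tp == btp) next
        dcts <- sub$dct[sub$condition == cond & sub$timepoint == tp]
        if (length(dcts) < 2) stop("fewer than 2 replicates for ", g,
                                   " at ", cond, "/", tp)
        ddct_val <- mean(dcts) - mean(base_dct)
        if (stats::sd(dcts) == 0 && stats::sd(base_dct) == 0) {
          # degenerate (noise-free) data: identical means are a clean null,
          # different means an exact difference
          tt <- list(statistic = if (ddct_val == 0) 0 else sign(ddct_val) * Inf,
                     p.value = if (ddct_val == 0) 1 else 0)
        } else {
          tt <- stats::t.test(dcts, base_dct, var.equal = !welch)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, condition = cond, timepoint = tp,
          delta_ct = mean(dcts), delta_delta_ct = ddct_val,
          fold = 2^(-ddct_val), log2fc = -ddct_val,
          t_statistic = unname(tt$statistic), p_value = tt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$stars <- ifelse(out$p_value < 0.01, "**",
                      ifelse(out$p_value < 0.05, "*", ""))
  out
}
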