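test_that("family generator plants domains exactly as recorded", {
  # zero mutation, one clade: identical planted 55-mers at recorded offsets
  fam <- make_family(4, c(cladeA = 4), mutation_rate = 0, seed = 3)
  doms <- unique(fam$truth$members$domain55)
  expect_length(doms, 1L)
  for (i in 1:4) {
    prot <- fam$proteins[[i]]
    off <- fam$truth$members$offset[i]
    expect_identical(substr(prot, off + 1, off + 55),
                     fam$truth$members$domain55[i])
  }

  # requested G-box category forces the rule residues and basic count
  fam_g <- make_family(6, c(a = 3, b = 3), 0.1, seed = 5,
                       categories = "G_box")
  for (basic in fam_g$truth$members$basic_region) {
    ch <- strsplit(basic, "")[[1]]
    expect_true(ch[9] %in% c("H", "K"))
    expect_identical(ch[13], "E")
    expect_identical(ch[16], "R")
    expect_identical(ch[17], "R")
    expect_gte(sum(ch %in% c("R", "K", "H")), 6)
  }

  # determinism at the full fixture scale
  spec <- default_family_spec()
  f1 <- make_family(98, spec$clade_spec, 0.05, seed = 1,
                    categories = spec$categories)
  f2 <- make_family(98, spec$clade_spec, 0.05, seed = 1,
                    categories = spec$categories)
  expect_identical(f1$proteins, f2$proteins)
  expect_identical(f1$truth$members, f2$truth$members)

  expect_error(make_family(4, c(a = 4), mutation_rate = 0.5), "mutation_rate")
  expect_error(make_family(3, c(a = 2, b = 1)), "clade size")
})

test_that("gene generator produces GT..AG introns with truthful intervals", {
  g0 <- make_gene(0, seed = 1)
  expect_identical(unname(g0$genomic), unname(g0$cds))

  g11 <- make_gene(11, seed = 4)
  expect_identical(nrow(g11$truth$exons), 12L)
  expect_identical(nrow(g11$truth$introns), 11L)
  gen <- as.character(g11$genomic)
  for (i in 1:11) {
    s <- g11$truth$introns[i, 1]; e <- g11$truth$introns[i, 2]
    expect_identical(substr(gen, s + 1, s + 2), "GT")
    expect_identical(substr(gen, e - 1, e), "AG")
  }
  lens <- g11$truth$introns[, 2] - g11$truth$introns[, 1]
  expect_true(all(lens >= 44 & lens <= 2000))

  expect_error(make_gene(1, exon_len_range = c(300, 30)), "inverted")
})

test_that("promoter generator records planted instances and is seeded", {
  pr <- make_promoters(3, plant = c(`G-box` = 3), seed = 6)
  counts <- table(pr$truth$planted$promoter_id)
  expect_true(all(counts == 3))
  expect_true(all(nchar(pr$promoters) == 2000))
  # planted instances actually sit in the sequence
  for (i in seq_len(nrow(pr$truth$planted))) {
    row <- pr$truth$planted[i, ]
    site <- substr(pr$promoters[[row$promoter_id]],
                   row$position + 1, row$position + 6)
    expect_identical(site, "CACGTG")  # palindrome: same on both strands
  }

  none <- make_promoters(2, plant = c(), seed = 6)
  expect_identical(nrow(none$truth$planted), 0L)

  a <- make_promoters(2, plant = c(MBS = 2), seed = 9)
  b <- make_promoters(2, plant = c(MBS = 2), seed = 9)
  expect_identical(a$promoters, b$promoters)

  expect_error(make_promoters(1, length = 30, plant = c(`G-box` = 10)),
               "infeasible packing")
})

test_that("expression generator obeys tier bounds and group bookkeeping", {
  one <- make_expression(1, group_spec = list(
    list(name = "all_abundant", size = 1,
         tiers = stats::setNames(rep("abundant", 8),
                                 c("column", "flower_buds", "lip", "sepal",
                                   "leaf", "stem", "white_root",
                                   "green_root_tip")))),
    noise_sd = 0, seed = 2)
  expect_true(all(one$fpkm >= 50))

  # root-specific pattern: below the expression threshold outside roots
  expr <- make_expression(75, noise_sd = 0, seed = 2)
  iii <- names(expr$truth$groups)[expr$truth$groups == "III"]
  non_root <- c("column", "flower_buds", "lip", "sepal", "leaf", "stem")
  expect_true(all(expr$fpkm[iii, non_root] < 2))

  # five blocks summing to 75
  expect_identical(sort(unique(expr$truth$groups)), c("I", "II", "III", "IV", "V"))
  expect_identical(sum(table(expr$truth$groups)), 75L)

  expect_error(make_expression(2, group_spec = list(
    list(name = "x", size = 2,
         tiers = stats::setNames(rep("huge", 8),
                                 c("column", "flower_buds", "lip", "sepal",
                                   "leaf", "stem", "white_root",
                                   "green_root_tip")))), seed = 1),
    "unknown tier")
})

test_that("qPCR generator plants recoverable fold changes", {
  fc <- data.frame(gene = "t1", condition = "MeJA", timepoint = "3h",
                   log2fc = 2)
  qp <- make_qpcr("t1", fc, ct_noise_sd = 0, seed = 1)
  tab <- qp$table
  ct_ctrl <- tab$ct[tab$gene == "t1" & tab$condition == "control" &
                      tab$timepoint == "0h"]
  ct_trt <- tab$ct[tab$gene == "t1" & tab$condition == "MeJA" &
                     tab$timepoint == "3h"]
  expect_equal(unique(ct_ctrl) - unique(ct_trt), 2)
  expect_length(unique(tab$ct[tab$gene == "DoActin"]), 1L)

  # null case: downstream analysis recovers fold 1 everywhere
  qp0 <- make_qpcr(c("t1", "t2"), NULL, ct_noise_sd = 0, seed = 1)
  r0 <- ddct(qp0$table)
  expect_true(all(abs(r0$fold - 1) < 1e-12))

  expect_error(make_qpcr("t1", NULL, n_bio = 1), "n_bio")
})

test_that("planted log2 fold changes are recovered within 3 SE almost always", {
  # Monte-Carlo calibration: noise 0.2, 3 biological replicates
  fc <- data.frame(gene = "t1", condition = "MeJA", timepoint = "3h",
                   log2fc = 1)
  inside <- vapply(1:200, function(s) {
    qp <- make_qpcr("t1", fc, ct_noise_sd = 0.2, seed = s)
    r <- ddct(qp$table)
    r <- r[r$condition == "MeJA" & r$timepoint == "3h", ]
    # SE of ddCT from 3 + 3 replicate dCT values at noise 0.2:
    # var(dCT) = 2 * 0.2^2 / 3 (technical averaging), two groups
    se <- sqrt(2 * (2 * 0.2^2 / 3) / 3)
    abs(r$log2fc - 1) <= 3 * se
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})
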