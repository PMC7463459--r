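test_that("profile building matches closed forms and normalization", {
  # single row, vanishing pseudocount: consensus equals the row and the
  # self-scan is the maximal attainable score
  row <- test_profile()$consensus
  p1 <- build_profile(row, pseudocount = 1e-9)
  expect_identical(p1$consensus, row)
  hit <- scan_domain(row, p1, threshold = -Inf, id = "self")
  expect_identical(hit$start, 0L)
  expect_equal(hit$score, sum(apply(p1$weights, 2, max)))

  # all-'R' column at background 0.05, pseudocount -> 0: log2(1/0.05) bits
  rows <- rep(paste(rep("R", 55), collapse = ""), 3)
  p2 <- build_profile(rows, pseudocount = 1e-12)
  expect_equal(unname(p2$weights["R", 1]), log2(1 / 0.05), tolerance = 1e-6)

  # per-column probabilities sum to 1 for random seeded alignments
  aa <- rownames(p2$weights)
  for (s in 1:100) {
    rows <- withr::with_seed(s, vapply(1:4, function(i) {
      paste(sample(aa, 55, TRUE), collapse = "")
    }, character(1)))
    p <- build_profile(rows, pseudocount = runif(1, 0.1, 2))
    expect_true(all(abs(colSums(p$probs) - 1) < 1e-9))
  }

  expect_error(build_profile(c("MK", "MKL")), "ragged|55")
  expect_error(build_profile(paste(rep("J", 55), collapse = "")),
               "non-amino-acid")
})

test_that("domain scanning finds planted consensus and rejects noise", {
  prof <- test_profile()
  flank <- random_protein(30, seed = 1)
  prot <- paste0(flank, prof$consensus, random_protein(30, seed = 2))
  hit <- scan_domain(prot, prof, threshold = 0)
  expect_identical(hit$start, 30L)
  expect_identical(hit$aligned55, prof$consensus)

  # calibrated threshold: i.i.d. random proteins nearly always absent
  thr <- calibrate_threshold(prof, n = 500, length = 500, seed = 1)
  absent <- vapply(1:200, function(s) {
    is.null(scan_domain(random_protein(500, seed = 1000 + s), prof, thr))
  }, logical(1))
  expect_gte(mean(absent), 0.99)

  # planted domain with 5 substitutions is recovered at the planted offset
  dom <- strsplit(prof$consensus, "")[[1]]
  dom[c(20, 25, 33, 44, 50)] <- c("A", "A", "A", "A", "A")
  prot5 <- paste0(random_protein(40, seed = 3), paste(dom, collapse = ""),
                  random_protein(25, seed = 4))
  hit5 <- scan_domain(prot5, prof, thr)
  expect_identical(hit5$start, 40L)

  expect_error(scan_domain("MKLV", prof, 0), "too short")
})

test_that("region partition is 17/15/8/15 and places landmark columns", {
  s <- paste0(strrep("B", 17), strrep("H", 15), strrep("L", 8), strrep("X", 15))
  reg <- partition_regions(s)
  expect_identical(nchar(unlist(reg)), c(basic = 17L, helix1 = 15L,
                                         loop = 8L, helix2 = 15L))
  expect_identical(paste0(reg$basic, reg$helix1, reg$loop, reg$helix2), s)
  # column 40 (conserved Asp in the family survey) falls in the loop,
  # column 27 (conserved Leu) in helix 1
  region_of <- rep(names(reg), nchar(unlist(reg)))
  expect_identical(region_of[40], "loop")
  expect_identical(region_of[27], "helix1")
})

test_that("conservation identities are exact fractions with gaps in the denominator", {
  doms <- rep(test_profile()$consensus, 98)
  cons <- conservation(doms)
  expect_true(all(cons$identity == 1))
  expect_true(all(cons$consensus_flag))

  # 50 L + 48 M at one column of 98 sequences
  base <- strsplit(test_profile()$consensus, "")[[1]]
  mk <- function(ch) {
    v <- base; v[30] <- ch; paste(v, collapse = "")
  }
  doms2 <- c(rep(mk("L"), 50), rep(mk("M"), 48))
  c30 <- conservation(doms2)[30, ]
  expect_identical(c30$top_residue, "L")
  expect_equal(c30$identity, 50 / 98)
  expect_true(c30$consensus_flag)

  # gapped column: gaps count in the denominator
  doms3 <- c(rep(mk("L"), 5), rep(sub("^.", "-", mk("L")), 5))
  expect_equal(conservation(doms3)[1, "identity"], 5 / 10)

  # identity is always a multiple of 1/n
  n <- length(doms2)
  expect_true(all(abs(conservation(doms2)$identity * n -
                        round(conservation(doms2)$identity * n)) < 1e-9))

  expect_error(conservation(c("AB", "ABC")), "ragged|55")
})

test_that("binding classification follows the residue rules", {
  pad <- strrep("L", 38)
  call1 <- classify_binding(paste0(strrep("A", 17), pad))
  expect_identical(call1$category, "non_DNA_binding")
  expect_identical(call1$basic_count, 0L)

  allr <- strsplit(strrep("R", 17), "")[[1]]
  g <- allr; g[9] <- "H"; g[13] <- "E"
  call2 <- classify_binding(paste0(paste(g, collapse = ""), pad))
  expect_identical(call2$category, "G_box")
  expect_identical(call2$basic_count, 16L)

  ne <- allr; ne[13] <- "A"
  call3 <- classify_binding(paste0(paste(ne, collapse = ""), pad))
  expect_identical(call3$category, "non_E_box")

  # a gap at a rule position fails that test
  gp <- g; gp[16] <- "-"
  call4 <- classify_binding(paste0(paste(gp, collapse = ""), pad))
  expect_identical(call4$category, "non_E_box")

  # category counts are order-invariant and additive
  spec <- default_family_spec()
  fam <- make_family(98, spec$clade_spec, 0.05, seed = 8,
                     categories = spec$categories)
  cats <- vapply(fam$truth$members$domain55, function(d) {
    classify_binding(d)$category
  }, character(1))
  perm <- withr::with_seed(1, sample(seq_along(cats)))
  expect_identical(c(table(cats)), c(table(cats[perm])))
  tab <- table(factor(cats, levels = c("G_box", "E_box_non_G_box",
                                       "non_E_box", "non_DNA_binding")))
  expect_identical(sum(tab), 98L)
  expect_identical(unname(tab["G_box"] + tab["E_box_non_G_box"]), 65L)
})

test_that("protein properties match reference masses and charge balance", {
  g <- protein_properties("G")
  expect_equal(g$mw, 75.07, tolerance = 1e-3)

  # net charge at the reported pI is zero by an independent evaluation
  for (s in 1:100) {
    pep <- random_protein(withr::with_seed(s, sample(10:80, 1)), seed = s)
    pi <- protein_properties(pep)$pi
    expect_lt(abs(oracle_charge(pep, pi)), 1e-3)
  }

  # basic peptides have higher pI than acidic ones
  expect_gt(protein_properties(strrep("K", 20))$pi,
            protein_properties(strrep("D", 20))$pi)

  expect_error(protein_properties(""), "empty")
})

test_that("isoelectric points agree with an external implementation", {
  for (s in 1:20) {
    pep <- random_protein(60, seed = 200 + s)
    ours <- protein_properties(pep)$pi
    theirs <- seqinr::computePI(strsplit(pep, "")[[1]])
    expect_lt(abs(ours - theirs), 0.75)
  }
})
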