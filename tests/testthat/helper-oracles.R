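# Shared fixtures and independently coded oracles used across the suite.

test_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_profile(system.file("extdata",
                                          "bhlh_seed_alignment_synthetic.fasta",
                                          package = "bhlhscan"))
    }
    cache
  }
})

# Independent truth-table oracle for the DNA-binding classifier, written as
# boolean predicates indexing a decision table (a different structure from
# the implementation's nested if-tree).
oracle_classify <- function(basic17, basic_set = c("R", "K", "H"),
                            cutoff = 6L) {
  ch <- strsplit(basic17, "")[[1]]
  n_basic <- sum(ch %in% basic_set)
  bind <- n_basic >= cutoff
  ebox <- ch[13] == "E" & ch[16] == "R"
  gbox <- (ch[9] == "H" | ch[9] == "K") & ch[17] == "R"
  states <- c("non_DNA_binding", "non_E_box", "E_box_non_G_box", "G_box")
  states[1L + bind * (1L + ebox * (1L + gbox))]
}

# Independent Henderson-Hasselbalch net charge (recoded from scratch;
# Expasy constants restated rather than shared with the implementation).
oracle_charge <- function(seq, ph) {
  ch <- strsplit(toupper(seq), "")[[1]]
  pos_pka <- c(7.5, rep(5.98, sum(ch == "H")), rep(10.0, sum(ch == "K")),
               rep(12.0, sum(ch == "R")))
  neg_pka <- c(3.55, rep(4.05, sum(ch == "D")), rep(4.45, sum(ch == "E")),
               rep(9.0, sum(ch == "C")), rep(10.0, sum(ch == "Y")))
  sum(1 / (1 + 10^(ph - pos_pka))) - sum(1 / (1 + 10^(neg_pka - ph)))
}

# Brute-force per-pair p-distance recount (explicit loops, no vectorization)
oracle_pdist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ncomp <- 0L; nmis <- 0L
  for (t in seq_along(ca)) {
    if (ca[t] != "-" && cb[t] != "-") {
      ncomp <- ncomp + 1L
      if (ca[t] != cb[t]) nmis <- nmis + 1L
    }
  }
  nmis / ncomp
}

# Exact integer half-up rounding of 100 * count / n to 2 decimals,
# returned in hundredths of a percent
oracle_percent_hundredths <- function(count, n) {
  num <- 10000L * count
  q <- num %/% n
  r <- num %% n
  q + as.integer(2L * r >= n)
}

round_half_up_test <- function(x) floor(x * 100 + 0.5) / 100

# A small random protein from a private stream (does not disturb global RNG)
random_protein <- function(len, seed) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  withr::with_seed(seed, paste(sample(aa, len, TRUE), collapse = ""))
}
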