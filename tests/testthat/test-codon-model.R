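test_that("the MG94xHKY rate matrix has the stated structure", {
  pi_eq <- codon_frequencies("equal")
  # kappa = omega = 1, equal pi: all single-step off-diagonals equal
  Q1 <- build_rate_matrix(1, 1, pi_eq)
  off <- Q1[Q1 > 0]
  expect_lt(diff(range(off)), 1e-12)
  expect_lt(max(abs(rowSums(Q1))), 1e-12)
  # multi-nucleotide changes have rate zero
  expect_identical(unname(Q1["AAA", "ACC"]), 0)
  expect_identical(unname(Q1["AAA", "CCC"]), 0)
})

test_that("hand-computed entry and detailed balance hold", {
  pi_eq <- codon_frequencies("equal")
  kappa <- 2.5; omega <- 0.2
  Q <- build_rate_matrix(kappa, omega, pi_eq)
  # independent normalizer: brute-force loop over all single-step pairs
  cods <- sense_codons()
  tab <- setNames(as.character(Biostrings::GENETIC_CODE),
                  names(Biostrings::GENETIC_CODE))
  raw <- matrix(0, 61, 61, dimnames = list(cods, cods))
  is_ts <- function(a, b) paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT")
  for (i in 1:61) for (j in 1:61) {
    if (i == j) next
    d <- which(strsplit(cods[i], "")[[1]] != strsplit(cods[j], "")[[1]])
    if (length(d) != 1L) next
    r <- pi_eq[j]
    if (is_ts(substr(cods[i], d, d), substr(cods[j], d, d))) r <- r * kappa
    if (tab[cods[i]] != tab[cods[j]]) r <- r * omega
    raw[i, j] <- r
  }
  norm <- sum(pi_eq * rowSums(raw))
  expect_equal(unname(Q["AAA", "AAG"]),
               unname(kappa * pi_eq["AAG"] / norm), tolerance = 1e-12)
  expect_equal(unname(Q[upper.tri(Q) | lower.tri(Q)]),
               unname((raw / norm)[upper.tri(raw) | lower.tri(raw)]),
               tolerance = 1e-12)
  # detailed balance and unit normalization for random parameter draws
  set.seed(11)
  for (i in 1:25) {
    k <- exp(runif(1, -1, 2)); w <- exp(runif(1, -3, 1))
    p <- runif(61, 0.2, 1); p <- p / sum(p)
    Qr <- build_rate_matrix(k, w, p)
    M <- p * Qr  # (i, j) entry: pi_i q_ij; detailed balance makes M symmetric
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_lt(abs(sum(p * -diag(Qr)) - 1), 1e-10)
  }
})

test_that("increasing omega increases the expected nonsynonymous fraction", {
  set.seed(12)
  for (i in 1:10) {
    p <- runif(61, 0.2, 1); p <- p / sum(p)
    k <- exp(runif(1, -0.5, 1.5))
    fr <- vapply(c(0.1, 0.5, 1, 2), function(w) {
      1 - pseudochron:::.syn_fraction(build_rate_matrix(k, w, p), p)
    }, numeric(1))
    expect_true(all(diff(fr) > 0))
  }
})

test_that("two-taxon and zero-branch likelihoods match closed forms", {
  pi_eq <- codon_frequencies("equal")
  tr <- status_tree("(a:1,b:1);")
  aln <- codon_alignment(c(a = "ATGAAACCC", b = "ATGAAGCCA"))
  params <- list(kappa = 2, omega = c(all = 0.3), pi = pi_eq,
                 branch_lengths = c(0.25, 0.15), categories = c("all", "all"))
  Q <- build_rate_matrix(2, 0.3, pi_eq)
  dec <- pseudochron:::.decompose_q(Q, pi_eq)
  P <- pseudochron:::.pmat(dec, 0.4)  # reversible: both branches collapse
  cods <- sense_codons()
  ia <- match(c("ATG", "AAA", "CCC"), cods)
  ib <- match(c("ATG", "AAG", "CCA"), cods)
  manual <- sum(log(pi_eq[ia] * P[cbind(ia, ib)]))
  expect_equal(log_likelihood(tr, aln, params), manual, tolerance = 1e-10)
  # t = 0, identical sequences: sum of log pi over observed codons
  aln0 <- codon_alignment(c(a = "ATGAAACCC", b = "ATGAAACCC"))
  params0 <- params
  params0$branch_lengths <- c(1e-12, 1e-12)
  expect_equal(log_likelihood(tr, aln0, params0),
               sum(log(pi_eq[ia])), tolerance = 1e-6)
})

test_that("pruning equals brute-force enumeration over internal states", {
  pi_eq <- codon_frequencies("equal")
  set.seed(13)
  brute <- function(phy, aln, params) {
    n_tip <- length(phy$tip.label)
    dec <- pseudochron:::.decompose_q(
      build_rate_matrix(params$kappa, params$omega[["all"]], params$pi),
      params$pi)
    P <- lapply(seq_len(nrow(phy$edge)), function(e)
      pseudochron:::.pmat(dec, params$branch_lengths[e]))
    n_int <- phy$Nnode
    root <- n_tip + 1L
    combos <- as.matrix(expand.grid(rep(list(1:61), n_int)))
    total <- 0
    for (site in seq_len(aln$n_sites)) {
      states <- aln$states[phy$tip.label, site]
      term <- params$pi[combos[, root - n_tip]]
      for (e in seq_len(nrow(phy$edge))) {
        pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
        i <- combos[, pa - n_tip]
        j <- if (ch <= n_tip) rep(states[ch], nrow(combos)) else
          combos[, ch - n_tip]
        if (is.na(j[1])) next  # missing tip marginalizes out
        term <- term * P[[e]][cbind(i, j)]
      }
      total <- total + log(sum(term))
    }
    total
  }
  # 3 taxa (1 internal node beyond root = 2 internal) and 4 taxa
  for (nw in c("((a:0.3,b:0.2):0.1,c:0.4);",
               "((a:0.3,b:0.2):0.1,(c:0.4,d:0.1):0.2);")) {
    phy <- ape::read.tree(text = nw)
    n_tip <- length(phy$tip.label)
    for (rep_i in 1:2) {
      cods <- sense_codons()
      n_sites <- sample(2:3, 1)
      seqs <- vapply(seq_len(n_tip), function(i)
        paste0(sample(cods, n_sites, replace = TRUE), collapse = ""),
        character(1))
      names(seqs) <- phy$tip.label
      aln <- codon_alignment(seqs, pseudogenic = phy$tip.label)
      params <- list(kappa = runif(1, 1, 4), omega = c(all = runif(1, .1, 1)),
                     pi = pi_eq,
                     branch_lengths = phy$edge.length,
                     categories = rep("all", nrow(phy$edge)))
      expect_equal(log_likelihood(phy, aln, params), brute(phy, aln, params),
                   tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to leaf relabeling and re-rooting", {
  pi_eq <- codon_frequencies("equal")
  set.seed(14)
  phy <- ape::read.tree(text = "((a:0.3,b:0.2):0.1,(c:0.4,d:0.1):0.2);")
  cods <- sense_codons()
  seqs <- setNames(vapply(1:4, function(i)
    paste0(sample(cods, 5, replace = TRUE), collapse = ""), character(1)),
    phy$tip.label)
  aln <- codon_alignment(seqs, pseudogenic = names(seqs))
  params <- list(kappa = 2, omega = c(all = 0.4), pi = pi_eq,
                 branch_lengths = phy$edge.length,
                 categories = rep("all", nrow(phy$edge)))
  ll <- log_likelihood(phy, aln, params)
  # leaf order in the alignment does not matter
  aln2 <- codon_alignment(seqs[c("d", "b", "a", "c")],
                          pseudogenic = names(seqs))
  expect_equal(log_likelihood(phy, aln2, params), ll, tolerance = 1e-10)
  # re-rooting along a branch preserves the likelihood (reversible model)
  phy2 <- ape::root(phy, outgroup = "c", resolve.root = TRUE)
  params2 <- params
  params2$branch_lengths <- phy2$edge.length
  params2$categories <- rep("all", nrow(phy2$edge))
  expect_equal(log_likelihood(phy2, aln, params2), ll, tolerance = 1e-8)
})

test_that("stop codons are rejected in functional rows, recoded otherwise", {
  expect_error(codon_alignment(c(a = "ATGTAA", b = "ATGAAA")), "stop codon")
  aln <- codon_alignment(c(a = "ATGTAA", b = "ATGAAA"), pseudogenic = "a")
  expect_true(is.na(aln$states["a", 2]))
  expect_false(is.na(aln$states["b", 2]))
  # gaps are missing data
  aln2 <- codon_alignment(c(a = "ATG---", b = "ATGAAA"))
  expect_true(is.na(aln2$states["a", 2]))
})

test_that("codon alignments round-trip through FASTA and PHYLIP", {
  sim <- sim8(61, sites = 20)
  aln <- sim$alignment
  fa <- tempfile(fileext = ".fa"); ph <- tempfile(fileext = ".phy")
  write_codon_alignment(aln, fa, format = "fasta")
  write_codon_alignment(aln, ph, format = "phylip")
  back_fa <- read_codon_alignment(fa, "fasta", pseudogenic = aln$taxa)
  back_ph <- read_codon_alignment(ph, "phylip", pseudogenic = aln$taxa)
  expect_identical(back_fa$states, aln$states)
  expect_identical(back_ph$states[aln$taxa, ], aln$states)
})
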