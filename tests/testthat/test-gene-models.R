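test_that("splicing concatenates exons and validates the model", {
  expect_identical(splice(gene_model("s", "g", "ATGTAA")), "ATGTAA")
  expect_identical(splice(gene_model("s", "g", c("ATGAA", "ATAA"))),
                   "ATGAAATAA")
  fx <- make_fixture("rodent")
  expect_identical(nchar(splice(fx$reference)),
                   sum(vapply(fx$reference$exons,
                              function(e) nchar(e$sequence), integer(1))))
  expect_error(gene_model("s", "g", c("ATG", "")), "empty")
  expect_error(gene_model("s", "g", "ATGN"), "non-ACGT")
})

test_that("exon phases follow the cumulative spliced length", {
  gm <- gene_model("s", "g", c("ATGC", "AACCA", "GGG"))
  phases <- vapply(gm$exons, `[[`, integer(1), "phase")
  # lengths 4, 5: phase2 = (3 - 4 %% 3) %% 3 = 2; phase3 = (3 - 9 %% 3) %% 3 = 0
  expect_identical(phases, c(0L, 2L, 0L))
})

test_that("translation reports amino acids and stop codon positions", {
  tr <- translate_cds("ATGTAA")
  expect_identical(tr$protein, "M*")
  expect_identical(tr$stops$base, 4L)
  expect_identical(translate_cds("GAA")$protein, "E")
  expect_identical(translate_cds("TAA")$protein, "*")
  # shifted frame of ATGAAATAG: TGA AAT -> stop at base 1 then Asn
  tr2 <- translate_cds("ATGAAATAG", frame_offset = 1)
  expect_identical(tr2$protein, "*N")
  expect_identical(tr2$stops$base, 1L)
  expect_error(translate_cds("ATGNCC"), "position 4")
  expect_error(translate_cds("AT"), "fewer than 3")
})

test_that("catalogued substitutions create the described premature stops", {
  fx <- make_fixture("galliform")
  ref <- fx$reference
  # chicken: G -> T at base 69 of exon-2 turns GAA (codons start at base 3,
  # phase 2) into TAA
  expect_identical(substr(ref$exons[[2]]$sequence, 69, 71), "GAA")
  chick <- apply_mutations(ref, fx$catalog[fx$catalog$species == "chicken", ])
  expect_identical(substr(chick$exons[[2]]$sequence, 69, 71), "TAA")
  # Japanese quail: substitutions at bases 48 and 50 turn AAC into TAA
  expect_identical(substr(ref$exons[[2]]$sequence, 48, 50), "AAC")
  jq <- apply_mutations(ref,
                        fx$catalog[fx$catalog$species == "japanese_quail", ])
  expect_identical(substr(jq$exons[[2]]$sequence, 48, 50), "TAA")
  # empty catalog is the identity
  expect_identical(apply_mutations(ref, fx$catalog[0, ]), ref)
})

test_that("mutation application validates edits and rebuilds phases", {
  gm <- gene_model("s", "g", c("ATGCACGA", "CCAGGGTAA"))
  expect_warning(apply_mutations(gm, mutation_record("s", 1, "substitution",
                                                     4, 1, "C")), "no-op")
  expect_error(apply_mutations(gm, mutation_record("s", 2, "deletion", 9, 3)),
               "out of range")
  expect_error(
    apply_mutations(gm, catalog(
      mutation_record("s", 1, "deletion", 2, 3),
      mutation_record("s", 1, "substitution", 4, 1, "T"))),
    "overlapping")
  ed <- apply_mutations(gm, mutation_record("s", 1, "deletion", 4, 2))
  expect_identical(ed$exons[[1]]$sequence, "ATGCGA")
  expect_identical(ed$exons[[2]]$phase, 0L)
  ed2 <- apply_mutations(gm, mutation_record("s", 1, "insertion", 0, 1, "G"))
  expect_identical(substr(ed2$exons[[1]]$sequence, 1, 4), "GATG")
  expect_identical(ed2$exons[[2]]$phase, (3L - 9L %% 3L) %% 3L)
})

test_that("status classification follows the disruption rules", {
  fx <- make_fixture("galliform")
  ref <- fx$reference
  # identical sequences: intact, zero mutations
  rep0 <- scan_disruptions(ref, ref)
  expect_identical(rep0$status, "intact")
  expect_identical(nrow(rep0$mutations_detected), 0L)
  # one premature stop: disrupted
  chick <- apply_mutations(ref, fx$catalog[fx$catalog$species == "chicken", ])
  expect_identical(scan_disruptions(ref, chick)$status, "disrupted")
  # net +2 terminal frameshift, no stop needed for the call
  fs <- apply_mutations(ref, mutation_record("x", 4, "insertion", 90, 2, "CC"))
  rfs <- scan_disruptions(ref, fs)
  expect_identical(rfs$status, "disrupted")
  expect_identical(rfs$raw_indel_sum %% 3L, 2L)
  # start-codon loss alone is disruption
  sl <- apply_mutations(ref, mutation_record("x", 1, "substitution", 2, 1, "C"))
  rsl <- scan_disruptions(ref, sl)
  expect_false(rsl$start_codon_intact)
  expect_identical(rsl$status, "disrupted")
})

test_that("an in-frame deletion is detected without calling disruption", {
  fx <- make_fixture("rodent")
  ref <- fx$reference
  ed <- apply_mutations(ref, mutation_record("x", 3, "deletion", 40, 3))
  rep <- scan_disruptions(ref, ed)
  expect_identical(rep$status, "intact")
  expect_identical(nrow(rep$mutations_detected), 1L)
  expect_identical(rep$mutations_detected$kind, "deletion")
  expect_identical(tail(rep$net_frame_offset_per_exon, 1), -3L)
  # translated protein is the reference protein minus one residue
  p_ref <- translate_cds(splice(ref))$protein
  p_ed <- translate_cds(splice(ed))$protein
  expect_identical(nchar(p_ed), nchar(p_ref) - 1L)
})

test_that("a destroyed terminal stop is stop-loss, not disruption", {
  fx <- make_fixture("rodent")
  ref <- fx$reference
  L4 <- nchar(ref$exons[[4]]$sequence)
  ed <- apply_mutations(ref, mutation_record("x", 4, "substitution",
                                             L4 - 2L, 1, "C"))
  rep <- scan_disruptions(ref, ed)
  expect_true(rep$stop_loss)
  expect_identical(rep$status, "intact")
})

test_that("scan recovers random mutation catalogs (round trip)", {
  fx <- make_fixture("galliform")
  ref <- fx$reference
  lens <- vapply(ref$exons, function(e) nchar(e$sequence), integer(1))
  set.seed(101)
  for (iter in 1:150) {
    # well-separated random edits (>= 8 bp apart) so the optimum is unique
    n_mut <- sample(1:4, 1)
    exons <- sample(1:4, n_mut, replace = TRUE)
    muts <- NULL
    used <- lapply(1:4, function(i) integer(0))
    for (k in seq_len(n_mut)) {
      ex <- exons[k]
      pos <- sample(5:(lens[ex] - 12L), 1)
      if (any(abs(used[[ex]] - pos) < 12L)) next
      used[[ex]] <- c(used[[ex]], pos)
      kind <- sample(c("substitution", "insertion", "deletion"), 1)
      len <- sample(1:4, 1)
      ref_b <- substr(ref$exons[[ex]]$sequence, pos, pos + len - 1L)
      alt <- paste0(sample(c("A", "C", "G"), len, replace = TRUE),
                    collapse = "")
      if (kind == "substitution" && alt == ref_b) next
      muts <- rbind(muts, mutation_record(
        "r", ex, kind, pos, len, if (kind == "deletion") "" else alt))
    }
    if (is.null(muts)) next
    obs <- apply_mutations(ref, muts)
    rep <- scan_disruptions(ref, obs)
    got <- rep$mutations_detected
    # frame conservation: indel balance matches the reported terminal offset
    net <- sum(muts$length[muts$kind == "insertion"]) -
      sum(muts$length[muts$kind == "deletion"])
    expect_identical(rep$raw_indel_sum, as.integer(net))
    # edit equivalence: re-applying the recovered records rebuilds obs
    rebuilt <- apply_mutations(ref, got)
    expect_identical(splice(rebuilt), splice(obs))
    # phase bookkeeping invariant after the edits
    cum <- 0L
    for (ex in obs$exons) {
      expect_identical(ex$phase,
                       if (ex$index == 1L) 0L else (3L - cum %% 3L) %% 3L)
      cum <- cum + nchar(ex$sequence)
    }
  }
})

test_that("premature stop calls agree with brute-force translation", {
  for (fxn in c("galliform", "rodent", "cheetah")) {
    fx <- make_fixture(fxn)
    for (sp in fx$disrupted_species) {
      obs <- apply_mutations(fx$reference,
                             fx$catalog[fx$catalog$species == sp, ])
      rep <- scan_disruptions(fx$reference, obs)
      tr <- translate_cds(splice(obs))
      n_all <- nrow(tr$stops)
      # reported premature stops are a subset of all observed stops, and any
      # stop that is not premature must sit at/after the terminal position
      expect_lte(nrow(rep$premature_stops), n_all)
      if (rep$status == "disrupted" && !rep$stop_loss) {
        expect_identical(n_all - nrow(rep$premature_stops), 1L)
      }
    }
  }
})

test_that("exon FASTA and mutation catalog TSV round-trip exactly", {
  fx <- make_fixture("rodent")
  obs <- fixture_observed(fx)
  fa <- tempfile(fileext = ".fa")
  write_exon_fasta(obs[c("rabbit", "beaver")], fa)
  back <- read_exon_fasta(fa)
  expect_identical(back[["rabbit|focal"]]$exons, obs$rabbit$exons)
  tsv <- tempfile(fileext = ".tsv")
  write_mutation_catalog(fx$catalog, tsv)
  back2 <- read_mutation_catalog(tsv)
  expect_identical(as.data.frame(back2), as.data.frame(fx$catalog),
                   ignore_attr = TRUE)
})
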