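# Worked-example fixtures: synthetic 4-exon reference genes engineered so
# that every catalogued disruption realizes its described consequence
# (premature stops in the named exons, shared deletions, start loss). The
# reference sequences are synthetic, not real COA1; only the catalogued
# mutations and their consequences are guaranteed. Fillers use {A,C,G} only
# (no T), so stop codons can arise solely at the engineered motifs or
# through catalogued substitutions; TAA motifs are placed at positions that
# are read as codons only in the intended frameshift class.

# deterministic filler over {A,C,G} from a small LCG (independent of R's RNG)
.filler <- function(n, seed) {
  x <- seed
  out <- character(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2147483648
    out[i] <- c("A", "C", "G")[x %% 3 + 1]
  }
  out
}

.alt_base <- function(b) c(A = "C", C = "G", G = "A", T = "C")[[b]]

.place <- function(v, at, motif) {
  v[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
  v
}

.galliform_reference <- function() {
  e1 <- c("A", "T", "G", "C", .filler(36, 11))
  e2 <- .filler(110, 22)
  e2 <- .place(e2, 48, "AAC")   # Japanese quail target (-> TAA)
  e2 <- .place(e2, 69, "GAA")   # chicken target (G->T -> TAA)
  e2 <- .place(e2, 94, "TAA")   # stop read in frame class 2 (net -1 bases)
  e3 <- .filler(70, 33)
  e3 <- .place(e3, 38, "TAA")   # class-2 stop
  e3 <- .place(e3, 60, "TAA")   # class-1 stop
  e4 <- .filler(98, 44)
  e4 <- .place(e4, 72, "GAA")   # Amazonian wood quail target (G->T -> TAA)
  e4 <- .place(e4, 83, "TAA")   # class-1 stop
  e4 <- .place(e4, 96, "TAA")   # terminal stop
  gene_model("reference", "focal", vapply(list(e1, e2, e3, e4),
                                          paste0, character(1), collapse = ""))
}

.rodent_reference <- function() {
  e1 <- c("A", "T", "G", "C", .filler(101, 55))
  e2 <- .filler(120, 66)
  e2 <- .place(e2, 44, "TAA")   # class-2 stop (beaver path)
  e2 <- .place(e2, 116, "TAA")  # class-2 stop (rabbit path, after codon 37)
  e3 <- .filler(90, 77)
  e3 <- .place(e3, 71, "TAA")   # class-2 stop (beaver path)
  e4 <- .filler(120, 88)
  e4 <- .place(e4, 12, "TAA")   # class-1 stop (rabbit path)
  e4 <- .place(e4, 118, "TAA")  # terminal stop
  gene_model("reference", "focal", vapply(list(e1, e2, e3, e4),
                                          paste0, character(1), collapse = ""))
}

.feliform_reference <- function() {
  e1 <- c("A", "T", "G", "C", .filler(36, 99))
  e2 <- .filler(110, 111)
  e2 <- .place(e2, 27, "CAA")   # cheetah target (C->T -> TAA)
  e2 <- .place(e2, 47, "TAA")   # class-1 stop ending at base 49 (dup copy)
  e3 <- .filler(70, 122)
  e4 <- .filler(98, 133)
  e4 <- .place(e4, 96, "TAA")   # terminal stop
  gene_model("reference", "focal", vapply(list(e1, e2, e3, e4),
                                          paste0, character(1), collapse = ""))
}

.exon_base <- function(ref, exon, pos) {
  substr(ref$exons[[exon]]$sequence, pos, pos)
}

.galliform_newick <- paste0(
  "((magpie_goose:90,(swan_goose:30,duck:30):60):10,",
  "(australian_brushturkey:80,(white_crested_guan:70,",
  "(helmeted_guineafowl:55,((amazonian_wood_quail:35,",
  "(northern_bobwhite:20,blue_quail:20):15):13,(japanese_quail:44,",
  "((indian_peafowl:3,green_peafowl:3):37,(chicken:35,",
  "((mikado_pheasant:20,(ring_necked_pheasant:15,golden_pheasant:15):5):10,",
  "(turkey:25,((pinnated_grouse:8,gunnison_grouse:8):7,",
  "(rock_ptarmigan:10,black_grouse:10):5):10):5):5):5):4):4):7):15):10):20);")

.rodent_newick <- paste0(
  "(rabbit:82,((sciurus_vulgaris:34,(marmota_marmota:14,",
  "(urocitellus_parryii:12,(spermophilus_dauricus:10,",
  "ictidomys_tridecemlineatus:10):2):2):20):41,",
  "(naked_mole_rat:71,beaver:71):4):7);")

.feliform_newick <- paste0(
  "(spotted_hyena:38,((cheetah:7,puma:7):23,",
  "(domestic_cat:25,(tiger:11,lion:11):14):5):8);")

#' Build a worked-example gene-loss fixture
#'
#' Returns a synthetic intact reference gene, the per-species mutation
#' catalog transcribing the published disruption descriptions, the clade's
#' time-calibrated topology, and the expected scan/event outcomes. Fixtures:
#' `"galliform"` (12 disrupted species, 8 independent events),
#' `"rodent"` (7 species, 4 events), `"sciuridae"` (the shared
#' squirrel event alone), `"cheetah"` (1 event, plus the duplicated-copy
#' record in `dup_catalog`).
#'
#' @param name Fixture name.
#' @return List: `reference` ([gene_model()]), `catalog`
#'   (`mutation_catalog`), `tree` ([status_tree()]), `newick`,
#'   `disrupted_species`, `intact_species`, `expected` (event count, stop
#'   exons for key species), and for `"cheetah"` a `dup_catalog`.
#' @export
make_fixture <- function(name = c("galliform", "rodent", "sciuridae",
                                  "cheetah")) {
  name <- match.arg(name)
  if (name == "galliform") {
    ref <- .galliform_reference()
    cat_ <- catalog(
      mutation_record("chicken", 2, "substitution", 69, 1, "T"),
      mutation_record("amazonian_wood_quail", 4, "substitution", 72, 1, "T"),
      mutation_record(rep(c("indian_peafowl", "green_peafowl"), each = 2),
                      c(1, 4, 1, 4), "deletion", c(37, 31, 37, 31), 1),
      mutation_record(c("pinnated_grouse", "gunnison_grouse",
                        "rock_ptarmigan", "black_grouse"),
                      2, "deletion", 20, 13),
      mutation_record("helmeted_guineafowl", 2, "deletion", 51, 17),
      mutation_record("turkey", 2, "substitution", 7, 2,
                      paste0(.alt_base(.exon_base(ref, 2, 7)),
                             .alt_base(.exon_base(ref, 2, 8)))),
      mutation_record("turkey", 2, "deletion", 37, 1),
      mutation_record("japanese_quail", 2, "substitution", c(48, 50), 1,
                      c("T", "A")),
      mutation_record("mikado_pheasant", 4, "deletion", 40, 11))
    tree <- status_tree(.galliform_newick)
    disrupted <- unique(cat_$species)
    list(name = name, reference = ref, catalog = cat_, tree = tree,
         newick = .galliform_newick,
         disrupted_species = disrupted,
         intact_species = setdiff(tree$phylo$tip.label, disrupted),
         expected = list(n_events = 8L,
                         shared_clades = list(
                           c("indian_peafowl", "green_peafowl"),
                           c("pinnated_grouse", "gunnison_grouse",
                             "rock_ptarmigan", "black_grouse"))))
  } else if (name %in% c("rodent", "sciuridae")) {
    ref <- .rodent_reference()
    sciuridae <- c("urocitellus_parryii", "spermophilus_dauricus",
                   "ictidomys_tridecemlineatus", "marmota_marmota")
    shared_sci <- function(sp) catalog(
      mutation_record(sp, 1, "insertion", 2, 1, "C", anchor_unit = "codon"),
      mutation_record(sp, 2, "insertion", 25, 2, "CA", anchor_unit = "codon"),
      mutation_record(sp, 4, "deletion", 74, 7),
      if (sp == "spermophilus_dauricus") {
        # the shared 2-base insertion extended to five bases in this species
        mutation_record(sp, 4, "insertion", 33, 5, "CACGC",
                        anchor_unit = "codon")
      } else {
        mutation_record(sp, 4, "insertion", 33, 2, "CA", anchor_unit = "codon")
      })
    cat_sci <- do.call(catalog, lapply(sciuridae, shared_sci))
    cat_sci <- catalog(cat_sci,
      mutation_record("marmota_marmota", 1, "insertion", 8, 2, "GC",
                      anchor_unit = "codon"),
      mutation_record("marmota_marmota", 2, "substitution", 26, 1,
                      .alt_base(.exon_base(ref, 2, 76)),
                      anchor_unit = "codon"))
    cat_rabbit <- catalog(
      mutation_record("rabbit", 1, "deletion", 22, 2, anchor_unit = "codon"),
      mutation_record("rabbit", 2, "deletion", c(13, 37), 1,
                      anchor_unit = "codon"),
      mutation_record("rabbit", 3, "insertion", 11, 5, "CCGCA",
                      anchor_unit = "codon"),
      mutation_record("rabbit", 3, "insertion", 17, 1, "G",
                      anchor_unit = "codon"),
      mutation_record("rabbit", 3, "deletion", 23, 1, anchor_unit = "codon"))
    cat_nmr <- catalog(
      mutation_record("naked_mole_rat", 1, "substitution", 3, 1, "A"),
      mutation_record("naked_mole_rat", 1, "deletion", 21, 1,
                      anchor_unit = "codon"))
    cat_beaver <- catalog(
      mutation_record("beaver", 1, "deletion", c(3, 20), 1,
                      anchor_unit = "codon"),
      mutation_record("beaver", 1, "insertion", 33, 4, "CAGC",
                      anchor_unit = "codon"),
      mutation_record("beaver", 2, "deletion", 86, 7),
      mutation_record("beaver", 2, "deletion", 33, 1, anchor_unit = "codon"),
      mutation_record("beaver", 3, "deletion", 12, 1, anchor_unit = "codon"))
    if (name == "sciuridae") {
      sci_newick <- paste0("(sciurus_vulgaris:34,(marmota_marmota:14,",
                           "(urocitellus_parryii:12,(spermophilus_dauricus:10,",
                           "ictidomys_tridecemlineatus:10):2):2):20);")
      tree <- status_tree(sci_newick)
      list(name = name, reference = ref, catalog = cat_sci, tree = tree,
           newick = sci_newick, disrupted_species = sciuridae,
           intact_species = "sciurus_vulgaris",
           expected = list(n_events = 1L))
    } else {
      cat_ <- catalog(cat_rabbit, cat_nmr, cat_sci, cat_beaver)
      tree <- status_tree(.rodent_newick)
      disrupted <- unique(cat_$species)
      list(name = name, reference = ref, catalog = cat_, tree = tree,
           newick = .rodent_newick, disrupted_species = disrupted,
           intact_species = setdiff(tree$phylo$tip.label, disrupted),
           expected = list(n_events = 4L, n_disrupted = 7L,
                           rabbit_n_mutations = 6L,
                           rabbit_stop_exons = c(2L, 4L)))
    }
  } else {
    ref <- .feliform_reference()
    cat_ <- catalog(mutation_record("cheetah", 2, "substitution", 27, 1, "T"))
    dup <- catalog(mutation_record("cheetah_duplicate", 2, "insertion",
                                   11, 1, "C"))
    tree <- status_tree(.feliform_newick)
    list(name = name, reference = ref, catalog = cat_, dup_catalog = dup,
         tree = tree, newick = .feliform_newick,
         disrupted_species = "cheetah",
         intact_species = setdiff(tree$phylo$tip.label, "cheetah"),
         expected = list(n_events = 1L, stop_exon = 2L))
  }
}

#' Observed gene models implied by a fixture
#'
#' Applies each catalogued species' mutations to the fixture reference;
#' species without catalog entries get the reference sequence unchanged.
#'
#' @param fx A fixture from [make_fixture()].
#' @return Named list of [gene_model()] objects, one per tree tip.
#' @export
fixture_observed <- function(fx) {
  out <- list()
  for (sp in fx$tree$phylo$tip.label) {
    muts <- fx$catalog[fx$catalog$species == sp, , drop = FALSE]
    gm <- fx$reference
    gm$species <- sp
    if (nrow(muts) > 0L) gm <- apply_mutations(gm, muts)
    out[[sp]] <- gm
  }
  out
}
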