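test_that("the worked-example catalogs yield the published event counts", {
  fx <- make_fixture("galliform")
  ev <- infer_loss_events(fx$tree, fx$catalog, ref = fx$reference)
  expect_length(ev, 8L)
  # the two multi-species events sit on the stems of their clades
  branches <- vapply(ev, `[[`, character(1), "branch")
  spsets <- lapply(ev, `[[`, "species")
  peafowl <- spsets[[which(vapply(spsets, function(s)
    "indian_peafowl" %in% s, logical(1)))]]
  expect_setequal(peafowl, c("indian_peafowl", "green_peafowl"))
  grouse <- spsets[[which(vapply(spsets, function(s)
    "rock_ptarmigan" %in% s, logical(1)))]]
  expect_setequal(grouse, c("pinnated_grouse", "gunnison_grouse",
                            "rock_ptarmigan", "black_grouse"))
  expect_false(any(vapply(ev, `[[`, logical(1), "homoplastic")))

  fr <- make_fixture("rodent")
  evr <- infer_loss_events(fr$tree, fr$catalog, ref = fr$reference)
  expect_length(evr, 4L)
  expect_identical(length(unique(fr$catalog$species)), 7L)
  # the Daurian ground squirrel's extended insertion still joins the shared
  # Sciuridae event (containment rule)
  sci <- evr[[which(vapply(evr, function(e)
    "spermophilus_dauricus" %in% e$species, logical(1)))]]
  expect_length(sci$species, 4L)
})

test_that("a single disrupted species forms a terminal singleton event", {
  fx <- make_fixture("cheetah")
  ev <- infer_loss_events(fx$tree, fx$catalog, ref = fx$reference)
  expect_length(ev, 1L)
  expect_identical(ev[[1]]$branch, "cheetah")
  expect_identical(ev[[1]]$species, "cheetah")
})

test_that("event inference is invariant to catalog row and species order", {
  fx <- make_fixture("galliform")
  base <- infer_loss_events(fx$tree, fx$catalog, ref = fx$reference)
  key <- function(ev) sort(vapply(ev, `[[`, character(1), "branch"))
  set.seed(5)
  for (i in 1:10) {
    shuf <- fx$catalog[sample(nrow(fx$catalog)), ]
    ev <- infer_loss_events(fx$tree, shuf, ref = fx$reference)
    expect_identical(key(ev), key(base))
  }
})

test_that("shared mutations across a non-monophyletic set are flagged", {
  st <- status_tree("((a:1,b:1):1,(c:1,d:1):1);")
  cat_ <- catalog(
    mutation_record("a", 1, "deletion", 10, 2),
    mutation_record("c", 1, "deletion", 10, 2))
  ev <- infer_loss_events(st, cat_)
  expect_length(ev, 1L)
  expect_true(ev[[1]]$homoplastic)
  expect_setequal(ev[[1]]$species, c("a", "c"))
})

test_that("simulated non-nested losses are recovered exactly", {
  set.seed(77)
  tr <- random_ultrametric(12, depth = 60, seed = 9)
  st <- status_tree(tr)
  bt <- branch_table(st)
  for (iter in 1:40) {
    # pick k branches, none ancestral to another, share one mutation per event
    k <- sample(1:4, 1)
    picked <- integer(0)
    subtree <- function(e) {
      st$phylo$edge[pseudochron:::.edges_below(st, bt$child[e]), 2]
    }
    for (cand in sample(nrow(bt))) {
      disjoint <- all(vapply(picked, function(p) {
        !(bt$child[cand] %in% c(bt$child[p], subtree(p))) &&
          !(bt$child[p] %in% subtree(cand))
      }, logical(1)))
      if (disjoint) picked <- c(picked, cand)
      if (length(picked) == k) break
    }
    cat_ <- do.call(catalog, lapply(seq_along(picked), function(i) {
      tips <- pseudochron:::.tips_below(st, bt$child[picked[i]])
      mutation_record(tips, 1, "deletion", 10 + 20L * i, 2)
    }))
    ev <- infer_loss_events(st, cat_)
    expect_length(ev, length(picked))
    expect_setequal(vapply(ev, `[[`, character(1), "branch"),
                    bt$branch[picked])
  }
})

test_that("branch labeling is complete, idempotent and rejects nesting", {
  fx <- make_fixture("galliform")
  ev <- infer_loss_events(fx$tree, fx$catalog, ref = fx$reference)
  st <- label_branches(fx$tree, ev)
  expect_length(st$labels, nrow(st$phylo$edge))
  expect_identical(sum(st$labels == "mixed"), 8L)
  expect_true(all(st$labels %in% c("functional", "mixed", "pseudogenic")))
  # brute-force check: every branch below a mixed branch is pseudogenic
  for (e in which(st$labels == "mixed")) {
    below <- pseudochron:::.edges_below(st, st$phylo$edge[e, 2])
    expect_true(all(st$labels[below] == "pseudogenic"))
  }
  # grouse-clade internal branches below the grouse stem are pseudogenic
  gnode <- ape::getMRCA(st$phylo, c("pinnated_grouse", "black_grouse"))
  below_g <- pseudochron:::.edges_below(st, gnode)
  expect_true(all(st$labels[below_g] == "pseudogenic"))
  # idempotent
  st2 <- label_branches(st, ev)
  expect_identical(st2$labels, st$labels)
  # zero events: all functional
  st0 <- label_branches(fx$tree, structure(list(), class = "loss_events"))
  expect_true(all(st0$labels == "functional"))
  # singleton on a leaf: one mixed, no pseudogenic
  ev1 <- infer_loss_events(fx$tree,
                           mutation_record("chicken", 2, "substitution",
                                           69, 1, "T"))
  stx <- label_branches(fx$tree, ev1)
  expect_identical(sum(stx$labels == "mixed"), 1L)
  expect_identical(sum(stx$labels == "pseudogenic"), 0L)
  # two events nested on one root-to-leaf path is an error
  # three grouse share a deletion (their MRCA is the grouse crown, which
  # contains pinnated_grouse); pinnated carries only a private mutation, so
  # its terminal event nests inside the crown event
  ev_nested <- infer_loss_events(fx$tree, catalog(
    mutation_record("pinnated_grouse", 1, "deletion", 5, 1),
    mutation_record(c("gunnison_grouse", "rock_ptarmigan", "black_grouse"),
                    2, "deletion", 20, 13)))
  expect_error(label_branches(fx$tree, ev_nested), "nested")
})

test_that("breakpoint detection reports broken adjacencies and moved runs", {
  genes <- c("BLVRA", "VOPP1", "LANCL2", "EGFR", "SEC61G", "COA1",
             "STK17A", "HECW1", "MRPL32", "PSMA2", "C7orf25")
  ref <- gene_order("reference", genes, chromosome = "chr1")
  # identical order: fully conserved
  bird <- gene_order("bird", genes, chromosome = "chrZ")
  rep0 <- detect_breakpoints(ref, bird)
  expect_identical(nrow(rep0$broken), 0L)
  expect_length(rep0$missing_genes, 0L)
  # internal 2-gene block excised to another chromosome
  qgenes <- setdiff(genes, c("LANCL2", "EGFR"))
  q <- gene_order("query", c(qgenes, "LANCL2", "EGFR"),
                  chromosome = c(rep("chr1", length(qgenes)),
                                 "chr4", "chr4"))
  rep1 <- detect_breakpoints(ref, q)
  expect_identical(nrow(rep1$broken), 2L)
  expect_identical(nrow(rep1$moved_segments), 1L)
  expect_identical(rep1$moved_segments$start, "LANCL2")
  # single-gene reference: trivially conserved
  rep2 <- detect_breakpoints(gene_order("r", "COA1"), gene_order("q", "COA1"))
  expect_identical(nrow(rep2$broken), 0L)
  # duplicate symbols in the query are an error naming the symbol
  qq <- gene_order("q", c("COA1", "EGFR"))
  qq$genes <- c("COA1", "COA1")
  expect_error(detect_breakpoints(ref, qq), "COA1")
  # missing genes are listed and their adjacencies broken
  q3 <- gene_order("q3", setdiff(genes, "EGFR"), chromosome = "chr1")
  rep3 <- detect_breakpoints(ref, q3)
  expect_identical(rep3$missing_genes, "EGFR")
  expect_identical(nrow(rep3$broken), 2L)
})

test_that("self-comparison of any gene order has no breakpoints", {
  set.seed(3)
  for (i in 1:20) {
    g <- gene_order("s", paste0("g", sample(30, sample(2:12, 1))),
                    chromosome = "c1")
    expect_identical(nrow(detect_breakpoints(g, g)$broken), 0L)
  }
})
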