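test_that("simulation is a pure function of spec and seed", {
  a <- sim8(3)
  b <- sim8(3)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$alignment$states, b$alignment$states)
  expect_identical(a$truth$branch_counts, b$truth$branch_counts)
  c_ <- sim8(4)
  expect_false(identical(a$sequences, c_$sequences))
})

test_that("the functional regime never emits premature stops", {
  spec <- simulation_spec(tree8_newick, omega_functional = 0.3, sites = 150,
                          seed = 5)
  sim <- simulate_alignment(spec)
  expect_length(sim$truth$pseudogenic_tips, 0L)
  for (s in sim$sequences) {
    expect_identical(nrow(translate_cds(s)$stops), 0L)
  }
  # and the scan agrees: everything intact
  sc <- scan_simulation(sim)
  expect_true(all(sc$status$status == "intact"))
  expect_length(sc$events, 0L)
})

test_that("loss events leave detectable footprints with known truth", {
  sim <- sim8(6, t_p = 12)
  expect_identical(sim$truth$pseudogenic_tips, "t8")
  expect_equal(sim$truth$events$inactivation_age, 12)
  sc <- scan_simulation(sim)
  expect_identical(sc$status$status[sc$status$species == "t8"], "disrupted")
  expect_length(sc$events, 1L)
  expect_identical(sc$events[[1]]$branch, "t8")
  bt <- branch_table(sc$tree)
  expect_identical(bt$label[bt$branch == "t8"], "mixed")
  # invalid event placement is rejected
  expect_error(simulation_spec(tree8_newick, seed = 1,
    loss_events = data.frame(branch = "nope", t_p = 5)), "absent")
  expect_error(simulation_spec(tree8_newick, seed = 1,
    loss_events = data.frame(branch = "t8", t_p = 31)), "within the branch")
})

test_that("omega shifts the realized nonsynonymous/synonymous ratio", {
  ratio <- function(omega, seed) {
    spec <- simulation_spec(tree6_newick, omega_functional = omega,
                            sites = 200, seed = seed)
    cnt <- simulate_alignment(spec)$truth$branch_counts
    sum(cnt$nonsyn) / max(sum(cnt$syn), 1)
  }
  for (s in 1:10) {
    expect_gt(ratio(1, 200 + s), ratio(0.1, 200 + s))
  }
})

test_that("synonymous substitution counts scale with branch length", {
  tot <- NULL
  sites <- 200
  for (s in 1:20) {
    spec <- simulation_spec(tree8_newick, omega_functional = 0.2,
                            sites = sites, seed = 300 + s)
    cnt <- simulate_alignment(spec)$truth$branch_counts
    bt <- branch_table(spec$tree)
    tot <- rbind(tot, data.frame(T = bt$T, syn = cnt$syn))
  }
  # through-origin regression slope of per-branch synonymous counts on
  # branch duration, against the exact per-MY expectation from the
  # simulator generator
  slope <- sum(tot$syn) / sum(tot$T)
  Qmy <- pseudochron:::.sim_q_my(2, 0.2, codon_frequencies("equal"), 0.006)
  syn_mask <- pseudochron:::.codon_env$single & !pseudochron:::.codon_env$nonsyn
  pi_eq <- codon_frequencies("equal")
  exp_rate <- sites * sum(pi_eq * rowSums(Qmy * syn_mask))
  expect_lt(abs(slope - exp_rate) / exp_rate, 0.1)
})

test_that("fixtures reproduce their printed consequences", {
  for (fxn in c("galliform", "rodent", "sciuridae", "cheetah")) {
    fx <- make_fixture(fxn)
    expect_true(is_intact_orf(fx$reference))
    ev <- infer_loss_events(fx$tree, fx$catalog, ref = fx$reference)
    expect_length(ev, fx$expected$n_events)
    obs <- fixture_observed(fx)
    for (sp in fx$disrupted_species) {
      rep <- scan_disruptions(fx$reference, obs[[sp]])
      expect_identical(rep$status, "disrupted")
      # edit equivalence of the recovered catalog
      rebuilt <- apply_mutations(fx$reference, rep$mutations_detected)
      expect_identical(splice(rebuilt), splice(obs[[sp]]))
    }
    for (sp in fx$intact_species) {
      expect_identical(scan_disruptions(fx$reference, obs[[sp]])$status,
                       "intact")
    }
  }
  # cheetah: the duplicated-copy insertion creates its own premature stop
  fc <- make_fixture("cheetah")
  dup <- fc$reference
  dup$species <- "cheetah_duplicate"
  dup <- apply_mutations(dup, fc$dup_catalog)
  rd <- scan_disruptions(fc$reference, dup)
  expect_identical(rd$status, "disrupted")
  expect_identical(unique(rd$premature_stops$exon), 2L)
})

test_that("the rabbit catalog is recovered record-for-record", {
  fx <- make_fixture("rodent")
  obs <- fixture_observed(fx)
  rep <- scan_disruptions(fx$reference, obs$rabbit)
  got <- rep$mutations_detected
  want <- pseudochron:::resolve_positions(
    fx$reference, fx$catalog[fx$catalog$species == "rabbit", ])
  # substitutions and deletions anchor uniquely; insertion anchors can
  # slide between equal-scoring placements, so compare them without position
  key <- function(d) {
    d <- as.data.frame(d)[order(d$exon, d$kind, d$position), ]
    ifelse(d$kind == "insertion",
           paste(d$exon, d$kind, d$length, d$alt),
           paste(d$exon, d$kind, d$position, d$length, d$alt))
  }
  expect_identical(sort(key(got)), sort(key(want)))
})
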