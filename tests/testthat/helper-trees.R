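# shared test scaffolding: small trees and simulation shortcuts

tree8_newick <- paste0(
  "((((t1:15,t2:15):15,(t3:20,t4:20):10):20,",
  "(t5:25,t6:25):25):10,(t7:30,t8:30):30);")

tree6_newick <- "(((t1:10,t2:10):15,(t3:15,t4:15):10):15,(t5:20,t6:20):20);"

sim8 <- function(seed, t_p = 10, sites = 300, omega = 0.15, ...) {
  simulate_alignment(simulation_spec(
    tree8_newick, omega_functional = omega, sites = sites,
    loss_events = data.frame(branch = "t8", t_p = t_p), seed = seed, ...))
}

# near-star tree: tiny internal branches, equal tip depths
near_star_tree <- function(n, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tip <- tr$edge[, 2] <= n
  tr$edge.length[tip] <- 50
  tr$edge.length[!tip] <- 1e-6
  tr
}

random_ultrametric <- function(n, depth = 50, seed = 1) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * depth /
    max(ape::node.depth.edgelength(tr))
  tr
}
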