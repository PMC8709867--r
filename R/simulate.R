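#' Specification for a gene-loss simulation
#'
#' Defines the generative model behind the validation pipeline: codon sites
#' evolve along a time-calibrated tree under MG94xHKY with a per-category
#' omega; on a branch carrying a loss event the process switches, at the
#' true inactivation point, to neutral nucleotide evolution (omega = 1,
#' stop codons tolerated) plus an indel accrual process; descendants of a
#' loss stay pseudogenic (Dollo). Time is converted to substitutions via
#' `subst_rate`, the neutral substitution rate per codon site per MY
#' (default 0.006, i.e. 2e-9 per base per year, a typical mammalian nuclear
#' rate). Indels occur only after inactivation at `indel_rate` per codon
#' site per MY with geometric(0.5) base lengths.
#'
#' @param tree Newick string/file, `phylo`, or [status_tree()] (MY).
#' @param omega_functional dN/dS of functional branches.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default equal over sense codons).
#' @param sites Number of codon sites.
#' @param loss_events data.frame with columns `branch` (child-node name)
#'   and `t_p` (true pseudogenic duration, MY, within the branch).
#' @param subst_rate Neutral substitutions per codon site per MY.
#' @param indel_rate Post-loss indels per codon site per MY.
#' @param indel_geom_p Geometric length parameter for indels.
#' @param seed Mandatory RNG seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(tree, omega_functional = 0.15, kappa = 2,
                            pi = NULL, sites = 300,
                            loss_events = NULL, subst_rate = 0.006,
                            indel_rate = 0.002, indel_geom_p = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  st <- if (inherits(tree, "status_tree")) tree else status_tree(tree)
  if (is.null(pi)) pi <- codon_frequencies("equal")
  if (is.null(loss_events)) {
    loss_events <- data.frame(branch = character(0), t_p = numeric(0))
  }
  bt <- branch_table(st)
  for (i in seq_len(nrow(loss_events))) {
    j <- match(loss_events$branch[i], bt$branch)
    if (is.na(j)) stop("loss event on branch absent from tree: ",
                       loss_events$branch[i])
    if (loss_events$t_p[i] <= 0 || loss_events$t_p[i] >= bt$T[j]) {
      stop("true t_p must lie strictly within the branch duration")
    }
  }
  stopifnot(subst_rate >= 0, indel_rate >= 0)
  structure(list(tree = st, omega_functional = omega_functional,
                 kappa = kappa, pi = pi, sites = sites,
                 loss_events = loss_events, subst_rate = subst_rate,
                 indel_rate = indel_rate, indel_geom_p = indel_geom_p,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# MG94xHKY generator in per-MY units: the omega = 1 matrix has expected rate
# `rate` per codon per MY; synonymous entries are omega-independent, so dS
# accrues at the same clock in every category (the equal-dS premise).
.sim_q_my <- function(kappa, omega, pi, rate) {
  sense_codons()
  S1 <- .codon_env$single * 1
  S1[.codon_env$transition] <- kappa
  base <- S1 * rep(pi, each = length(pi))
  diag(base) <- 0
  c1 <- sum(pi * rowSums(base))  # normalizer at omega = 1
  S <- base
  S[.codon_env$nonsyn] <- S[.codon_env$nonsyn] * omega
  Q <- rate * S / c1
  diag(Q) <- -rowSums(Q)
  Q
}

# nucleotide HKY per-MY generator (neutral regime), rate per base per MY
.sim_qnt_my <- function(kappa, pint, rate) {
  nt <- c("T", "C", "A", "G")
  Q <- matrix(rep(pint, each = 4), 4, 4, dimnames = list(nt, nt))
  ts <- matrix(FALSE, 4, 4, dimnames = list(nt, nt))
  ts["A", "G"] <- ts["G", "A"] <- ts["C", "T"] <- ts["T", "C"] <- TRUE
  Q[ts] <- Q[ts] * kappa
  diag(Q) <- 0
  Q <- rate * Q / sum(pint * rowSums(Q))
  diag(Q) <- -rowSums(Q)
  Q
}

# exact per-site Gillespie on a finite-state generator; returns end states
# and the list of jump events (site, from, to)
.gillespie <- function(states, Q, T) {
  rates <- -diag(Q)
  events <- list()
  for (s in seq_along(states)) {
    t <- 0; cur <- states[s]
    if (is.na(cur)) next
    repeat {
      r <- rates[cur]
      if (r <= 0) break
      t <- t + stats::rexp(1, r)
      if (t > T) break
      prob <- Q[cur, ]; prob[cur] <- 0
      prev <- cur
      cur <- sample.int(length(prob), 1, prob = prob)
      events[[length(events) + 1L]] <- c(s, prev, cur)
    }
    states[s] <- cur
  }
  list(states = states, events = events)
}

#' Simulate a codon alignment with known gene-loss ground truth
#'
#' Evolves codon sequences along the spec's tree by exact stochastic
#' simulation from the rate matrices (see [simulation_spec()]). Returns the
#' gap-aware alignment (deleted codons become gaps; insertions are kept out
#' of the reference-coordinate alignment and reported in the truth table),
#' the unaligned per-tip sequences with insertions applied, and a truth
#' table with per-event inactivation ages and per-branch realized
#' synonymous/nonsynonymous substitution counts. Deterministic given the
#' spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return List: `alignment` ([codon_alignment()]), `sequences` (named
#'   character, indels applied), `root_seq`, `truth` (events, branch_counts,
#'   indels), `tree` (the [status_tree()] with true labels).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  st <- spec$tree
  phy <- st$phylo
  bt <- branch_table(st)
  n_edge <- nrow(phy$edge)
  cods <- sense_codons()
  ntvec <- c("T", "C", "A", "G")
  pint <- .nt_freqs_from_codon(spec$pi)

  Qf <- .sim_q_my(spec$kappa, spec$omega_functional, spec$pi, spec$subst_rate)
  Qnt <- .sim_qnt_my(spec$kappa, pint, spec$subst_rate / 3)
  Pnt_cache <- new.env(parent = emptyenv())

  loss_edge <- match(spec$loss_events$branch, bt$branch)
  # branch regimes: functional / mixed / pseudogenic via event descendants
  labels <- rep("functional", n_edge)
  for (k in seq_along(loss_edge)) {
    e <- loss_edge[k]
    labels[e] <- "mixed"
    labels[.edges_below(st, phy$edge[e, 2])] <- "pseudogenic"
  }
  if (any(labels[loss_edge] == "pseudogenic")) {
    stop("nested loss events in simulation spec")
  }
  st$labels <- labels

  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  root_codons <- sample.int(length(cods), spec$sites, replace = TRUE,
                            prob = spec$pi)
  root_seq <- paste0(cods[root_codons], collapse = "")
  # lineage state: list(codons=int vector) while functional;
  # list(nt=char vector with NA, ins=list) once pseudogenic
  states <- vector("list", length(phy$tip.label) + phy$Nnode)
  states[[root]] <- list(codons = root_codons, functional = TRUE, ins = list())
  counts <- data.frame(branch = bt$branch, syn = 0L, nonsyn = 0L,
                       stringsAsFactors = FALSE)
  indel_log <- list()

  eord <- .preorder_edges(phy)  # parents before children
  classify <- function(ev) {
    # ev = (site, from, to) in codon states
    if (.codon_env$nonsyn[ev[2], ev[3]]) "nonsyn" else "syn"
  }

  for (e in eord) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    T <- bt$T[e]
    stt <- states[[par]]
    lab <- labels[e]
    t_pseudo <- if (lab == "mixed") {
      spec$loss_events$t_p[match(e, loss_edge)]
    } else if (lab == "pseudogenic") T else 0
    t_func <- T - t_pseudo

    if (stt$functional && t_func > 0) {
      g <- .gillespie(stt$codons, Qf, t_func)
      stt$codons <- g$states
      for (ev in g$events) {
        if (classify(ev) == "syn") counts$syn[e] <- counts$syn[e] + 1L
        else counts$nonsyn[e] <- counts$nonsyn[e] + 1L
      }
    }
    if (t_pseudo > 0) {
      if (stt$functional) {
        stt <- list(nt = strsplit(paste0(cods[stt$codons], collapse = ""),
                                  "")[[1]],
                    functional = FALSE, ins = stt$ins)
      }
      live <- which(!is.na(stt$nt))
      # neutral substitutions: exact endpoint sampling is enough for states,
      # but realized counts are wanted, so jump-simulate here too
      ntidx <- match(stt$nt[live], ntvec)
      g <- .gillespie(ntidx, Qnt, t_pseudo)
      for (ev in g$events) {
        pos <- live[ev[1]]
        syn_change <- .nt_event_is_syn(stt$nt, pos, ntvec[ev[3]])
        if (syn_change) counts$syn[e] <- counts$syn[e] + 1L
        else counts$nonsyn[e] <- counts$nonsyn[e] + 1L
        stt$nt[pos] <- ntvec[ev[3]]
      }
      stt$nt[live] <- ntvec[g$states]
      # indel accrual
      n_ind <- stats::rpois(1, spec$indel_rate * spec$sites * t_pseudo)
      for (k in seq_len(n_ind)) {
        len <- stats::rgeom(1, spec$indel_geom_p) + 1L
        alive <- which(!is.na(stt$nt))
        if (length(alive) < len + 3L) break
        if (stats::runif(1) < 0.5) {
          at <- sample(alive, 1)
          stt$ins[[length(stt$ins) + 1L]] <-
            list(after = at,
                 bases = paste0(sample(ntvec, len, replace = TRUE,
                                       prob = pint), collapse = ""))
          indel_log[[length(indel_log) + 1L]] <-
            data.frame(branch = bt$branch[e], kind = "insertion",
                       after = at, length = len)
        } else {
          start <- sample(seq_len(length(alive) - len + 1L), 1)
          stt$nt[alive[start:(start + len - 1L)]] <- NA
          indel_log[[length(indel_log) + 1L]] <-
            data.frame(branch = bt$branch[e], kind = "deletion",
                       after = alive[start], length = len)
        }
      }
    }
    states[[ch]] <- stt
  }

  tips <- seq_along(phy$tip.label)
  aligned <- vapply(tips, function(i) {
    stt <- states[[i]]
    v <- if (stt$functional) strsplit(paste0(cods[stt$codons], collapse = ""),
                                      "")[[1]] else stt$nt
    v[is.na(v)] <- "-"
    paste0(v, collapse = "")
  }, character(1))
  names(aligned) <- phy$tip.label
  sequences <- vapply(tips, function(i) {
    stt <- states[[i]]
    if (stt$functional) {
      paste0(cods[stt$codons], collapse = "")
    } else {
      v <- stt$nt
      ins <- stt$ins
      out <- as.list(ifelse(is.na(v), "", v))
      for (iv in ins) out[[iv$after]] <- paste0(out[[iv$after]], iv$bases)
      paste0(unlist(out), collapse = "")
    }
  }, character(1))
  names(sequences) <- phy$tip.label

  pseudo_tips <- phy$tip.label[vapply(tips, function(i)
    !states[[i]]$functional, logical(1))]
  aln <- codon_alignment(aligned, pseudogenic = pseudo_tips)

  events <- spec$loss_events
  if (nrow(events) > 0L) {
    events$child_age <- bt$child_age[loss_edge]
    events$inactivation_age <- events$child_age + events$t_p
  }
  list(alignment = aln, sequences = sequences, root_seq = root_seq,
       truth = list(events = events, branch_counts = counts,
                    indels = if (length(indel_log)) do.call(rbind, indel_log)
                             else NULL,
                    pseudogenic_tips = pseudo_tips),
       tree = st)
}

.nt_freqs_from_codon <- function(pi) {
  sense_codons()
  m <- .codon_env$ntmat
  nt <- c("T", "C", "A", "G")
  f <- vapply(nt, function(b) sum(pi * rowSums(m == b)) / 3, numeric(1))
  f / sum(f)
}

# does changing base `pos` (1-based within the reference frame) to `new`
# preserve the encoded amino acid of its (positional) codon?
.nt_event_is_syn <- function(ntv, pos, new) {
  cs <- pos - (pos - 1L) %% 3L
  old_cod <- ntv[cs:(cs + 2L)]
  if (anyNA(old_cod)) return(FALSE)
  new_cod <- old_cod
  new_cod[pos - cs + 1L] <- new
  tab <- .codon_table()
  identical(unname(tab[paste0(old_cod, collapse = "")]),
            unname(tab[paste0(new_cod, collapse = "")]))
}

#' Simulate correlated retention and fiber-composition traits
#'
#' White (fast-glycolytic) fiber percentage evolves as reflected Brownian
#' motion on [0, 100] along the tree; pink and red percentages split the
#' remainder in a fixed ratio plus noise. Retention is drawn from the
#' phylogenetic binary model used by [fit_phylo_logistic()]: marginal
#' logit P(retention) = beta0 + beta1 white_pct, with between-species
#' dependence exp(-alpha d_ij) induced via a Gaussian copula.
#'
#' @param st A [status_tree()] or ultrametric `phylo`.
#' @param beta0,beta1 Logit-scale intercept and slope on white percentage.
#' @param alpha Phylogenetic signal of the retention process (1/MY).
#' @param white_root Root state of the white percentage.
#' @param sigma2_white BM variance of white percentage per MY.
#' @param pink_ratio Mean share of the non-white remainder that is pink.
#' @param seed Mandatory RNG seed.
#' @return A trait data.frame: species, retention, white_pct, pink_pct,
#'   red_pct.
#' @export
simulate_traits <- function(st, beta0, beta1, alpha, white_root = 50,
                            sigma2_white = 8, pink_ratio = 0.4, seed) {
  if (missing(seed)) stop("seed is mandatory")
  phy <- if (inherits(st, "status_tree")) st$phylo else st
  set.seed(seed)
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  vals <- rep(NA_real_, n_node)
  vals[root] <- white_root
  eord <- .preorder_edges(phy)
  reflect <- function(x) {
    while (x < 0 || x > 100) x <- ifelse(x < 0, -x, 200 - x)
    x
  }
  for (e in eord) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    vals[ch] <- reflect(vals[par] +
                          stats::rnorm(1, 0, sqrt(sigma2_white *
                                                    phy$edge.length[e])))
  }
  white <- vals[seq_len(n_tip)]
  rem <- 100 - white
  pr <- pmin(pmax(pink_ratio + stats::rnorm(n_tip, 0, 0.05), 0), 1)
  pink <- rem * pr
  red <- rem - pink
  D <- ape::cophenetic.phylo(phy)
  C <- exp(-alpha * D)
  eta <- beta0 + beta1 * white
  retention <- .sim_correlated_binary(eta, C)
  data.frame(species = phy$tip.label, retention = retention,
             white_pct = white, pink_pct = pink, red_pct = red,
             stringsAsFactors = FALSE)
}

#' Scan a simulated dataset and reconstruct its loss events
#'
#' Runs the forensic chain on [simulate_alignment()] output: wraps the root
#' sequence and every simulated tip as single-exon gene models (padded with
#' a start codon and terminal stop so the ORF conventions apply), scans each
#' tip against the root reference, clusters the detected disruptions into
#' loss events and labels the tree. This is the scan -> events -> label
#' front half of the validation pipeline; [branch_omegas_for_dating()] and
#' [date_all()] complete it.
#'
#' @param sim Output of [simulate_alignment()].
#' @return List: `status` (per-tip data.frame), `catalogs` (detected
#'   mutations of disrupted tips), `events`, `tree` (labeled
#'   [status_tree()]).
#' @export
scan_simulation <- function(sim) {
  pad <- function(s) paste0("ATG", s, "TAA")
  ref <- gene_model("reference", "sim", pad(sim$root_seq))
  tips <- names(sim$sequences)
  reports <- lapply(tips, function(sp) {
    scan_disruptions(ref, gene_model(sp, "sim", pad(sim$sequences[[sp]])))
  })
  names(reports) <- tips
  status <- data.frame(
    species = tips,
    status = vapply(reports, `[[`, character(1), "status"),
    stringsAsFactors = FALSE, row.names = NULL)
  disrupted <- status$species[status$status == "disrupted"]
  catalogs <- do.call(rbind, lapply(reports[disrupted], function(r)
    r$mutations_detected))
  st <- sim$tree
  st$labels <- rep("functional", nrow(st$phylo$edge))
  events <- infer_loss_events(st, catalogs)
  st <- label_branches(st, events)
  list(status = status, catalogs = catalogs, events = events, tree = st)
}
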