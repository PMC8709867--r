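# MG94xHKY codon substitution model on the 61 sense codons of the standard
# nuclear code. Single-nucleotide exchanges only; transitions weighted by
# kappa, nonsynonymous exchanges by omega, targets by codon frequency pi.

.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the standard nuclear code
#'
#' @return Character vector of the 61 sense codons (TAA/TAG/TGA excluded),
#'   in fixed lexicographic order.
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$codons)) {
    nt <- c("T", "C", "A", "G")
    all64 <- apply(expand.grid(nt, nt, nt, stringsAsFactors = FALSE)[, 3:1],
                   1, paste0, collapse = "")
    all64 <- sort(all64)
    tab <- .codon_table()
    .codon_env$codons <- all64[tab[all64] != "*"]
    .codon_env$aa <- tab[.codon_env$codons]
    # pairwise single-step structure
    n <- length(.codon_env$codons)
    m1 <- matrix(unlist(strsplit(.codon_env$codons, "")), ncol = 3, byrow = TRUE)
    diffpos <- matrix(0L, n, n)
    for (k in 1:3) diffpos <- diffpos + outer(m1[, k], m1[, k], "!=")
    single <- diffpos == 1L
    ts_pair <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
    transition <- matrix(FALSE, n, n)
    for (k in 1:3) {
      transition <- transition | (single & outer(m1[, k], m1[, k], ts_pair) &
                                    (diffpos == 1L))
    }
    .codon_env$single <- single
    .codon_env$transition <- transition & single
    .codon_env$nonsyn <- single & outer(.codon_env$aa, .codon_env$aa, "!=")
    .codon_env$ntmat <- m1
  }
  .codon_env$codons
}

#' Codon frequency vectors
#'
#' Builds the 61-codon equilibrium frequency vector: `equal`, `f1x4`
#' (products of overall nucleotide frequencies) or `f3x4` (products of
#' position-specific nucleotide frequencies), renormalized over sense codons.
#'
#' @param mode One of `"equal"`, `"f1x4"`, `"f3x4"`.
#' @param sequences Character vector of in-frame CDS strings (required for
#'   the empirical modes).
#' @return Named numeric vector over [sense_codons()], summing to 1.
#' @export
codon_frequencies <- function(mode = c("f3x4", "f1x4", "equal"),
                              sequences = NULL) {
  mode <- match.arg(mode)
  cods <- sense_codons()
  if (mode == "equal") {
    return(setNames(rep(1 / length(cods), length(cods)), cods))
  }
  if (is.null(sequences)) stop("empirical codon frequencies need sequences")
  s <- gsub("-", "", toupper(paste0(sequences, collapse = "")))
  n <- nchar(s) - nchar(s) %% 3L
  bases <- strsplit(substr(s, 1, n), "")[[1]]
  pos <- rep_len(1:3, length(bases))
  nt <- c("T", "C", "A", "G")
  m <- .codon_env$ntmat
  if (mode == "f1x4") {
    f <- (table(factor(bases, nt)) + 1) / (length(bases) + 4)
    pi <- as.numeric(f[m[, 1]] * f[m[, 2]] * f[m[, 3]])
  } else {
    f <- sapply(1:3, function(k) {
      (table(factor(bases[pos == k], nt)) + 1) / (sum(pos == k) + 4)
    })
    pi <- as.numeric(f[m[, 1], 1] * f[m[, 2], 2] * f[m[, 3], 3])
  }
  setNames(pi / sum(pi), cods)
}

#' Build the MG94xHKY instantaneous rate matrix
#'
#' Off-diagonal entries are zero for multi-nucleotide changes; a single-step
#' change i -> j has rate proportional to pi_j, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes. The matrix is
#' scaled so the expected substitution rate at equilibrium is one:
#' sum_i pi_i sum_(j != i) q_ij = 1.
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega Nonsynonymous/synonymous ratio (> 0).
#' @param pi Codon frequency vector over [sense_codons()].
#' @return 61 x 61 rate matrix (rows sum to zero).
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  cods <- sense_codons()
  stopifnot(kappa > 0, omega > 0, length(pi) == length(cods))
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("invalid pi vector")
  S <- .codon_env$single * 1
  S[.codon_env$transition] <- kappa
  S[.codon_env$nonsyn] <- S[.codon_env$nonsyn] * omega
  Q <- S * rep(pi, each = length(pi))
  diag(Q) <- 0
  scale <- sum(pi * rowSums(Q))
  Q <- Q / scale
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(cods, cods)
  Q
}

# eigendecomposition of a reversible Q for fast transition matrices
.decompose_q <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values,
       U = e$vectors / sp,        # rows scaled: diag(1/sp) %*% V
       Uinv = t(e$vectors * sp))  # t(diag(sp) %*% V)
}

.pmat <- function(dec, t) {
  P <- dec$U %*% (exp(dec$vals * t) * dec$Uinv)
  P[P < 0] <- 0
  P
}

# expected synonymous / nonsynonymous substitution fractions of a unit-rate Q
.syn_fraction <- function(Q, pi) {
  syn <- .codon_env$single & !.codon_env$nonsyn
  sum(pi * rowSums(Q * syn))
}

#' Gap-aware codon alignment
#'
#' Stores aligned in-frame coding sequences as codon-state indices over
#' [sense_codons()]; gaps and ambiguous codons are missing (NA). Stop codons
#' are an error in rows flagged functional and are recoded as missing in
#' rows flagged pseudogenic (the model runs on sense codons only).
#'
#' @param sequences Named character vector of aligned CDS strings (equal
#'   length, multiple of 3; `-` for gaps).
#' @param pseudogenic Character vector of row names in which stop codons are
#'   tolerated.
#' @return A `codon_alignment`: `taxa`, integer `states` matrix (taxa x
#'   sites), `n_sites`.
#' @export
codon_alignment <- function(sequences, pseudogenic = character(0)) {
  stopifnot(!is.null(names(sequences)))
  w <- unique(nchar(sequences))
  if (length(w) != 1L || w %% 3L != 0L) {
    stop("sequences must be aligned and of equal length divisible by 3")
  }
  cods <- sense_codons()
  tab <- .codon_table()
  n_sites <- w / 3L
  states <- matrix(NA_integer_, length(sequences), n_sites,
                   dimnames = list(names(sequences), NULL))
  starts <- 3L * seq_len(n_sites) - 2L
  for (i in seq_along(sequences)) {
    cs <- substring(toupper(sequences[[i]]), starts, starts + 2L)
    idx <- match(cs, cods)
    is_stop <- cs %in% c("TAA", "TAG", "TGA")
    if (any(is_stop)) {
      if (!(names(sequences)[i] %in% pseudogenic)) {
        stop("in-frame stop codon in functional row ", names(sequences)[i],
             " at site ", which(is_stop)[1L])
      }
    }
    states[i, ] <- idx
  }
  structure(list(taxa = names(sequences), states = states,
                 n_sites = n_sites, sequences = sequences),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codon sites (%.1f%% missing)\n",
              length(x$taxa), x$n_sites, 100 * mean(is.na(x$states))))
  invisible(x)
}

# unique site patterns and weights
.compress_patterns <- function(states) {
  key <- apply(states, 2, paste0, collapse = ",")
  u <- !duplicated(key)
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]))
}

#' Felsenstein-pruning log-likelihood under MG94xHKY
#'
#' Computes the phylogenetic log-likelihood of a codon alignment, summing
#' site log-likelihoods with the root weighted by the equilibrium codon
#' frequencies. Gaps/missing codons contribute all-ones partials. Transition
#' probabilities come from the matrix exponential of the branch category's
#' rate matrix scaled by its length (expected substitutions per codon).
#'
#' @param st A [status_tree()] (or `phylo`) whose tips match the alignment.
#' @param aln A [codon_alignment()].
#' @param params List: `kappa`, `omega` (named vector by category), `pi`,
#'   `branch_lengths` (per edge, in the tree's edge order), `categories`
#'   (per edge, names into `omega`).
#' @return Total log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(st, aln, params) {
  phy <- if (inherits(st, "status_tree")) st$phylo else st
  eng <- .likelihood_engine(phy, aln)
  eng$loglik(params)
}

# Reusable likelihood engine with cached tip partials and postorder.
# Returns closures sharing precomputed structures.
.likelihood_engine <- function(phy, aln) {
  stopifnot(inherits(phy, "phylo"))
  if (!setequal(phy$tip.label, aln$taxa)) {
    stop("tree tips and alignment taxa differ: ",
         paste(symdiff <- union(setdiff(phy$tip.label, aln$taxa),
                                setdiff(aln$taxa, phy$tip.label)),
               collapse = ", "))
  }
  pat <- .compress_patterns(aln$states[phy$tip.label, , drop = FALSE])
  S <- ncol(pat$states)
  w <- pat$weights
  nst <- length(sense_codons())
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  edge <- phy$edge
  po <- ape::reorder.phylo(phy, "postorder")
  eord <- match(paste(po$edge[, 1], po$edge[, 2]), paste(edge[, 1], edge[, 2]))
  # tip partial matrices (nst x S), shared across parameter values
  tipL <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    M <- matrix(0, nst, S)
    idx <- pat$states[i, ]
    M[cbind(ifelse(is.na(idx), 1L, idx), seq_len(S))] <- 1
    M[, is.na(idx)] <- 1
    tipL[[i]] <- M
  }
  root <- setdiff(edge[, 1], edge[, 2])[1]

  pmats <- function(params) {
    cats <- unique(params$categories)
    decs <- lapply(cats, function(cc) {
      Q <- build_rate_matrix(params$kappa, params$omega[[cc]], params$pi)
      .decompose_q(Q, params$pi)
    })
    names(decs) <- cats
    lapply(seq_len(nrow(edge)), function(e) {
      .pmat(decs[[params$categories[e]]], params$branch_lengths[e])
    })
  }

  # full postorder pass; returns per-node partials and log-scalers
  downpass <- function(P) {
    part <- vector("list", n_node)
    lsc <- matrix(0, n_node, S)
    for (i in seq_len(n_tip)) part[[i]] <- tipL[[i]]
    for (k in seq_along(eord)) {
      e <- eord[k]
      par <- edge[e, 1]; ch <- edge[e, 2]
      contrib <- P[[e]] %*% part[[ch]]
      contrib[contrib < 1e-300] <- 1e-300
      if (is.null(part[[par]])) {
        part[[par]] <- contrib
        lsc[par, ] <- lsc[ch, ]
      } else {
        part[[par]] <- part[[par]] * contrib
        lsc[par, ] <- lsc[par, ] + lsc[ch, ]
      }
      pp <- part[[par]]
      mx <- pp[cbind(max.col(t(pp), ties.method = "first"), seq_len(S))]
      part[[par]] <- pp * rep(1 / mx, each = nst)
      lsc[par, ] <- lsc[par, ] + log(mx)
    }
    list(part = part, lsc = lsc)
  }

  loglik_from_down <- function(dp, pi) {
    site <- colSums(dp$part[[root]] * pi)
    if (any(!is.finite(log(site) + dp$lsc[root, ]))) {
      stop("non-finite likelihood at site pattern ",
           which(!is.finite(log(site) + dp$lsc[root, ]))[1L])
    }
    sum(w * (log(site) + dp$lsc[root, ]))
  }

  list(
    n_patterns = S,
    weights = w,
    edge = edge,
    root = root,
    pmats = pmats,
    downpass = downpass,
    loglik = function(params) {
      loglik_from_down(downpass(pmats(params)), params$pi)
    },
    # per-branch cached objects for single-branch-length optimization:
    # B (outside partial at parent end, excluding edge) and D (below child)
    branch_cache = function(params) {
      P <- pmats(params)
      dp <- downpass(P)
      part <- dp$part; lsc <- dp$lsc
      # outside partials: for edge e = (par, ch), Bmat[[e]] is the partial of
      # all data outside the subtree under e, evaluated at par (with scaler)
      A <- vector("list", n_node); Alsc <- matrix(0, n_node, S)
      A[[root]] <- matrix(params$pi, nst, S)
      Bmat <- vector("list", nrow(edge)); Blsc <- vector("list", nrow(edge))
      for (k in rev(seq_along(eord))) {
        e <- eord[k]
        par <- edge[e, 1]; ch <- edge[e, 2]
        sibs <- setdiff(which(edge[, 1] == par), e)
        B <- A[[par]]
        Bl <- Alsc[par, ]
        for (se in sibs) {
          contrib <- P[[se]] %*% part[[edge[se, 2]]]
          contrib[contrib < 1e-300] <- 1e-300
          B <- B * contrib
          Bl <- Bl + lsc[edge[se, 2], ]
        }
        mx <- B[cbind(max.col(t(B), ties.method = "first"), seq_len(S))]
        B <- B * rep(1 / mx, each = nst)
        Bl <- Bl + log(mx)
        A[[ch]] <- crossprod(P[[e]], B)
        Alsc[ch, ] <- Bl
        Bmat[[e]] <- B
        Blsc[[e]] <- Bl
      }
      list(P = P, part = part, lsc = lsc, B = Bmat, Blsc = Blsc)
    },
    branch_loglik = function(cache, e, t, dec) {
      Pm <- .pmat(dec, t)
      ch <- edge[e, 2]
      site <- colSums(cache$B[[e]] * (Pm %*% cache$part[[ch]]))
      site[site < 1e-300] <- 1e-300
      sum(w * (log(site) + cache$Blsc[[e]] + cache$lsc[ch, ]))
    }
  )
}
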