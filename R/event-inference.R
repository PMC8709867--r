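#' Cluster shared disruptions into independent gene-loss events
#'
#' Species whose mutation catalogs share at least one identical inactivating
#' mutation are grouped into one loss event under Dollo parsimony (a complex
#' character is lost once and never regained). Mutation identity requires
#' equal exon, kind, resolved base position, length and alt; in addition a
#' mutation that contains a shared mutation's interval at the same anchor
#' (e.g. a longer insertion at the same position) counts as the shared
#' mutation plus a private extension. Each event is assigned to the stem
#' branch of its species set's MRCA (the terminal branch for singletons); a
#' shared mutation spanning a non-monophyletic set keeps a single MRCA event
#' but is flagged homoplastic.
#'
#' @param st A [status_tree()] whose tips cover the catalog species.
#' @param catalogs A `mutation_catalog` data.frame covering one or more
#'   species, or a list of such tables.
#' @param ref Optional reference [gene_model()], required to resolve
#'   codon-anchored records to base coordinates.
#' @return A `loss_events` object: list of events, each with `id`, `species`,
#'   `branch` (child-node name), `node`, `shared` and `private` mutation
#'   tables, and `homoplastic` flag.
#' @export
infer_loss_events <- function(st, catalogs, ref = NULL) {
  stopifnot(inherits(st, "status_tree"))
  if (is.list(catalogs) && !is.data.frame(catalogs)) {
    catalogs <- do.call(rbind, lapply(catalogs, as.data.frame))
  }
  catalogs <- as.data.frame(catalogs)
  if (nrow(catalogs) == 0L) {
    return(structure(list(), class = "loss_events"))
  }
  if (any(catalogs$anchor_unit == "codon")) {
    if (is.null(ref)) stop("codon-anchored records require a reference gene model")
    catalogs <- resolve_positions(ref, catalogs)
  }
  species <- unique(catalogs$species)
  missing_sp <- setdiff(species, st$phylo$tip.label)
  if (length(missing_sp) > 0L) {
    stop("catalog species not on tree: ", paste(missing_sp, collapse = ", "))
  }

  # union-find over species joined by shared mutations
  parent <- seq_along(species)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(i, j) parent[find(i)] <<- find(j)
  n_sp <- length(species)
  shared_pairs <- list()
  if (n_sp > 1L) {
    for (i in seq_len(n_sp - 1L)) {
      for (j in seq(i + 1L, n_sp)) {
        mi <- catalogs[catalogs$species == species[i], , drop = FALSE]
        mj <- catalogs[catalogs$species == species[j], , drop = FALSE]
        if (.any_shared(mi, mj)) link(i, j)
      }
    }
  }
  comp <- vapply(seq_len(n_sp), find, integer(1))

  events <- list()
  for (cid in unique(comp)) {
    sp_set <- species[comp == cid]
    node <- .mrca_node(st, sp_set)
    clade_tips <- .tips_below(st, node)
    homoplastic <- !setequal(clade_tips, sp_set) && length(sp_set) > 1L
    muts <- catalogs[catalogs$species %in% sp_set, , drop = FALSE]
    shared <- .shared_subset(muts, sp_set)
    priv <- muts[!rownames(muts) %in% rownames(shared), , drop = FALSE]
    events[[length(events) + 1L]] <- list(
      id = NA_integer_,
      species = sort(sp_set),
      node = node,
      branch = st$node_names[node],
      shared = shared,
      private = priv,
      homoplastic = homoplastic)
  }
  # deterministic order: by branch child-node name
  ord <- order(vapply(events, `[[`, character(1), "branch"))
  events <- events[ord]
  for (i in seq_along(events)) events[[i]]$id <- i
  structure(events, class = "loss_events")
}

# do catalogs mi and mj share at least one mutation (identity or containment)?
.any_shared <- function(mi, mj) {
  for (a in seq_len(nrow(mi))) {
    for (b in seq_len(nrow(mj))) {
      if (.muts_match(mi[a, ], mj[b, ])) return(TRUE)
    }
  }
  FALSE
}

.muts_match <- function(x, y) {
  if (x$exon != y$exon || x$kind != y$kind) return(FALSE)
  if (x$kind == "substitution") {
    return(x$position == y$position && x$length == y$length && x$alt == y$alt)
  }
  if (x$kind == "insertion") {
    # same anchor; one insertion may extend the other
    return(x$position == y$position)
  }
  # deletion: identity, or one interval contains the other
  a <- c(x$position, x$position + x$length - 1L)
  b <- c(y$position, y$position + y$length - 1L)
  (a[1] <= b[1] && a[2] >= b[2]) || (b[1] <= a[1] && b[2] >= a[2])
}

# mutations matched (identity/containment) in >= 2 species of the set
.shared_subset <- function(muts, sp_set) {
  if (length(sp_set) < 2L) return(muts[0, , drop = FALSE])
  keep <- logical(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    others <- muts[muts$species != muts$species[i], , drop = FALSE]
    for (j in seq_len(nrow(others))) {
      if (.muts_match(muts[i, ], others[j, ])) { keep[i] <- TRUE; break }
    }
  }
  muts[keep, , drop = FALSE]
}

#' @export
print.loss_events <- function(x, ...) {
  cat(sprintf("<loss_events> %d independent event(s)\n", length(x)))
  for (ev in x) {
    cat(sprintf("  [%d] branch %s: %d species (%s)%s\n", ev$id, ev$branch,
                length(ev$species), paste(ev$species, collapse = ", "),
                if (ev$homoplastic) " [homoplastic]" else ""))
  }
  invisible(x)
}

#' Label tree branches from loss events
#'
#' Event stem branches become `mixed`; every branch below a mixed branch
#' becomes `pseudogenic`; all remaining branches stay `functional`. Two
#' events nested on one root-to-leaf path are an error (a lineage cannot
#' lose the gene twice under Dollo parsimony). Labeling is idempotent.
#'
#' @param st A [status_tree()].
#' @param events A `loss_events` object from [infer_loss_events()].
#' @return The `status_tree` with updated branch labels.
#' @export
label_branches <- function(st, events) {
  stopifnot(inherits(st, "status_tree"))
  labels <- rep("functional", nrow(st$phylo$edge))
  nodes <- vapply(events, `[[`, integer(1), "node")
  for (i in seq_along(nodes)) {
    below_i <- st$phylo$edge[.edges_below(st, nodes[i]), 2]
    if (any(nodes[-i] %in% c(below_i, nodes[i])[-1]) ||
        any(nodes[-i] %in% below_i)) {
      stop("nested loss events on one root-to-leaf path (branches ",
           st$node_names[nodes[i]], " and ",
           paste(st$node_names[intersect(nodes[-i], below_i)], collapse = ","),
           ")")
    }
  }
  for (nd in nodes) {
    stem <- .stem_edge(st, nd)
    if (length(stem) == 0L) stop("event assigned to the root: no stem branch")
    labels[stem] <- "mixed"
    labels[.edges_below(st, nd)] <- "pseudogenic"
  }
  st$labels <- labels
  st
}
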