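#' Time-calibrated status trees
#'
#' A `status_tree` wraps a rooted ultrametric `ape::phylo` tree with branch
#' lengths in million years (MY) and attaches one label per branch:
#' `functional`, `mixed` (the gene was lost partway along the branch) or
#' `pseudogenic`. Branches are identified by their child node: tip labels for
#' terminal branches, node labels (or `node<k>`) for internal ones.
#'
#' @param tree An `ape::phylo` object, a Newick string, or a Newick file path.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return An object of class `status_tree`.
#' @export
status_tree <- function(tree, tol = 1e-6) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths (MY)")
  if (!ape::is.ultrametric(tree, option = 2, tol = tol)) {
    stop("tree is not ultrametric within tolerance ", tol)
  }
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(n_tip)]) - depth
  ages[seq_len(n_tip)][abs(ages[seq_len(n_tip)]) < tol * max(depth)] <- 0
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    tree$node.label <- paste0("node", seq_len(tree$Nnode) + n_tip)
  }
  node_names <- c(tree$tip.label, tree$node.label)
  st <- structure(list(
    phylo = tree,
    ages = ages,
    node_names = node_names,
    labels = rep("functional", nrow(tree$edge))
  ), class = "status_tree")
  st
}

#' @export
print.status_tree <- function(x, ...) {
  cat(sprintf("<status_tree> %d tips, root age %.2f MY\n",
              length(x$phylo$tip.label), max(x$ages)))
  print(table(x$labels))
  invisible(x)
}

#' Per-branch summary of a status tree
#'
#' @param st A [status_tree()].
#' @return data.frame with branch id (child node name), parent/child node
#'   numbers, duration `T` (MY), child age (MY) and label.
#' @export
branch_table <- function(st) {
  e <- st$phylo$edge
  data.frame(branch = st$node_names[e[, 2]],
             parent = e[, 1], child = e[, 2],
             T = st$ages[e[, 1]] - st$ages[e[, 2]],
             child_age = st$ages[e[, 2]],
             label = st$labels,
             stringsAsFactors = FALSE)
}

# edge index whose child is `node`
.stem_edge <- function(st, node) which(st$phylo$edge[, 2] == node)

# node number of the MRCA of a species set (the node itself for singletons)
.mrca_node <- function(st, species) {
  tips <- match(species, st$phylo$tip.label)
  if (anyNA(tips)) stop("species not in tree: ",
                        paste(species[is.na(tips)], collapse = ", "))
  if (length(tips) == 1L) tips else ape::getMRCA(st$phylo, tips)
}

.tips_below <- function(st, node) {
  n_tip <- length(st$phylo$tip.label)
  if (node <= n_tip) return(st$phylo$tip.label[node])
  ape::extract.clade(st$phylo, node)$tip.label
}

# edge indices ordered so every parent precedes its children
.preorder_edges <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  rev(match(paste(po$edge[, 1], po$edge[, 2]),
            paste(phy$edge[, 1], phy$edge[, 2])))
}

# all edge indices in the subtree below `node` (excluding its stem edge)
.edges_below <- function(st, node) {
  e <- st$phylo$edge
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- which(e[, 1] == nd)
    out <- c(out, kids)
    stack <- c(stack, e[kids, 2])
  }
  out
}
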