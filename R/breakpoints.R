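#' Signed gene orders and adjacency breakpoints
#'
#' A `gene_order` is the ordered list of gene symbols flanking a focal locus
#' in one species, with optional transcriptional orientation and
#' chromosome/scaffold assignment per gene. Orientation is ignored for
#' adjacency comparisons.
#'
#' @param species Species identifier.
#' @param genes Character vector of gene symbols (unique).
#' @param strand Optional orientation per gene (`"+"`/`"-"`/NA).
#' @param chromosome Optional chromosome/scaffold id per gene.
#' @return A `gene_order` object.
#' @export
gene_order <- function(species, genes, strand = NA, chromosome = NA) {
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol: ", genes[duplicated(genes)][1L])
  }
  structure(list(species = species, genes = as.character(genes),
                 strand = rep_len(strand, length(genes)),
                 chromosome = rep_len(as.character(chromosome), length(genes))),
            class = "gene_order")
}

#' Detect broken gene adjacencies between two gene orders
#'
#' A reference adjacency (a, b) is retained iff a and b are adjacent in the
#' query (either order) on the same chromosome; otherwise it is broken. The
#' report also lists reference genes absent from the query and the maximal
#' reference-contiguous runs retained intact in the query, with their query
#' chromosome; runs off the query's modal chromosome are flagged as moved
#' segments.
#'
#' @param reference,query [gene_order()] objects.
#' @return A `breakpoint_report` with `broken` (data.frame of adjacencies),
#'   `missing_genes`, `runs` and `moved_segments`.
#' @export
detect_breakpoints <- function(reference, query) {
  stopifnot(inherits(reference, "gene_order"), inherits(query, "gene_order"))
  if (anyDuplicated(query$genes)) {
    stop("duplicate gene symbol in query: ",
         query$genes[duplicated(query$genes)][1L])
  }
  rg <- reference$genes
  qpos <- match(rg, query$genes)
  missing_genes <- rg[is.na(qpos)]
  broken <- data.frame(a = character(0), b = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  retained <- logical(max(length(rg) - 1L, 0L))
  for (i in seq_len(max(length(rg) - 1L, 0L))) {
    a <- rg[i]; b <- rg[i + 1L]
    pa <- qpos[i]; pb <- qpos[i + 1L]
    if (is.na(pa) || is.na(pb)) {
      broken <- rbind(broken, data.frame(a = a, b = b, reason = "missing_gene"))
      next
    }
    same_chr <- is.na(query$chromosome[pa]) || is.na(query$chromosome[pb]) ||
      query$chromosome[pa] == query$chromosome[pb]
    if (abs(pa - pb) == 1L && same_chr) {
      retained[i] <- TRUE
    } else {
      broken <- rbind(broken, data.frame(
        a = a, b = b,
        reason = if (!same_chr) "split_chromosomes" else "non_adjacent"))
    }
  }
  # maximal reference-contiguous retained runs
  runs <- list()
  i <- 1L
  while (i <= length(rg)) {
    j <- i
    while (j < length(rg) && retained[j]) j <- j + 1L
    if (!is.na(qpos[i])) {
      runs[[length(runs) + 1L]] <- data.frame(
        start = rg[i], end = rg[j], n_genes = j - i + 1L,
        chromosome = query$chromosome[qpos[i]], stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(start = character(0), end = character(0),
               n_genes = integer(0), chromosome = character(0))
  modal <- if (nrow(runs) > 0L && !all(is.na(runs$chromosome))) {
    names(sort(table(rep(runs$chromosome, runs$n_genes)), decreasing = TRUE))[1L]
  } else NA_character_
  moved <- runs[!is.na(runs$chromosome) & runs$chromosome != modal, ,
                drop = FALSE]
  structure(list(reference_species = reference$species,
                 query_species = query$species,
                 broken = broken, missing_genes = missing_genes,
                 runs = runs, moved_segments = moved),
            class = "breakpoint_report")
}

#' @export
print.breakpoint_report <- function(x, ...) {
  cat(sprintf("<breakpoint_report> %s vs %s: %d broken adjacenc%s, %d missing gene(s), %d moved segment(s)\n",
              x$query_species, x$reference_species, nrow(x$broken),
              if (nrow(x$broken) == 1L) "y" else "ies",
              length(x$missing_genes), nrow(x$moved_segments)))
  invisible(x)
}
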