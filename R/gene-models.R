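#' Exon-structured gene models
#'
#' A `gene_model` represents one species' copy of a protein-coding gene as an
#' ordered list of coding exons. Each exon carries its sequence (coding
#' strand, uppercase ACGT) and its phase: the number of 5'-terminal bases that
#' complete a codon begun in the previous exon. Phases are always recomputed
#' from the cumulative spliced length, so they stay consistent after edits.
#'
#' @param species Species identifier.
#' @param gene Gene identifier.
#' @param exons Character vector of exon sequences, in order.
#' @return An object of class `gene_model` with elements `species`, `gene`
#'   and `exons` (a list of `index`/`sequence`/`phase` records).
#' @examples
#' gm <- gene_model("sp1", "G", c("ATGAA", "ATAA"))
#' splice(gm)
#' @export
gene_model <- function(species, gene, exons) {
  stopifnot(is.character(exons), length(exons) >= 1L)
  exons <- toupper(exons)
  bad <- grepl("[^ACGT]", exons)
  if (any(bad)) {
    stop("exon ", which(bad)[1L], " contains non-ACGT characters")
  }
  if (any(nchar(exons) == 0L)) {
    stop("empty exon sequence in gene model for ", species)
  }
  obj <- structure(
    list(species = species, gene = gene,
         exons = lapply(seq_along(exons), function(i) {
           list(index = i, sequence = exons[[i]], phase = 0L)
         })),
    class = "gene_model")
  recompute_phases(obj)
}

#' @export
print.gene_model <- function(x, ...) {
  lens <- exon_lengths(x)
  cat(sprintf("<gene_model> %s / %s: %d exon(s), spliced length %d\n",
              x$species, x$gene, length(lens), sum(lens)))
  for (e in x$exons) {
    cat(sprintf("  exon %d: %d bp, phase %d\n", e$index,
                nchar(e$sequence), e$phase))
  }
  invisible(x)
}

exon_lengths <- function(gene) {
  vapply(gene$exons, function(e) nchar(e$sequence), integer(1))
}

# phase(k+1) = (3 - cumulative length through exon k mod 3) mod 3; phase(1) = 0
recompute_phases <- function(gene) {
  cum <- 0L
  for (i in seq_along(gene$exons)) {
    gene$exons[[i]]$index <- i
    gene$exons[[i]]$phase <- if (i == 1L) 0L else (3L - cum %% 3L) %% 3L
    cum <- cum + nchar(gene$exons[[i]]$sequence)
  }
  gene
}

#' Splice a gene model into its coding sequence
#'
#' @param gene A [gene_model()].
#' @return Single string: exon sequences concatenated in order.
#' @export
splice <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  seqs <- vapply(gene$exons, `[[`, character(1), "sequence")
  if (any(nchar(seqs) == 0L)) stop("malformed gene model: empty exon")
  paste0(seqs, collapse = "")
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Translate a coding sequence and locate stop codons
#'
#' Translates complete codons of `cds` after discarding the first
#' `frame_offset` bases (the standard nuclear genetic code); trailing 1-2
#' bases are ignored. Stop codons are reported with the base coordinate of
#' the codon start, in the coordinates of the offset sequence.
#'
#' @param cds DNA string (ACGT).
#' @param frame_offset Number of leading bases to skip (0, 1 or 2).
#' @return List with `protein` (string, stops as `*`) and `stops`
#'   (data.frame: `base` = codon start position, `codon`).
#' @export
translate_cds <- function(cds, frame_offset = 0L) {
  stopifnot(length(cds) == 1L, frame_offset %in% 0:2)
  bad <- regexpr("[^ACGT]", cds)
  if (bad > 0) stop("non-ACGT character at position ", bad)
  s <- substr(cds, frame_offset + 1L, nchar(cds))
  n_codon <- nchar(s) %/% 3L
  if (n_codon < 1L) stop("fewer than 3 bases after applying frame offset")
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(s, starts, starts + 2L)
  tab <- .codon_table()
  aa <- tab[codons]
  if (anyNA(aa)) stop("untranslatable codon at base ", starts[which(is.na(aa))[1L]])
  stop_idx <- which(aa == "*")
  list(protein = paste0(aa, collapse = ""),
       stops = data.frame(base = starts[stop_idx],
                          codon = codons[stop_idx],
                          stringsAsFactors = FALSE))
}

#' Build a mutation catalog table
#'
#' Mutation records use exon-local, 1-based coordinates on the coding strand.
#' For insertions `position` is the base AFTER which the bases are inserted
#' (0 = before the first base). Codon-anchored records (`anchor_unit =
#' "codon"`) give the codon index within the exon and are resolved to base
#' coordinates with the exon phase: codon k of an exon with phase p starts at
#' local base p + 3(k-1) + 1; a codon-anchored insertion at position k goes
#' after codon k (local base p + 3k).
#'
#' @param species,exon,kind,anchor_unit,position,length,alt Record fields,
#'   recycled to a common length. `kind` is one of `"substitution"`,
#'   `"insertion"`, `"deletion"`; `alt` is the inserted/replacement sequence
#'   (empty for deletions).
#' @return A data.frame of class `mutation_catalog`.
#' @export
mutation_record <- function(species, exon, kind, position, length = 1L,
                            alt = "", anchor_unit = "base") {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"),
                    several.ok = TRUE)
  df <- data.frame(species = species, exon = as.integer(exon), kind = kind,
                   anchor_unit = anchor_unit, position = as.integer(position),
                   length = as.integer(length), alt = toupper(alt),
                   stringsAsFactors = FALSE)
  ok_sub <- df$kind != "substitution" | nchar(df$alt) == df$length
  ok_ins <- df$kind != "insertion" | nchar(df$alt) == df$length
  ok_del <- df$kind != "deletion" | df$alt == ""
  if (!all(ok_sub & ok_ins & ok_del)) {
    stop("alt length inconsistent with kind/length in mutation record")
  }
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

empty_catalog <- function() {
  df <- data.frame(species = character(0), exon = integer(0),
                   kind = character(0), anchor_unit = character(0),
                   position = integer(0), length = integer(0),
                   alt = character(0), stringsAsFactors = FALSE)
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

#' @rdname mutation_record
#' @param ... `mutation_catalog` tables to combine.
#' @export
catalog <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

# codon-anchored records -> base coordinates, using the gene's exon phases
resolve_positions <- function(gene, muts) {
  muts <- as.data.frame(muts)
  for (i in seq_len(nrow(muts))) {
    if (muts$anchor_unit[i] == "codon") {
      ex <- gene$exons[[muts$exon[i]]]
      k <- muts$position[i]
      muts$position[i] <- if (muts$kind[i] == "insertion") {
        ex$phase + 3L * k
      } else {
        ex$phase + 3L * (k - 1L) + 1L
      }
      muts$anchor_unit[i] <- "base"
    }
  }
  class(muts) <- c("mutation_catalog", "data.frame")
  muts
}

mut_interval <- function(m) {
  # closed interval of reference bases consumed; insertions sit between bases
  if (m$kind == "insertion") c(m$position + 0.25, m$position + 0.75)
  else c(m$position, m$position + m$length - 1)
}

#' Apply catalogued mutations to a gene model
#'
#' Records are resolved to base coordinates and applied within each exon in
#' descending position order so that earlier edits do not invalidate later
#' coordinates. Exon phases downstream of a length-changing edit are
#' recomputed. A substitution whose replacement equals the reference emits a
#' no-op warning; overlapping edits are an error.
#'
#' @param gene A [gene_model()].
#' @param muts A `mutation_catalog` (see [mutation_record()]).
#' @return The edited `gene_model`.
#' @export
apply_mutations <- function(gene, muts) {
  stopifnot(inherits(gene, "gene_model"))
  if (is.null(muts) || nrow(muts) == 0L) return(gene)
  muts <- resolve_positions(gene, muts)
  for (ex in unique(muts$exon)) {
    if (ex < 1L || ex > length(gene$exons)) stop("mutation references exon ", ex,
                                                 " absent from gene model")
    sub <- muts[muts$exon == ex, , drop = FALSE]
    n <- nchar(gene$exons[[ex]]$sequence)
    ivs <- lapply(seq_len(nrow(sub)), function(i) mut_interval(sub[i, ]))
    if (nrow(sub) > 1L) {
      ord <- order(vapply(ivs, `[[`, numeric(1), 1L))
      for (j in seq_len(nrow(sub) - 1L)) {
        if (ivs[[ord[j + 1L]]][1] <= ivs[[ord[j]]][2]) {
          stop("overlapping edits in exon ", ex)
        }
      }
    }
    sub <- sub[order(sub$position, decreasing = TRUE), , drop = FALSE]
    s <- gene$exons[[ex]]$sequence
    for (i in seq_len(nrow(sub))) {
      m <- sub[i, ]
      if (m$kind == "insertion") {
        if (m$position < 0L || m$position > n) stop("insertion position out of range")
        s <- paste0(substr(s, 1L, m$position), m$alt,
                    substr(s, m$position + 1L, nchar(s)))
      } else {
        if (m$position < 1L || m$position + m$length - 1L > n) {
          stop("position out of range in exon ", ex, " (", m$position, ")")
        }
        ref_bases <- substr(s, m$position, m$position + m$length - 1L)
        if (m$kind == "substitution") {
          if (identical(ref_bases, m$alt)) {
            warning("no-op substitution at exon ", ex, " base ", m$position)
          }
          s <- paste0(substr(s, 1L, m$position - 1L), m$alt,
                      substr(s, m$position + m$length, nchar(s)))
        } else {
          s <- paste0(substr(s, 1L, m$position - 1L),
                      substr(s, m$position + m$length, nchar(s)))
        }
      }
    }
    gene$exons[[ex]]$sequence <- s
  }
  recompute_phases(gene)
}

#' Check that a gene model is an intact open reading frame
#'
#' Intact means: spliced length divisible by 3, starts with ATG, exactly one
#' stop codon and that stop terminal.
#'
#' @param gene A [gene_model()].
#' @return TRUE/FALSE.
#' @export
is_intact_orf <- function(gene) {
  cds <- splice(gene)
  if (nchar(cds) %% 3L != 0L) return(FALSE)
  if (substr(cds, 1L, 3L) != "ATG") return(FALSE)
  tr <- translate_cds(cds)
  nrow(tr$stops) == 1L && tr$stops$base[1L] == nchar(cds) - 2L
}
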