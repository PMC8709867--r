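#' Read and write exon-tagged FASTA
#'
#' Headers follow the convention `species|gene|exonN|phaseP`, one record per
#' exon. `read_exon_fasta()` returns a list of [gene_model()] objects (one
#' per species/gene pair); declared phases are checked against the phases
#' recomputed from exon lengths. A spliced-CDS FASTA (headers `species|gene`)
#' is accepted when `exon_lengths_tsv` supplies the per-exon lengths
#' (columns: species, gene, exon, length).
#'
#' @param path FASTA file path.
#' @param exon_lengths_tsv Optional sidecar TSV for spliced-CDS input.
#' @return Named list of `gene_model` objects.
#' @export
read_exon_fasta <- function(path, exon_lengths_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  nfield <- lengths(parts)
  out <- list()
  if (all(nfield >= 4)) {
    key <- vapply(parts, function(p) paste(p[1], p[2], sep = "|"), character(1))
    for (k in unique(key)) {
      idx <- which(key == k)
      exn <- as.integer(sub("^exon", "", vapply(parts[idx], `[[`, character(1), 3)))
      ph <- as.integer(sub("^phase", "", vapply(parts[idx], `[[`, character(1), 4)))
      ord <- order(exn)
      gm <- gene_model(parts[[idx[1]]][1], parts[[idx[1]]][2],
                       as.character(seqs[idx])[ord])
      got <- vapply(gm$exons, `[[`, integer(1), "phase")
      if (!all(got == ph[ord])) {
        stop("declared phases disagree with exon lengths for ", k)
      }
      out[[k]] <- gm
    }
  } else {
    if (is.null(exon_lengths_tsv)) {
      stop("spliced-CDS FASTA requires an exon-length sidecar TSV")
    }
    lens <- utils::read.table(exon_lengths_tsv, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    for (i in seq_along(seqs)) {
      sp <- parts[[i]][1]; gn <- parts[[i]][2]
      li <- lens[lens$species == sp & lens$gene == gn, ]
      li <- li[order(li$exon), ]
      if (sum(li$length) != Biostrings::width(seqs)[i]) {
        stop("exon lengths do not sum to CDS length for ", headers[i])
      }
      ends <- cumsum(li$length)
      starts <- c(1, utils::head(ends, -1) + 1)
      out[[headers[i]]] <- gene_model(sp, gn,
        substring(as.character(seqs[i]), starts, ends))
    }
  }
  out
}

#' @rdname read_exon_fasta
#' @param genes List of `gene_model` objects.
#' @export
write_exon_fasta <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    for (e in g$exons) {
      lines <- c(lines,
                 sprintf(">%s|%s|exon%d|phase%d", g$species, g$gene,
                         e$index, e$phase),
                 e$sequence)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Mutation catalog TSV I/O
#'
#' Columns: species, exon, kind, anchor_unit, position, length, alt. The
#' write/read pair round-trips bit-exactly (empty `alt` preserved).
#'
#' @param path TSV path.
#' @return A `mutation_catalog` data.frame.
#' @export
read_mutation_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c("character", "integer", "character",
                                         "character", "integer", "integer",
                                         "character"),
                          na.strings = NULL, stringsAsFactors = FALSE)
  class(df) <- c("mutation_catalog", "data.frame")
  df
}

#' @rdname read_mutation_catalog
#' @param cat A `mutation_catalog`.
#' @export
write_mutation_catalog <- function(cat, path) {
  utils::write.table(as.data.frame(cat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene order and trait table I/O
#'
#' Gene-order TSVs have columns species, rank, gene, strand, chromosome;
#' trait TSVs have columns species, retention, white_pct, pink_pct, red_pct.
#'
#' @param path TSV path.
#' @return For [read_gene_orders()], a named list of [gene_order()] objects;
#'   for [read_trait_table()], a validated data.frame.
#' @export
read_gene_orders <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- list()
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, ]
    sub <- sub[order(sub$rank), ]
    out[[sp]] <- gene_order(sp, sub$gene, strand = sub$strand,
                            chromosome = sub$chromosome)
  }
  out
}

#' @rdname read_gene_orders
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_trait_table(df)
}

validate_trait_table <- function(df) {
  need <- c("species", "retention", "white_pct", "pink_pct", "red_pct")
  if (!all(need %in% names(df))) {
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$retention %in% c(0, 1))) stop("retention must be 0/1")
  pct <- df$white_pct + df$pink_pct + df$red_pct
  if (any(abs(pct - 100) > 0.5)) {
    stop("fiber percentages must sum to 100 (+/- 0.5) per species")
  }
  df
}

#' Codon alignment I/O
#'
#' Reads an in-frame codon alignment from FASTA or sequential PHYLIP;
#' writes FASTA. Rows listed in `pseudogenic` may contain in-frame stops
#' (recoded as missing for likelihood work).
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @param pseudogenic Rows in which stop codons are tolerated.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, format = c("fasta", "phylip"),
                                 pseudogenic = character(0)) {
  format <- match.arg(format)
  seqs <- if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
  } else {
    x <- ape::read.dna(path, format = "sequential", as.character = TRUE)
    setNames(toupper(apply(x, 1, paste0, collapse = "")), rownames(x))
  }
  codon_alignment(seqs, pseudogenic = pseudogenic)
}

#' @rdname read_codon_alignment
#' @param aln A [codon_alignment()].
#' @export
write_codon_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(paste0(">", aln$taxa, "\n", unname(aln$sequences[aln$taxa])),
               path)
  } else {
    w <- nchar(aln$sequences[[1]])
    lines <- c(paste(length(aln$taxa), w),
               paste(formatC(aln$taxa, width = -10), aln$sequences[aln$taxa]))
    writeLines(lines, path)
  }
  invisible(path)
}
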