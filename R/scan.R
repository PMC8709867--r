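#' Scan an observed gene copy for reading-frame disruptions
#'
#' Each observed exon is globally aligned to the corresponding reference exon
#' (affine gap penalties: match +1, mismatch -1, gap open -4, gap extend -1;
#' ties resolved by the aligner's deterministic leftmost placement) and the
#' differences are reduced to substitution / insertion / deletion records in
#' reference exon-local coordinates. The spliced observed sequence is then
#' translated from its start codon, cumulative frame offsets are tracked
#' across exons, and stop codons mapping upstream of the reference terminal
#' stop are reported as premature.
#'
#' Exons with under 50% alignable identity are flagged unalignable and
#' excluded from mutation calling; absent exons (NA) are flagged missing.
#' A substitution destroying the reference terminal stop is recorded as
#' stop-loss and does not by itself mark the gene disrupted.
#'
#' @param ref Intact reference [gene_model()].
#' @param obs Observed copy: a `gene_model` with the same exon count, or a
#'   character vector of exon sequences (NA = exon missing).
#' @return A `disruption_report`: detected mutations, premature stops
#'   (observed exon-local codon starts), cumulative per-exon frame offsets,
#'   start-codon and stop-loss flags, and the resulting [classify_status()].
#' @export
scan_disruptions <- function(ref, obs) {
  stopifnot(inherits(ref, "gene_model"))
  if (!is_intact_orf(ref)) stop("reference gene model is not an intact ORF")
  species <- if (inherits(obs, "gene_model")) obs$species else "observed"
  obs_seqs <- if (inherits(obs, "gene_model")) {
    vapply(obs$exons, `[[`, character(1), "sequence")
  } else as.character(obs)
  ne <- length(ref$exons)
  if (length(obs_seqs) != ne) {
    stop("observed exon count (", length(obs_seqs),
         ") does not match reference (", ne, ")")
  }

  muts <- NULL
  missing_exons <- integer(0)
  unalignable_exons <- integer(0)
  # per reference spliced position: matched observed spliced position (NA in
  # deletions); built exon by exon
  ref_to_obs <- integer(0)
  obs_cum <- 0L
  ref_cum <- 0L
  offsets <- integer(ne)  # cumulative net indel offset through each exon
  net <- 0L

  for (i in seq_len(ne)) {
    rseq <- ref$exons[[i]]$sequence
    oseq <- obs_seqs[[i]]
    if (is.na(oseq) || nchar(oseq) == 0L) {
      missing_exons <- c(missing_exons, i)
      ref_to_obs <- c(ref_to_obs, rep(NA_integer_, nchar(rseq)))
      ref_cum <- ref_cum + nchar(rseq)
      offsets[i] <- net
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = oseq, subject = rseq, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 4, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ident <- sum(p == s & s != "-") / nchar(rseq)
    if (ident < 0.5) {
      unalignable_exons <- c(unalignable_exons, i)
      ref_to_obs <- c(ref_to_obs, rep(NA_integer_, nchar(rseq)))
      ref_cum <- ref_cum + nchar(rseq)
      obs_cum <- obs_cum + nchar(oseq)
      offsets[i] <- net
      next
    }
    ex_muts <- .columns_to_records(p, s, species, i)
    muts <- rbind(muts, ex_muts)
    net <- net + sum(ex_muts$length[ex_muts$kind == "insertion"]) -
      sum(ex_muts$length[ex_muts$kind == "deletion"])
    offsets[i] <- net
    # column map
    rpos <- cumsum(s != "-")
    opos <- cumsum(p != "-")
    keep <- s != "-"
    m <- ifelse(p[keep] == "-", NA_integer_, opos[keep] + obs_cum)
    ref_to_obs <- c(ref_to_obs, m)
    ref_cum <- ref_cum + nchar(rseq)
    obs_cum <- obs_cum + nchar(oseq)
  }
  if (!is.null(muts)) class(muts) <- c("mutation_catalog", "data.frame")

  all_missing <- length(missing_exons) == ne
  obs_ok <- !is.na(obs_seqs) & nchar(ifelse(is.na(obs_seqs), "", obs_seqs)) > 0
  spliced_obs <- paste0(obs_seqs[obs_ok], collapse = "")

  premature <- data.frame(exon = integer(0), base = integer(0),
                          codon = character(0), stringsAsFactors = FALSE)
  start_ok <- FALSE
  stop_loss <- FALSE
  if (nchar(spliced_obs) >= 3L) {
    start_ok <- substr(spliced_obs, 1L, 3L) == "ATG"
    tr <- translate_cds(spliced_obs)
    ref_len <- sum(exon_lengths(ref))
    term_start <- ref_len - 2L
    # observed spliced position of each reference position (carry last known)
    obs_of_ref <- ref_to_obs
    if (anyNA(obs_of_ref)) {
      for (k in seq_along(obs_of_ref)) {
        if (is.na(obs_of_ref[k])) obs_of_ref[k] <- if (k > 1L) obs_of_ref[k - 1L] else 0L
      }
    }
    terminal_obs <- obs_of_ref[term_start]
    if (nrow(tr$stops) > 0L) {
      prem_idx <- tr$stops$base < terminal_obs
      at_term <- tr$stops$base >= terminal_obs
      stop_loss <- !any(at_term)
      st <- tr$stops[prem_idx, , drop = FALSE]
      if (nrow(st) > 0L) {
        loc <- .spliced_to_exon_local(st$base, nchar(obs_seqs[obs_ok]),
                                      which(obs_ok))
        premature <- data.frame(exon = loc$exon, base = loc$base,
                                codon = st$codon, stringsAsFactors = FALSE)
      }
    } else {
      stop_loss <- TRUE
    }
  }

  rep <- structure(list(
    species = species,
    mutations_detected = muts,
    premature_stops = premature,
    net_frame_offset_per_exon = offsets,
    raw_indel_sum = net,
    start_codon_intact = start_ok,
    stop_loss = stop_loss,
    missing_exons = missing_exons,
    unalignable_exons = unalignable_exons,
    status = NA_character_,
    all_missing = all_missing
  ), class = "disruption_report")
  rep$status <- classify_status(rep)
  rep
}

# merge alignment columns into substitution / insertion / deletion records
.columns_to_records <- function(p, s, species, exon) {
  kind <- ifelse(s == "-", "ins", ifelse(p == "-", "del",
                 ifelse(p == s, "match", "sub")))
  rpos <- cumsum(s != "-")  # reference coordinate of each column (last seen)
  out <- list()
  i <- 1L
  n <- length(kind)
  while (i <= n) {
    if (kind[i] == "match") { i <- i + 1L; next }
    j <- i
    while (j < n && kind[j + 1L] == kind[i]) j <- j + 1L
    run_p <- paste0(p[i:j], collapse = "")
    if (kind[i] == "sub") {
      out[[length(out) + 1L]] <- mutation_record(
        species, exon, "substitution", position = rpos[i],
        length = j - i + 1L, alt = run_p)
    } else if (kind[i] == "del") {
      out[[length(out) + 1L]] <- mutation_record(
        species, exon, "deletion", position = rpos[i],
        length = j - i + 1L)
    } else {
      after <- if (i == 1L) 0L else rpos[i - 1L]
      out[[length(out) + 1L]] <- mutation_record(
        species, exon, "insertion", position = after,
        length = j - i + 1L, alt = run_p)
    }
    i <- j + 1L
  }
  if (length(out) == 0L) empty_catalog() else do.call(rbind, out)
}

.spliced_to_exon_local <- function(pos, lens, exon_ids) {
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  ex <- findInterval(pos, starts)
  list(exon = exon_ids[ex], base = pos - starts[ex] + 1L)
}

#' Classify gene status from a disruption report
#'
#' `disrupted` iff the report shows at least one premature stop, a terminal
#' cumulative frame offset not divisible by 3, or a lost start codon;
#' `missing` iff no sequence was supplied; `intact` otherwise.
#'
#' @param report A `disruption_report` from [scan_disruptions()].
#' @return One of `"intact"`, `"disrupted"`, `"missing"`.
#' @export
classify_status <- function(report) {
  if (isTRUE(report$all_missing)) return("missing")
  term <- report$net_frame_offset_per_exon[length(report$net_frame_offset_per_exon)]
  if (nrow(report$premature_stops) > 0L || term %% 3L != 0L ||
      !isTRUE(report$start_codon_intact)) "disrupted" else "intact"
}

#' @export
print.disruption_report <- function(x, ...) {
  nmut <- if (is.null(x$mutations_detected)) 0L else nrow(x$mutations_detected)
  cat(sprintf("<disruption_report> %s: status %s\n", x$species, x$status))
  cat(sprintf("  mutations: %d; premature stops: %d (exons %s)\n", nmut,
              nrow(x$premature_stops),
              paste(unique(x$premature_stops$exon), collapse = ",")))
  cat(sprintf("  terminal frame offset: %+d (mod 3 = %d); start codon %s\n",
              x$raw_indel_sum, x$raw_indel_sum %% 3L,
              if (x$start_codon_intact) "intact" else "lost"))
  invisible(x)
}
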