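#' Strand-aware promoter windows upstream of TSSs
#'
#' For every gene feature, reports the upstream window of the requested
#' length, 5' to 3' in gene orientation, excluding the TSS base itself:
#' plus-strand genes take bases \code{[tss - length, tss - 1]} as written,
#' minus-strand genes the reverse complement of \code{[tss + 1,
#' tss + length]}. Windows are truncated at contig edges and the realized
#' length recorded. The 3 kb default matches the upstream regulatory window
#' scanned for E-boxes.
#'
#' @param genome a \code{Biostrings::DNAStringSet} or path to a FASTA file.
#' @param annotation a \code{GenomicRanges::GRanges} with gene features (or
#'   path to a GFF3 file); the TSS is the strand-aware 5' end. Features of
#'   type "gene" are used when a \code{type} column is present.
#' @param length upstream window size in bp.
#' @return data.frame: gene_id, contig, strand, tss, length (realized),
#'   sequence (character, 5'->3' in gene orientation).
#' @export
extract_promoters <- function(genome, annotation, length = 3000) {
  .assert(length >= 6, "promoter length must be >= 6")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  gr <- annotation
  if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  ids <- gr$ID %||% gr$gene_id %||% names(gr) %||%
    sprintf("feature%d", seq_along(gr))

  out <- vector("list", base::length(gr))
  for (k in seq_along(gr)) {
    contig <- as.character(GenomicRanges::seqnames(gr)[k])
    .assert(contig %in% names(genome),
            sprintf("contig '%s' of gene '%s' missing from FASTA",
                    contig, ids[k]))
    strand <- as.character(GenomicRanges::strand(gr)[k])
    .assert(strand %in% c("+", "-"),
            sprintf("gene '%s' has no strand", ids[k]))
    clen <- base::length(genome[[contig]])
    if (strand == "+") {
      tss <- GenomicRanges::start(gr)[k]
      from <- max(1, tss - length); to <- tss - 1
      seq <- if (to >= from)
        as.character(Biostrings::subseq(genome[[contig]], from, to)) else ""
    } else {
      tss <- GenomicRanges::end(gr)[k]
      from <- tss + 1; to <- min(clen, tss + length)
      seq <- if (to >= from)
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(genome[[contig]], from, to))) else ""
    }
    out[[k]] <- data.frame(gene_id = ids[k], contig = contig, strand = strand,
                           tss = tss, length = nchar(seq), sequence = seq,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Scan promoter windows for canonical and non-canonical E-boxes
#'
#' Slides a 6 bp window over each promoter sequence (overlaps allowed) and
#' reports every CANNTG match: CACGTG is CANONICAL, the other fifteen
#' CANNTG hexamers NONCANONICAL. Positions containing N never match.
#' Scanning is on the reported (gene-orientation) strand only; the CANNTG
#' class is closed under reverse complement, so class-level counts are
#' strand-complete. \code{distance_bp} is the 1-based distance from the TSS
#' to the motif base nearest it.
#'
#' @param promoters data.frame from \code{\link{extract_promoters}} (columns
#'   gene_id, sequence), or a single character sequence.
#' @param gene_id id used when \code{promoters} is a bare sequence.
#' @return data.frame: gene_id, start (1-based in the promoter window),
#'   motif, category, distance_bp. Zero rows when nothing matches.
#' @examples
#' scan_eboxes("AACACGTGTT", gene_id = "g1")  # canonical hit, distance 3
#' @export
scan_eboxes <- function(promoters, gene_id = "seq1") {
  if (is.character(promoters)) {
    promoters <- data.frame(gene_id = gene_id, sequence = promoters,
                            stringsAsFactors = FALSE)
  }
  hits <- lapply(seq_len(nrow(promoters)), function(k) {
    s <- toupper(promoters$sequence[k])
    L <- nchar(s)
    if (L < 6) return(NULL)
    mp <- Biostrings::matchPattern("CANNTG", Biostrings::DNAString(s),
                                   fixed = "subject")
    if (base::length(mp) == 0) return(NULL)
    motif <- as.character(mp)
    keep <- grepl("^[ACGT]{6}$", motif)  # ambiguity codes in the window never match
    if (!any(keep)) return(NULL)
    st <- Biostrings::start(mp)[keep]
    motif <- motif[keep]
    data.frame(gene_id = promoters$gene_id[k], start = st, motif = motif,
               category = ifelse(motif == "CACGTG", "CANONICAL", "NONCANONICAL"),
               distance_bp = L - st - 4, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(gene_id = character(0), start = integer(0),
                       motif = character(0), category = character(0),
                       distance_bp = integer(0), stringsAsFactors = FALSE)
  }
  hits
}

#' Per-class E-box density (mean hits per gene)
#'
#' Mean number of canonical, non-canonical and total E-box hits per gene in
#' each phase class. Genes without hits count with zero, so the density is
#' total hits in the class divided by genes in the class ("E-box per gene").
#'
#' @param hits data.frame from \code{\link{scan_eboxes}}.
#' @param labels data.frame from \code{\link{classify_phase}} covering every
#'   gene (including zero-hit genes).
#' @return data.frame: phase_class, n_genes, canonical, noncanonical, total
#'   (densities), n_hits.
#' @export
ebox_density_by_class <- function(hits, labels) {
  .assert(all(hits$gene_id %in% labels$gene_id),
          "every hit's gene must be labelled")
  classes <- c("DAY", "NIGHT", "ARRHYTHMIC")
  out <- lapply(classes, function(cl) {
    genes <- labels$gene_id[labels$phase_class == cl]
    h <- hits[hits$gene_id %in% genes, , drop = FALSE]
    ng <- base::length(genes)
    data.frame(phase_class = cl, n_genes = ng,
               canonical = if (ng) sum(h$category == "CANONICAL") / ng else NA_real_,
               noncanonical = if (ng) sum(h$category == "NONCANONICAL") / ng else NA_real_,
               total = if (ng) nrow(h) / ng else NA_real_,
               n_hits = nrow(h), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' TSS-distance histogram of E-box hits
#'
#' Bins hits by their TSS distance and also counts, per bin, the genes with
#' at least one hit in the bin. Reports the fraction of all hits whose
#' distance lies within the 300-1800 bp window in which daytime-gene
#' E-boxes concentrate.
#'
#' @param hits data.frame from \code{\link{scan_eboxes}}.
#' @param bin_width bin width in bp; must divide \code{max_distance}.
#' @param max_distance histogram ceiling in bp.
#' @param focus_range distance window for the reported mass fraction
#'   (inclusive bounds).
#' @return list with \code{bins} (data.frame: bin_start, bin_end, n_hits,
#'   n_genes) and \code{mass_fraction_focus}.
#' @export
positional_histogram <- function(hits, bin_width = 300, max_distance = 3000,
                                 focus_range = c(300, 1800)) {
  .assert(max_distance %% bin_width == 0, "bin_width must divide max_distance")
  starts <- seq(0, max_distance - bin_width, by = bin_width)
  bin_of <- pmin(floor(hits$distance_bp / bin_width), base::length(starts) - 1)
  bins <- data.frame(bin_start = starts, bin_end = starts + bin_width,
                     n_hits = 0L, n_genes = 0L)
  for (b in seq_along(starts)) {
    sel <- bin_of == b - 1
    bins$n_hits[b] <- sum(sel)
    bins$n_genes[b] <- base::length(unique(hits$gene_id[sel]))
  }
  mass <- if (nrow(hits)) {
    mean(hits$distance_bp >= focus_range[1] & hits$distance_bp <= focus_range[2])
  } else NA_real_
  list(bins = bins, mass_fraction_focus = mass)
}

#' Permutation test for class differences in per-gene E-box counts
#'
#' Label-shuffling null for the difference in class mean counts, for
#' DAY > NIGHT and DAY > ARRHYTHMIC (one-sided). The p-value is
#' \code{(1 + #[perm >= observed]) / (1 + n_perm)}.
#'
#' @param per_gene_counts named numeric vector of hit counts per gene.
#' @param labels data.frame from \code{\link{classify_phase}}.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame: comparison, observed_diff, p_value.
#' @export
permutation_enrichment <- function(per_gene_counts, labels, n_perm = 999,
                                   seed = 1L) {
  .assert(n_perm >= 99, "n_perm must be >= 99")
  cls <- labels$phase_class[match(names(per_gene_counts), labels$gene_id)]
  .assert(!anyNA(cls), "every counted gene must be labelled")
  comparisons <- list(c("DAY", "NIGHT"), c("DAY", "ARRHYTHMIC"))
  for (cmp in comparisons) {
    .assert(all(cmp %in% cls),
            sprintf("class %s is empty", cmp[!(cmp %in% cls)][1]))
  }
  set.seed(as.integer(seed))
  out <- lapply(comparisons, function(cmp) {
    sel <- cls %in% cmp
    y <- per_gene_counts[sel]
    g <- cls[sel]
    obs <- mean(y[g == cmp[1]]) - mean(y[g == cmp[2]])
    perm <- replicate(n_perm, {
      gs <- sample(g)
      mean(y[gs == cmp[1]]) - mean(y[gs == cmp[2]])
    })
    data.frame(comparison = paste(cmp, collapse = ">"), observed_diff = obs,
               p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Replace canonical E-boxes in a promoter sequence
#'
#' Replaces every canonical CACGTG occurrence left to right, re-scanning
#' after each replacement, emulating in-silico construction of an E-box
#' mutant promoter. With the default replacement no canonical hit remains,
#' and the operation is idempotent.
#'
#' @param sequence promoter sequence (character).
#' @param replacement 6 bp replacement string (default TGTACA).
#' @return list with \code{sequence} (mutated) and \code{n_replaced}.
#' @export
mutate_ebox <- function(sequence, replacement = "TGTACA") {
  .assert(nchar(replacement) == 6, "replacement must be 6 bp")
  .assert(!grepl("CACGTG", toupper(replacement), fixed = TRUE),
          "replacement must not itself be a canonical E-box")
  s <- toupper(sequence)
  n <- 0L
  repeat {
    at <- regexpr("CACGTG", s, fixed = TRUE)
    if (at < 0) break
    substr(s, at, at + 5) <- replacement
    n <- n + 1L
  }
  list(sequence = s, n_replaced = n)
}
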