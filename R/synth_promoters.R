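#' Simulate per-gene promoter contigs with planted E-boxes
#'
#' Builds one synthetic contig per gene — a promoter window of the given
#' length followed by a short gene body — with strand alternating between
#' genes, and plants E-box motifs in the promoter: per gene, canonical and
#' non-canonical counts are drawn from Poisson laws with the class means,
#' and TSS distances from the stated positional distribution. Planted
#' windows are kept >= 6 bp apart so each occurrence is unambiguous. With
#' \code{mask_background} set, spontaneous (unplanted) CANNTG occurrences in
#' the promoter are destroyed by resampling single bases, so a downstream
#' scan recovers exactly the planted hits; without masking, scans include
#' the spontaneous background (about \eqn{2995/4096 \approx 0.73} canonical
#' hits expected per 3 kb window of uniform sequence).
#'
#' @param truth per-gene truth data.frame (columns gene_id, class), e.g.
#'   from \code{\link{simulate_expression}}.
#' @param promoter_length upstream window length in bp (default 3000).
#' @param class_ebox_means named list per class of
#'   \code{c(canonical, noncanonical)} mean planted counts per gene. The
#'   default splits the observed per-class totals (DAY 2.54, NIGHT 1.77,
#'   ARRHYTHMIC 0.57 E-boxes per gene) evenly between the two categories.
#' @param positional positional distribution of planted TSS distances:
#'   \code{list(type = "uniform", min, max)} or
#'   \code{list(type = "triangular", min, max, mode)}.
#' @param mask_background destroy spontaneous CANNTG occurrences so scan
#'   counts equal planted counts exactly.
#' @param fixed_planted optional data.frame (gene_id, motif, distance_bp)
#'   overriding the Poisson draw for the listed genes with exactly these
#'   motifs at these TSS distances.
#' @param body_length gene-body length appended downstream of the TSS.
#' @param max_tries retry budget for motif placement and masking passes.
#' @param seed integer seed; fully determines all outputs.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{annotation}
#'   (\code{GRanges} of gene features), \code{planted} (data.frame gene_id,
#'   category, motif, distance_bp), \code{truth_ebox} (per-gene planted
#'   canonical/noncanonical counts and class).
#' @export
simulate_promoters <- function(truth, promoter_length = 3000,
                               class_ebox_means = list(
                                 DAY = c(canonical = 1.27, noncanonical = 1.27),
                                 NIGHT = c(canonical = 0.885, noncanonical = 0.885),
                                 ARRHYTHMIC = c(canonical = 0.285, noncanonical = 0.285)),
                               positional = list(type = "uniform", min = 1,
                                                 max = NULL),
                               mask_background = TRUE, body_length = 60,
                               max_tries = 200, fixed_planted = NULL,
                               seed = 1L) {
  .assert(promoter_length >= 6, "promoter_length must be >= 6")
  .assert(all(c("gene_id", "class") %in% names(truth)),
          "truth needs gene_id and class columns")
  L <- promoter_length
  if (is.null(positional$max)) positional$max <- L - 5
  .assert(positional$min >= 1 && positional$max <= L - 5,
          "positional distances must lie in [1, promoter_length - 5]")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  nc_pairs <- setdiff(apply(expand.grid(bases, bases), 1, paste, collapse = ""),
                      "CG")

  draw_distance <- function(n) {
    if (n == 0) return(integer(0))
    u <- switch(positional$type,
      uniform = runif(n, positional$min, positional$max + 1),
      triangular = {
        # inverse-CDF triangular on [min, max] with the given mode
        a <- positional$min; b <- positional$max + 1; cm <- positional$mode
        p <- runif(n)
        fc <- (cm - a) / (b - a)
        ifelse(p < fc, a + sqrt(p * (b - a) * (cm - a)),
               b - sqrt((1 - p) * (b - a) * (b - cm)))
      },
      stop("unknown positional distribution type", call. = FALSE))
    pmin(pmax(as.integer(floor(u)), positional$min), positional$max)
  }

  genes <- truth$gene_id
  seqs <- character(length(genes))
  planted <- vector("list", length(genes))
  truth_ebox <- data.frame(gene_id = genes, class = truth$class,
                           n_canonical = 0L, n_noncanonical = 0L,
                           stringsAsFactors = FALSE)

  for (g in seq_along(genes)) {
    cls <- as.character(truth$class[g])
    fixed <- if (!is.null(fixed_planted))
      fixed_planted[fixed_planted$gene_id == genes[g], , drop = FALSE]
    else NULL
    if (!is.null(fixed) && nrow(fixed) > 0) {
      motifs <- toupper(fixed$motif)
      dists <- as.integer(fixed$distance_bp)
      .assert(all(grepl("^CA[ACGT]{2}TG$", motifs)),
              sprintf("fixed motifs for gene '%s' must match CANNTG", genes[g]))
      n_can <- sum(motifs == "CACGTG")
      n_non <- length(motifs) - n_can
      n_tot <- length(motifs)
    } else {
      means <- class_ebox_means[[cls]]
      .assert(!is.null(means), sprintf("no E-box means for class '%s'", cls))
      n_can <- rpois(1, means[["canonical"]])
      n_non <- rpois(1, means[["noncanonical"]])
      n_tot <- n_can + n_non

      # non-overlapping distances (start separation >= 12 bp keeps planted
      # windows unambiguous and every spurious overlap maskable)
      dists <- integer(0)
      tries <- 0
      while (length(dists) < n_tot) {
        d <- draw_distance(1)
        if (all(abs(d - dists) >= 12)) dists <- c(dists, d)
        else {
          tries <- tries + 1
          .assert(tries <= max_tries,
                  sprintf("could not place %d E-boxes in gene '%s'",
                          n_tot, genes[g]))
        }
      }
      motifs <- c(rep("CACGTG", n_can),
                  if (n_non > 0) paste0("CA", nc_pairs[sample.int(15, n_non,
                                                                  replace = TRUE)],
                                        "TG"))
    }
    seq <- paste(sample(bases, L, replace = TRUE), collapse = "")
    starts <- L - dists - 4
    for (k in seq_len(n_tot)) substr(seq, starts[k], starts[k] + 5) <- motifs[k]

    if (mask_background) {
      protected <- unlist(lapply(starts, function(s) s:(s + 5)))
      pass <- 0
      repeat {
        hits <- scan_eboxes(seq, gene_id = genes[g])
        spurious <- hits[!(hits$start %in% starts), , drop = FALSE]
        if (nrow(spurious) == 0) break
        pass <- pass + 1
        .assert(pass <= max_tries,
                sprintf("background masking failed for gene '%s'", genes[g]))
        for (s0 in spurious$start) {
          pos <- setdiff(s0:(s0 + 5), protected)
          .assert(length(pos) > 0,
                  sprintf("unmaskable spurious E-box in gene '%s'", genes[g]))
          p <- pos[sample.int(length(pos), 1)]
          cur <- substr(seq, p, p)
          substr(seq, p, p) <- sample(setdiff(bases, cur), 1)
        }
      }
    }

    seqs[g] <- seq
    truth_ebox$n_canonical[g] <- n_can
    truth_ebox$n_noncanonical[g] <- n_non
    if (n_tot > 0) {
      planted[[g]] <- data.frame(
        gene_id = genes[g], category = ifelse(motifs == "CACGTG",
                                              "CANONICAL", "NONCANONICAL"),
        motif = motifs, distance_bp = dists, stringsAsFactors = FALSE)
    }
  }

  # assemble contigs: promoter + body in gene orientation; minus-strand
  # genes store the reverse complement so extraction round-trips
  strands <- rep(c("+", "-"), length.out = length(genes))
  bodies <- vapply(seq_along(genes), function(g)
    paste(sample(bases, body_length, replace = TRUE), collapse = ""),
    character(1))
  contigs <- vapply(seq_along(genes), function(g) {
    oriented <- paste0(seqs[g], bodies[g])
    if (strands[g] == "+") oriented else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(oriented)))
  }, character(1))
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- paste0("contig_", genes)

  starts_g <- ifelse(strands == "+", L + 1, 1)
  ends_g <- ifelse(strands == "+", L + body_length, body_length)
  annotation <- GenomicRanges::GRanges(
    seqnames = names(genome),
    ranges = IRanges::IRanges(start = starts_g, end = ends_g),
    strand = strands)
  annotation$type <- "gene"
  annotation$ID <- genes
  annotation$source <- "circadetox"

  list(genome = genome, annotation = annotation,
       planted = do.call(rbind, planted) %||% data.frame(
         gene_id = character(0), category = character(0), motif = character(0),
         distance_bp = integer(0), stringsAsFactors = FALSE),
       truth_ebox = truth_ebox, seed = as.integer(seed))
}

#' Write simulated genome and annotation to FASTA / GFF3
#'
#' @param sim result of \code{\link{simulate_promoters}}.
#' @param fasta_path,gff_path output paths.
#' @return named character vector of the paths, invisibly.
#' @export
write_promoter_files <- function(sim, fasta_path, gff_path) {
  Biostrings::writeXStringSet(sim$genome, fasta_path, width = 60)
  rtracklayer::export(sim$annotation, gff_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff = gff_path))
}
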