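test_that("promoter extraction is strand-aware with correct arithmetic", {
  # + strand, tss 5001 on a 6000 bp contig: bases 2001-5000
  set.seed(31)
  contig <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5600), "+")
  gr$type <- "gene"; gr$ID <- "gplus"
  prom <- extract_promoters(genome, gr)
  expect_equal(prom$length, 3000)
  expect_equal(prom$sequence, substr(contig, 2001, 5000))

  # - strand, tss 100 on a 4000 bp contig: revcomp of 101-3100
  grm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 100), "-")
  grm$type <- "gene"; grm$ID <- "gminus"
  genome2 <- Biostrings::DNAStringSet(c(chr1 = substr(contig, 1, 4000)))
  promm <- extract_promoters(genome2, grm)
  expect_equal(promm$length, 3000)
  expect_equal(promm$sequence, revcomp_chr(substr(contig, 101, 3100)))

  # truncation at the contig edge records the realized length
  grt <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 900), "+")
  grt$type <- "gene"; grt$ID <- "gshort"
  promt <- extract_promoters(genome, grt)
  expect_equal(promt$length, 500)

  # toy construction: motif planted 10 bp upstream of the TSS is recovered
  toy <- paste0(strrep("A", 100), "CACGTG", strrep("T", 10))
  gt <- GenomicRanges::GRanges("c", IRanges::IRanges(117, 120), "+")
  gt$type <- "gene"; gt$ID <- "toy"
  ph <- scan_eboxes(extract_promoters(
    Biostrings::DNAStringSet(c(c = toy)), gt, length = 116))
  expect_equal(ph$distance_bp, 11)  # motif ends 11 bp before the TSS base

  # missing contig names the gene
  gbad <- GenomicRanges::GRanges("nope", IRanges::IRanges(50, 60), "+")
  gbad$type <- "gene"; gbad$ID <- "lost"
  expect_error(extract_promoters(genome, gbad), "lost")
})

test_that("E-box scanner matches hand counts, variants and the N rule", {
  h <- scan_eboxes("AACACGTGTT", gene_id = "g")
  expect_equal(nrow(h), 1)
  expect_equal(h$category, "CANONICAL")
  expect_equal(h$distance_bp, 3)

  h2 <- scan_eboxes("CAACTGCATGTG", gene_id = "g")
  expect_setequal(h2$motif, c("CAACTG", "CATGTG"))
  expect_true(all(h2$category == "NONCANONICAL"))

  # N in the sequence never matches
  expect_equal(nrow(scan_eboxes("AACANNTGTT")), 0)
  expect_equal(nrow(scan_eboxes("CANGTGCACGNG")), 0)

  # overlapping occurrences are all counted
  h3 <- scan_eboxes("CACATGTG")  # CACATG at 1, CATGTG at 3
  expect_equal(h3$start, c(1, 3))
})

test_that("scanner equals the brute-force oracle and respects strand involution", {
  set.seed(41)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    got <- scan_eboxes(s, gene_id = "r")
    want <- brute_force_ebox_scan(s)
    expect_equal(got$start, want$start)
    expect_equal(got$motif, want$motif)

    # reverse complement: identical class-level count, canonical identical
    rc <- scan_eboxes(revcomp_chr(s), gene_id = "r")
    expect_equal(nrow(rc), nrow(got))
    expect_equal(sum(rc$category == "CANONICAL"),
                 sum(got$category == "CANONICAL"))
  }
})

test_that("per-class densities average hits over all genes in the class", {
  labels <- data.frame(gene_id = c("d1", "d2", "n1", "a1"),
                       phase_class = c("DAY", "DAY", "NIGHT", "ARRHYTHMIC"))
  hits <- data.frame(gene_id = c(rep("d1", 3), rep("d2", 2)),
                     category = c("CANONICAL", "CANONICAL", "NONCANONICAL",
                                  "NONCANONICAL", "NONCANONICAL"))
  dens <- ebox_density_by_class(hits, labels)
  expect_equal(dens$total[dens$phase_class == "DAY"], 2.5)
  expect_equal(dens$canonical[dens$phase_class == "DAY"], 1)
  expect_equal(dens$total[dens$phase_class == "NIGHT"], 0)
  expect_error(ebox_density_by_class(
    data.frame(gene_id = "zz", category = "CANONICAL"), labels), "labelled")
})

test_that("positional histogram bins distances and reports the focus mass", {
  hits <- data.frame(gene_id = c("a", "a", "b", "c"),
                     distance_bp = c(150, 450, 450, 2900))
  ph <- positional_histogram(hits)
  expect_equal(ph$bins$n_hits[ph$bins$bin_start == 0], 1)
  expect_equal(ph$bins$n_hits[ph$bins$bin_start == 300], 2)
  expect_equal(ph$bins$n_hits[ph$bins$bin_start == 2700], 1)
  # the two 450 bp hits come from distinct genes
  expect_equal(ph$bins$n_genes[ph$bins$bin_start == 300], 2)
  expect_equal(ph$mass_fraction_focus, 0.5)
  expect_error(positional_histogram(hits, bin_width = 400), "divide")
})

test_that("permutation enrichment is calibrated and exact at separation", {
  labels <- data.frame(gene_id = sprintf("g%02d", 1:30),
                       phase_class = rep(c("DAY", "NIGHT", "ARRHYTHMIC"), each = 10))
  # complete separation: minimal attainable p = 1 / (n_perm + 1)
  counts <- setNames(c(rep(5, 10), rep(0, 20)), labels$gene_id)
  enr <- permutation_enrichment(counts, labels, n_perm = 999, seed = 1)
  expect_equal(enr$p_value, c(1 / 1000, 1 / 1000))

  # identical distributions: p roughly uniform; median over seeds in [0.3, 0.7]
  set.seed(10)
  counts0 <- setNames(rpois(30, 2), labels$gene_id)
  ps <- vapply(1:11, function(s)
    permutation_enrichment(counts0, labels, n_perm = 199, seed = s)$p_value[1],
    numeric(1))
  expect_gte(median(ps), 0.3)
  expect_lte(median(ps), 0.7)

  # n_perm changes p resolution, not the observed statistic
  e1 <- permutation_enrichment(counts, labels, n_perm = 199, seed = 2)
  e2 <- permutation_enrichment(counts, labels, n_perm = 398, seed = 2)
  expect_equal(e1$observed_diff, e2$observed_diff)

  # empty class errors
  lab2 <- labels[labels$phase_class != "NIGHT", ]
  expect_error(permutation_enrichment(counts[lab2$gene_id], lab2, 199), "empty")
})

test_that("E-box mutation removes all canonical sites and is idempotent", {
  prom <- paste0(strrep("T", 20), "CACGTG", strrep("A", 20), "CACGTG",
                 strrep("G", 20), "CACGTG", strrep("T", 20))
  mut <- mutate_ebox(prom)
  expect_equal(mut$n_replaced, 3)
  expect_equal(sum(scan_eboxes(mut$sequence)$category == "CANONICAL"), 0)

  # idempotent; identity on motif-free input
  again <- mutate_ebox(mut$sequence)
  expect_equal(again$n_replaced, 0)
  expect_equal(again$sequence, mut$sequence)

  # overlapping construct collapses to a single replacement after re-scan
  ov <- mutate_ebox("CACGTGTG")
  expect_equal(ov$n_replaced, 1)
  expect_equal(ov$sequence, "TGTACATG")
})
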