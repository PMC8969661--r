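test_that("plus-strand regions follow the coordinate definitions with clipping", {
  g <- setNames(random_dna(10000), "chrT")
  m <- gene_model("tx", "chrT", "+",
                  rbind(c(1000, 1200), c(1400, 1600), c(1800, 2000)))
  rs <- extract_regions(m, g)
  reg <- rs$regions
  expect_equal(reg$start[reg$label == "upstream5k"], 0)    # clipped at 0
  expect_equal(reg$end[reg$label == "upstream5k"], 1000)
  expect_equal(unlist(reg[reg$label == "intron1", c("start", "end")],
                      use.names = FALSE), c(1200, 1400))
  expect_equal(unlist(reg[reg$label == "intron2", c("start", "end")],
                      use.names = FALSE), c(1600, 1800))
  expect_equal(unlist(reg[reg$label == "downstream5k", c("start", "end")],
                      use.names = FALSE), c(2000, 7000))
  expect_equal(rs$seqs[["intron1"]], unname(substr(g, 1201, 1400)))
})

test_that("minus-strand regions reflect transcript orientation and reverse-complement", {
  g <- setNames(random_dna(10000), "chrT")
  m <- gene_model("tx", "chrT", "-", rbind(c(3000, 3200), c(3500, 3700)))
  rs <- extract_regions(m, g)
  reg <- rs$regions
  expect_equal(unlist(reg[reg$label == "upstream5k", c("start", "end")],
                      use.names = FALSE), c(3700, 8700))
  expect_equal(unlist(reg[reg$label == "intron1", c("start", "end")],
                      use.names = FALSE), c(3200, 3500))
  expect_false("intron2" %in% reg$label)
  expect_equal(unlist(reg[reg$label == "downstream5k", c("start", "end")],
                      use.names = FALSE), c(0, 3000))
  # transcript-sense = reverse complement of the genomic slice
  slice <- substr(g, 3201, 3500)
  expect_equal(rs$seqs[["intron1"]],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(slice))))
})

test_that("single-exon transcripts have flanks only; degenerate regions warn", {
  g <- setNames(random_dna(2000), "chrT")
  m <- gene_model("solo", "chrT", "+", rbind(c(500, 800)))
  rs <- extract_regions(m, g)
  expect_setequal(rs$regions$label, c("upstream5k", "downstream5k"))
  # exon starting at 0 leaves an empty upstream region
  m0 <- gene_model("edge", "chrT", "+", rbind(c(0, 100)))
  expect_warning(rs0 <- extract_regions(m0, g), "zero-length")
  expect_equal(rs0$seqs[["upstream5k"]], "")
  expect_error(extract_regions(m, c(other = "ACGT")), "not present")
})

test_that("regions never overlap the transcript's exons and have consistent widths", {
  set.seed(77)
  g <- setNames(random_dna(30000), "chrT")
  for (strand in c("+", "-")) {
    m <- gene_model("tx", "chrT", strand,
                    rbind(c(9000, 9400), c(10500, 10800), c(12000, 12500)))
    rs <- extract_regions(m, g)
    for (i in seq_len(nrow(rs$regions))) {
      s <- rs$regions$start[i]; e <- rs$regions$end[i]
      expect_equal(nchar(rs$seqs[[rs$regions$label[i]]]), e - s)
      overlaps <- m$exons[, "start"] < e & s < m$exons[, "end"]
      expect_false(any(overlaps))
    }
  }
})

test_that("motif scanning classifies spacers from the sequence itself", {
  h2 <- scan_motifs("TTCAGGAA")
  expect_equal(h2$spacer_len, 2L)
  expect_equal(h2$spacer, "AG")
  h4 <- scan_motifs("TTCGAGGGAA")
  expect_equal(h4$spacer_len, 4L)
  expect_equal(h4$spacer, "GAGG")
  # two abutting spacer-2 motifs at distinct starts
  hh <- scan_motifs("TTCAGGAATTCCAGAA")
  expect_equal(hh$offset, c(0L, 8L))
  expect_equal(hh$spacer_len, c(2L, 2L))
  expect_equal(nrow(scan_motifs("ACGTACGTACGT")), 0)
  expect_equal(nrow(scan_motifs("")), 0)
  # lowercase input is normalised
  expect_equal(scan_motifs("ttcaggaa")$seq, "TTCAGGAA")
})

test_that("ambiguity codes never occupy a spacer position", {
  expect_equal(nrow(scan_motifs("TTCNNGAA")), 0)
  expect_equal(nrow(scan_motifs("TTCANTGAA")), 0)
  # but N elsewhere does not disturb a clean motif
  expect_equal(nrow(scan_motifs("NNTTCAGGAANN")), 1)
})

test_that("scanner agrees exactly with the brute-force reference on random sequence", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- random_dna(2000)
    expect_equal(scan_motifs(s), scan_motifs_bruteforce(s),
                 ignore_attr = TRUE)
  }
  # including sequences with interspersed Ns
  set.seed(99)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 3000, TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  expect_equal(scan_motifs(s), scan_motifs_bruteforce(s), ignore_attr = TRUE)
})

test_that("motif family is closed under reverse complement: counts match", {
  for (seed in 11:15) {
    set.seed(seed)
    s <- random_dna(3000)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(nrow(scan_motifs(s)), nrow(scan_motifs(rc)))
  }
})

test_that("no start offset ever matches two spacer lengths", {
  set.seed(123)
  for (i in 1:10) {
    s <- random_dna(5000)
    h <- scan_motifs(s)
    expect_false(any(duplicated(h$offset)))
  }
  # exhaustive-style subsample of 10-mers
  tenmers <- vapply(1:2000, function(i) random_dna(10), "")
  multi <- vapply(tenmers, function(s) {
    h <- scan_motifs(s)
    any(duplicated(h$offset))
  }, NA)
  expect_false(any(multi))
})

test_that("scan_gene attaches regions, genomic coordinates and STAT6 flags", {
  spec <- genome_sim_spec(
    planted = data.frame(
      transcript = c("TXPLUS1", "TXPLUS1", "TXMINUS1"),
      region = c("intron1", "upstream5k", "intron2"),
      offset = c(40L, 120L, 30L),
      spacer = c("AGGC", "TTGC", "CCA"),
      stringsAsFactors = FALSE),
    seed = 14)
  g <- gen_genome(spec)
  hits <- do.call(rbind, lapply(g$models, function(m) scan_gene(m, g$genome)))
  rownames(hits) <- NULL
  # exact agreement with the emitted truth
  expect_equal(hits[, c("transcript", "region", "offset", "seq",
                        "spacer_len", "spacer")],
               g$truth, ignore_attr = TRUE)
  # flag rules: N4 in intron 1 preferred; N4 upstream compatible only
  in1 <- hits[hits$transcript == "TXPLUS1" & hits$region == "intron1" &
                hits$offset == 40, ]
  expect_true(in1$stat6_compatible && in1$stat6_preferred && in1$in_intron1)
  up <- hits[hits$transcript == "TXPLUS1" & hits$region == "upstream5k" &
               hits$offset == 120, ]
  expect_true(up$stat6_compatible)
  expect_false(up$stat6_preferred)
  in2 <- hits[hits$transcript == "TXMINUS1" & hits$region == "intron2" &
                hits$offset == 30, ]
  expect_equal(in2$spacer_len, 3L)
  expect_true(in2$stat6_compatible)
  expect_false(in2$stat6_preferred)  # N3, not N4
  # genomic coordinates point at a real TTC in the genome
  for (j in seq_len(nrow(hits))) {
    chrom <- g$models[[hits$transcript[j]]]$chrom
    strand <- g$models[[hits$transcript[j]]]$strand
    sub <- substr(g$genome[[chrom]], hits$genomic_start[j],
                  hits$genomic_start[j] + nchar(hits$seq[j]) - 1)
    expected <- if (strand == "+") hits$seq[j] else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(hits$seq[j])))
    expect_equal(sub, expected)
  }
})

test_that("tabulation conserves totals across regions and spacer classes", {
  g <- gen_genome(genome_sim_spec(seed = 5))
  hits <- lapply(g$models, function(m) scan_gene(m, g$genome))
  tab <- tabulate_motifs(hits)
  expect_equal(sum(tab$summary$total), sum(tab$counts$n))
  expect_equal(sum(tab$summary$total), nrow(tab$long))
  for (i in seq_len(nrow(tab$summary))) {
    s <- tab$summary[i, ]
    expect_equal(s$total, s$n2 + s$n3 + s$n4)
    expect_equal(s$n34, s$n3 + s$n4)
    expect_lte(s$n4_first_two_introns, s$n4)
  }
  empty <- tabulate_motifs(scan_gene(gene_model("bare", "chrZ", "+",
                                                rbind(c(100, 200))),
                                     c(chrZ = paste(rep("A", 400),
                                                    collapse = ""))))
  expect_equal(nrow(empty$summary), 0)
})

test_that("printed report cells expand to hits with recomputed spacer classes", {
  cells <- data.frame(gene = c("X", "X"),
                      region = c("upstream", "introns1_2"),
                      sequence = c("TTCATGAATTCCTGAA", "TTCGAGGGAA"),
                      intron1 = c(FALSE, TRUE))
  h <- motif_hits_from_cells(cells)
  expect_equal(nrow(h), 3)
  expect_equal(sum(h$spacer_len == 2), 2)
  expect_true(h$stat6_preferred[h$seq == "TTCGAGGGAA"])
  expect_true(h$in_intron1[h$seq == "TTCGAGGGAA"])
})
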