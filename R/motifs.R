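## Gene-region extraction and STAT consensus motif scanning.
##
## The motif family is the palindromic GAS-like STAT consensus
## 5'-TTC(N)k GAA-3' with spacer length k in {2,3,4}. STAT6 binds the N3/N4
## forms and prefers N4 sites, particularly within a gene's first two
## introns; those rules are carried on every hit as flags.

REGION_LABELS <- c("upstream5k", "intron1", "intron2", "downstream5k")

## genomic coordinates (0-based half-open) of the four scanned regions,
## independent of sequence. "first exon"/introns follow TRANSCRIPT
## orientation: on the minus strand the first exon has the highest
## genomic coordinates.
region_coordinates <- function(model, chrom_len, flank = 5000L) {
  ex <- model$exons
  n <- nrow(ex)
  gaps <- if (n > 1) cbind(ex[-n, 2], ex[-1, 1]) else
    matrix(integer(0), ncol = 2)
  regions <- list()
  if (model$strand == "+") {
    regions$upstream5k   <- c(max(0L, ex[1, 1] - flank), ex[1, 1])
    if (n >= 2) regions$intron1 <- gaps[1, ]
    if (n >= 3) regions$intron2 <- gaps[2, ]
    regions$downstream5k <- c(ex[n, 2], min(chrom_len, ex[n, 2] + flank))
  } else {
    regions$upstream5k   <- c(ex[n, 2], min(chrom_len, ex[n, 2] + flank))
    if (n >= 2) regions$intron1 <- gaps[n - 1, ]
    if (n >= 3) regions$intron2 <- gaps[n - 2, ]
    regions$downstream5k <- c(max(0L, ex[1, 1] - flank), ex[1, 1])
  }
  out <- data.frame(label = names(regions),
                    start = vapply(regions, `[`, 0, 1),
                    end = vapply(regions, `[`, 0, 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[match(intersect(REGION_LABELS, out$label), out$label), , drop = FALSE]
}

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the scanned regions of a gene
#'
#' For one transcript, the four regions the motif analysis covers: 5 kb
#' upstream of the first exon, introns 1 and 2, and 5 kb downstream of the
#' last exon. "First" and "last" follow transcript orientation (on the
#' minus strand the first exon is the one with the highest genomic
#' coordinates). Regions are clipped at chromosome ends; intron regions
#' are absent when the transcript has fewer than 2 (or 3) exons. Region
#' sequences are returned transcript-sense (reverse-complemented for minus
#' strand genes).
#'
#' @param model A [gene_model()].
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param flank Flank size in bp (default 5000).
#' @return Object of class `RegionSet`: `transcript_id`, `chrom`, `strand`,
#'   `regions` (data.frame `label`, `start`, `end`, 0-based half-open
#'   genomic) and `seqs` (named character, transcript-sense).
#' @export
extract_regions <- function(model, genome, flank = 5000L) {
  genome <- as_genome(genome)
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " not present in genome")
  chrom_seq <- genome[[model$chrom]]
  chrom_len <- nchar(chrom_seq)
  if (max(model$exons[, 2]) > chrom_len)
    stop("exons of ", model$transcript_id, " extend beyond ", model$chrom)
  reg <- region_coordinates(model, chrom_len, flank)
  seqs <- vapply(seq_len(nrow(reg)), function(i) {
    s <- reg$start[i]; e <- reg$end[i]
    if (e <= s) {
      warning("zero-length region ", reg$label[i], " for ",
              model$transcript_id)
      return("")
    }
    sub <- substr(chrom_seq, s + 1L, e)
    if (model$strand == "-") revcomp(sub) else sub
  }, "")
  names(seqs) <- reg$label
  structure(list(transcript_id = model$transcript_id, chrom = model$chrom,
                 strand = model$strand, regions = reg, seqs = seqs),
            class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet %s (%s:%s)\n", x$transcript_id, x$chrom, x$strand))
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  %-12s [%d,%d) %d bp\n", x$regions$label[i],
                x$regions$start[i], x$regions$end[i],
                x$regions$end[i] - x$regions$start[i]))
  invisible(x)
}

empty_hits <- function() {
  data.frame(offset = integer(0), seq = character(0),
             spacer_len = integer(0), spacer = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for TTC(N)k GAA motifs
#'
#' Every start offset is tested for `TTC` + k unambiguous bases + `GAA`,
#' k in `spacer_range`. All occurrences are reported, including overlapping
#' ones at distinct starts; a given start can structurally match at most
#' one spacer length. `N` (or any non-ACGT code) never matches a spacer
#' position.
#'
#' @param sequence A single DNA string (A/C/G/T/N and IUPAC codes).
#' @param spacer_range Integer spacer lengths to test (default `2:4`).
#' @return data.frame ordered by offset: `offset` (0-based start within
#'   `sequence`), `seq` (matched 8-10-mer), `spacer_len`, `spacer`.
#' @examples
#' scan_motifs("TTCAGGAA")      # one N2 hit, spacer "AG"
#' scan_motifs("TTCGAGGGAA")    # one N4 hit, spacer "GAGG"
#' @export
scan_motifs <- function(sequence, spacer_range = 2:4) {
  stopifnot(length(sequence) == 1)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) return(empty_hits())
  hits <- lapply(spacer_range, function(k) {
    pat <- sprintf("(?=TTC[ACGT]{%d}GAA)", k)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    starts <- as.integer(m)          # 1-based
    data.frame(offset = starts - 1L,
               seq = substring(sequence, starts, starts + 5L + k),
               spacer_len = k,
               spacer = substring(sequence, starts + 3L, starts + 2L + k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) return(empty_hits())
  out[order(out$offset), , drop = FALSE]
}

## STAT6 rules: compatible = N3/N4 spacer; preferred = N4 spacer within
## the first two introns.
stat6_flags <- function(spacer_len, region) {
  first_two_introns <- region %in% c("intron1", "intron2") |
    region %in% "introns1_2"
  list(compatible = spacer_len %in% c(3L, 4L),
       preferred = spacer_len == 4L & first_two_introns)
}

#' Scan a gene's regions for STAT consensus motifs
#'
#' Applies [scan_motifs()] to each transcript-sense region sequence of
#' [extract_regions()] and annotates every hit with its region, genomic
#' coordinate, STAT6 flags and intron-1 membership.
#'
#' @inheritParams extract_regions
#' @param spacer_range Spacer lengths to scan (default `2:4`).
#' @return data.frame of class `MotifTable` with columns `transcript`,
#'   `region`, `offset` (0-based within the region sequence),
#'   `genomic_start` (1-based leftmost genomic base of the match, for
#'   reports), `seq`, `spacer_len`, `spacer`, `stat6_compatible`,
#'   `stat6_preferred`, `in_intron1`.
#' @export
scan_gene <- function(model, genome, flank = 5000L, spacer_range = 2:4) {
  rs <- extract_regions(model, genome, flank)
  rows <- lapply(seq_len(nrow(rs$regions)), function(i) {
    lab <- rs$regions$label[i]
    h <- scan_motifs(rs$seqs[[lab]], spacer_range)
    if (!nrow(h)) return(NULL)
    len <- nchar(h$seq)
    g0 <- if (model$strand == "+") rs$regions$start[i] + h$offset else
      rs$regions$end[i] - h$offset - len
    fl <- stat6_flags(h$spacer_len, lab)
    data.frame(transcript = model$transcript_id, region = lab,
               offset = h$offset, genomic_start = g0 + 1L,
               seq = h$seq, spacer_len = h$spacer_len, spacer = h$spacer,
               stat6_compatible = fl$compatible,
               stat6_preferred = fl$preferred,
               in_intron1 = lab == "intron1",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript = character(0), region = character(0),
                      offset = integer(0), genomic_start = integer(0),
                      seq = character(0), spacer_len = integer(0),
                      spacer = character(0), stat6_compatible = logical(0),
                      stat6_preferred = logical(0), in_intron1 = logical(0),
                      stringsAsFactors = FALSE)
  class(out) <- c("MotifTable", "data.frame")
  out
}

## map the four scan labels onto the three report columns
region_group_of <- function(region) {
  map <- c(upstream5k = "upstream", intron1 = "introns1_2",
           intron2 = "introns1_2", downstream5k = "downstream",
           upstream = "upstream", introns1_2 = "introns1_2",
           downstream = "downstream")
  unname(map[region])
}

#' Expand printed motif report cells into hits
#'
#' Reports of this motif family are commonly typeset as one cell per gene x
#' region x spacer class, where a cell may concatenate several abutting
#' motifs into one string. This helper re-scans each cell with
#' [scan_motifs()], so spacer classes come from the sequences themselves
#' rather than from the column a cell was printed under.
#'
#' @param cells data.frame with columns `gene`, `region` (one of
#'   `upstream`, `introns1_2`, `downstream`), `sequence` (the printed cell
#'   string) and optionally `intron1` (logical: cell marked as intron 1).
#' @return Hit data.frame with columns `gene`, `region_group`, `seq`,
#'   `spacer_len`, `spacer`, `stat6_compatible`, `stat6_preferred`,
#'   `in_intron1`.
#' @export
motif_hits_from_cells <- function(cells) {
  for (col in c("gene", "region", "sequence"))
    if (!col %in% names(cells)) stop("cells need column '", col, "'")
  if (is.null(cells$intron1)) cells$intron1 <- FALSE
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    h <- scan_motifs(cells$sequence[i])
    if (!nrow(h)) return(NULL)
    fl <- stat6_flags(h$spacer_len, cells$region[i])
    data.frame(gene = cells$gene[i],
               region_group = region_group_of(cells$region[i]),
               seq = h$seq, spacer_len = h$spacer_len, spacer = h$spacer,
               stat6_compatible = fl$compatible,
               stat6_preferred = fl$preferred,
               in_intron1 = as.logical(cells$intron1[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tabulate motif hits per gene, region and spacer class
#'
#' Aggregates hits (from [scan_gene()], [motif_hits_from_cells()] or a list
#' of either) into a long-format report plus per-gene summary counts: total
#' motifs, N2 count, N3/N4 (STAT6-compatible) count, and the count of N4
#' motifs within the first two introns (the STAT6-preferred configuration).
#'
#' @param hits A hit data.frame, or a list of them (rbound).
#' @return List with `long` (one row per hit: `gene`, `region_group`,
#'   `spacer_class`, `seq`, `in_intron1`), `counts` (per gene x
#'   region_group x spacer class) and `summary` (per gene: `total`, `n2`,
#'   `n3`, `n4`, `n34`, `n4_first_two_introns`).
#' @export
tabulate_motifs <- function(hits) {
  if (is.data.frame(hits)) hits <- list(hits)
  hits <- do.call(rbind, lapply(hits, function(h) {
    h <- as.data.frame(h)
    gene <- if (!is.null(h$gene)) h$gene else h$transcript
    rg <- if (!is.null(h$region_group)) h$region_group else
      region_group_of(h$region)
    in1 <- if (!is.null(h$in_intron1)) h$in_intron1 else
      rep(FALSE, nrow(h))
    data.frame(gene = gene, region_group = rg, spacer_len = h$spacer_len,
               seq = h$seq, in_intron1 = in1, stringsAsFactors = FALSE)
  }))
  if (is.null(hits) || !nrow(hits))
    return(list(long = data.frame(), counts = data.frame(),
                summary = data.frame(gene = character(0), total = integer(0),
                                     n2 = integer(0), n3 = integer(0),
                                     n4 = integer(0), n34 = integer(0),
                                     n4_first_two_introns = integer(0))))
  hits$spacer_class <- paste0("N", hits$spacer_len)
  long <- hits[, c("gene", "region_group", "spacer_class", "seq", "in_intron1")]
  counts <- as.data.frame(table(gene = hits$gene,
                                region_group = hits$region_group,
                                spacer_class = hits$spacer_class),
                          responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0, , drop = FALSE]
  per_gene <- function(g) {
    h <- hits[hits$gene == g, ]
    introns <- h$region_group == "introns1_2"
    data.frame(gene = g, total = nrow(h),
               n2 = sum(h$spacer_len == 2), n3 = sum(h$spacer_len == 3),
               n4 = sum(h$spacer_len == 4),
               n34 = sum(h$spacer_len %in% 3:4),
               n4_first_two_introns = sum(h$spacer_len == 4 & introns),
               stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, lapply(sort(unique(hits$gene)), per_gene))
  rownames(summary) <- NULL
  rownames(counts) <- NULL
  list(long = long, counts = counts, summary = summary)
}

#' Curated STAT-motif reference cells for six tight-junction genes
#'
#' A curated tabulation of the TTC(N)2-4GAA motif occurrences reported for
#' six human tight-junction genes (CLDN4, CLDN7, CLDN12, CLDN15, TJP1,
#' TJP2) across the three scanned region groups (5 kb upstream, first two
#' introns, 5 kb downstream). Cells are stored as printed — abutting
#' motifs may share one string — and `intron1` marks occurrences within
#' intron 1. Feed through [motif_hits_from_cells()] and
#' [tabulate_motifs()] to recover per-gene spacer-class counts.
#'
#' @return data.frame with columns `gene`, `region`, `sequence`, `intron1`.
#' @export
stat_motif_reference_cells <- function() {
  path <- system.file("extdata", "stat_motif_table1.tsv", package = "th2axis",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "character", "logical"))
}

#' Brute-force reference scan for TTC(N)k GAA motifs
#'
#' Independent check of [scan_motifs()]: tests every substring of length
#' 6 + k at every offset by direct string comparison, with no shared code
#' or regular expressions. Intended for validation and for emitting ground
#' truth from [gen_genome()].
#'
#' @inheritParams scan_motifs
#' @return Same shape as [scan_motifs()].
#' @export
scan_motifs_bruteforce <- function(sequence, spacer_range = 2:4) {
  stopifnot(length(sequence) == 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rows <- list()
  for (k in spacer_range) {
    w <- 6L + k
    if (n < w) next
    starts <- seq_len(n - w + 1L)                       # 1-based
    left <- substring(sequence, starts, starts + 2L)
    right <- substring(sequence, starts + 3L + k, starts + 5L + k)
    spacer <- substring(sequence, starts + 3L, starts + 2L + k)
    spacer_ok <- rep(TRUE, length(starts))
    for (j in seq_len(k)) {
      base_j <- substring(sequence, starts + 2L + j, starts + 2L + j)
      spacer_ok <- spacer_ok & base_j %in% c("A", "C", "G", "T")
    }
    ok <- left == "TTC" & right == "GAA" & spacer_ok
    if (any(ok))
      rows[[length(rows) + 1L]] <-
        data.frame(offset = starts[ok] - 1L,
                   seq = substring(sequence, starts[ok], starts[ok] + w - 1L),
                   spacer_len = k, spacer = spacer[ok],
                   stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_hits())
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
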