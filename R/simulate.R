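## Seeded generators producing inputs with the statistical structure the
## analysis assumes, each alongside its ground truth. All draws happen in a
## fixed documented order, so output is bit-reproducible given (spec, seed).

#' Specification for a synthetic two-group expression matrix
#'
#' The generator emulates the latent co-expression structure the
#' heterodimer screen assumes: per sample a latent factor z ~ N(0,1)
#' drives the two receptor-subunit probes (`subunit = a*z + e`) and the
#' planted target genes (`gene = +/- b*z + e`, sign per list), while null
#' probes are independent noise. Defaults mirror a 12-case/6-control
#' microarray study.
#'
#' @param n_group_a,n_group_b Sample counts for the two groups (defaults
#'   12 and 6; labels `"AR"` and `"control"`).
#' @param n_null_probes Number of independent background probes (default 500).
#' @param planted_positive,planted_negative Named numeric vectors: gene
#'   symbol -> loading b in (0, 1] (defaults: 10 genes each at 0.9).
#' @param subunit_loading Loading a in (0, 1] of the two subunit probes on
#'   the latent factor (default 0.9).
#' @param noise_sd Gaussian noise sd added to every probe (default 0.5).
#' @param subunit_a_probe,subunit_b_probe Probe ids of the receptor
#'   subunits (defaults: the IL4R and IL13RA1 array probes).
#' @param baseline Constant added to all values, mimicking a log2
#'   intensity scale (default 8).
#' @param seed Integer seed.
#' @return List of class `ExpressionSimSpec`.
#' @export
expression_sim_spec <- function(n_group_a = 12, n_group_b = 6,
                                n_null_probes = 500,
                                planted_positive =
                                  setNames(rep(0.9, 10), sprintf("POSG%02d", 1:10)),
                                planted_negative =
                                  setNames(rep(0.9, 10), sprintf("NEGG%02d", 1:10)),
                                subunit_loading = 0.9, noise_sd = 0.5,
                                subunit_a_probe = "203233_PM_at",
                                subunit_b_probe = "201887_PM_at",
                                baseline = 8, seed = 1) {
  loadings <- c(planted_positive, planted_negative, subunit_loading)
  if (length(loadings) && (any(loadings <= 0) || any(loadings > 1)))
    stop("loadings must lie in (0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_group_a < 0 || n_group_b < 0 || n_null_probes < 0)
    stop("counts must be >= 0")
  if (identical(subunit_a_probe, subunit_b_probe))
    stop("subunit probes must be distinct")
  if (anyDuplicated(c(names(planted_positive), names(planted_negative))))
    stop("planted gene symbols must be unique")
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 n_null_probes = n_null_probes,
                 planted_positive = planted_positive,
                 planted_negative = planted_negative,
                 subunit_loading = subunit_loading, noise_sd = noise_sd,
                 subunit_a_probe = subunit_a_probe,
                 subunit_b_probe = subunit_b_probe,
                 baseline = baseline, seed = as.integer(seed)),
            class = "ExpressionSimSpec")
}

#' Generate a synthetic expression matrix with planted correlated genes
#'
#' Draw order (fixed for reproducibility): latent factor per sample, then
#' noise for subunit A, subunit B, each planted positive gene, each planted
#' negative gene, then the null probe block.
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `matrix` (an [expression_matrix()]), `annotation`
#'   (probe id -> symbol; subunits annotated `IL4R`/`IL13RA1`, planted
#'   probes to their symbols, null probes to unique `BG*` symbols) and
#'   `truth` (list of `positive` and `negative` planted symbols).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "ExpressionSimSpec"))
  set.seed(spec$seed)
  n <- spec$n_group_a + spec$n_group_b
  if (n < 3) stop("need at least 3 samples in total")
  sample_ids <- sprintf("S%03d", seq_len(n))
  groups <- setNames(rep(c("AR", "control"),
                         c(spec$n_group_a, spec$n_group_b)), sample_ids)
  z <- rnorm(n)
  noise <- function() rnorm(n, 0, spec$noise_sd)
  a <- spec$subunit_loading
  rows <- list()
  rows[[spec$subunit_a_probe]] <- a * z + noise()
  rows[[spec$subunit_b_probe]] <- a * z + noise()
  annot <- setNames(c("IL4R", "IL13RA1"),
                    c(spec$subunit_a_probe, spec$subunit_b_probe))
  for (g in names(spec$planted_positive)) {
    pid <- paste0(g, "_at")
    rows[[pid]] <- spec$planted_positive[[g]] * z + noise()
    annot[pid] <- g
  }
  for (g in names(spec$planted_negative)) {
    pid <- paste0(g, "_at")
    rows[[pid]] <- -spec$planted_negative[[g]] * z + noise()
    annot[pid] <- g
  }
  if (spec$n_null_probes > 0) {
    null_ids <- sprintf("BG%05d_at", seq_len(spec$n_null_probes))
    null_block <- matrix(rnorm(spec$n_null_probes * n, 0, spec$noise_sd),
                         nrow = spec$n_null_probes, byrow = TRUE)
    for (i in seq_len(spec$n_null_probes)) rows[[null_ids[i]]] <- null_block[i, ]
    annot[null_ids] <- sprintf("BG%05d", seq_len(spec$n_null_probes))
  }
  values <- do.call(rbind, rows) + spec$baseline
  dimnames(values) <- list(names(rows), sample_ids)
  list(matrix = expression_matrix(values, groups),
       annotation = annot,
       truth = list(positive = names(spec$planted_positive),
                    negative = names(spec$planted_negative)))
}

#' Specification for a synthetic cohort table
#'
#' Emulates a two-group (case/control) cohort with lognormal serum analyte
#' levels shifted upwards in cases, and per-gene qPCR Ct values drawn
#' normally per group against a shared reference gene. Defaults sketch a
#' Th2-high allergic cohort: IL-4/IL-5/IL-6/IL-13 elevated in cases and a
#' modestly increased IL13RA1 transcript (lower target Ct).
#'
#' @param n_per_group Subjects per group (>= 3, default 30).
#' @param analytes Named list; each element a list with `meanlog`, `sdlog`
#'   (control lognormal parameters, natural-log scale of pg/ml) and
#'   `shift` (added to `meanlog` in cases).
#' @param genes Named list; each element a list with `ct_control`,
#'   `ct_case` (target-gene Ct means), `ct_ref` (reference-gene Ct mean,
#'   both groups) and `sd` (Ct sd).
#' @param seed Integer seed.
#' @return List of class `CohortSimSpec`.
#' @export
cohort_sim_spec <- function(n_per_group = 30,
                            analytes = list(
                              IL4  = list(meanlog = log(10), sdlog = 0.5, shift = log(2.0)),
                              IL5  = list(meanlog = log(15), sdlog = 0.5, shift = log(1.6)),
                              IL6  = list(meanlog = log(5),  sdlog = 0.5, shift = log(1.4)),
                              IL13 = list(meanlog = log(30), sdlog = 0.5, shift = log(2.5))),
                            genes = list(
                              IL13RA1 = list(ct_control = 26, ct_case = 25.3,
                                             ct_ref = 18, sd = 0.6)),
                            seed = 1) {
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  for (a in analytes) if (a$sdlog <= 0) stop("sdlog must be > 0")
  for (g in genes) if (g$sd <= 0) stop("Ct sd must be > 0")
  structure(list(n_per_group = n_per_group, analytes = analytes,
                 genes = genes, seed = as.integer(seed)),
            class = "CohortSimSpec")
}

#' Generate a synthetic cohort table
#'
#' Draw order: per analyte (control block then case block), then per gene
#' (reference Ct for all subjects, then target Ct control block, target Ct
#' case block).
#'
#' @param spec A [cohort_sim_spec()].
#' @return data.frame with columns `subject_id`, `group`
#'   (`"control"`/`"case"`), one `<analyte>_pgml` column per analyte, one
#'   `Ct_<gene>` column per gene and a shared `Ct_ref` column.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSimSpec"))
  set.seed(spec$seed)
  n <- spec$n_per_group
  out <- data.frame(subject_id = c(sprintf("C%03d", seq_len(n)),
                                   sprintf("A%03d", seq_len(n))),
                    group = rep(c("control", "case"), each = n),
                    stringsAsFactors = FALSE)
  for (nm in names(spec$analytes)) {
    a <- spec$analytes[[nm]]
    out[[paste0(nm, "_pgml")]] <-
      c(rlnorm(n, a$meanlog, a$sdlog), rlnorm(n, a$meanlog + a$shift, a$sdlog))
  }
  first <- TRUE
  for (nm in names(spec$genes)) {
    g <- spec$genes[[nm]]
    if (first) {
      out$Ct_ref <- rnorm(2 * n, g$ct_ref, g$sd)
      first <- FALSE
    }
    out[[paste0("Ct_", nm)]] <-
      c(rnorm(n, g$ct_control, g$sd), rnorm(n, g$ct_case, g$sd))
  }
  out
}

#' Specification for a synthetic genome with planted STAT motifs
#'
#' Random background sequence at a stated GC fraction, multi-exon gene
#' models, and TTC + spacer + GAA motifs written at requested transcript-
#' sense offsets inside named regions. Spontaneous background motifs are
#' not suppressed: ground truth is always a brute-force rescan of the
#' final sequence.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param models List of [gene_model()] objects.
#' @param planted data.frame with columns `transcript`, `region` (one of
#'   `upstream5k`, `intron1`, `intron2`, `downstream5k`), `offset` (0-based
#'   within the transcript-sense region sequence) and `spacer` (2-4
#'   unambiguous bases).
#' @param gc Background GC fraction (default 0.41).
#' @param flank Flank size used for region arithmetic (default 5000).
#' @param seed Integer seed.
#' @return List of class `GenomeSimSpec`.
#' @export
genome_sim_spec <- function(chrom_lengths = c(chrSim1 = 30000L),
                            models = list(
                              gene_model("TXPLUS1", "chrSim1", "+",
                                         rbind(c(6000, 6400), c(7000, 7300),
                                               c(8000, 8500))),
                              gene_model("TXMINUS1", "chrSim1", "-",
                                         rbind(c(15000, 15300), c(16000, 16250),
                                               c(17000, 17400)))),
                            planted = data.frame(
                              transcript = c("TXPLUS1", "TXPLUS1", "TXMINUS1"),
                              region = c("intron1", "upstream5k", "intron2"),
                              offset = c(50L, 100L, 20L),
                              spacer = c("AGGC", "AG", "TGA"),
                              stringsAsFactors = FALSE),
                            gc = 0.41, flank = 5000L, seed = 1) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (nrow(planted)) {
    k <- nchar(planted$spacer)
    if (any(!k %in% 2:4)) stop("spacer length must be 2, 3 or 4")
    if (any(grepl("[^ACGT]", toupper(planted$spacer))))
      stop("spacers must be unambiguous A/C/G/T")
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  structure(list(chrom_lengths = chrom_lengths, models = models,
                 planted = planted, gc = gc, flank = as.integer(flank),
                 seed = as.integer(seed)),
            class = "GenomeSimSpec")
}

#' Generate a synthetic genome with planted motifs and ground truth
#'
#' Background bases are drawn i.i.d. at the spec's GC fraction; each
#' planted motif `TTC<spacer>GAA` is written at its transcript-sense
#' region offset (reverse-complemented into the genome for minus-strand
#' transcripts). The truth table is produced by
#' [scan_motifs_bruteforce()] on the final region sequences, so
#' background motifs that arise by chance are part of the truth.
#'
#' @param spec A [genome_sim_spec()].
#' @return List with `genome` (named character), `models` (list of
#'   `GeneModel`) and `truth` (data.frame in the shape of [scan_gene()]
#'   minus the genomic columns: `transcript`, `region`, `offset`, `seq`,
#'   `spacer_len`, `spacer`).
#' @export
gen_genome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSimSpec"))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
         G = spec$gc / 2, T = (1 - spec$gc) / 2)
  chroms <- lapply(spec$chrom_lengths, function(len)
    sample(names(p), len, replace = TRUE, prob = p))
  # resolve planted motifs to genomic coordinates and check overlaps
  placements <- list()
  if (nrow(spec$planted)) for (i in seq_len(nrow(spec$planted))) {
    pl <- spec$planted[i, ]
    m <- spec$models[[pl$transcript]]
    if (is.null(m)) stop("unknown transcript in planted motifs: ", pl$transcript)
    reg <- region_coordinates(m, spec$chrom_lengths[[m$chrom]], spec$flank)
    r <- reg[reg$label == pl$region, ]
    if (!nrow(r)) stop("transcript ", pl$transcript, " has no region ", pl$region)
    motif <- paste0("TTC", toupper(pl$spacer), "GAA")
    len <- nchar(motif)
    if (pl$offset < 0 || pl$offset + len > r$end - r$start)
      stop("planted motif outside region bounds: ", pl$transcript, "/",
           pl$region, " offset ", pl$offset)
    g0 <- if (m$strand == "+") r$start + pl$offset else
      r$end - pl$offset - len
    written <- if (m$strand == "+") motif else revcomp(motif)
    placements[[i]] <- list(chrom = m$chrom, start = g0, end = g0 + len,
                            bases = strsplit(written, "")[[1]])
  }
  if (length(placements) > 1) {
    for (i in seq_along(placements)) for (j in seq_len(i - 1)) {
      a <- placements[[i]]; b <- placements[[j]]
      if (a$chrom == b$chrom && a$start < b$end && b$start < a$end)
        stop("planted motifs overlap in the genome")
    }
  }
  for (pl in placements)
    chroms[[pl$chrom]][(pl$start + 1):pl$end] <- pl$bases
  genome <- vapply(chroms, paste, "", collapse = "")
  # ground truth: independent brute-force scan of the final region sequences
  truth <- do.call(rbind, lapply(spec$models, function(m) {
    rs <- extract_regions(m, genome, spec$flank)
    do.call(rbind, lapply(rs$regions$label, function(lab) {
      h <- scan_motifs_bruteforce(rs$seqs[[lab]])
      if (!nrow(h)) return(NULL)
      cbind(data.frame(transcript = m$transcript_id, region = lab,
                       stringsAsFactors = FALSE), h)
    }))
  }))
  if (is.null(truth))
    truth <- data.frame(transcript = character(0), region = character(0),
                        offset = integer(0), seq = character(0),
                        spacer_len = integer(0), spacer = character(0))
  rownames(truth) <- NULL
  list(genome = genome, models = spec$models, truth = truth)
}
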