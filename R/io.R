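## Readers/writers for the external formats the pipeline touches.
## Internal coordinates are 0-based half-open everywhere; 1-based inclusive
## appears only in report columns.

#' Construct an expression matrix object
#'
#' Container for a processed (log-scale) probe-by-sample expression matrix
#' with a group label per sample. Values are used as supplied: no
#' renormalisation or log transform is applied.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing values.
#' @param sample_groups Named character vector mapping every sample id to a
#'   group label (e.g. `"AR"`, `"control"`).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `groups`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, c(s1 = "AR", s2 = "control"))
#' @export
expression_matrix <- function(values, sample_groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  missing_grp <- setdiff(colnames(values), names(sample_groups))
  if (length(missing_grp))
    stop("no group mapping for sample(s): ", paste(missing_grp, collapse = ", "))
  groups <- as.character(sample_groups[colnames(values)])
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  if (anyNA(x$values))
    cat(sprintf("missing values: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' Read a sample-to-group mapping
#'
#' Two-column headerless TSV: sample id, group label. Group membership is
#' always taken from this explicit mapping, never inferred from file
#' metadata.
#'
#' @param path Path to the TSV.
#' @return Named character vector `sample id -> group`.
#' @export
read_sample_groups <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("sample-group file needs two columns: sample id, group")
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample id in group mapping: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  setNames(df[[2]], df[[1]])
}

#' Read an expression matrix from TSV or a GEO series-matrix file
#'
#' The plain `tsv` dialect is a header line of sample ids (first column
#' name arbitrary) followed by one row per probe. The `series_matrix`
#' dialect is the GEO series-matrix layout: metadata lines prefixed `!`,
#' with the numeric table delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end`. Series-matrix metadata is never trusted for
#' sample grouping; `sample_groups` must be supplied explicitly.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"series_matrix"`.
#' @param sample_groups Named character vector (or path to a two-column TSV,
#'   see [read_sample_groups()]) mapping each sample id to its group.
#' @return An [expression_matrix()] object. Empty cells and `NA`/`NaN`
#'   tokens become `NA`; any other non-numeric cell is an error naming the
#'   offending probe and sample.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "series_matrix"),
                                   sample_groups) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(sample_groups) && length(sample_groups) == 1 &&
      is.null(names(sample_groups)) && file.exists(sample_groups))
    sample_groups <- read_sample_groups(sample_groups)

  if (dialect == "series_matrix") {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
      stop("malformed series-matrix file: table delimiters not found")
    tbl <- lines[(beg + 1):(end - 1)]
    df <- read.delim(text = paste(tbl, collapse = "\n"), header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE,
                     quote = "\"", colClasses = "character")
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE, colClasses = "character")
  }
  if (ncol(df) < 2) stop("expression table has no sample columns")
  probe_ids <- df[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells[cells %in% c("", "NA", "NaN", "null")] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], probe_ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]))
  dimnames(vals) <- list(probe_ids, colnames(cells))
  expression_matrix(vals, sample_groups)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]'s `tsv` dialect (group labels are
#' carried separately and are not written).
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param digits Significant digits for values (default 10).
#' @export
write_expression_matrix <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(probe_id = rownames(x$values),
                   signif(x$values, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' TSV with header and at least two columns: probe id, gene symbol. Symbols
#' are upper-cased on ingest; an empty symbol marks an unannotated probe.
#'
#' @param path File path.
#' @return Named character vector `probe id -> symbol` ("" = unannotated).
#' @export
read_probe_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("annotation needs columns: probe id, gene symbol")
  if (anyDuplicated(df[[1]]))
    stop("duplicate probe id in annotation: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  sym <- toupper(df[[2]])
  sym[is.na(sym)] <- ""
  setNames(sym, df[[1]])
}

#' Write a probe annotation table
#' @param annot Named character vector `probe id -> symbol`.
#' @param path Output path.
#' @export
write_probe_annotation <- function(annot, path) {
  write.table(data.frame(probe_id = names(annot), symbol = unname(annot)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene model
#'
#' One transcript: chromosome, strand and an ordered exon list. Exon
#' coordinates are 0-based half-open and sorted by ascending genomic start.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (start, end), 0-based half-open.
#' @return Object of class `GeneModel`.
#' @export
gene_model <- function(transcript_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1) stop("gene model needs at least one exon")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("zero- or negative-length exon in transcript ", transcript_id)
  if (any(exons[, 1] < 0)) stop("negative exon coordinate in ", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exons = exons), class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s:%s) %d exon(s), span [%d,%d)\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              min(x$exons[, 1]), max(x$exons[, 2])))
  invisible(x)
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 blocks, or GFF3 `exon` features grouped by their `Parent`
#' (falling back to a `transcript_id` attribute), become one [gene_model()]
#' per transcript. Coordinates are normalised to 0-based half-open
#' regardless of source convention (GFF3 starts are decremented).
#'
#' @param path File path.
#' @param format `"bed12"` or `"gff3"`.
#' @param genome Optional genome (as from [read_fasta()]) used to validate
#'   that exons lie within chromosome bounds.
#' @return List of `GeneModel` objects, named by transcript id.
#' @export
read_gene_models <- function(path, format = c("bed12", "gff3"), genome = NULL) {
  format <- match.arg(format)
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$name) || anyNA(gr$name))
      stop("BED12 records must carry a name (transcript id)")
    blk <- rtracklayer::blocks(gr)  # absolute 1-based exon ranges
    models <- lapply(seq_along(gr), function(i) {
      ex <- blk[[i]]
      gene_model(gr$name[i], as.character(GenomicRanges::seqnames(gr)[i]),
                 as.character(GenomicRanges::strand(gr)[i]),
                 cbind(BiocGenerics::start(ex) - 1L, BiocGenerics::end(ex)))
    })
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "exon"]
    if (!length(gr)) stop("no exon features found in GFF3 file")
    tx <- if (!is.null(gr$Parent) && all(lengths(gr$Parent) > 0))
      vapply(gr$Parent, `[[`, "", 1) else gr$transcript_id
    if (is.null(tx) || anyNA(tx))
      stop("GFF3 exons must carry Parent or transcript_id")
    idx <- split(seq_along(gr), tx)
    models <- lapply(names(idx), function(id) {
      g <- gr[idx[[id]]]
      gene_model(id, as.character(GenomicRanges::seqnames(g)[1]),
                 as.character(GenomicRanges::strand(g)[1]),
                 cbind(BiocGenerics::start(g) - 1L, BiocGenerics::end(g)))
    })
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    for (m in models) {
      if (!m$chrom %in% names(genome))
        stop("chromosome ", m$chrom, " of ", m$transcript_id, " not in genome")
      if (max(m$exons[, 2]) > nchar(genome[[m$chrom]]))
        stop("exon of ", m$transcript_id, " beyond end of ", m$chrom)
    }
  }
  models
}

#' Write gene models as BED12
#' @param models List of `GeneModel` objects.
#' @param path Output path.
#' @export
write_bed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- m$exons
    chrom_start <- min(ex[, 1]); chrom_end <- max(ex[, 2])
    paste(m$chrom, chrom_start, chrom_end, m$transcript_id, 0L, m$strand,
          chrom_start, chrom_end, "0", nrow(ex),
          paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
          paste0(paste(ex[, 1] - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## normalize genome representations to a named character vector of
## upper-case sequences
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector or DNAStringSet")
  toupper(genome)
}

#' Read a (multi-)FASTA file
#'
#' Sequences are upper-cased; IUPAC ambiguity codes are preserved. The
#' sequence name is the first whitespace-delimited token of the header.
#'
#' @param path File path.
#' @return Named character vector `chrom -> sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  setNames(toupper(as.character(ss)), nm)
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member symbols. Members are upper-cased and deduplicated per set.
#'
#' @param path File path.
#' @return Named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  setNames(sets, nm)
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
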