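## The receptor-heterodimer co-correlation screen: every probe on the
## array is correlated against the two receptor-subunit probes within one
## sample group, thresholded at the sample-size critical r, categorised,
## and collapsed from probes to annotated genes.

SCREEN_CATEGORIES <- c("both_positive", "both_negative", "a_only", "b_only",
                       "discordant", "none")

#' Tight-junction / JAK-STAT watchlist gene symbols
#'
#' The epithelial-junction and JAK/STAT signalling genes conventionally
#' highlighted in heterodimer screens of airway epithelium: claudins
#' CLDN1-CLDN23, junctional adhesion molecules JAM1-3, desmogleins DSG1-4,
#' desmocollins DSC1-3, cadherins CDH1/2/3/12, zonula occludens TJP1-3,
#' and JAK1-3, STAT1/2/3/6, LTK, TYK2.
#'
#' @return Character vector of gene symbols.
#' @export
watchlist_tj_jakstat <- function() {
  c(paste0("CLDN", 1:23), paste0("JAM", 1:3),
    paste0("DSG", 1:4), paste0("DSC", 1:3),
    paste0("CDH", c(1, 2, 3, 12)), paste0("TJP", 1:3),
    paste0("JAK", 1:3), paste0("STAT", c(1, 2, 3, 6)), "LTK", "TYK2")
}

## two-tailed p for a vector of correlations at per-element sample sizes
cor_p_two_tailed <- function(r, n) {
  df <- n - 2
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & df >= 1
  tt <- abs(r[ok]) * sqrt(df[ok] / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * pt(tt, df[ok], lower.tail = FALSE)
  pmin(p, 1)
}

categorize_pair <- function(r_a, r_b, threshold) {
  sig_a <- !is.na(r_a) & abs(r_a) > threshold
  sig_b <- !is.na(r_b) & abs(r_b) > threshold
  cat <- rep("none", length(r_a))
  cat[sig_a & !sig_b] <- "a_only"
  cat[!sig_a & sig_b] <- "b_only"
  both <- sig_a & sig_b
  cat[both] <- "discordant"
  cat[both & r_a > threshold & r_b > threshold] <- "both_positive"
  cat[both & r_a < -threshold & r_b < -threshold] <- "both_negative"
  cat
}

#' Heterodimer co-correlation screen
#'
#' Within one sample group, Pearson-correlates every probe (except the two
#' subunit probes themselves) against each receptor-subunit probe, using
#' pairwise complete observations. Probes are categorised against the
#' significance threshold r* = [critical_r()](n, alpha) (or an explicit
#' override reproducing a published cutoff): `both_positive` (r_a > r* and
#' r_b > r*), `both_negative` (both < -r*), `a_only`/`b_only` (exactly one
#' |r| > r*), `discordant` (both significant, opposite signs), else
#' `none`. Probes with fewer than 3 complete pairs against either subunit
#' are flagged `low_n` and categorised `none`.
#'
#' @param mat An [expression_matrix()].
#' @param annot Named character vector probe id -> gene symbol ("" =
#'   unannotated); probes missing from `annot` are treated as unannotated.
#' @param subunit_a,subunit_b Probe ids of the two receptor subunits.
#' @param group Group label selecting the samples (n >= 3 required).
#' @param alpha Significance level defining r* (default 0.05).
#' @param r_threshold Optional explicit threshold overriding
#'   `critical_r(n, alpha)`.
#' @param watchlist Character vector of gene symbols to flag in the
#'   records (default [watchlist_tj_jakstat()]).
#' @return List of class `ScreenResult` with `records` (data.frame:
#'   `probe_id`, `gene`, `r_a`, `p_a`, `r_b`, `p_b`, `n_a`, `n_b`,
#'   `category`, `low_n`, `watchlist`) and `summary` (list: `threshold`,
#'   `alpha`, `group`, `n_samples`, `probe_counts`, `gene_counts`,
#'   `watchlist_genes` per category).
#' @export
screen_heterodimer <- function(mat, annot, subunit_a, subunit_b, group,
                               alpha = 0.05, r_threshold = NULL,
                               watchlist = watchlist_tj_jakstat()) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  vals <- mat$values
  for (s in c(subunit_a, subunit_b))
    if (!s %in% rownames(vals)) stop("subunit probe absent from matrix: ", s)
  if (identical(subunit_a, subunit_b)) stop("subunit probes must be distinct")
  samples <- names(mat$groups)[mat$groups == group]
  n <- length(samples)
  if (n < 3) stop("group '", group, "' has fewer than 3 samples")
  threshold <- if (is.null(r_threshold)) critical_r(n, alpha) else r_threshold
  if (threshold <= 0 || threshold >= 1) stop("r threshold must be in (0, 1)")

  sub <- vals[, samples, drop = FALSE]
  probes <- setdiff(rownames(sub), c(subunit_a, subunit_b))
  x <- t(sub[probes, , drop = FALSE])        # samples x probes
  va <- sub[subunit_a, ]
  vb <- sub[subunit_b, ]
  r_a <- suppressWarnings(as.vector(cor(x, va, use = "pairwise.complete.obs")))
  r_b <- suppressWarnings(as.vector(cor(x, vb, use = "pairwise.complete.obs")))
  n_a <- as.vector(crossprod(!is.na(x), !is.na(va)))
  n_b <- as.vector(crossprod(!is.na(x), !is.na(vb)))
  p_a <- cor_p_two_tailed(r_a, n_a)
  p_b <- cor_p_two_tailed(r_b, n_b)
  low_n <- n_a < 3 | n_b < 3 | is.na(r_a) | is.na(r_b)
  category <- categorize_pair(r_a, r_b, threshold)
  category[low_n] <- "none"
  gene <- unname(annot[probes])
  gene[is.na(gene)] <- ""
  records <- data.frame(probe_id = probes, gene = gene,
                        r_a = r_a, p_a = p_a, r_b = r_b, p_b = p_b,
                        n_a = n_a, n_b = n_b,
                        category = factor(category, SCREEN_CATEGORIES),
                        low_n = low_n,
                        watchlist = gene %in% watchlist,
                        stringsAsFactors = FALSE)
  gene_sets <- collapse_to_genes(records)
  summary <- list(threshold = threshold, alpha = alpha, group = group,
                  n_samples = n,
                  probe_counts = table(records$category),
                  gene_counts = vapply(gene_sets, length, 0L),
                  watchlist_genes = lapply(gene_sets, intersect, watchlist))
  structure(list(records = records, summary = summary),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Heterodimer screen: group '%s' (n = %d), |r| threshold %.4f\n",
              s$group, s$n_samples, s$threshold))
  for (cat_ in SCREEN_CATEGORIES)
    cat(sprintf("  %-13s %5d probes  %5d genes\n", cat_,
                s$probe_counts[[cat_]], s$gene_counts[[cat_]]))
  invisible(x)
}

#' Collapse probe-level screen records to unique gene symbols
#'
#' Unannotated probes (empty symbol) are dropped. Under the default
#' `"any"` rule a gene carries a category if at least one of its probes
#' does; under `"all"` every probe of the gene must agree.
#'
#' @param records Record data.frame from [screen_heterodimer()] (or a
#'   `ScreenResult`).
#' @param rule `"any"` (default) or `"all"`.
#' @return Named list of unique gene-symbol vectors, one per category.
#' @export
collapse_to_genes <- function(records, rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (inherits(records, "ScreenResult")) records <- records$records
  ann <- records[nzchar(records$gene), , drop = FALSE]
  out <- lapply(SCREEN_CATEGORIES, function(cat_) {
    if (!nrow(ann)) return(character(0))
    if (rule == "any") {
      sort(unique(ann$gene[ann$category == cat_]))
    } else {
      agg <- tapply(ann$category == cat_, ann$gene, all)
      sort(names(agg)[agg])
    }
  })
  setNames(out, SCREEN_CATEGORIES)
}

#' Export scatter-plot data for the screen
#'
#' One row per scored probe with both correlations, the category and the
#' watchlist flag — sufficient to regenerate dual-subunit correlation
#' scatter plots.
#'
#' @param screen A `ScreenResult`.
#' @param path Optional TSV output path.
#' @return (Invisibly, when `path` given) the exported data.frame with
#'   columns `probe_id`, `gene`, `r_a`, `r_b`, `category`, `watchlist`.
#' @export
export_scatter_data <- function(screen, path = NULL) {
  stopifnot(inherits(screen, "ScreenResult"))
  df <- screen$records[, c("probe_id", "gene", "r_a", "r_b", "category",
                           "watchlist")]
  df$category <- as.character(df$category)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
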