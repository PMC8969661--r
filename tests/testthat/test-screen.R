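toy_screen_matrix <- function() {
  # subunit rows identical; probe "dup" duplicates them exactly
  set.seed(21)
  z <- rnorm(8)
  vals <- rbind(subA = z, subB = z, dup = z, anti = -z,
                flat = rnorm(8, 0, 1))
  colnames(vals) <- paste0("s", 1:8)
  expression_matrix(vals, setNames(rep("AR", 8), colnames(vals)))
}

test_that("a probe duplicating both subunit signals is both_positive with r = 1", {
  em <- toy_screen_matrix()
  annot <- c(subA = "ILR_A", subB = "ILR_B", dup = "DUPG", anti = "ANTIG",
             flat = "FLATG")
  sc <- screen_heterodimer(em, annot, "subA", "subB", "AR")
  rec <- sc$records
  expect_equal(rec$r_a[rec$probe_id == "dup"], 1)
  expect_equal(rec$r_b[rec$probe_id == "dup"], 1)
  expect_equal(as.character(rec$category[rec$probe_id == "dup"]),
               "both_positive")
  expect_equal(as.character(rec$category[rec$probe_id == "anti"]),
               "both_negative")
  # the subunit probes themselves are never scored
  expect_false(any(rec$probe_id %in% c("subA", "subB")))
})

test_that("screen equals a brute-force recomputation on small matrices", {
  for (seed in 1:8) {
    set.seed(seed)
    em <- random_matrix(15, 10, group = "AR",
                        na_frac = if (seed %% 2) 0 else 0.08)
    annot <- setNames(sprintf("G%02d", 1:15), rownames(em$values))
    sc <- screen_heterodimer(em, annot, "p01", "p02", "AR")
    ref <- brute_screen(em, annot, "p01", "p02", "AR", sc$summary$threshold)
    rec <- sc$records[match(ref$probe_id, sc$records$probe_id), ]
    expect_equal(rec$r_a, ref$r_a, tolerance = 1e-12)
    expect_equal(rec$r_b, ref$r_b, tolerance = 1e-12)
    ok <- !is.na(ref$p_a)
    expect_equal(rec$p_a[ok], ref$p_a[ok], tolerance = 1e-12)
    expect_equal(rec$p_b[ok], ref$p_b[ok], tolerance = 1e-12)
    expect_equal(as.character(rec$category), ref$category)
  }
})

test_that("every scored probe gets exactly one category and counts conserve", {
  set.seed(31)
  em <- random_matrix(60, 9, group = "AR", na_frac = 0.05)
  annot <- setNames(sprintf("G%02d", 1:60), rownames(em$values))
  sc <- screen_heterodimer(em, annot, "p01", "p02", "AR")
  expect_equal(sum(sc$summary$probe_counts), nrow(sc$records))
  expect_true(all(!is.na(sc$records$category)))
  expect_true(all(sc$summary$gene_counts <= sum(sc$summary$probe_counts)))
})

test_that("raising the threshold never grows the both_* sets", {
  set.seed(17)
  em <- random_matrix(80, 12, group = "AR")
  annot <- setNames(sprintf("G%02d", 1:80), rownames(em$values))
  lo <- screen_heterodimer(em, annot, "p01", "p02", "AR", alpha = 0.05)
  hi <- screen_heterodimer(em, annot, "p01", "p02", "AR", alpha = 0.01)
  g_lo <- collapse_to_genes(lo)
  g_hi <- collapse_to_genes(hi)
  expect_true(all(g_hi$both_positive %in% g_lo$both_positive))
  expect_true(all(g_hi$both_negative %in% g_lo$both_negative))
})

test_that("swapping subunits mirrors a_only/b_only and fixes both_*", {
  set.seed(23)
  em <- random_matrix(50, 10, group = "AR")
  annot <- setNames(sprintf("G%02d", 1:50), rownames(em$values))
  ab <- screen_heterodimer(em, annot, "p01", "p02", "AR")
  ba <- screen_heterodimer(em, annot, "p02", "p01", "AR")
  g_ab <- collapse_to_genes(ab)
  g_ba <- collapse_to_genes(ba)
  expect_equal(g_ab$both_positive, g_ba$both_positive)
  expect_equal(g_ab$both_negative, g_ba$both_negative)
  expect_equal(g_ab$a_only, g_ba$b_only)
  expect_equal(g_ab$b_only, g_ba$a_only)
  expect_equal(g_ab$discordant, g_ba$discordant)
})

test_that("probes with too few complete pairs are flagged and unclassified", {
  vals <- matrix(rnorm(40), 5, 8,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:8)))
  vals["p3", 1:6] <- NA  # only 2 complete pairs
  em <- expression_matrix(vals, setNames(rep("AR", 8), colnames(vals)))
  sc <- screen_heterodimer(em, setNames(paste0("G", 1:5), paste0("p", 1:5)),
                           "p1", "p2", "AR")
  rec <- sc$records[sc$records$probe_id == "p3", ]
  expect_true(rec$low_n)
  expect_equal(as.character(rec$category), "none")
})

test_that("screen validates subunits, group size and threshold overrides", {
  em <- toy_screen_matrix()
  annot <- setNames(rep("", 5), rownames(em$values))
  expect_error(screen_heterodimer(em, annot, "nope", "subB", "AR"), "absent")
  expect_error(screen_heterodimer(em, annot, "subA", "subA", "AR"), "distinct")
  expect_error(screen_heterodimer(em, annot, "subA", "subB", "missing"),
               "fewer than 3")
  sc <- screen_heterodimer(em, annot, "subA", "subB", "AR", r_threshold = 0.603)
  expect_equal(sc$summary$threshold, 0.603)
})

test_that("null probes reach per-subunit significance at about the alpha rate", {
  sim <- gen_expression(expression_sim_spec(
    n_null_probes = 2000, planted_positive = setNames(0.9, "PP"),
    planted_negative = setNames(0.9, "NN"), seed = 12))
  sc <- screen_heterodimer(sim$matrix, sim$annotation,
                           "203233_PM_at", "201887_PM_at", "AR")
  nulls <- sc$records[grepl("^BG", sc$records$probe_id), ]
  rate <- mean(abs(nulls$r_a) > sc$summary$threshold)
  # binomial 3-sigma band around alpha = 0.05 for 2000 draws
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 0.001)
})

test_that("gene collapsing dedups symbols and drops unannotated probes", {
  rec <- data.frame(
    probe_id = paste0("p", 1:5),
    gene = c("CLDN4", "CLDN4", "", "TJP1", "TJP1"),
    category = factor(c("both_positive", "both_positive", "both_positive",
                        "both_negative", "none"),
                      levels = c("both_positive", "both_negative", "a_only",
                                 "b_only", "discordant", "none")),
    stringsAsFactors = FALSE)
  g_any <- collapse_to_genes(rec)
  expect_equal(g_any$both_positive, "CLDN4")
  expect_equal(g_any$both_negative, "TJP1")
  # under the all-probes rule TJP1 no longer qualifies
  g_all <- collapse_to_genes(rec, rule = "all")
  expect_equal(g_all$both_positive, "CLDN4")
  expect_equal(g_all$both_negative, character(0))
})

test_that("scatter export has one row per scored probe and flags the watchlist", {
  set.seed(41)
  vals <- matrix(rnorm(32), 4, 8,
                 dimnames = list(c("sa", "sb", "p1", "p2"), paste0("s", 1:8)))
  em <- expression_matrix(vals, setNames(rep("AR", 8), colnames(vals)))
  annot <- c(sa = "IL4R", sb = "IL13RA1", p1 = "CLDN4", p2 = "ZZZ9")
  sc <- screen_heterodimer(em, annot, "sa", "sb", "AR")
  df <- export_scatter_data(sc)
  expect_equal(nrow(df), 2)
  expect_true(df$watchlist[df$gene == "CLDN4"])
  expect_false(df$watchlist[df$gene == "ZZZ9"])
  tf <- withr::local_tempfile(fileext = ".tsv")
  export_scatter_data(sc, tf)
  expect_equal(nrow(read.delim(tf)), 2)
})
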