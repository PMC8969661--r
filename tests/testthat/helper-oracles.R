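# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# brute-force dual-subunit screen: per-probe cor.test loop with explicit
# category logic
brute_screen <- function(mat, annot, subunit_a, subunit_b, group, threshold) {
  samples <- names(mat$groups)[mat$groups == group]
  vals <- mat$values[, samples, drop = FALSE]
  probes <- setdiff(rownames(vals), c(subunit_a, subunit_b))
  va <- vals[subunit_a, ]
  vb <- vals[subunit_b, ]
  res <- lapply(probes, function(p) {
    x <- vals[p, ]
    one <- function(y) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) return(c(NA_real_, NA_real_, sum(ok)))
      ct <- cor.test(x[ok], y[ok])
      c(unname(ct$estimate), ct$p.value, sum(ok))
    }
    a <- one(va); b <- one(vb)
    cat_ <- if (anyNA(c(a[1], b[1]))) "none"
    else if (a[1] > threshold && b[1] > threshold) "both_positive"
    else if (a[1] < -threshold && b[1] < -threshold) "both_negative"
    else if (abs(a[1]) > threshold && abs(b[1]) > threshold) "discordant"
    else if (abs(a[1]) > threshold) "a_only"
    else if (abs(b[1]) > threshold) "b_only"
    else "none"
    data.frame(probe_id = p, r_a = a[1], p_a = a[2], r_b = b[1], p_b = b[2],
               category = cat_, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# random expression matrix with some missing values
random_matrix <- function(n_probes, n_samples, group = "g", na_frac = 0) {
  vals <- matrix(rnorm(n_probes * n_samples), n_probes, n_samples,
                 dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  if (na_frac > 0)
    vals[sample(length(vals), round(na_frac * length(vals)))] <- NA
  expression_matrix(vals, setNames(rep(group, n_samples), colnames(vals)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
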