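# helper: single-column grouped alignment from per-group residue vectors
column_aln <- function(frl, vl) {
  ids <- c(sprintf("f%02d", seq_along(frl)), sprintf("v%02d", seq_along(vl)))
  grouped_alignment(setNames(c(frl, vl), ids),
                    setNames(rep(c("FRL", "VL"), c(length(frl), length(vl))),
                             ids))
}

# independent re-evaluation of the specificity rule for one column
brute_rule <- function(frl, vl, rule = specificity_rule()) {
  freqs <- function(x) {
    x <- x[!x %in% c("-", "X")]
    table(x) / length(x)
  }
  gf <- mean(frl == "-"); gv <- mean(vl == "-")
  if (gf > rule$max_gap_fraction || gv > rule$max_gap_fraction)
    return("GAP_DOMINATED")
  f <- freqs(frl); v <- freqs(vl)
  f <- f[f > rule$max_noise_freq]; v <- v[v > rule$max_noise_freq]
  if (length(f) && !any(names(f) %in% names(v))) {
    single <- length(f) == 1L && f[[1L]] >= rule$min_frl_dominance
    classes <- list(c("I","L","V","M"), c("F","Y","W"), c("S","T"),
                    c("D","E"), c("K","R"), c("N","Q"))
    in_class <- any(vapply(classes, function(cl) all(names(f) %in% cl),
                           logical(1L)))
    class_ok <- rule$allow_similarity_class && in_class &&
      sum(f) >= rule$min_frl_dominance
    return(if (single || class_ok) "GROUP_SPECIFIC" else "VARIABLE")
  }
  shared <- length(f) && length(v) &&
    any(names(f)[f >= rule$min_frl_dominance] %in%
          names(v)[v >= rule$min_frl_dominance])
  if (shared) "SHARED_CONSERVED" else "VARIABLE"
}

test_that("fixed-residue replacements classify as group-specific", {
  # Ser-for-Gly replacement (the PsaB2-667 motif)
  aln <- column_aln(rep("S", 20), rep("G", 20))
  cls <- classify_columns(aln)
  expect_equal(cls$status, "GROUP_SPECIFIC")
  expect_equal(cls$frl_set, "S")
  expect_equal(cls$frl_consensus, "S")

  # identical Trp everywhere: shared, no group signal
  expect_equal(classify_columns(column_aln(rep("W", 20),
                                           rep("W", 20)))$status,
               "SHARED_CONSERVED")
})

test_that("similarity classes rescue mixed conserved columns", {
  # Val/Ile against Thr (the PsaB2-666 motif): specific only when
  # similarity classes are allowed
  set.seed(2)
  frl <- sample(c(rep("V", 12), rep("I", 8)))
  aln <- column_aln(frl, rep("T", 20))
  on <- classify_columns(aln, specificity_rule(allow_similarity_class = TRUE))
  off <- classify_columns(aln, specificity_rule(allow_similarity_class = FALSE))
  expect_equal(on$status, "GROUP_SPECIFIC")
  expect_equal(off$status, "VARIABLE")
  expect_equal(on$status, brute_rule(frl, rep("T", 20)))
  expect_equal(off$status,
               brute_rule(frl, rep("T", 20),
                          specificity_rule(allow_similarity_class = FALSE)))
})

test_that("classification agrees with brute-force rule evaluation", {
  set.seed(31)
  for (rep in 1:60) {
    frl <- sample(c(AA, "-"), 15, replace = TRUE,
                  prob = c(rep(0.02, 5), rep(0.12, 4), rep(0.02, 11), 0.3)[1:21])
    vl <- sample(c(AA, "-"), 15, replace = TRUE,
                 prob = c(rep(0.12, 4), rep(0.02, 16), 0.3))
    got <- classify_columns(column_aln(frl, vl))$status
    expect_equal(got, brute_rule(frl, vl), info = paste(rep))
  }
})

test_that("gap-dominated columns are flagged before any group call", {
  aln <- column_aln(c(rep("-", 12), rep("S", 8)), rep("G", 20))
  expect_equal(classify_columns(aln)$status, "GAP_DOMINATED")
})

test_that("tightening dominance never increases the specific count", {
  g <- generate_grouped_alignment(n_columns = 120, n_specific = 8,
                                  n_class_planted = 3, seed = 17)
  counts <- vapply(c(0.6, 0.75, 0.9, 0.97, 1.0), function(dom) {
    sum(classify_columns(g$aln,
                         specificity_rule(min_frl_dominance = dom))$status ==
          "GROUP_SPECIFIC")
  }, integer(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("label permutation destroys the planted group signal", {
  g <- generate_grouped_alignment(n_columns = 100, n_specific = 10,
                                  seed = 29)
  set.seed(53)
  fp <- replicate(100, {
    shuffled <- setNames(sample(g$aln$group), names(g$aln$group))
    perm <- grouped_alignment(g$aln$seq, shuffled)
    sum(classify_columns(perm)$status == "GROUP_SPECIFIC")
  })
  expect_lte(mean(fp), 0.01 * g$aln$n_columns)
})

test_that("classification ignores sequence order but weighs duplicates", {
  g <- generate_grouped_alignment(n_columns = 80, n_specific = 6, seed = 3)
  ord <- sample(names(g$aln$seq))
  perm <- grouped_alignment(g$aln$seq[ord], g$aln$group[ord])
  expect_equal(classify_columns(perm)$status, classify_columns(g$aln)$status)

  # raw-count frequencies: duplicating a minority variant can break a call
  frl <- c(rep("S", 29), "P")            # P at 1/30 <= noise -> specific
  aln1 <- column_aln(frl, rep("G", 10))
  expect_equal(classify_columns(aln1)$status, "GROUP_SPECIFIC")
  frl_dup <- c(frl, rep("P", 3))         # now 4/33 > noise threshold
  aln2 <- column_aln(frl_dup, rep("G", 10))
  expect_equal(classify_columns(aln2)$status, "VARIABLE")
})

test_that("planted alignments are classified with high sensitivity", {
  hits <- fps <- numeric(20)
  for (r in 1:20) {
    g <- generate_grouped_alignment(seed = 100 + r)
    cls <- classify_columns(g$aln)
    found <- which(cls$status == "GROUP_SPECIFIC")
    hits[r] <- mean(g$truth$column %in% found)
    fps[r] <- length(setdiff(found, g$truth$column)) /
      (g$aln$n_columns - nrow(g$truth))
  }
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(fps), 0.01)
})

test_that("ancestral conservation scoring counts retained columns", {
  # vacuous case: no specific columns
  aln <- column_aln(rep("W", 5), rep("W", 5))
  cls <- classify_columns(aln)
  sc <- score_ancestral_conservation(cls, "W")
  expect_equal(sc$n_specific, 0L)
  expect_equal(sc$n_conserved, 0L)
  expect_true(is.na(sc$fraction))

  # planted 10 specific, ancestor retains 7 by construction
  g <- generate_grouped_alignment(n_specific = 10, retained_fraction = 0.7,
                                  seed = 42)
  cls <- classify_columns(g$aln)
  sc <- score_ancestral_conservation(cls, g$ancestral_sequence)
  expect_equal(sc$n_specific, 10L)
  expect_equal(sc$n_conserved, 7L)
  expect_equal(sc$fraction, 0.7)
  flags <- sc$classifications$ancestral_conserved[g$truth$column]
  expect_equal(flags, g$truth$ancestral_retained)

  # unmapped columns (insertions relative to the ancestor) never count
  colmap <- seq_len(g$aln$n_columns)
  colmap[g$truth$column] <- NA
  sc2 <- score_ancestral_conservation(cls, g$ancestral_sequence, colmap)
  expect_equal(sc2$n_conserved, 0L)
})

test_that("per-subunit summary computes percent specific of consensus length", {
  g1 <- generate_grouped_alignment(n_columns = 50, n_specific = 8, seed = 8)
  g2 <- generate_grouped_alignment(n_columns = 50, n_specific = 0, seed = 9)
  tab <- per_subunit_summary(list(
    subA = list(cols = classify_columns(g1$aln), aln = g1$aln),
    subB = list(cols = classify_columns(g2$aln), aln = g2$aln)))
  expect_equal(tab$percent_specific[tab$subunit == "subA"], 16)
  expect_equal(tab$percent_specific[tab$subunit == "subB"], 0)
  expect_equal(tab$subunit, c("subA", "subB"))   # sorted descending
})
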