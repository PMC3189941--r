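# Site classification and the stratified divergence statistics.

# minimal annotated pair around explicit sequences (single region)
toy_annotated <- function(seq_a, seq_b, region = "utr3", id = "t1|t2") {
  n <- nchar(seq_a)
  structure(list(
    id_a = "t1", id_b = "t2", seq_a = seq_a, seq_b = seq_b,
    strand_a = "+", strand_b = "+",
    cds_a = c(0L, if (region == "cds") n else 0L),
    cds_b = c(0L, if (region == "cds") n else 0L),
    has_utr5 = FALSE, has_utr3 = region == "utr3",
    regions = data.frame(region = region, pos_a = 0:(n - 1),
                         pos_b = 0:(n - 1), stringsAsFactors = FALSE),
    rejected = FALSE, reason = NA_character_),
    class = "annotated_ortholog")
}

test_that("codon degeneracy classes follow the genetic code", {
  s <- classify_sites(toy_annotated("ATG", "ATG", region = "cds"))
  expect_identical(s$degeneracy, rep("nd", 3))   # Met: unique codon
  s2 <- classify_sites(toy_annotated("GGA", "GGG", region = "cds"))
  expect_identical(s2$degeneracy[3], "fourfold") # Gly family third position
  expect_true(s2$diff[3])
  # serine TCx vs AGy disagree in degeneracy at position 3 -> excluded
  s3 <- classify_sites(toy_annotated("TCT", "AGT", region = "cds"))
  expect_true(is.na(s3$degeneracy[3]))
})

test_that("exactly 32 sense codons have a fourfold-degenerate third position", {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  sense <- names(code)[code != "*"]
  # independent enumeration of the code
  oracle <- vapply(sense, function(cod) {
    alt <- vapply(c("A", "C", "G", "T"), function(b) {
      c2 <- cod; substr(c2, 3, 3) <- b; code[[c2]]
    }, character(1))
    all(alt == code[[cod]])
  }, logical(1))
  expect_identical(sum(oracle), 32L)
  impl <- site_degeneracy(sense, 3) == "fourfold"
  expect_identical(unname(impl), unname(oracle))
})

test_that("divergence arithmetic on a constructed alignment", {
  set.seed(71)
  a <- random_dna(100)
  s <- classify_sites(toy_annotated(a, a))
  row <- compute_divergence(s)
  expect_equal(row$pct_diff, 0)
  # force 2 transitions + 1 transversion at CpG-free spots
  v <- strsplit(a, "")[[1]]
  spots <- which(v %in% c("A", "C"))[1:3]
  v[spots[1]] <- c(A = "G", C = "T")[[v[spots[1]]]]
  v[spots[2]] <- c(A = "G", C = "T")[[v[spots[2]]]]
  v[spots[3]] <- c(A = "C", C = "A")[[v[spots[3]]]]
  b <- paste0(v, collapse = "")
  row2 <- compute_divergence(classify_sites(toy_annotated(a, b)))
  expect_equal(row2$pct_diff, 3.0)
  expect_equal(row2$ts_tv, 2.0)
  expect_equal(row2$compared_kb, 0.1)
})

test_that("CpG context uses the either-member rule", {
  s <- classify_sites(toy_annotated("ACGT", "ACGT"))
  expect_identical(s$cpg, c(FALSE, TRUE, TRUE, FALSE))
  comp <- composition(s)
  expect_equal(comp$pct_cpg, 50)
  expect_equal(comp$pct_gc, 50)
  expect_equal(composition(classify_sites(toy_annotated("ATAT", "ATAT")))$pct_cpg, 0)
  expect_equal(composition(classify_sites(toy_annotated("GCGC", "GCGC")))$pct_gc, 100)
  # a substitution destroying the CpG still leaves the column CpG-flagged
  s2 <- classify_sites(toy_annotated("ACGT", "ATGT"))
  expect_true(s2$cpg[2])
  # ... but not under the both-member rule
  s3 <- classify_sites(toy_annotated("ACGT", "ATGT"), cpg_rule = "both")
  expect_false(s3$cpg[2])
})

test_that("substitution counts are conserved across strata", {
  fx <- clean_fixture()
  sites <- do.call(rbind, lapply(truth_annotated(fx), classify_sites))
  for (region in c("utr5", "cds", "utr3")) {
    s <- sites[sites$region == region, ]
    n_all <- sum(s$diff)
    expect_identical(n_all, sum(s$diff & s$cpg) + sum(s$diff & !s$cpg))
    expect_identical(n_all, sum(s$diff & s$ts) + sum(s$diff & !s$ts))
  }
  # degeneracy classes partition the CDS columns
  cds <- sites[sites$region == "cds", ]
  tab <- table(factor(cds$degeneracy,
                      levels = c("nd", "twofold", "threefold", "fourfold")),
               useNA = "always")
  expect_identical(sum(tab), nrow(cds))
})

test_that("pooled divergence is invariant to locus order and splitting", {
  fx <- clean_fixture()
  ann <- truth_annotated(fx)
  sites <- do.call(rbind, lapply(ann, classify_sites))
  full <- compute_divergence(sites)
  shuffled <- compute_divergence(sites[sample(nrow(sites)), ])
  expect_equal(full$pct_diff, shuffled$pct_diff)
  expect_equal(full$ts_tv, shuffled$ts_tv)
  # merging two halves reproduces the pooled estimate
  h1 <- sites[sites$pair_id %in% unique(sites$pair_id)[1:20], ]
  h2 <- sites[!sites$pair_id %in% unique(sites$pair_id)[1:20], ]
  pooled <- (sum(h1$diff) + sum(h2$diff)) / (nrow(h1) + nrow(h2))
  expect_equal(full$pct_diff, 100 * pooled)
})

test_that("divergence table covers every stratum with compared sites", {
  fx <- clean_fixture()
  dt <- divergence_table(truth_annotated(fx))
  expect_true(all(c("utr5", "cds", "nd", "4d", "utr3") %in% dt$group))
  expect_true(all(dt$compared_kb > 0))
  expect_true(all(dt$pct_diff >= 0 & dt$pct_diff <= 100))
  # compared_kb adds up: All = CpG + non-CpG within each group
  for (g in unique(dt$group)) {
    all_kb <- dt$compared_kb[dt$group == g & dt$context == "All"]
    parts <- sum(dt$compared_kb[dt$group == g & dt$context != "All"])
    expect_equal(all_kb, parts)
  }
})

test_that("fold ratios handle equal strata and zero denominators", {
  tbl <- data.frame(group = c("cds", "cds"), context = c("No CpG", "CpG"),
                    pct_diff = c(2, 2))
  expect_equal(fold_ratios(tbl)$ratio, 1.0)
  tbl0 <- data.frame(group = c("cds", "cds"), context = c("No CpG", "CpG"),
                     pct_diff = c(0, 5))
  expect_true(is.na(fold_ratios(tbl0)$ratio))
})
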