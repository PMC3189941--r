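# Ka/Ks estimation: NG86 against the exhaustive pathway oracle, the
# YN-style estimator against NG86 in its reduction limit, and selection
# banding.

test_that("identical sequences give Ka = Ks = 0 for both methods", {
  set.seed(81)
  cds <- random_cds(60)
  for (r in list(ng86(cds, cds), yn(cds, cds))) {
    expect_equal(r$Ka, 0)
    expect_equal(r$Ks, 0)
    expect_true(is.na(r$ka_ks))
  }
})

test_that("a single synonymous change is counted as one S substitution", {
  cods <- c(rep("GAA", 50), "GGA", rep("GAA", 49))
  cods2 <- cods
  cods2[51] <- "GGG"                     # Gly third position: synonymous
  r <- ng86(paste0(cods, collapse = ""), paste0(cods2, collapse = ""))
  expect_equal(r$S_sub, 1)
  expect_equal(r$N_sub, 0)
  expect_equal(r$n_codons, 100)
  expect_equal(r$S_sites + r$N_sites, 300)
  expect_gt(r$Ks, 0)
  expect_equal(r$Ka, 0)
  # a Met-only background has no synonymous sites at all: the one
  # substitution saturates the synonymous proportion and is flagged
  r2 <- ng86(paste0(c(rep("ATG", 99), "GGA"), collapse = ""),
             paste0(c(rep("ATG", 99), "GGG"), collapse = ""))
  expect_true(r2$flagged)
})

test_that("pathway-averaged counts equal exhaustive enumeration for all codon pairs", {
  sense <- sense_codons()
  for (c1 in sense) {
    for (c2 in sense) {
      if (c1 == c2) next
      got <- orthodiv:::pathway_counts(c1, c2)
      want <- oracle_pathway_counts(c1, c2)
      expect_equal(unname(got[c("sd", "nd")]), unname(want),
                   tolerance = 1e-12,
                   info = paste(c1, c2))
    }
  }
})

test_that("ng86 substitution counts on 2-codon inputs match the oracle", {
  set.seed(83)
  sense <- sense_codons()
  for (rep in 1:200) {
    ca <- sample(sense, 2, replace = TRUE)
    cb <- sample(sense, 2, replace = TRUE)
    r <- ng86(paste0(ca, collapse = ""), paste0(cb, collapse = ""))
    want <- oracle_pathway_counts(ca[1], cb[1]) +
      oracle_pathway_counts(ca[2], cb[2])
    expect_equal(r$S_sub, unname(want["sd"]), tolerance = 1e-12)
    expect_equal(r$N_sub, unname(want["nd"]), tolerance = 1e-12)
  }
})

test_that("Ka and Ks are invariant to swapping the sequences", {
  set.seed(84)
  for (rep in 1:10) {
    a <- random_cds(150)
    b <- mutate_cds(a, 12)
    f <- ng86(a, b); g <- ng86(b, a)
    expect_equal(f$Ka, g$Ka)
    expect_equal(f$Ks, g$Ks)
    y1 <- yn(a, b); y2 <- yn(b, a)
    expect_equal(y1$Ka, y2$Ka, tolerance = 1e-10)
    expect_equal(y1$Ks, y2$Ks, tolerance = 1e-10)
  }
})

test_that("site counts are additive under concatenation", {
  set.seed(85)
  a1 <- random_cds(80); b1 <- mutate_cds(a1, 6)
  a2 <- random_cds(90); b2 <- mutate_cds(a2, 8)
  r1 <- ng86(a1, b1); r2 <- ng86(a2, b2)
  rc <- ng86(paste0(a1, a2), paste0(b1, b2))
  expect_equal(rc$S_sites, r1$S_sites + r2$S_sites)
  expect_equal(rc$S_sub, r1$S_sub + r2$S_sub)
  expect_equal(rc$N_sub, r1$N_sub + r2$N_sub)
  # same with the YN path under fixed kappa and uniform frequencies
  y1 <- yn(a1, b1, weighting = "uniform", kappa = 2)
  y2 <- yn(a2, b2, weighting = "uniform", kappa = 2)
  yc <- yn(paste0(a1, a2), paste0(b1, b2), weighting = "uniform", kappa = 2)
  expect_equal(yc$S_sites, y1$S_sites + y2$S_sites, tolerance = 1e-10)
})

test_that("yn reduces to ng86 with kappa 1 and uniform frequencies", {
  set.seed(86)
  for (rep in 1:10) {
    a <- random_cds(200)
    b <- mutate_cds(a, 18)          # ~3% divergence
    r <- ng86(a, b)
    y <- yn(a, b, weighting = "uniform", kappa = 1)
    expect_equal(y$S_sites, r$S_sites, tolerance = 1e-10)
    expect_equal(y$S_sub, r$S_sub, tolerance = 1e-10)
    expect_lt(abs(y$Ks - r$Ks), 0.05 * r$Ks + 1e-8)
    expect_lt(abs(y$Ka - r$Ka), 0.05 * r$Ka + 1e-8)
  }
})

test_that("selection bands follow the documented boundary conventions", {
  res <- data.frame(pair_id = c("p", "q", "r", "s", "t"),
                    Ka = 1, Ks = 1,
                    ka_ks = c(2.0, 0.7, 0.1, 1.0, 0.5))
  cl <- classify_selection(res)
  expect_identical(unname(cl$bands),
                   c(1L, 3L, 1L))  # >1; [0.5,1] incl. both boundaries; <0.5
  expect_identical(cl$results$selection_class[cl$results$pair_id == "s"],
                   "relaxed")
  expect_identical(cl$results$selection_class[cl$results$pair_id == "t"],
                   "relaxed")
  # sorted by descending ratio
  expect_identical(cl$results$pair_id[1], "p")
  # empty input
  cl0 <- classify_selection(res[0, ])
  expect_identical(unname(cl0$bands), c(0L, 0L, 0L))
})

test_that("pairs without synonymous changes report an undefined ratio", {
  cds <- strrep("GAA", 60)
  # one nonsynonymous change, no synonymous change
  cds2 <- paste0("GTA", strrep("GAA", 59))  # Glu -> Val
  r <- yn(cds, cds2, weighting = "uniform", kappa = 2)
  expect_gt(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ka_ks))
  cl <- classify_selection(rbind(r, yn(cds, cds)))
  expect_identical(sum(cl$bands), 0L)
  # under F3x4 weighting this monomorphic-codon fixture has zero
  # synonymous opportunity: Ks is undefined and the pair is flagged
  r2 <- yn(cds, cds2)
  expect_true(r2$flagged)
  expect_true(is.na(r2$ka_ks))
})
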