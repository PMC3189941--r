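# Generator: ancestral structure, composition control, substitution
# process, ground-truth consistency, fixture round-trips.

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cds_length_range = c(600, 300)), "inverted")
  expect_error(sim_config(cds_length_range = c(301, 302)),
               "no multiple of 3|>= 150")
  expect_error(sim_config(cds_length_range = c(120, 120)), ">= 150")
  expect_error(sim_config(utr5_length_range = c(0, 10)), "positive")
  expect_error(sim_config(gc_content = 1.2), "gc_content")
  expect_error(sim_config(branch_divergence = 0.5), "branch_divergence")
  expect_error(sim_config(kappa = 0), "kappa")
  expect_error(sim_config(omega = -1), "omega")
})

test_that("ancestors have the forced UTR5+CDS+UTR3 structure", {
  cfg <- sim_config(n_transcripts = 10, cds_length_range = c(300, 300),
                    utr5_length_range = c(50, 50),
                    utr3_length_range = c(80, 80), seed = 11)
  anc <- generate_ancestor_set(cfg)
  expect_length(anc$ancestors, 10)
  expect_true(all(nchar(anc$ancestors) == 430))
  for (i in seq_len(10)) {
    cds <- substr(anc$ancestors[[i]], anc$features$cds_start[i] + 1,
                  anc$features$cds_end[i])
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    aa <- translate_seq(cds)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    # reference protein is the exact translation
    expect_identical(anc$proteins[[anc$features$protein_id[i]]],
                     sub("\\*$", "", aa))
  }
})

test_that("cpg_enrichment = 0 eliminates CG dinucleotides", {
  cfg <- sim_config(n_transcripts = 8, cpg_enrichment = 0, seed = 12)
  anc <- generate_ancestor_set(cfg)
  expect_false(any(grepl("CG", anc$ancestors, fixed = TRUE)))
})

test_that("realized GC tracks the target over ~100 kb", {
  cfg <- sim_config(n_transcripts = 120, cds_length_range = c(600, 600),
                    utr5_length_range = c(100, 100),
                    utr3_length_range = c(150, 150), gc_content = 0.5,
                    cpg_enrichment = 1, paralog_fraction = 0, seed = 13)
  anc <- generate_ancestor_set(cfg)
  v <- strsplit(paste0(anc$ancestors, collapse = ""), "")[[1]]
  expect_gte(length(v), 1e5)
  gc <- mean(v %in% c("G", "C"))
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
})

test_that("CpG dinucleotide frequency increases with cpg_enrichment", {
  freqs <- vapply(c(0.4, 1, 1.6), function(e) {
    cfg <- sim_config(n_transcripts = 40, cpg_enrichment = e, seed = 14)
    anc <- generate_ancestor_set(cfg)
    s <- paste0(anc$ancestors, collapse = "")
    length(gregexpr("CG", s, fixed = TRUE)[[1]]) / nchar(s)
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
})

test_that("zero divergence leaves descendants identical to the ancestor", {
  cfg <- sim_config(n_transcripts = 5, branch_divergence = 0,
                    paralog_fraction = 0, seed = 15)
  fx <- simulate_transcriptomes(cfg)
  for (i in 1:5) {
    id <- sprintf("gene%04d", i)
    expect_identical(fx$species_a[[paste0("A_", id)]], fx$ancestors[[id]])
    expect_identical(fx$species_b[[paste0("B_", id)]], fx$ancestors[[id]])
  }
  expect_identical(nrow(fx$truth$substitutions), 0L)
})

test_that("omega = 0 suppresses all nonsynonymous substitutions", {
  cfg <- sim_config(n_transcripts = 20, omega = 0, paralog_fraction = 0,
                    branch_divergence = 0.04, seed = 16)
  fx <- simulate_transcriptomes(cfg)
  cds_subs <- subset(fx$truth$substitutions, region == "cds")
  expect_gt(nrow(cds_subs), 0)
  expect_true(all(cds_subs$syn))
})

test_that("extreme transition bias yields almost exclusively transitions", {
  cfg <- sim_config(n_transcripts = 60, kappa = 1000,
                    branch_divergence = 0.02, paralog_fraction = 0,
                    seed = 17)
  fx <- simulate_transcriptomes(cfg)
  subs <- fx$truth$substitutions
  expect_gt(nrow(subs), 300)
  # in UTRs the kappa mapping acts alone: ts fraction ~ kappa/(kappa+2)
  utr <- subs[subs$region != "cds", ]
  expect_gt(mean(utr$ts), 0.99)
  # in the CDS, redraws at stop-adjacent sites divert a little mass to
  # transversions, so the overall fraction sits slightly lower
  expect_gt(mean(subs$ts), 0.95)
})

test_that("truth log matches the Hamming differences between descendants", {
  fx <- clean_fixture()
  tr <- subset(fx$truth$transcripts, species == "A")
  for (i in seq_len(nrow(tr))) {
    a <- strsplit(fx$species_a[[tr$id[i]]], "")[[1]]
    b <- strsplit(fx$species_b[[tr$partner_id[i]]], "")[[1]]
    diffs <- which(a != b) - 1L
    subs <- subset(fx$truth$substitutions, ancestor_id == tr$ancestor_id[i] &
                     lineage %in% c("A", "B"))
    hit_counts <- table(subs$position)
    once <- as.integer(names(hit_counts)[hit_counts == 1])
    # every once-hit site differs; every difference lies at a logged site
    expect_true(all(once %in% diffs))
    expect_true(all(diffs %in% subs$position))
  }
})

test_that("descendant CDS translations contain no internal stop", {
  fx <- small_fixture()
  tr <- fx$truth$transcripts
  for (i in seq_len(nrow(tr))) {
    s <- if (tr$species[i] == "A") fx$species_a[[tr$id[i]]] else
      fx$species_b[[tr$id[i]]]
    aa <- translate_seq(substr(s, tr$cds_start[i] + 1, tr$cds_end[i]))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("paralog spiking adds the configured number of duplicates", {
  cfg0 <- sim_config(n_transcripts = 10, paralog_fraction = 0, seed = 18)
  fx0 <- simulate_transcriptomes(cfg0)
  expect_identical(sum(fx0$truth$transcripts$is_paralog), 0L)
  cfg1 <- sim_config(n_transcripts = 30, paralog_fraction = 0.1, seed = 18)
  fx1 <- simulate_transcriptomes(cfg1)
  expect_identical(sum(fx1$truth$transcripts$is_paralog), 3L)
  expect_length(fx1$species_a, 33)
  expect_length(fx1$species_b, 30)
  # duplicates carry their own protein id
  par <- subset(fx1$truth$transcripts, is_paralog)
  expect_true(all(par$protein_id %in% names(fx1$proteins)))
  expect_false(any(par$protein_id %in%
                     subset(fx1$truth$transcripts, !is_paralog)$protein_id))
})

test_that("fixtures round-trip through write_fixture/read_fixture", {
  for (seed in c(21, 22, 23)) {
    fx <- simulate_transcriptomes(sim_config(n_transcripts = 4, seed = seed))
    dir <- tempfile("fx")
    write_fixture(fx, dir)
    back <- read_fixture(dir)
    expect_identical(back$species_a, fx$species_a)
    expect_identical(back$species_b, fx$species_b)
    expect_identical(back$proteins, fx$proteins)
    expect_equal(back$truth$transcripts, fx$truth$transcripts)
    unlink(dir, recursive = TRUE)
  }
})

test_that("truth-channel CpG/non-CpG rate ratio tracks the multiplier", {
  fx <- small_fixture()  # default cpg_rate_multiplier = 4
  r <- truth_context_divergence(fx)
  expect_gt(r$ratio, 2)
  expect_lt(r$ratio, 8)
})
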