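# Protein-guided CDS/UTR delineation and the acceptance filters.

test_that("start codon search obeys the +/-30 bp in-frame window", {
  seq <- paste0(strrep("C", 60), "ATGAAATTT", strrep("C", 31))
  expect_identical(locate_start(seq, 60), 60L)      # exact
  expect_identical(locate_start(seq, 75), 60L)      # 15 bp upstream
  expect_identical(locate_start(seq, 90), 60L)      # 30 bp boundary
  expect_identical(locate_start(seq, 93), NA_integer_)  # 33 bp: outside
  expect_identical(locate_start(strrep("C", 99), 48), NA_integer_)
  # nearest candidate wins; exact tie goes upstream
  two <- paste0(strrep("C", 30), "ATG", strrep("C", 9), "ATG", strrep("C", 30))
  expect_identical(locate_start(two, 36), 30L)      # 6 up vs 6 down: upstream
  expect_identical(locate_start(two, 39), 42L)      # 3 down nearer than 9 up
})

test_that("stop codon search mirrors the start search with stop motifs", {
  seq <- paste0(strrep("C", 60), "TGA", strrep("C", 40))
  expect_identical(locate_stop(seq, 60), 60L)
  expect_identical(locate_stop(seq, 48), 60L)       # TGA 12 bp downstream
  expect_identical(locate_stop(seq, 27), NA_integer_)
  expect_identical(locate_stop(strrep("C", 99), 48), NA_integer_)
})

test_that("annotation recovers the true CDS on clean simulated pairs", {
  fx <- clean_fixture()
  tr <- subset(fx$truth$transcripts, species == "A")
  n_checked <- 0L
  for (i in seq_len(nrow(tr))) {
    ann <- annotate_pair(fx$species_a[[tr$id[i]]],
                         fx$species_b[[tr$partner_id[i]]],
                         fx$proteins[[tr$protein_id[i]]],
                         tr$id[i], tr$partner_id[i])
    expect_false(ann$rejected)
    expect_identical(ann$cds_a, c(tr$cds_start[i], tr$cds_end[i]))
    expect_identical(ann$cds_b, c(tr$cds_start[i], tr$cds_end[i]))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, nrow(tr))  # frame recovery 100%
})

test_that("reverse-complemented input recovers the same CDS on minus strand", {
  fx <- clean_fixture()
  tr <- subset(fx$truth$transcripts, species == "A")[1:3, ]
  for (i in 1:3) {
    fwd <- annotate_pair(fx$species_a[[tr$id[i]]],
                         fx$species_b[[tr$partner_id[i]]],
                         fx$proteins[[tr$protein_id[i]]])
    rev <- annotate_pair(revcomp(fx$species_a[[tr$id[i]]]),
                         fx$species_b[[tr$partner_id[i]]],
                         fx$proteins[[tr$protein_id[i]]])
    expect_false(rev$rejected)
    expect_identical(rev$strand_a, "-")
    expect_identical(substr(rev$seq_a, rev$cds_a[1] + 1, rev$cds_a[2]),
                     substr(fwd$seq_a, fwd$cds_a[1] + 1, fwd$cds_a[2]))
  }
})

test_that("short and broken CDS pairs are rejected with reason codes", {
  member <- function(seq, cs, ce) {
    list(seq = seq, strand = "+", frame = 0L, score = 100,
         cds_start = cs, cds_end = ce, start_found = TRUE, stop_found = TRUE)
  }
  set.seed(61)
  s147 <- paste0("ATG", random_cds(47), "TAA")  # 153 bp total
  a <- member(s147, 0L, 147L)                    # 147 bp CDS
  b <- member(s147, 0L, 147L)
  r <- extract_regions(a, b)
  expect_true(r$rejected)
  expect_identical(r$reason, "cds_too_short")
  r2 <- extract_regions(member(s147, 0L, 147L), member(s147, 0L, 149L))
  expect_identical(r2$reason, "cds_length_mismatch")
  r3 <- extract_regions(member(s147, 0L, 149L), member(s147, 0L, 149L))
  expect_identical(r3$reason, "cds_out_of_frame")
  # internal stop
  s_stop <- paste0("ATG", "TAA", random_cds(60), "TAA")
  m <- member(s_stop, 0L, nchar(s_stop))
  expect_identical(extract_regions(m, m)$reason, "internal_stop")
})

test_that("regions tile the annotated transcript without overlap", {
  fx <- clean_fixture()
  tr <- subset(fx$truth$transcripts, species == "A")[1:5, ]
  for (i in 1:5) {
    ann <- annotate_pair(fx$species_a[[tr$id[i]]],
                         fx$species_b[[tr$partner_id[i]]],
                         fx$proteins[[tr$protein_id[i]]])
    expect_false(any(duplicated(ann$regions$pos_a)))
    cds_pos <- ann$regions$pos_a[ann$regions$region == "cds"]
    expect_identical(range(cds_pos), c(ann$cds_a[1], ann$cds_a[2] - 1L))
    expect_true(all(ann$regions$pos_a[ann$regions$region == "utr5"] <
                      ann$cds_a[1]))
    expect_true(all(ann$regions$pos_a[ann$regions$region == "utr3"] >=
                      ann$cds_a[2]))
  }
})

test_that("acceptance is monotone in the minimum CDS length", {
  fx <- clean_fixture()
  tr <- subset(fx$truth$transcripts, species == "A")
  accepted <- vapply(c(150L, 400L, 700L), function(minlen) {
    p <- align_params(min_cds_length = minlen)
    sum(vapply(seq_len(nrow(tr)), function(i) {
      !annotate_pair(fx$species_a[[tr$id[i]]],
                     fx$species_b[[tr$partner_id[i]]],
                     fx$proteins[[tr$protein_id[i]]], params = p)$rejected
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(accepted) <= 0))
})
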