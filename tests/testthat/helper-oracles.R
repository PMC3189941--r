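# Independent oracles and shared fixtures for the test suite. Oracles are
# written from scratch against Biostrings primitives so they share no code
# with the package paths they check.

# ---- random sequence generators ------------------------------------------

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# scatter k random substitutions over a sequence
mutate_seq <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  idx <- sample(length(v), k)
  v[idx] <- vapply(v[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste0(v, collapse = "")
}

# random in-frame CDS of n_codons sense codons (no stops)
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  sense <- names(gc)[gc != "*"]
  paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS by k substitutions without creating internal stops
mutate_cds <- function(cds, k) {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  v <- strsplit(cds, "")[[1]]
  done <- 0L
  while (done < k) {
    i <- sample(length(v), 1)
    old <- v[i]
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    v[i] <- new
    ci <- (i - 1) %/% 3
    cod <- paste0(v[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    if (gc[[cod]] == "*") v[i] <- old else done <- done + 1L
  }
  paste0(v, collapse = "")
}

# ---- Smith-Waterman oracle (Biostrings) ----------------------------------

# local alignment score under the package's default scoring scheme
# (match 2, mismatch -3, linear gap -5)
sw_oracle_score <- function(a, b) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3),
    gapOpening = 0, gapExtension = 5))
}

# ---- exhaustive pathway-enumeration oracle -------------------------------

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})

.all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# equal-weight average of synonymous/nonsynonymous step counts over all
# minimal pathways between two sense codons, skipping pathways through a
# stop intermediate (falling back to all pathways if every one is blocked)
oracle_pathway_counts <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  walk <- function(ord, allow_stop) {
    cur <- c1
    sd <- nd <- 0
    for (s in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[s], ord[s]) <- substr(c2, ord[s], ord[s])
      if (.oracle_code[[nxt]] == "*" && s < length(ord) && !allow_stop) {
        return(NULL)
      }
      syn <- .oracle_code[[nxt]] == .oracle_code[[cur]] &&
        .oracle_code[[nxt]] != "*" && .oracle_code[[cur]] != "*"
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  perms <- .all_perms(dpos)
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

# ---- truth-channel helpers ------------------------------------------------

# build annotated_ortholog objects straight from the simulator ground truth
# (bypasses orthology/annotation, for testing the statistics modules alone)
truth_annotated <- function(fx) {
  tr <- fx$truth$transcripts
  rows <- which(tr$species == "A" & !tr$is_paralog)
  lapply(rows, function(i) {
    r <- tr[i, ]
    L <- nchar(fx$species_a[[r$id]])
    pos <- 0:(L - 1)
    region <- ifelse(pos < r$cds_start, "utr5",
                     ifelse(pos < r$cds_end, "cds", "utr3"))
    structure(list(
      id_a = r$id, id_b = r$partner_id,
      seq_a = fx$species_a[[r$id]], seq_b = fx$species_b[[r$partner_id]],
      strand_a = "+", strand_b = "+",
      cds_a = c(r$cds_start, r$cds_end), cds_b = c(r$cds_start, r$cds_end),
      has_utr5 = TRUE, has_utr3 = TRUE,
      regions = data.frame(region = region, pos_a = pos, pos_b = pos,
                           stringsAsFactors = FALSE),
      rejected = FALSE, reason = NA_character_),
      class = "annotated_ortholog")
  })
}

# memoised fixtures shared across test files
.fx_cache <- new.env(parent = emptyenv())
cached <- function(key, maker) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- maker()
  .fx_cache[[key]]
}

small_fixture <- function() {
  cached("small", function() {
    simulate_transcriptomes(sim_config(n_transcripts = 24, seed = 301))
  })
}

clean_fixture <- function() {
  cached("clean", function() {
    simulate_transcriptomes(sim_config(n_transcripts = 40,
                                       paralog_fraction = 0, seed = 302))
  })
}
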