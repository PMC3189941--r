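# Protein-guided CDS/UTR delineation on ortholog pairs: six-frame
# translation against the shared reference protein, in-frame start/stop
# search within a +/-30 bp window, then region extraction with the
# quality filters (CDS >= 150 bp, no internal stop, no indels;
# high-stringency UTR alignments only).

#' Protein-guided CDS localisation on a transcript
#'
#' Translates all six reading frames, aligns each translation to the
#' reference protein (BLOSUM62 Smith-Waterman) and returns the best frame
#' passing `min_protein_score`. Minus-strand hits are reported against the
#' reverse-complemented transcript, which downstream steps use as the
#' working sequence.
#'
#' @param transcript,protein Character scalars.
#' @param params An [align_params()].
#' @return `NULL` if no frame passes, else a list: `seq` (plus-strand
#'   working sequence), `strand`, `frame`, `score`, `aligned_start`,
#'   `aligned_end` (0-based half-open nt interval covered by the aligned
#'   protein residues), `ref_start`, `ref_end` (the interval extrapolated
#'   to the protein's first/last residue, clamped in frame to the
#'   transcript).
#' @export
protein_guided_cds <- function(transcript, protein, params = align_params()) {
  if (!nzchar(transcript) || !nzchar(protein)) stop("empty sequence")
  frames <- six_frame_translations(transcript)
  best <- NULL
  for (r in seq_len(nrow(frames))) {
    h <- protein_align(frames$aa[r], protein, params)
    if (is.null(h) || h$score < params$min_protein_score) next
    if (is.null(best) || h$score > best$hit$score) {
      best <- list(hit = h, frame = frames$frame[r], strand = frames$strand[r])
    }
  }
  if (is.null(best)) return(NULL)
  seq_used <- if (best$strand == "+") transcript else revcomp(transcript)
  f <- best$frame
  h <- best$hit
  n <- nchar(seq_used)
  aligned_start <- f + 3L * (h$q_start - 1L)
  aligned_end <- f + 3L * h$q_end
  ref_start <- aligned_start - 3L * (h$s_start - 1L)
  ref_end <- aligned_end + 3L * (nchar(protein) - h$s_end)
  # clamp extrapolated ends to the transcript while staying in frame
  while (ref_start < 0L) ref_start <- ref_start + 3L
  while (ref_end > n) ref_end <- ref_end - 3L
  list(seq = seq_used, strand = best$strand, frame = f, score = h$score,
       aligned_start = aligned_start, aligned_end = aligned_end,
       ref_start = ref_start, ref_end = ref_end)
}

#' Locate the start codon near the aligned reference start
#'
#' Searches in-frame positions within `window` bp (default 30) upstream or
#' downstream of `ref_start` for an ATG codon; among multiple candidates
#' the nearest wins, ties going upstream.
#'
#' @param seq Working (plus-strand) transcript sequence.
#' @param ref_start 0-based in-frame position of the reference protein's
#'   first residue on `seq`.
#' @param window Search half-width in bp.
#' @return 0-based start position, or `NA` if no in-frame ATG is in range.
#' @export
locate_start <- function(seq, ref_start, window = 30L) {
  locate_codon(seq, ref_start, window, "ATG")
}

#' Locate the stop codon near the aligned reference end
#'
#' Mirror of [locate_start()] for the TAA/TAG/TGA motifs around the
#' position just past the reference protein's last codon.
#'
#' @param seq Working (plus-strand) transcript sequence.
#' @param ref_stop 0-based in-frame position where the stop codon is
#'   expected to begin (i.e. the position just after the coding region
#'   implied by the reference protein).
#' @param window Search half-width in bp.
#' @return 0-based stop-codon position, or `NA`.
#' @export
locate_stop <- function(seq, ref_stop, window = 30L) {
  locate_codon(seq, ref_stop, window, STOP_CODONS)
}

locate_codon <- function(seq, ref_pos, window, motifs) {
  n <- nchar(seq)
  k <- window %/% 3L
  cand <- ref_pos + 3L * (-k:k)
  cand <- cand[cand >= 0L & cand + 3L <= n]
  if (!length(cand)) return(NA_integer_)
  cods <- substring(seq, cand + 1L, cand + 3L)
  hit <- cand[cods %in% motifs]
  if (!length(hit)) return(NA_integer_)
  d <- abs(hit - ref_pos)
  hit <- hit[d == min(d)]
  as.integer(min(hit))  # tie -> upstream
}

# annotate one member of a pair against the shared protein
annotate_member <- function(transcript, protein, params) {
  g <- protein_guided_cds(transcript, protein, params)
  if (is.null(g)) return(NULL)
  w <- params$start_stop_window
  st <- locate_start(g$seq, g$ref_start, w)
  sp <- locate_stop(g$seq, g$ref_end, w)
  cds_start <- if (!is.na(st)) st else g$ref_start
  cds_end <- if (!is.na(sp)) sp + 3L else g$ref_end
  list(seq = g$seq, strand = g$strand, frame = g$frame, score = g$score,
       cds_start = cds_start, cds_end = cds_end,
       start_found = !is.na(st), stop_found = !is.na(sp))
}

#' Extract and quality-filter CDS and UTR regions for an ortholog pair
#'
#' Builds the column-matched CDS alignment (codon-aware, substitution-only:
#' equal-length CDSs paired position by position; unequal lengths imply an
#' indel or frame disagreement and reject the pair) and applies the
#' filters: CDS alignment >= `min_cds_length` bp, length a multiple of 3,
#' no internal stop codon in either member. UTR alignments are attached
#' only when both members have the region, the start (resp. stop) codon
#' was located on both, and the UTR alignment passes the high-stringency
#' gate (>= `utr_min_length` gap-free columns at >= `utr_min_identity`).
#'
#' @param member_a,member_b Per-member annotations from the protein-guided
#'   step (internal structure; produced by [annotate_pair()]).
#' @param id_a,id_b Transcript ids.
#' @param params An [align_params()].
#' @return An `annotated_ortholog` (list with the working sequences, CDS
#'   intervals, and a `regions` data frame of compared columns: `region`,
#'   `pos_a`, `pos_b`, 0-based), or a rejection list with `rejected = TRUE`
#'   and a `reason` code.
#' @export
extract_regions <- function(member_a, member_b, id_a = "a", id_b = "b",
                            params = align_params()) {
  reject <- function(reason) {
    structure(list(id_a = id_a, id_b = id_b, rejected = TRUE, reason = reason),
              class = "annotated_ortholog")
  }
  la <- member_a$cds_end - member_a$cds_start
  lb <- member_b$cds_end - member_b$cds_start
  if (la != lb) return(reject("cds_length_mismatch"))
  if (la %% 3L != 0L) return(reject("cds_out_of_frame"))
  if (la < params$min_cds_length) return(reject("cds_too_short"))
  cds_a <- substr(member_a$seq, member_a$cds_start + 1L, member_a$cds_end)
  cds_b <- substr(member_b$seq, member_b$cds_start + 1L, member_b$cds_end)
  internal_stop <- function(cds) {
    aa <- translate_seq(cds)
    grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
  }
  if (internal_stop(cds_a) || internal_stop(cds_b)) {
    return(reject("internal_stop"))
  }
  regions <- data.frame(
    region = "cds",
    pos_a = member_a$cds_start + seq_len(la) - 1L,
    pos_b = member_b$cds_start + seq_len(lb) - 1L,
    stringsAsFactors = FALSE)
  utr5 <- utr3 <- FALSE
  if (member_a$start_found && member_b$start_found &&
      member_a$cds_start > 0L && member_b$cds_start > 0L) {
    u <- align_utr(substr(member_a$seq, 1L, member_a$cds_start),
                   substr(member_b$seq, 1L, member_b$cds_start),
                   0L, 0L, params)
    if (!is.null(u)) { regions <- rbind(regions, cbind(region = "utr5", u)); utr5 <- TRUE }
  }
  if (member_a$stop_found && member_b$stop_found &&
      member_a$cds_end < nchar(member_a$seq) &&
      member_b$cds_end < nchar(member_b$seq)) {
    u <- align_utr(substr(member_a$seq, member_a$cds_end + 1L, nchar(member_a$seq)),
                   substr(member_b$seq, member_b$cds_end + 1L, nchar(member_b$seq)),
                   member_a$cds_end, member_b$cds_end, params)
    if (!is.null(u)) { regions <- rbind(regions, cbind(region = "utr3", u)); utr3 <- TRUE }
  }
  structure(list(
    id_a = id_a, id_b = id_b,
    seq_a = member_a$seq, seq_b = member_b$seq,
    strand_a = member_a$strand, strand_b = member_b$strand,
    cds_a = c(member_a$cds_start, member_a$cds_end),
    cds_b = c(member_b$cds_start, member_b$cds_end),
    has_utr5 = utr5, has_utr3 = utr3,
    regions = regions, rejected = FALSE, reason = NA_character_),
    class = "annotated_ortholog")
}

# high-stringency UTR alignment; returns matched-column position maps
# (0-based, offset into the full working sequences) or NULL
align_utr <- function(utr_a, utr_b, off_a, off_b, params) {
  if (!nzchar(utr_a) || !nzchar(utr_b)) return(NULL)
  h <- tryCatch(local_align(utr_a, utr_b, params), error = function(e) NULL)
  if (is.null(h)) {
    # short UTRs can lack seeds; fall back to exhaustive DP
    h <- tryCatch(full_sw_align(utr_a, utr_b, params), error = function(e) NULL)
  }
  if (is.null(h) || h$n_gaps > 0L) return(NULL)
  if (h$n_columns < params$utr_min_length) return(NULL)
  if (is.na(h$identity) || h$identity < params$utr_min_identity) return(NULL)
  both <- h$q_idx > 0L & h$s_idx > 0L
  data.frame(pos_a = off_a + h$q_idx[both] - 1L,
             pos_b = off_b + h$s_idx[both] - 1L)
}

#' Annotate an ortholog pair with CDS and UTR regions
#'
#' Runs [protein_guided_cds()], [locate_start()] and [locate_stop()] on
#' both members against the shared reference protein, then
#' [extract_regions()].
#'
#' @param seq_a,seq_b Transcript sequences of the two members.
#' @param protein Shared reference protein sequence.
#' @param id_a,id_b Transcript ids carried into the result.
#' @param params An [align_params()].
#' @return An `annotated_ortholog` (possibly rejected; reason codes:
#'   `no_protein_hit`, `cds_length_mismatch`, `cds_out_of_frame`,
#'   `cds_too_short`, `internal_stop`).
#' @export
annotate_pair <- function(seq_a, seq_b, protein, id_a = "a", id_b = "b",
                          params = align_params()) {
  ma <- annotate_member(seq_a, protein, params)
  mb <- annotate_member(seq_b, protein, params)
  if (is.null(ma) || is.null(mb)) {
    return(structure(list(id_a = id_a, id_b = id_b, rejected = TRUE,
                          reason = "no_protein_hit"),
                     class = "annotated_ortholog"))
  }
  extract_regions(ma, mb, id_a, id_b, params)
}

#' Annotate all ortholog pairs in a pair table
#'
#' @param pairs Pair data frame from [paralog_filter()] (needs
#'   `shared_protein_id`).
#' @param set_a,set_b Transcript sets.
#' @param proteins Reference protein set.
#' @param params An [align_params()].
#' @return List of `annotated_ortholog` objects (accepted and rejected).
#' @export
annotate_pairs <- function(pairs, set_a, set_b, proteins,
                           params = align_params()) {
  lapply(seq_len(nrow(pairs)), function(r) {
    annotate_pair(set_a[[pairs$id_a[r]]], set_b[[pairs$id_b[r]]],
                  proteins[[pairs$shared_protein_id[r]]],
                  pairs$id_a[r], pairs$id_b[r], params)
  })
}
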