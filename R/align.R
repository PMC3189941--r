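# Pairwise local alignment: k-mer seeded, banded Smith-Waterman with linear
# gap penalties (the C++ kernel in src/banded_sw.cpp). Designed for the
# >= 80% identity regime of closely related orthologs, where the optimal
# local alignment hugs a single diagonal.

#' Alignment parameters
#'
#' @param match,mismatch Nucleotide match/mismatch scores. `N` against
#'   anything (including `N`) scores as a mismatch and never counts as a
#'   match; `N` columns are excluded from the identity denominator.
#' @param gap Linear gap penalty per gapped column (negative).
#' @param word_size k-mer length used for seeding (default 11).
#' @param band Band width in diagonals around the dominant seed diagonal
#'   (odd, default 31).
#' @param min_score Minimum local alignment score to report a hit.
#' @param min_pair_length RBH pairs whose alignment spans no more than this
#'   many columns are discarded (default 200, i.e. "longer than 200 bp").
#' @param min_identity Reporting floor on pair identity (default 0.80).
#' @param protein_gap Linear gap penalty for amino-acid alignments.
#' @param min_protein_score Minimum BLOSUM62 score for a protein hit to be
#'   considered significant. This raw-score cutoff is the package's
#'   surrogate for a BLAST E-value threshold (~1e-5 at short lengths);
#'   BLAST's Karlin-Altschul statistics are not reimplemented.
#' @param protein_tie_margin Two best protein hits to different proteins
#'   whose scores differ by at most this margin make the assignment
#'   ambiguous (default 0: exact ties).
#' @param protein_word_size k-mer length for the amino-acid candidate
#'   screen (default 4).
#' @param utr_min_length,utr_min_identity High-stringency UTR alignment
#'   quality gate (surrogate for an E-value < 1e-30 cutoff): at least 40
#'   aligned bp at identity >= 0.9.
#' @param start_stop_window Window (bp) around the aligned reference
#'   protein's ends searched for in-frame start/stop codons (default 30).
#' @param min_cds_length Minimum accepted CDS alignment length (bp).
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap = -5,
                         word_size = 11L, band = 31L, min_score = 40,
                         min_pair_length = 200L, min_identity = 0.80,
                         protein_gap = -10, min_protein_score = 60,
                         protein_tie_margin = 0,
                         protein_word_size = 4L,
                         utr_min_length = 40L, utr_min_identity = 0.9,
                         start_stop_window = 30L, min_cds_length = 150L) {
  if (word_size <= 0) stop("word_size must be positive")
  if (band <= 0 || band %% 2L == 0L) stop("band must be a positive odd integer")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 word_size = as.integer(word_size), band = as.integer(band),
                 min_score = min_score,
                 min_pair_length = as.integer(min_pair_length),
                 min_identity = min_identity,
                 protein_gap = protein_gap,
                 min_protein_score = min_protein_score,
                 protein_tie_margin = protein_tie_margin,
                 protein_word_size = as.integer(protein_word_size),
                 utr_min_length = as.integer(utr_min_length),
                 utr_min_identity = utr_min_identity,
                 start_stop_window = as.integer(start_stop_window),
                 min_cds_length = as.integer(min_cds_length)),
            class = "align_params")
}

# 5x5 DNA scoring matrix; N never matches
dna_score_matrix <- function(params) {
  m <- matrix(params$mismatch, 5, 5,
              dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(m)[1:4] <- params$match
  m
}

# integer k-mer codes (base 4) at every position; NA where the window
# contains a non-ACGT character
kmer_codes <- function(seq, k) {
  v <- match(chars(seq), DNA_BASES) - 1L
  L <- length(v)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  code <- numeric(n)
  bad <- logical(n)
  for (off in 0:(k - 1L)) {
    w <- v[(1L + off):(n + off)]
    bad <- bad | is.na(w)
    w[is.na(w)] <- 0L
    code <- code + w * 4^off
  }
  code[bad] <- NA_real_
  code
}

# dominant seed diagonal between two sequences, or NULL if no shared word
seed_diagonal <- function(query, subject, k) {
  qc <- kmer_codes(query, k)
  sc <- kmer_codes(subject, k)
  if (!length(qc) || !length(sc)) return(NULL)
  sp <- split(seq_along(sc), sc)
  qk <- as.character(qc)
  hit <- !is.na(qc) & qk %in% names(sp)
  if (!any(hit)) return(NULL)
  diags <- unlist(lapply(which(hit), function(i) i - sp[[qk[i]]]),
                  use.names = FALSE)
  tab <- table(diags)
  as.integer(names(tab)[which.max(tab)])
}

# shared helper: wrap the C++ kernel and compute alignment statistics
run_sw <- function(q_enc, s_enc, mat, gap, d_lo, d_hi,
                   q_chars = NULL, s_chars = NULL) {
  r <- .sw_band(q_enc, s_enc, mat, gap, d_lo, d_hi)
  ncol_aln <- length(r$q_idx)
  if (ncol_aln == 0L) return(NULL)
  both <- r$q_idx > 0L & r$s_idx > 0L
  if (!is.null(q_chars)) {
    qa <- q_chars[r$q_idx[both]]
    sa <- s_chars[r$s_idx[both]]
    informative <- qa != "N" & sa != "N"
    matches <- sum(qa == sa & informative)
    denom <- sum(informative)
  } else {
    qa <- q_enc[r$q_idx[both]]
    sa <- s_enc[r$s_idx[both]]
    matches <- sum(qa == sa)
    denom <- sum(both)
  }
  list(score = r$score,
       q_start = r$q_start, q_end = r$q_end,
       s_start = r$s_start, s_end = r$s_end,
       n_columns = ncol_aln, n_gaps = sum(!both),
       matches = matches,
       identity = if (denom > 0) matches / denom else NA_real_,
       q_idx = r$q_idx, s_idx = r$s_idx)
}

#' Local nucleotide alignment (k-mer seeded, banded Smith-Waterman)
#'
#' Finds shared `word_size`-mers, picks the diagonal with the most seed
#' support and runs a banded Smith-Waterman (`band` diagonals wide, linear
#' gap penalty) around it. Suitable for pairs at >= 80% identity. Returns
#' `NULL` when no seed exists or the best score is below `min_score`.
#'
#' @param query,subject Nucleotide sequences (character scalars, A/C/G/T/N).
#' @param params An [align_params()].
#' @return `NULL`, or a list with `score`, 1-based inclusive `q_start`,
#'   `q_end`, `s_start`, `s_end`, `n_columns` (alignment columns incl.
#'   gaps), `n_gaps`, `matches`, `identity` (N columns excluded from the
#'   denominator) and the aligned index maps `q_idx`, `s_idx` (0 = gap).
#' @export
local_align <- function(query, subject, params = align_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  d0 <- seed_diagonal(query, subject, params$word_size)
  if (is.null(d0)) return(NULL)
  half <- (params$band - 1L) %/% 2L
  qch <- chars(query); sch <- chars(subject)
  hit <- run_sw(encode_dna(qch), encode_dna(sch), dna_score_matrix(params),
                params$gap, d0 - half, d0 + half, qch, sch)
  if (is.null(hit) || hit$score < params$min_score) return(NULL)
  hit
}

#' Full (unbanded) Smith-Waterman nucleotide alignment
#'
#' Exhaustive dynamic programming over all diagonals; intended for short
#' sequences and for cross-checking the banded path.
#' @inheritParams local_align
#' @return As [local_align()], or `NULL` if the best score is below
#'   `min_score`.
#' @export
full_sw_align <- function(query, subject, params = align_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  qch <- chars(query); sch <- chars(subject)
  hit <- run_sw(encode_dna(qch), encode_dna(sch), dna_score_matrix(params),
                params$gap, 1L - length(sch), length(qch) - 1L, qch, sch)
  if (is.null(hit) || hit$score < params$min_score) return(NULL)
  hit
}

# ---- amino-acid alignment -------------------------------------------------

blosum62 <- function() {
  if (is.null(.odv$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .odv$blosum <- e$BLOSUM62
  }
  .odv$blosum
}

encode_aa <- function(chars_vec, alphabet) {
  v <- match(chars_vec, alphabet)
  v[is.na(v)] <- match("X", alphabet)
  v
}

#' Local protein alignment (full Smith-Waterman, BLOSUM62)
#'
#' @param query,subject Amino-acid sequences (character scalars; `*`
#'   allowed and scored by BLOSUM62's stop row).
#' @param params An [align_params()] (uses `protein_gap`).
#' @return As [local_align()] (identity over exact residue matches), or
#'   `NULL` for an empty alignment.
#' @export
protein_align <- function(query, subject, params = align_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  B <- blosum62()
  alph <- rownames(B)
  qch <- chars(query); sch <- chars(subject)
  run_sw(encode_aa(qch, alph), encode_aa(sch, alph), B, params$protein_gap,
         1L - length(sch), length(qch) - 1L, qch, sch)
}

# amino-acid k-mer codes over the 20 standard residues (base 25 on the
# BLOSUM62 alphabet); NA where the window contains X/*/unknown
aa_kmer_codes <- function(seq, k) {
  alph <- rownames(blosum62())[1:20]
  v <- match(chars(seq), alph) - 1L
  L <- length(v)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  code <- numeric(n)
  bad <- logical(n)
  for (off in 0:(k - 1L)) {
    w <- v[(1L + off):(n + off)]
    bad <- bad | is.na(w)
    w[is.na(w)] <- 0L
    code <- code + w * 25^off
  }
  code[bad] <- NA_real_
  code
}
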