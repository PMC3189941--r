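# Reciprocal-best-hit orthology with paralog removal through unambiguous
# shared best protein hits.

# k-mer index over a named set of nucleotide sequences:
# list(codes = per-seq unique codes, map = code -> integer seq indices)
build_kmer_index <- function(seqs, k) {
  per <- lapply(seqs, function(s) unique(kmer_codes(s, k)))
  per <- lapply(per, function(x) x[!is.na(x)])
  all_codes <- unlist(per, use.names = FALSE)
  seq_id <- rep(seq_along(per), lengths(per))
  list(map = split(seq_id, all_codes), n = length(seqs))
}

# candidate subject indices sharing >= min_shared k-mers with the query
kmer_candidates <- function(query_codes, index, min_shared = 1L) {
  qc <- unique(query_codes[!is.na(query_codes)])
  if (!length(qc)) return(integer(0))
  hits <- index$map[as.character(qc)]
  hits <- unlist(hits[!vapply(hits, is.null, logical(1))], use.names = FALSE)
  if (!length(hits)) return(integer(0))
  tab <- tabulate(hits, nbins = index$n)
  which(tab >= min_shared)
}

# Best hit of `query` into the subject set. Tie-break: highest score, then
# most alignment columns, then lexicographically smallest subject id.
best_hit <- function(query, subjects, params, index = NULL) {
  qc <- kmer_codes(query, params$word_size)
  cand <- if (is.null(index)) seq_along(subjects)
          else kmer_candidates(qc, index)
  if (!length(cand)) return(NULL)
  best <- NULL
  for (i in cand[order(names(subjects)[cand])]) {
    h <- local_align(query, subjects[[i]], params)
    if (is.null(h)) next
    h$subject_id <- names(subjects)[i]
    if (is.null(best) ||
        h$score > best$score ||
        (h$score == best$score && h$n_columns > best$n_columns)) {
      best <- h
    }
  }
  best
}

#' Reciprocal best hits between two transcript sets
#'
#' A pair is reported when each member is the other's best-scoring hit and
#' the alignment spans more than `min_pair_length` columns (default: longer
#' than 200 bp). Pair identity must reach `min_identity` (default 0.80).
#' Tie-breaking is deterministic (score, then aligned columns, then subject
#' id), so each transcript appears in at most one pair.
#'
#' @param set_a,set_b Named character vectors of nucleotide sequences.
#' @param params An [align_params()].
#' @return Data frame with one row per pair: `id_a`, `id_b`, `score_ab`,
#'   `score_ba`, `identity`, `n_columns`, `shared_protein_id` (NA until
#'   [paralog_filter()]).
#' @export
reciprocal_best_hits <- function(set_a, set_b, params = align_params()) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  idx_b <- build_kmer_index(set_b, params$word_size)
  idx_a <- build_kmer_index(set_a, params$word_size)
  best_ab <- lapply(set_a, best_hit, subjects = set_b, params = params,
                    index = idx_b)
  best_ba <- lapply(set_b, best_hit, subjects = set_a, params = params,
                    index = idx_a)
  rows <- list()
  for (ia in seq_along(set_a)) {
    h <- best_ab[[ia]]
    if (is.null(h)) next
    back <- best_ba[[h$subject_id]]
    if (is.null(back) || back$subject_id != names(set_a)[ia]) next
    if (h$n_columns <= params$min_pair_length) next
    identity <- mean(c(h$identity, back$identity))
    if (is.na(identity) || identity < params$min_identity) next
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = names(set_a)[ia], id_b = h$subject_id,
      score_ab = h$score, score_ba = back$score,
      identity = identity, n_columns = h$n_columns,
      shared_protein_id = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score_ab = numeric(0), score_ba = numeric(0),
                      identity = numeric(0), n_columns = integer(0),
                      shared_protein_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# All six reading-frame translations of a transcript.
# Returns data.frame(frame 0:2, strand +/-, aa) with the translated string.
six_frame_translations <- function(seq) {
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      L <- nchar(s) - f
      L <- L - (L %% 3L)
      if (L < 3L) next
      aa <- translate_seq(substr(s, f + 1L, f + L))
      out[[length(out) + 1L]] <- data.frame(
        frame = f, strand = strand, aa = aa, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Best protein hit for one transcript over a protein index: six-frame
# translations, k-mer candidate screen, full SW on candidates.
# Returns list(protein_id, score, frame, strand, hit, ambiguous).
best_protein_hit <- function(seq, proteins, params, index = NULL) {
  frames <- six_frame_translations(seq)
  scored <- list()
  for (r in seq_len(nrow(frames))) {
    aa <- frames$aa[r]
    cand <- if (is.null(index)) seq_along(proteins) else {
      kmer_candidates(aa_kmer_codes(aa, params$protein_word_size), index,
                      min_shared = 2L)
    }
    for (i in cand) {
      h <- protein_align(aa, proteins[[i]], params)
      if (is.null(h) || h$score < params$min_protein_score) next
      scored[[length(scored) + 1L]] <- list(
        protein_id = names(proteins)[i], score = h$score,
        frame = frames$frame[r], strand = frames$strand[r], hit = h)
    }
  }
  if (!length(scored)) return(NULL)
  sc <- vapply(scored, `[[`, numeric(1), "score")
  pid <- vapply(scored, `[[`, character(1), "protein_id")
  ord <- order(-sc, pid)
  best <- scored[[ord[1]]]
  # ambiguous if a different protein scores within the tie margin of the top
  others <- pid != best$protein_id
  best$ambiguous <- any(others & sc >= best$score - params$protein_tie_margin)
  best
}

# protein k-mer index (amino-acid words)
build_protein_index <- function(proteins, k) {
  per <- lapply(proteins, function(s) {
    x <- unique(aa_kmer_codes(s, k)); x[!is.na(x)]
  })
  all_codes <- unlist(per, use.names = FALSE)
  seq_id <- rep(seq_along(per), lengths(per))
  list(map = split(seq_id, all_codes), n = length(proteins))
}

#' Remove paralogs via unambiguous shared best protein hits
#'
#' Both members of each putative ortholog pair are compared (all six
#' translated frames) against the reference protein set. A pair is kept
#' only if both best hits pass `min_protein_score`, are unique best hits
#' (no different protein within `protein_tie_margin`), and name the same
#' protein, which is then recorded in `shared_protein_id`.
#'
#' @param pairs Data frame from [reciprocal_best_hits()].
#' @param set_a,set_b The transcript sets the pairs refer to.
#' @param proteins Named character vector of reference protein sequences.
#' @param params An [align_params()].
#' @return The filtered pair data frame with `shared_protein_id` filled in.
#' @export
paralog_filter <- function(pairs, set_a, set_b, proteins,
                           params = align_params()) {
  if (!length(proteins)) stop("protein set must be non-empty")
  if (!nrow(pairs)) return(pairs)
  idx <- build_protein_index(proteins, params$protein_word_size)
  need <- unique(c(pairs$id_a, pairs$id_b))
  hits <- lapply(need, function(id) {
    s <- if (id %in% names(set_a)) set_a[[id]] else set_b[[id]]
    best_protein_hit(s, proteins, params, index = idx)
  })
  names(hits) <- need
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ha <- hits[[pairs$id_a[r]]]
    hb <- hits[[pairs$id_b[r]]]
    ok <- !is.null(ha) && !is.null(hb) && !ha$ambiguous && !hb$ambiguous &&
      ha$protein_id == hb$protein_id
    if (ok) {
      keep[r] <- TRUE
      pairs$shared_protein_id[r] <- ha$protein_id
    }
  }
  pairs[keep, , drop = FALSE]
}
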