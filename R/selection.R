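# Pairwise Ka/Ks estimation on gap-free, in-frame CDS alignments:
# Nei-Gojobori (1986) counting with Jukes-Cantor correction, and a
# Yang-Nielsen (2000)-style approximate method (F3x4 positional codon
# frequencies, kappa estimated from fourfold-degenerate and nondegenerate
# sites, pathway weights including kappa/frequency/omega, K80-style
# corrections per substitution class, omega iterated to stability).

# neighbor table: one row per (sense codon, single-base change)
codon_neighbors <- function() {
  if (!is.null(.odv$nb)) return(.odv$nb)
  gc <- genetic_code()
  rows <- list()
  for (c1 in sense_codons()) {
    for (pos in 1:3) {
      from <- substr(c1, pos, pos)
      for (to in setdiff(DNA_BASES, from)) {
        c2 <- c1
        substr(c2, pos, pos) <- to
        rows[[length(rows) + 1L]] <- data.frame(
          from_codon = c1, pos = pos, to_base = to, to_codon = c2,
          ts = is_transition(from, to), is_stop = gc[[c2]] == "*",
          syn = gc[[c2]] == gc[[c1]], stringsAsFactors = FALSE)
      }
    }
  }
  .odv$nb <- do.call(rbind, rows)
  .odv$nb
}

# Per-codon synonymous site counts (x3 normalisation) for all 61 sense
# codons, given kappa and a 4x3 positional nucleotide frequency matrix
# (rows A,C,G,T). Mutations to stop codons are excluded from the
# opportunity, so S_c + N_c = 3 for every codon.
codon_site_counts <- function(kappa = 1, posfreq = NULL) {
  nb <- codon_neighbors()
  nb <- nb[!nb$is_stop, ]
  f <- if (is.null(posfreq)) rep(1, nrow(nb)) else {
    posfreq[cbind(match(nb$to_base, DNA_BASES), nb$pos)]
  }
  w <- ifelse(nb$ts, kappa, 1) * f
  tot <- rowsum(w, nb$from_codon)
  syn <- rowsum(w * nb$syn, nb$from_codon)
  s <- 3 * syn[, 1] / tot[, 1]
  setNames(s, rownames(tot))
}

# all minimal mutational pathways between two differing codons; each
# pathway is a data.frame of steps (from_codon, to_codon, pos, ts, syn,
# stop_intermediate)
codon_pathways <- function(c1, c2) {
  key <- paste(c1, c2)
  if (is.null(.odv$paths)) .odv$paths <- new.env(parent = emptyenv())
  if (!is.null(.odv$paths[[key]])) return(.odv$paths[[key]])
  gc <- genetic_code()
  dpos <- which(chars(c1) != chars(c2))
  perms <- switch(as.character(length(dpos)),
    "1" = list(dpos),
    "2" = list(dpos, rev(dpos)),
    "3" = {
      p <- list()
      for (i in dpos) for (j in setdiff(dpos, i)) {
        p[[length(p) + 1L]] <- c(i, j, setdiff(dpos, c(i, j)))
      }
      p
    })
  paths <- lapply(perms, function(ord) {
    cur <- c1
    steps <- list()
    blocked <- FALSE
    for (s in seq_along(ord)) {
      pos <- ord[s]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[[nxt]] == "*" && s < length(ord)) blocked <- TRUE
      steps[[s]] <- data.frame(
        from_codon = cur, to_codon = nxt, pos = pos,
        ts = is_transition(substr(cur, pos, pos), substr(c2, pos, pos)),
        syn = gc[[nxt]] == gc[[cur]] && gc[[nxt]] != "*" && gc[[cur]] != "*",
        stringsAsFactors = FALSE)
      cur <- nxt
    }
    list(steps = do.call(rbind, steps), blocked = blocked)
  })
  .odv$paths[[key]] <- paths
  paths
}

# Pathway-averaged substitution counts between two sense codons.
# Weights per pathway: product over steps of kappa^ts * f(target base at
# position) * omega^(nonsynonymous). Pathways passing through a stop codon
# are excluded (unless all are blocked, in which case all are used).
# Returns c(sd, nd, sd_ts, sd_tv, nd_ts, nd_tv).
pathway_counts <- function(c1, c2, kappa = 1, omega = 1, posfreq = NULL) {
  paths <- codon_pathways(c1, c2)
  blocked <- vapply(paths, `[[`, logical(1), "blocked")
  use <- if (all(blocked)) paths else paths[!blocked]
  w <- numeric(length(use))
  per <- matrix(0, nrow = length(use), ncol = 6)
  for (i in seq_along(use)) {
    st <- use[[i]]$steps
    f <- if (is.null(posfreq)) rep(1, nrow(st)) else {
      tb <- substring(st$to_codon, st$pos, st$pos)
      posfreq[cbind(match(tb, DNA_BASES), st$pos)]
    }
    w[i] <- prod(ifelse(st$ts, kappa, 1) * f * ifelse(st$syn, 1, omega))
    per[i, ] <- c(sum(st$syn), sum(!st$syn),
                  sum(st$syn & st$ts), sum(st$syn & !st$ts),
                  sum(!st$syn & st$ts), sum(!st$syn & !st$ts))
  }
  if (all(w == 0)) w <- rep(1, length(w))
  cnt <- colSums(per * (w / sum(w)))
  names(cnt) <- c("sd", "nd", "sd_ts", "sd_tv", "nd_ts", "nd_tv")
  cnt
}

# split an aligned CDS pair into comparable codon pairs; strips a shared
# terminal stop codon; codons with non-ACGT characters are dropped pairwise
prepare_codon_pairs <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned CDS lengths differ")
  if (nchar(seq_a) %% 3L != 0L) stop("CDS length not a multiple of 3")
  ca <- codon_split(seq_a)
  cb <- codon_split(seq_b)
  n <- length(ca)
  if (n && ca[n] %in% STOP_CODONS && cb[n] %in% STOP_CODONS) {
    ca <- ca[-n]; cb <- cb[-n]
  }
  sense <- sense_codons()
  ok <- ca %in% sense & cb %in% sense
  if (any(ca[!ok] %in% STOP_CODONS) || any(cb[!ok] %in% STOP_CODONS)) {
    bad_a <- ca[!ok][ca[!ok] %in% STOP_CODONS]
    bad_b <- cb[!ok][cb[!ok] %in% STOP_CODONS]
    if (length(bad_a) || length(bad_b)) stop("internal stop codon in CDS")
  }
  list(a = ca[ok], b = cb[ok])
}

kaks_row <- function(pair_id, method, n_codons, S, N, cnt, Ka, Ks,
                     kappa_hat, converged, flagged) {
  data.frame(pair_id = pair_id, method = method, n_codons = n_codons,
             S_sites = S, N_sites = N,
             S_sub = cnt[["sd"]], N_sub = cnt[["nd"]],
             Ka = Ka, Ks = Ks,
             ka_ks = if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_,
             kappa_hat = kappa_hat, converged = converged, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Equal-weight mutational-opportunity site counts (averaged over the two
#' sequences), equal-weight averaging over minimal substitution pathways
#' (stop-codon intermediates excluded), and Jukes-Cantor correction applied
#' separately to the synonymous and nonsynonymous proportions. A shared
#' terminal stop codon is stripped before counting.
#'
#' @param seq_a,seq_b Gap-free aligned CDS sequences (equal length,
#'   multiple of 3, no internal stops).
#' @param pair_id Identifier carried into the result.
#' @return One-row data frame (`KaKsResult`): effective site counts,
#'   fractional substitution counts, `Ka`, `Ks`, `ka_ks` (`NA` when
#'   `Ks = 0`), `kappa_hat` (`NA` for this method), and a `flagged` column
#'   set when a proportion >= 0.75 makes the correction undefined.
#' @export
ng86 <- function(seq_a, seq_b, pair_id = "pair") {
  cp <- prepare_codon_pairs(seq_a, seq_b)
  sc <- codon_site_counts(kappa = 1, posfreq = NULL)
  S <- (sum(sc[cp$a]) + sum(sc[cp$b])) / 2
  N <- 3 * length(cp$a) - S
  cnt <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  for (i in which(cp$a != cp$b)) {
    cnt <- cnt + pathway_counts(cp$a[i], cp$b[i])
  }
  ps <- if (S > 0) cnt[["sd"]] / S else 0
  pn <- if (N > 0) cnt[["nd"]] / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps); Ka <- jc(pn)
  kaks_row(pair_id, "NG86", length(cp$a), S, N, cnt, Ka, Ks,
           NA_real_, TRUE, is.na(Ka) || is.na(Ks))
}

# K80-style distance from transition proportion P and transversion
# proportion Q; NA when the logs are undefined
k80_dist <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

# kappa (ts/tv rate ratio) from K80 on a site class; NA if inestimable
k80_kappa <- function(P, Q, cap = 50) {
  if (P + Q == 0) return(NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(cap)
  ts_part <- -0.5 * log(w1) + 0.25 * log(w2)
  tv_part <- -0.5 * log(w2)
  if (tv_part <= 0) return(cap)
  min(cap, max(2 * ts_part / tv_part, 1e-6))
}

# estimate kappa from nondegenerate and fourfold-degenerate sites of the
# aligned codon pairs (classes where both codons agree on the degeneracy)
estimate_kappa <- function(ca, cb) {
  cls_n <- c(nd = 0L, fd = 0L); cls_ts <- c(nd = 0L, fd = 0L)
  cls_tv <- c(nd = 0L, fd = 0L)
  for (pos in 1:3) {
    da <- site_degeneracy(ca, pos)
    db <- site_degeneracy(cb, pos)
    ba <- substring(ca, pos, pos)
    bb <- substring(cb, pos, pos)
    for (cls in c("nd", "fd")) {
      want <- if (cls == "nd") "nd" else "fourfold"
      sel <- !is.na(da) & !is.na(db) & da == want & db == want
      cls_n[cls] <- cls_n[cls] + sum(sel)
      d <- sel & ba != bb
      cls_ts[cls] <- cls_ts[cls] + sum(d & is_transition(ba, bb))
      cls_tv[cls] <- cls_tv[cls] + sum(d & !is_transition(ba, bb))
    }
  }
  ks <- ws <- numeric(0)
  for (cls in c("nd", "fd")) {
    if (cls_n[cls] == 0L) next
    k <- k80_kappa(cls_ts[cls] / cls_n[cls], cls_tv[cls] / cls_n[cls])
    if (!is.na(k)) { ks <- c(ks, k); ws <- c(ws, cls_n[cls]) }
  }
  if (!length(ks)) return(1)
  sum(ks * ws) / sum(ws)
}

# F3x4 positional nucleotide frequencies (4x3, rows A,C,G,T) pooled over
# both sequences' codons
f3x4_freqs <- function(ca, cb) {
  m <- matrix(0, 4, 3, dimnames = list(DNA_BASES, NULL))
  for (pos in 1:3) {
    b <- c(substring(ca, pos, pos), substring(cb, pos, pos))
    t <- table(factor(b, levels = DNA_BASES))
    m[, pos] <- as.numeric(t) / sum(t)
  }
  m
}

#' Ka/Ks by a Yang-Nielsen (2000)-style approximate method
#'
#' Site counts are weighted by the estimated transition/transversion rate
#' ratio and (optionally) F3x4 positional codon frequencies; substitution
#' counts average over minimal pathways with kappa/frequency/omega weights;
#' synonymous and nonsynonymous proportions are corrected with K80-style
#' formulas using their within-class transition and transversion parts;
#' omega is iterated until its relative change falls below `tol` (or
#' `max_iter` iterations, flagged as non-converged).
#'
#' @inheritParams ng86
#' @param weighting `"f3x4"` (default) or `"uniform"` codon frequencies.
#' @param kappa Fix the ts/tv rate ratio instead of estimating it from
#'   nondegenerate and fourfold-degenerate sites.
#' @param max_iter,tol Iteration controls.
#' @return One-row `KaKsResult` data frame (see [ng86()]); `kappa_hat`
#'   holds the ratio used, `converged` the iteration status.
#' @export
yn <- function(seq_a, seq_b, pair_id = "pair", weighting = c("f3x4", "uniform"),
               kappa = NULL, max_iter = 100L, tol = 1e-6) {
  weighting <- match.arg(weighting)
  cp <- prepare_codon_pairs(seq_a, seq_b)
  posfreq <- if (weighting == "f3x4") f3x4_freqs(cp$a, cp$b) else
    matrix(0.25, 4, 3, dimnames = list(DNA_BASES, NULL))
  kap <- if (is.null(kappa)) estimate_kappa(cp$a, cp$b) else kappa
  sc <- codon_site_counts(kappa = kap, posfreq = posfreq)
  S <- (sum(sc[cp$a]) + sum(sc[cp$b])) / 2
  N <- 3 * length(cp$a) - S
  diffs <- which(cp$a != cp$b)
  if (!length(diffs)) {
    cnt <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
    return(kaks_row(pair_id, "YN", length(cp$a), S, N, cnt, 0, 0, kap,
                    TRUE, FALSE))
  }
  om <- 1
  converged <- FALSE
  cnt <- NULL; Ka <- Ks <- NA_real_
  for (it in seq_len(max_iter)) {
    cnt <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
    for (i in diffs) {
      cnt <- cnt + pathway_counts(cp$a[i], cp$b[i], kappa = kap,
                                  omega = max(om, 1e-4), posfreq = posfreq)
    }
    Ks <- if (S > 0) k80_dist(cnt[["sd_ts"]] / S, cnt[["sd_tv"]] / S) else NA_real_
    Ka <- if (N > 0) k80_dist(cnt[["nd_ts"]] / N, cnt[["nd_tv"]] / N) else NA_real_
    if (is.na(Ka) || is.na(Ks) || Ks == 0) break
    om_new <- Ka / Ks
    if (abs(om_new - om) / max(om, 1e-8) < tol) {
      om <- om_new
      converged <- TRUE
      break
    }
    om <- om_new
  }
  flagged <- is.na(Ka) || is.na(Ks)
  kaks_row(pair_id, "YN", length(cp$a), S, N, cnt, Ka, Ks, kap,
           converged || length(diffs) == 0L, flagged)
}

#' Ka/Ks table for a list of annotated ortholog pairs
#'
#' @param annotated_list List of `annotated_ortholog` objects; rejected
#'   entries are skipped.
#' @param method `"yn"` (default) or `"ng86"`.
#' @param ... Passed to [yn()].
#' @return Data frame of `KaKsResult` rows.
#' @export
kaks_table <- function(annotated_list, method = c("yn", "ng86"), ...) {
  method <- match.arg(method)
  keep <- Filter(function(x) !isTRUE(x$rejected), annotated_list)
  rows <- lapply(keep, function(ann) {
    cds_a <- substr(ann$seq_a, ann$cds_a[1] + 1L, ann$cds_a[2])
    cds_b <- substr(ann$seq_b, ann$cds_b[1] + 1L, ann$cds_b[2])
    id <- paste(ann$id_a, ann$id_b, sep = "|")
    if (method == "yn") yn(cds_a, cds_b, id, ...) else ng86(cds_a, cds_b, id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify genes into selection bands by Ka/Ks
#'
#' Bands: positive selection (`ka_ks > 1`), relaxed constraint
#' (`0.5 <= ka_ks <= 1`; both boundaries fall in this band), strong
#' constraint (`ka_ks < 0.5`). Pairs where only Ka or only Ks is defined
#' keep their defined rate but are excluded from the banding.
#'
#' @param results Data frame of `KaKsResult` rows.
#' @return List: `results` (with `selection_class` added, sorted by
#'   descending `ka_ks`), `bands` (named counts), `scatter` (`pair_id`,
#'   `Ka`, `Ks` for pairs with both rates; the reference lines Ka = Ks and
#'   Ka = 0.5 Ks delimit the bands in a Ka-vs-Ks plot).
#' @export
classify_selection <- function(results) {
  res <- results
  res$selection_class <- ifelse(
    is.na(res$ka_ks), NA_character_,
    ifelse(res$ka_ks > 1, "positive",
           ifelse(res$ka_ks >= 0.5, "relaxed", "constrained")))
  res <- res[order(-ifelse(is.na(res$ka_ks), -Inf, res$ka_ks)), , drop = FALSE]
  rownames(res) <- NULL
  defined <- res[!is.na(res$ka_ks), , drop = FALSE]
  bands <- c(positive = sum(defined$selection_class == "positive"),
             relaxed = sum(defined$selection_class == "relaxed"),
             constrained = sum(defined$selection_class == "constrained"))
  scatter <- defined[, c("pair_id", "Ka", "Ks")]
  list(results = res, bands = bands, scatter = scatter)
}
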