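# Synthetic two-species transcriptome generator with a full ground-truth
# channel. Each transcript has 5'UTR + CDS + 3'UTR structure; orthologous
# pairs descend from a common ancestor by independent per-site substitution
# draws on two lineages. The generator's defaults emulate the divergence
# regime of closely related hemipteran cryptic species: ~1% pairwise
# divergence, CpG hypermutability, transition bias and purifying selection
# on the coding frame.

#' Simulation configuration
#'
#' @param n_transcripts Number of ancestral transcripts (ortholog pairs).
#' @param cds_length_range Length range (bp) of the CDS including start and
#'   stop codons; bounds must admit a multiple of 3 and the minimum usable
#'   length is 150 bp.
#' @param utr5_length_range,utr3_length_range Length ranges (bp) of the UTRs.
#' @param gc_content Target GC fraction in (0,1).
#' @param cpg_enrichment Multiplier on the expected CpG dinucleotide
#'   frequency relative to base independence (0 = no CpG at all; 1 =
#'   independence). Animal transcriptomes are typically CpG-depleted
#'   (values below 1).
#' @param branch_divergence Expected substitutions per non-CpG site summed
#'   over both lineages; must lie in `[0, 0.2]` (the regime where orthologs
#'   remain >= 80% identical).
#' @param cpg_rate_multiplier Fold-elevation of the substitution rate at
#'   sites currently in a CpG dinucleotide.
#' @param kappa Transition/transversion rate ratio; a proposed change is a
#'   transition with probability `kappa/(kappa + 2)`.
#' @param omega Nonsynonymous/synonymous rate ratio applied to CDS changes.
#' @param paralog_fraction Fraction of ancestors that also leave a
#'   within-genome duplicate in species A.
#' @param paralog_divergence_factor Branch length of the duplicate's private
#'   lineage, as a multiple of one ortholog lineage (default 2, so a
#'   paralog is about 1.5x as far from the other species as the true
#'   ortholog is).
#' @param seed Master integer seed; all child seeds derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 100L,
                       cds_length_range = c(300L, 900L),
                       utr5_length_range = c(30L, 150L),
                       utr3_length_range = c(50L, 250L),
                       gc_content = 0.43,
                       cpg_enrichment = 0.7,
                       branch_divergence = 0.01,
                       cpg_rate_multiplier = 4,
                       kappa = 2,
                       omega = 0.2,
                       paralog_fraction = 0.1,
                       paralog_divergence_factor = 2,
                       seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    cds_length_range = as.integer(cds_length_range),
    utr5_length_range = as.integer(utr5_length_range),
    utr3_length_range = as.integer(utr3_length_range),
    gc_content = gc_content,
    cpg_enrichment = cpg_enrichment,
    branch_divergence = branch_divergence,
    cpg_rate_multiplier = cpg_rate_multiplier,
    kappa = kappa,
    omega = omega,
    paralog_fraction = paralog_fraction,
    paralog_divergence_factor = paralog_divergence_factor,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_transcripts >= 1L)
  for (fld in c("cds_length_range", "utr5_length_range", "utr3_length_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || any(r <= 0L)) {
      stop(sprintf("%s must be two positive lengths", fld))
    }
    if (r[1] > r[2]) stop(sprintf("%s is inverted", fld))
  }
  r <- cfg$cds_length_range
  lo <- ceiling(r[1] / 3) * 3
  if (lo > r[2]) stop("cds_length_range admits no multiple of 3")
  if (max(lo, 150L) > r[2]) stop("cds_length_range must allow CDS >= 150 bp")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) stop("gc_content must be in (0,1)")
  if (cfg$cpg_enrichment < 0) stop("cpg_enrichment must be >= 0")
  if (cfg$branch_divergence < 0 || cfg$branch_divergence > 0.2) {
    stop("branch_divergence must be in [0, 0.2]")
  }
  if (cfg$cpg_rate_multiplier <= 0) stop("cpg_rate_multiplier must be > 0")
  if (cfg$kappa <= 0) stop("kappa must be > 0")
  if (cfg$omega < 0) stop("omega must be >= 0")
  if (cfg$paralog_fraction < 0 || cfg$paralog_fraction >= 1) {
    stop("paralog_fraction must be in [0,1)")
  }
  # the CpG-enriched transition matrix must stay a proper stochastic matrix
  piG <- cfg$gc_content / 2
  if (cfg$cpg_enrichment * piG >= 1) stop("cpg_enrichment too large for gc_content")
  invisible(cfg)
}

# First-order Markov transition matrix over A,C,G,T whose stationary
# distribution is exactly (at/2, gc/2, gc/2, at/2) and whose CpG
# dinucleotide frequency is exactly e * pi_C * pi_G. Rows = previous base.
cpg_transition_matrix <- function(gc_content, cpg_enrichment) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  e <- cpg_enrichment
  P <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  gC <- e * p[["G"]]                                      # P(G | C)
  gO <- p[["G"]] * (1 - e * p[["C"]]) / (1 - p[["C"]])    # P(G | not C)
  for (i in DNA_BASES) {
    g <- if (i == "C") gC else gO
    P[i, "G"] <- g
    for (j in setdiff(DNA_BASES, "G")) {
      P[i, j] <- p[[j]] * (1 - g) / (1 - p[["G"]])
    }
  }
  P
}

# sample one value from a vector (safe for length-1 vectors)
resample <- function(x, ...) x[sample.int(length(x), ...)]

# sample n bases from the chain; prev = previous base or NULL (stationary)
sample_markov <- function(n, P, stat, prev = NULL) {
  if (n == 0L) return(character(0))
  cum <- t(apply(P, 1, cumsum))
  u <- runif(n)
  out <- integer(n)
  prev_i <- if (is.null(prev)) {
    sum(runif(1) > cumsum(stat)) + 1L
  } else match(prev, DNA_BASES)
  for (t in seq_len(n)) {
    if (t == 1L && is.null(prev)) {
      out[t] <- sum(u[t] > cumsum(stat)) + 1L
    } else {
      out[t] <- sum(u[t] > cum[prev_i, ]) + 1L
    }
    prev_i <- out[t]
  }
  DNA_BASES[out]
}

# sample n_codons sense codons continuing the chain from prev
sample_sense_codons <- function(n_codons, P, stat, prev) {
  out <- character(0)
  for (k in seq_len(n_codons)) {
    repeat {
      cod <- sample_markov(3L, P, stat, prev)
      if (!(paste0(cod, collapse = "") %in% STOP_CODONS)) break
    }
    out <- c(out, cod)
    prev <- cod[3]
  }
  out
}

#' Generate the ancestral transcript set
#'
#' Builds `n_transcripts` ancestors with 5'UTR + CDS + 3'UTR structure
#' (CDS starts ATG, ends with a stop codon, no internal stop) plus the
#' reference protein set: the exact translation of each ancestral CDS.
#'
#' @param config A [sim_config()].
#' @return List with `ancestors` (named character vector of sequences),
#'   `features` (data frame: id, cds_start, cds_end (0-based half-open),
#'   protein_id), and `proteins` (named character vector of amino-acid
#'   sequences, stops stripped).
#' @export
generate_ancestor_set <- function(config) {
  validate_sim_config(config)
  P <- cpg_transition_matrix(config$gc_content, config$cpg_enrichment)
  stat <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
            G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  with_seed(derive_seed(config$seed, "ancestors"), {
    n <- config$n_transcripts
    ids <- sprintf("gene%04d", seq_len(n))
    seqs <- character(n)
    feats <- data.frame(id = ids, cds_start = 0L, cds_end = 0L,
                        protein_id = sprintf("PROT_%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
    prots <- character(n)
    cds_choices <- as.integer(seq(ceiling(config$cds_length_range[1] / 3) * 3,
                                  config$cds_length_range[2], by = 3L))
    cds_choices <- cds_choices[cds_choices >= 150L]
    for (i in seq_len(n)) {
      l5 <- resample(config$utr5_length_range[1]:config$utr5_length_range[2], 1L)
      l3 <- resample(config$utr3_length_range[1]:config$utr3_length_range[2], 1L)
      lc <- resample(cds_choices, 1L)
      utr5 <- sample_markov(l5, P, stat, prev = NULL)
      body <- sample_sense_codons(lc / 3L - 2L, P, stat, prev = "G")
      prev <- if (length(body)) body[length(body)] else "G"
      stop_w <- vapply(STOP_CODONS, function(sc) {
        b <- chars(sc)
        P[prev, b[1]] * P[b[1], b[2]] * P[b[2], b[3]]
      }, numeric(1))
      stop_cod <- resample(STOP_CODONS, 1L, prob = stop_w)
      prev <- substr(stop_cod, 3, 3)
      utr3 <- sample_markov(l3, P, stat, prev = prev)
      seqs[i] <- paste0(c(utr5, "A", "T", "G", body, chars(stop_cod), utr3),
                        collapse = "")
      feats$cds_start[i] <- l5
      feats$cds_end[i] <- l5 + lc
      cds <- substr(seqs[i], l5 + 1L, l5 + lc)
      prots[i] <- sub("\\*$", "", translate_seq(cds))
    }
    names(seqs) <- ids
    names(prots) <- feats$protein_id
    list(ancestors = seqs, features = feats, proteins = prots)
  })
}

# cpg context flag for position i (1-based) in char vector x
.is_cpg_at <- function(x, i) {
  n <- length(x)
  (x[i] == "C" && i < n && x[i + 1L] == "G") ||
    (x[i] == "G" && i > 1L && x[i - 1L] == "C")
}

# Evolve one lineage of a transcript by per-site substitution draws.
# rate = expected substitutions per non-CpG site on this lineage.
# Returns list(seq = character scalar, subs = data.frame log).
evolve_sequence <- function(seq, cds_start, cds_end, rate, config) {
  x <- chars(seq)
  n <- length(x)
  gc <- genetic_code()
  kap <- config$kappa
  om <- config$omega
  mult <- config$cpg_rate_multiplier
  p_max <- rate * max(1, mult)
  if (p_max > 1) stop("substitution probability exceeds 1; lower divergence")
  u <- runif(n)
  cand <- which(u < p_max)
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  log_pos <- integer(0); log_reg <- character(0); log_cpg <- logical(0)
  log_ts <- logical(0); log_syn <- logical(0)
  log_from <- character(0); log_to <- character(0)
  for (i in cand) {
    cpg <- .is_cpg_at(x, i)
    p_i <- rate * (if (cpg) mult else 1)
    if (u[i] >= p_i) next
    cur <- x[i]
    if (cur == "N") next
    i0 <- i - 1L  # 0-based
    region <- if (i0 < cds_start) "utr5" else if (i0 < cds_end) "cds" else "utr3"
    alts <- setdiff(DNA_BASES, cur)
    w <- ifelse(alts == ts_partner[[cur]], kap, 1)
    syn <- NA
    if (region == "cds") {
      ci <- (i0 - cds_start) %/% 3L            # codon index in CDS
      cs <- cds_start + 3L * ci                # 0-based codon start
      old_cod <- paste0(x[(cs + 1L):(cs + 3L)], collapse = "")
      pos_in_cod <- i0 - cs + 1L
      new_cods <- vapply(alts, function(b) {
        cc <- old_cod; substr(cc, pos_in_cod, pos_in_cod) <- b; cc
      }, character(1))
      terminal <- (cs + 3L) == cds_end
      ok <- if (terminal) {
        # the terminal stop may only wander among stop codons
        new_cods %in% STOP_CODONS
      } else {
        !(new_cods %in% STOP_CODONS)
      }
      if (!any(ok)) next
      alts <- alts[ok]; w <- w[ok]; new_cods <- new_cods[ok]
      k <- if (length(alts) == 1L) 1L else sample(seq_along(alts), 1L, prob = w)
      new <- alts[k]
      syn <- if (terminal) TRUE else gc[[new_cods[k]]] == gc[[old_cod]]
      om_eff <- max(1, om)
      acc <- if (syn) 1 / om_eff else om / om_eff
      if (acc < 1 && runif(1) >= acc) next
    } else {
      k <- if (length(alts) == 1L) 1L else sample(seq_along(alts), 1L, prob = w)
      new <- alts[k]
    }
    log_pos <- c(log_pos, i0); log_reg <- c(log_reg, region)
    log_cpg <- c(log_cpg, cpg); log_ts <- c(log_ts, is_transition(cur, new))
    log_syn <- c(log_syn, syn); log_from <- c(log_from, cur); log_to <- c(log_to, new)
    x[i] <- new
  }
  list(seq = paste0(x, collapse = ""),
       subs = data.frame(position = log_pos, region = log_reg, cpg = log_cpg,
                         ts = log_ts, syn = log_syn, from = log_from,
                         to = log_to, stringsAsFactors = FALSE))
}

#' Evolve an ancestral transcript into two orthologous descendants
#'
#' Each lineage receives independent per-site substitution draws at rate
#' `branch_divergence / 2` per non-CpG site, elevated by
#' `cpg_rate_multiplier` at sites currently in a CpG dinucleotide, with
#' transition probability `kappa/(kappa+2)` and nonsynonymous changes
#' thinned by `omega`. CDS changes never create an internal stop and the
#' process is substitution-only (no indels).
#'
#' @param ancestor Character scalar, ancestral transcript sequence.
#' @param cds_start,cds_end 0-based half-open CDS interval on the ancestor.
#' @param config A [sim_config()].
#' @param seed Integer seed for this pair.
#' @return List with `a`, `b` (descendant sequences) and `subs` (substitution
#'   log with a `lineage` column, positions 0-based on the transcript).
#' @export
evolve_pair <- function(ancestor, cds_start, cds_end, config, seed) {
  rate <- config$branch_divergence / 2
  with_seed(seed, {
    ra <- evolve_sequence(ancestor, cds_start, cds_end, rate, config)
    rb <- evolve_sequence(ancestor, cds_start, cds_end, rate, config)
    sa <- ra$subs; sb <- rb$subs
    if (nrow(sa)) sa$lineage <- "A"
    if (nrow(sb)) sb$lineage <- "B"
    subs <- rbind(
      if (nrow(sa)) sa else NULL,
      if (nrow(sb)) sb else NULL)
    if (is.null(subs)) {
      subs <- data.frame(position = integer(0), region = character(0),
                         cpg = logical(0), ts = logical(0), syn = logical(0),
                         from = character(0), to = character(0),
                         lineage = character(0), stringsAsFactors = FALSE)
    }
    list(a = ra$seq, b = rb$seq, subs = subs)
  })
}

#' Simulate a complete two-species transcriptome fixture
#'
#' Orchestrates [generate_ancestor_set()], [evolve_pair()] and
#' [add_paralogs()] under a single master seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_fixture`: list with `species_a`, `species_b` (named
#'   character vectors of transcript sequences), `proteins` (named
#'   amino-acid sequences), `truth` (list of `transcripts` and
#'   `substitutions` data frames) and `config`.
#' @export
simulate_transcriptomes <- function(config) {
  anc <- generate_ancestor_set(config)
  n <- length(anc$ancestors)
  ids <- names(anc$ancestors)
  species_a <- setNames(character(n), paste0("A_", ids))
  species_b <- setNames(character(n), paste0("B_", ids))
  subs_list <- vector("list", n)
  for (i in seq_len(n)) {
    f <- anc$features[i, ]
    ev <- evolve_pair(anc$ancestors[[i]], f$cds_start, f$cds_end, config,
                      derive_seed(config$seed, paste0("evolve:", ids[i])))
    species_a[[i]] <- ev$a
    species_b[[i]] <- ev$b
    if (nrow(ev$subs)) {
      ev$subs$ancestor_id <- ids[i]
      subs_list[[i]] <- ev$subs
    }
  }
  subs <- do.call(rbind, subs_list[!vapply(subs_list, is.null, logical(1))])
  if (is.null(subs)) {
    subs <- data.frame(position = integer(0), region = character(0),
                       cpg = logical(0), ts = logical(0), syn = logical(0),
                       from = character(0), to = character(0),
                       lineage = character(0), ancestor_id = character(0),
                       stringsAsFactors = FALSE)
  }
  tr <- rbind(
    data.frame(id = names(species_a), species = "A", ancestor_id = ids,
               partner_id = names(species_b), protein_id = anc$features$protein_id,
               cds_start = anc$features$cds_start, cds_end = anc$features$cds_end,
               is_paralog = FALSE, stringsAsFactors = FALSE),
    data.frame(id = names(species_b), species = "B", ancestor_id = ids,
               partner_id = names(species_a), protein_id = anc$features$protein_id,
               cds_start = anc$features$cds_start, cds_end = anc$features$cds_end,
               is_paralog = FALSE, stringsAsFactors = FALSE))
  fx <- list(species_a = species_a, species_b = species_b,
             proteins = anc$proteins, ancestors = anc$ancestors,
             truth = list(transcripts = tr, substitutions = subs),
             config = config)
  class(fx) <- "sim_fixture"
  if (config$paralog_fraction > 0) fx <- add_paralogs(fx, config)
  fx
}

#' Spike within-genome paralogs into a simulated fixture
#'
#' Duplicates a fraction of ancestors into species A with extra divergence
#' (an independent lineage of length `paralog_divergence_factor` times one
#' ortholog lineage). Each duplicate's own translated CDS is added to the
#' reference protein set under a new id, so a Swissprot-style shared-protein
#' filter can reject pairs involving the duplicate.
#'
#' @param fixture A `sim_fixture`.
#' @param config A [sim_config()] with `paralog_fraction > 0`.
#' @return The augmented fixture.
#' @export
add_paralogs <- function(fixture, config) {
  n <- length(fixture$ancestors)
  k <- round(config$paralog_fraction * n)
  if (k == 0L) return(fixture)
  ids <- names(fixture$ancestors)
  pick <- with_seed(derive_seed(config$seed, "paralog_pick"),
                    sort(sample(seq_len(n), k)))
  rate <- config$branch_divergence / 2 * config$paralog_divergence_factor
  for (i in pick) {
    f <- fixture$truth$transcripts[
      fixture$truth$transcripts$ancestor_id == ids[i] &
        fixture$truth$transcripts$species == "A", ][1, ]
    res <- with_seed(derive_seed(config$seed, paste0("paralog:", ids[i])), {
      evolve_sequence(fixture$ancestors[[i]], f$cds_start, f$cds_end,
                      rate, config)
    })
    pid <- paste0("A_par_", ids[i])
    prot_id <- paste0("PROT_par_", ids[i])
    fixture$species_a[[pid]] <- res$seq
    cds <- substr(res$seq, f$cds_start + 1L, f$cds_end)
    fixture$proteins[[prot_id]] <- sub("\\*$", "", translate_seq(cds))
    fixture$truth$transcripts <- rbind(
      fixture$truth$transcripts,
      data.frame(id = pid, species = "A", ancestor_id = ids[i],
                 partner_id = NA_character_, protein_id = prot_id,
                 cds_start = f$cds_start, cds_end = f$cds_end,
                 is_paralog = TRUE, stringsAsFactors = FALSE))
    if (nrow(res$subs)) {
      res$subs$lineage <- "P"
      res$subs$ancestor_id <- ids[i]
      fixture$truth$substitutions <- rbind(fixture$truth$substitutions, res$subs)
    }
  }
  fixture
}

#' Write a simulated fixture to disk
#'
#' Writes `speciesA.fasta`, `speciesB.fasta`, `proteins.fasta`, `truth.tsv`
#' (transcript table: id, species, ancestor_id, partner_id, protein_id,
#' cds_start, cds_end (0-based half-open), is_paralog) and
#' `truth_substitutions.tsv` (ancestor_id, lineage, position (0-based),
#' region, cpg, ts, syn, from, to).
#'
#' @param fixture A `sim_fixture`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(fixture, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("speciesA.fasta", "speciesB.fasta",
                                "proteins.fasta", "truth.tsv",
                                "truth_substitutions.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$species_a), paths[1])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$species_b), paths[2])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(fixture$proteins), paths[3])
  write.table(fixture$truth$transcripts, paths[4], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fixture$truth$substitutions, paths[5], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read FASTA transcript or protein files
#'
#' @param path FASTA file path.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A `sim_fixture` (without config).
#' @export
read_fixture <- function(dir) {
  fx <- list(
    species_a = read_fasta(file.path(dir, "speciesA.fasta")),
    species_b = read_fasta(file.path(dir, "speciesB.fasta")),
    proteins = read_fasta(file.path(dir, "proteins.fasta"), type = "aa"),
    truth = list(
      transcripts = read.delim(file.path(dir, "truth.tsv"),
                               stringsAsFactors = FALSE),
      substitutions = read.delim(file.path(dir, "truth_substitutions.tsv"),
                                 stringsAsFactors = FALSE)))
  class(fx) <- "sim_fixture"
  fx
}

#' Realized context-specific substitution rates from the truth channel
#'
#' Parameter-recovery view of the simulator: substitutions logged with a
#' CpG (resp. non-CpG) draw-time flag divided by the count of ancestral
#' sites in (resp. not in) CpG context, pooled over all non-paralog pairs.
#' The ratio estimates `cpg_rate_multiplier` directly, free of the
#' de novo CpG-context misattribution that affects descendant-based
#' measurement (see the methods vignette).
#'
#' @param fixture A `sim_fixture` with its `ancestors` present.
#' @return List: `cpg_rate`, `noncpg_rate` (substitutions per site, summed
#'   over both lineages), `ratio`.
#' @export
truth_context_divergence <- function(fixture) {
  if (is.null(fixture$ancestors)) stop("fixture lacks ancestral sequences")
  n_cpg <- n_non <- 0L
  for (s in fixture$ancestors) {
    x <- chars(s)
    nx <- length(x)
    nxt <- c(x[-1], "")
    prv <- c("", x[-nx])
    cpg <- (x == "C" & nxt == "G") | (x == "G" & prv == "C")
    n_cpg <- n_cpg + sum(cpg)
    n_non <- n_non + sum(!cpg)
  }
  subs <- fixture$truth$substitutions
  subs <- subs[subs$lineage %in% c("A", "B"), , drop = FALSE]
  cpg_rate <- sum(subs$cpg) / n_cpg
  noncpg_rate <- sum(!subs$cpg) / n_non
  list(cpg_rate = cpg_rate, noncpg_rate = noncpg_rate,
       ratio = cpg_rate / noncpg_rate)
}
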