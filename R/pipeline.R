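# Pipeline orchestration: simulate -> orthologs -> annotate -> divergence
# -> selection, with TSV report writers and a JSON run manifest recording
# parameters, input hashes and the counts entering/leaving every filter.

#' Pipeline configuration
#'
#' @param out_dir Output directory for fixture files, reports and manifest.
#' @param seed Master seed for the run (overrides `sim$seed`).
#' @param sim A [sim_config()] for the simulate stage; `NULL` when running
#'   on external FASTA inputs.
#' @param align An [align_params()].
#' @param species_a_fasta,species_b_fasta,proteins_fasta Input paths used
#'   when `sim` is `NULL` (or after a separate simulate run).
#' @param kaks_method `"yn"` or `"ng86"`.
#' @param verbose Emit per-stage messages to stderr.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                            align = align_params(),
                            species_a_fasta = NULL, species_b_fasta = NULL,
                            proteins_fasta = NULL,
                            kaks_method = "yn", verbose = FALSE) {
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 align = align, species_a_fasta = species_a_fasta,
                 species_b_fasta = species_b_fasta,
                 proteins_fasta = proteins_fasta,
                 kaks_method = kaks_method, verbose = verbose),
            class = "pipeline_config")
}

.stage_order <- c("simulate", "orthologs", "annotate", "divergence", "selection")

say <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Run one pipeline stage
#'
#' Stages are `"simulate"`, `"orthologs"`, `"annotate"`, `"divergence"`,
#' `"selection"`. Each stage is deterministic given the configuration and
#' seed, reads its inputs from the in-memory `state` (or from the files a
#' previous invocation wrote), appends its filter counts to the manifest
#' and returns the updated state.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @param state State list from the previous stage (or `NULL` to start).
#' @return The updated state list (fields filled in stage order: `fixture`,
#'   `pairs`, `annotated`, `div_table`, `ratios`, `kaks`, `selection`,
#'   `manifest`).
#' @export
run_stage <- function(name, config, state = NULL) {
  if (!name %in% .stage_order) stop("unknown stage: ", name)
  if (is.null(state)) {
    state <- list(manifest = list(seed = config$seed,
                                  align_params = unclass(config$align),
                                  counts = list(), stages = character(0)))
  }
  t0 <- Sys.time()
  state <- switch(name,
    simulate = stage_simulate(config, state),
    orthologs = stage_orthologs(config, state),
    annotate = stage_annotate(config, state),
    divergence = stage_divergence(config, state),
    selection = stage_selection(config, state))
  state$manifest$stages <- c(state$manifest$stages, name)
  say(config, "stage %-10s done in %.1fs", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  state
}

stage_simulate <- function(config, state) {
  if (is.null(config$sim)) stop("no simulation config; provide FASTA inputs instead")
  fx <- simulate_transcriptomes(config$sim)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fixture(fx, file.path(config$out_dir, "fixture"))
  state$fixture <- fx
  state$manifest$sim_config <- unclass(config$sim)
  state$manifest$counts$n_species_a <- length(fx$species_a)
  state$manifest$counts$n_species_b <- length(fx$species_b)
  state$manifest$input_md5 <- as.list(tools::md5sum(paths))
  state
}

# load external FASTA inputs if no simulate stage ran
ensure_inputs <- function(config, state) {
  if (!is.null(state$fixture)) return(state)
  paths <- list(config$species_a_fasta, config$species_b_fasta,
                config$proteins_fasta)
  if (any(vapply(paths, is.null, logical(1))) ||
      !all(file.exists(unlist(paths)))) {
    stop("missing inputs for stage")
  }
  state$fixture <- list(
    species_a = read_fasta(config$species_a_fasta),
    species_b = read_fasta(config$species_b_fasta),
    proteins = read_fasta(config$proteins_fasta, type = "aa"),
    truth = NULL)
  state$manifest$input_md5 <- as.list(tools::md5sum(
    c(config$species_a_fasta, config$species_b_fasta, config$proteins_fasta)))
  state$manifest$counts$n_species_a <- length(state$fixture$species_a)
  state$manifest$counts$n_species_b <- length(state$fixture$species_b)
  state
}

stage_orthologs <- function(config, state) {
  state <- ensure_inputs(config, state)
  fx <- state$fixture
  rbh <- reciprocal_best_hits(fx$species_a, fx$species_b, config$align)
  state$manifest$counts$putative_rbh_pairs <- nrow(rbh)
  pairs <- paralog_filter(rbh, fx$species_a, fx$species_b, fx$proteins,
                          config$align)
  state$manifest$counts$shared_protein_pairs <- nrow(pairs)
  state$pairs <- pairs
  state
}

stage_annotate <- function(config, state) {
  if (is.null(state$pairs)) stop("missing inputs for stage: run orthologs first")
  fx <- state$fixture
  ann <- annotate_pairs(state$pairs, fx$species_a, fx$species_b, fx$proteins,
                        config$align)
  ok <- !vapply(ann, function(x) isTRUE(x$rejected), logical(1))
  state$annotated <- ann
  state$manifest$counts$annotated_accepted <- sum(ok)
  state$manifest$counts$annotated_rejected <- sum(!ok)
  state$manifest$counts$with_utr5 <-
    sum(vapply(ann[ok], function(x) isTRUE(x$has_utr5), logical(1)))
  state$manifest$counts$with_utr3 <-
    sum(vapply(ann[ok], function(x) isTRUE(x$has_utr3), logical(1)))
  state
}

stage_divergence <- function(config, state) {
  if (is.null(state$annotated)) stop("missing inputs for stage: run annotate first")
  state$div_table <- divergence_table(state$annotated)
  state$ratios <- fold_ratios(state$div_table)
  state
}

stage_selection <- function(config, state) {
  if (is.null(state$annotated)) stop("missing inputs for stage: run annotate first")
  state$kaks <- kaks_table(state$annotated, method = config$kaks_method)
  state$selection <- classify_selection(state$kaks)
  state$manifest$counts$kaks_pairs <- nrow(state$kaks)
  state$manifest$counts$kaks_defined_ratio <- sum(!is.na(state$kaks$ka_ks))
  state$manifest$counts$selection_bands <- as.list(state$selection$bands)
  state
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run, in order (default: all five).
#' @return The final state list; reports and manifest are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, stages = .stage_order) {
  state <- NULL
  for (s in stages) state <- run_stage(s, config, state)
  write_reports(state, config$out_dir)
  state
}

# fixed column schemas for the report files
.report_schemas <- list(
  ortholog_pairs = c("id_a", "id_b", "score_ab", "score_ba", "identity",
                     "n_columns", "shared_protein_id"),
  divergence_table = c("group", "context", "loci", "pct_diff", "se",
                       "compared_kb", "ts_tv", "pct_gc", "pct_cpg"),
  ratios = c("name", "numerator", "denominator", "ratio"),
  kaks_table = c("pair_id", "method", "n_codons", "S_sites", "N_sites",
                 "S_sub", "N_sub", "Ka", "Ks", "ka_ks", "kappa_hat",
                 "converged", "flagged", "selection_class"),
  scatter = c("pair_id", "Ka", "Ks"))

#' Write the pipeline report files
#'
#' Emits `ortholog_pairs.tsv`, `divergence_table.tsv`, `ratios.tsv`,
#' `kaks_table.tsv`, `scatter.tsv` (Ka-vs-Ks scatter data; the Ka = Ks and
#' Ka = 0.5 Ks lines delimit the selection bands) and `manifest.json`.
#' Reports are byte-stable for a given configuration and seed.
#'
#' @param state Pipeline state from [run_pipeline()]/[run_stage()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(state, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    stopifnot(identical(names(df), .report_schemas[[name]]))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, path)
  }
  if (!is.null(state$pairs)) emit(state$pairs, "ortholog_pairs")
  if (!is.null(state$div_table)) emit(state$div_table, "divergence_table")
  if (!is.null(state$ratios)) emit(state$ratios, "ratios")
  if (!is.null(state$selection)) {
    emit(state$selection$results, "kaks_table")
    emit(state$selection$scatter, "scatter")
  }
  manifest <- state$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, file.path(out_dir, "manifest.json")))
}
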