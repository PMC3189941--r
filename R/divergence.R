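# Context-stratified divergence statistics: per region (5'UTR, CDS, 3'UTR)
# and site class (CpG/non-CpG, nondegenerate/fourfold-degenerate), percent
# difference, SE across loci, compared kb, ts/tv, %GC and %CpG.

#' Label every compared column of an annotated ortholog pair
#'
#' Each gap-free compared column receives: region, CpG-context flag
#' (default rule: the base participates in a CG dinucleotide in EITHER
#' member's sequence; switchable to require both), degeneracy class (CDS
#' only, assigned when both members' codons imply the same class, else
#' `NA`; stop codons `NA`), difference and transition flags. Columns with
#' `N` in either member are dropped.
#'
#' @param annotated An accepted `annotated_ortholog`.
#' @param cpg_rule `"either"` (default) or `"both"`.
#' @return Data frame: `pair_id`, `region`, `pos_a`, `pos_b`, `base_a`,
#'   `base_b`, `cpg`, `degeneracy`, `diff`, `ts`.
#' @export
classify_sites <- function(annotated, cpg_rule = c("either", "both")) {
  cpg_rule <- match.arg(cpg_rule)
  if (isTRUE(annotated$rejected)) stop("cannot classify a rejected pair")
  reg <- annotated$regions
  a <- chars(annotated$seq_a)
  b <- chars(annotated$seq_b)
  cpg_flags <- function(x) {
    n <- length(x)
    nxt <- c(x[-1], "")
    prv <- c("", x[-n])
    (x == "C" & nxt == "G") | (x == "G" & prv == "C")
  }
  cfa <- cpg_flags(a)[reg$pos_a + 1L]
  cfb <- cpg_flags(b)[reg$pos_b + 1L]
  cpg <- if (cpg_rule == "either") cfa | cfb else cfa & cfb
  ba <- a[reg$pos_a + 1L]
  bb <- b[reg$pos_b + 1L]
  deg <- rep(NA_character_, nrow(reg))
  is_cds <- reg$region == "cds"
  if (any(is_cds)) {
    off_a <- reg$pos_a[is_cds] - annotated$cds_a[1]
    off_b <- reg$pos_b[is_cds] - annotated$cds_b[1]
    cs_a <- annotated$cds_a[1] + (off_a %/% 3L) * 3L
    cs_b <- annotated$cds_b[1] + (off_b %/% 3L) * 3L
    cod_a <- substring(annotated$seq_a, cs_a + 1L, cs_a + 3L)
    cod_b <- substring(annotated$seq_b, cs_b + 1L, cs_b + 3L)
    da <- site_degeneracy(cod_a, off_a %% 3L + 1L)
    db <- site_degeneracy(cod_b, off_b %% 3L + 1L)
    deg[is_cds] <- ifelse(!is.na(da) & !is.na(db) & da == db, da, NA_character_)
  }
  out <- data.frame(
    pair_id = paste(annotated$id_a, annotated$id_b, sep = "|"),
    region = reg$region, pos_a = reg$pos_a, pos_b = reg$pos_b,
    base_a = ba, base_b = bb, cpg = cpg, degeneracy = deg,
    diff = ba != bb, ts = is_transition(ba, bb),
    stringsAsFactors = FALSE)
  out[ba != "N" & bb != "N", , drop = FALSE]
}

#' Divergence summary for one stratum of labeled sites
#'
#' Pooled percent difference (100 x substitutions / compared sites), SE of
#' the per-locus divergences across loci, compared kb, and the
#' transition/transversion ratio.
#'
#' @param sites Data frame from [classify_sites()] (possibly row-bound over
#'   many pairs), already subset to the stratum of interest.
#' @return One-row data frame: `loci`, `pct_diff`, `se`, `compared_kb`,
#'   `ts_tv`, `pct_gc`, `pct_cpg`. `NULL` when no sites are present.
#' @export
compute_divergence <- function(sites) {
  n <- nrow(sites)
  if (n == 0L) {
    warning("no compared sites in stratum; row omitted")
    return(NULL)
  }
  per_locus <- tapply(sites$diff, sites$pair_id, mean)
  nl <- length(per_locus)
  ts <- sum(sites$diff & sites$ts)
  tv <- sum(sites$diff & !sites$ts)
  data.frame(
    loci = nl,
    pct_diff = 100 * sum(sites$diff) / n,
    se = if (nl > 1L) 100 * stats::sd(per_locus) / sqrt(nl) else NA_real_,
    compared_kb = n / 1000,
    ts_tv = if (tv > 0L) ts / tv else if (ts > 0L) Inf else NA_real_,
    pct_gc = 100 * mean(c(sites$base_a, sites$base_b) %in% c("G", "C")),
    pct_cpg = 100 * mean(sites$cpg))
}

#' Base composition of compared sites per region
#'
#' @param sites Labeled sites from [classify_sites()].
#' @return Data frame per region: `pct_gc` (G+C among compared bases of
#'   both members) and `pct_cpg` (fraction of compared nucleotides in CpG
#'   context).
#' @export
composition <- function(sites) {
  do.call(rbind, lapply(split(sites, sites$region), function(s) {
    data.frame(region = s$region[1],
               pct_gc = 100 * mean(c(s$base_a, s$base_b) %in% c("G", "C")),
               pct_cpg = 100 * mean(s$cpg), stringsAsFactors = FALSE)
  }))
}

# stratum definitions for the divergence table
.strata <- function() list(
  utr5 = function(s) s$region == "utr5",
  cds = function(s) s$region == "cds",
  nd = function(s) s$region == "cds" & !is.na(s$degeneracy) & s$degeneracy == "nd",
  `4d` = function(s) s$region == "cds" & !is.na(s$degeneracy) & s$degeneracy == "fourfold",
  utr3 = function(s) s$region == "utr3")

#' Table of context-stratified divergences
#'
#' One row per (region or site class) x (All / non-CpG / CpG): the 5'UTR,
#' CDS, nondegenerate-site, fourfold-degenerate-site and 3'UTR strata.
#'
#' @param annotated_list List of `annotated_ortholog` objects (rejected
#'   entries are skipped) or a pre-built labeled-site data frame.
#' @param cpg_rule Passed to [classify_sites()].
#' @return Data frame with columns `group`, `context`, `loci`, `pct_diff`,
#'   `se`, `compared_kb`, `ts_tv`, `pct_gc`, `pct_cpg`.
#' @export
divergence_table <- function(annotated_list, cpg_rule = "either") {
  sites <- if (is.data.frame(annotated_list)) annotated_list else {
    keep <- Filter(function(x) !isTRUE(x$rejected), annotated_list)
    do.call(rbind, lapply(keep, classify_sites, cpg_rule = cpg_rule))
  }
  if (is.null(sites) || nrow(sites) == 0L) stop("no compared sites")
  rows <- list()
  for (g in names(.strata())) {
    sub <- sites[.strata()[[g]](sites), , drop = FALSE]
    if (!nrow(sub)) next
    for (ctx in c("All", "No CpG", "CpG")) {
      s2 <- switch(ctx, All = sub,
                   `No CpG` = sub[!sub$cpg, , drop = FALSE],
                   CpG = sub[sub$cpg, , drop = FALSE])
      row <- if (nrow(s2)) suppressWarnings(compute_divergence(s2)) else NULL
      if (is.null(row)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(group = g, context = ctx, stringsAsFactors = FALSE), row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold-ratios of divergences between site classes
#'
#' Reports the CpG / non-CpG percent-difference ratio within each region
#' or site class, and the fourfold-degenerate / nondegenerate ratio
#' (`cds_4d_vs_nd`, on the All context). Ratios with a zero denominator
#' are reported as `NA` (undefined).
#'
#' @param table A [divergence_table()]-shaped data frame (columns `group`,
#'   `context`, `pct_diff`).
#' @return Data frame: `name`, `numerator`, `denominator`, `ratio`.
#' @export
fold_ratios <- function(table) {
  rows <- list()
  grab <- function(g, ctx) {
    v <- table$pct_diff[table$group == g & table$context == ctx]
    if (length(v)) v[1] else NA_real_
  }
  for (g in unique(table$group)) {
    num <- grab(g, "CpG"); den <- grab(g, "No CpG")
    if (is.na(num) || is.na(den)) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(g, "_cpg_vs_noncpg"), numerator = num, denominator = den,
      ratio = if (den > 0) num / den else NA_real_, stringsAsFactors = FALSE)
  }
  num <- grab("4d", "All"); den <- grab("nd", "All")
  if (!is.na(num) && !is.na(den)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "cds_4d_vs_nd", numerator = num, denominator = den,
      ratio = if (den > 0) num / den else NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
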