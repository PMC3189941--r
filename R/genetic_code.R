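# Genetic-code lookup tables, built once per session from the standard code
# shipped with Biostrings. All internal coordinates are 0-based half-open;
# codon positions are 1..3.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Standard genetic code as a named character vector
#'
#' Codon (e.g. "ATG") to one-letter amino acid; stop codons map to `"*"`.
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  if (is.null(.odv$gc)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- gsub("U", "T", names(gc))
    .odv$gc <- gc
  }
  .odv$gc
}

#' Sense codons of the standard code
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Translate an in-frame nucleotide sequence
#'
#' @param seq Character scalar, length a multiple of 3. Codons containing
#'   characters outside A/C/G/T translate to `"X"`.
#' @return Character scalar of amino acids (stops as `"*"`).
#' @export
translate_seq <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  if (n == 0L) return("")
  cods <- codon_split(seq)
  gc <- genetic_code()
  aa <- unname(gc[cods])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# split an in-frame sequence into codon strings
codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Reverse complement of a nucleotide string
#' @param seq Character scalar over A/C/G/T/N.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Degeneracy class of each codon position: number of the 3 alternative
# bases that leave the amino acid unchanged. 0 = nondegenerate (nd),
# 3 = fourfold degenerate (4d). Stop codons get NA (excluded upstream).
degeneracy_table <- function() {
  if (!is.null(.odv$deg)) return(.odv$deg)
  gc <- genetic_code()
  cods <- names(gc)
  deg <- matrix(NA_integer_, nrow = 64L, ncol = 3L, dimnames = list(cods, NULL))
  for (c1 in cods) {
    if (gc[[c1]] == "*") next
    for (pos in 1:3) {
      nsyn <- 0L
      for (b in setdiff(DNA_BASES, substr(c1, pos, pos))) {
        c2 <- c1
        substr(c2, pos, pos) <- b
        if (gc[[c2]] == gc[[c1]]) nsyn <- nsyn + 1L
      }
      deg[c1, pos] <- nsyn
    }
  }
  .odv$deg <- deg
  deg
}

#' Degeneracy class of a codon position
#'
#' @param codon Character vector of codons.
#' @param pos Integer vector in 1..3 (recycled).
#' @return Character vector in `c("nd","twofold","threefold","fourfold")`,
#'   `NA` for stop codons or codons with ambiguous bases.
#' @export
site_degeneracy <- function(codon, pos) {
  deg <- degeneracy_table()
  idx <- match(codon, rownames(deg))
  n <- deg[cbind(idx, as.integer(pos))]
  c("nd", "twofold", "threefold", "fourfold")[n + 1L]
}

# TRUE if the base change b1 -> b2 is a transition (A<->G or C<->T)
is_transition <- function(b1, b2) {
  (b1 == "A" & b2 == "G") | (b1 == "G" & b2 == "A") |
    (b1 == "C" & b2 == "T") | (b1 == "T" & b2 == "C")
}

# integer encoding A=1 C=2 G=3 T=4 N=5 (vector of single chars)
encode_dna <- function(chars) {
  v <- match(chars, c(DNA_BASES, "N"))
  v[is.na(v)] <- 5L
  v
}

# split a string into single characters
chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
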