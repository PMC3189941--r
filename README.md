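# orthodiv

Comparative transcriptomics for pairs of closely related species:
ortholog identification, CDS/UTR delineation, context-stratified
sequence divergence, and Ka/Ks selection scans — with a synthetic
two-species transcriptome generator that carries complete ground truth,
so the whole pipeline is testable end to end without any external data.

The package is aimed at molecular-evolution analyses of de novo
transcriptome assemblies from species pairs in the 80-100% identity
range (the motivating case is a pair of cryptic whitefly species), where
the questions are: which transcripts are orthologs, how fast do
different site classes diverge, and which genes escape purifying
selection?

## What it computes

* **Orthology** by reciprocal best hit (RBH): pairs that are each
  other's best local alignment over more than 200 bp, followed by a
  paralog filter that keeps only pairs whose two members map
  *unambiguously* to the *same* reference protein (six-frame BLOSUM62
  alignment).
* **Annotation**: the shared protein fixes the reading frame; the start
  codon is the nearest in-frame ATG within ±30 bp of the protein's
  first residue, the stop the nearest in-frame TAA/TAG/TGA within
  ±30 bp of its end. CDS pairs with indels, internal stops, or under
  150 bp are rejected; UTR alignments are kept at high stringency only.
* **Divergence** per region (5'UTR, CDS, 3'UTR) and site class: for a
  stratum with `d` substitutions over `L` compared sites, percent
  difference `100·d/L`, SE across loci, compared kb, the
  transition/transversion ratio ts/tv, %GC and %CpG. Site classes are
  CpG context (a base in a CG dinucleotide in either member) versus
  non-CpG, and nondegenerate (nd) versus fourfold-degenerate (4d) codon
  positions. Fold ratios (CpG/non-CpG per region, 4d/nd) quantify
  hypermutability and constraint.
* **Selection**: per-pair synonymous and nonsynonymous rates,
  `Ks = S_sub/S_sites` and `Ka = N_sub/N_sites` after distance
  correction, by Nei-Gojobori (1986) counting and by a Yang-Nielsen
  (2000)-style approximate method (F3x4 codon frequencies, kappa
  estimated from nd and 4d sites, pathway weights including omega,
  iterated to convergence). Genes are banded at Ka/Ks > 1 (candidate
  positive selection), 0.5-1 (relaxed), < 0.5 (constrained).
* **Simulation**: ancestors with 5'UTR-CDS-3'UTR structure from a
  Markov chain with exact GC and CpG control, two-lineage substitution
  evolution with CpG hypermutability, transition bias kappa, selection
  intensity omega, and optional paralog spiking — all logged in a
  ground-truth channel (`truth.tsv`, `truth_substitutions.tsv`).

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated fixture (100 ortholog pairs at ~1% divergence, 10% paralog
spike, seed 101):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_orthologs.R
Rscript analysis/03_annotate.R
Rscript analysis/04_divergence.R
Rscript analysis/05_selection.R
```

Step 2 prints the ortholog funnel and, because the data are simulated,
its accuracy against ground truth:

```
putative RBH pairs (>200 bp): 100
pairs mapping unambiguously to a shared protein: 94
recall 0.940, precision 1.000, mean identity 0.9929
```

(The six lost pairs are the paralog confounder doing its job: a
duplicate occasionally out-competes the true ortholog at RBH, and a
duplicate with an identical protein makes the best-hit assignment
ambiguous; precision stays at 1.0.)

Step 4 prints the divergence table and fold ratios, e.g.:

```
  utr5_cpg_vs_noncpg     6.79
  cds_cpg_vs_noncpg      7.77
  4d_cpg_vs_noncpg       8.03
  cds_4d_vs_nd           6.06
```

CpG sites diverge several-fold faster than non-CpG sites and 4d sites
several-fold faster than nd sites — the measured ratios overshoot the
simulated 4x CpG rate multiplier because substitutions that *create* a
CpG are attributed to the CpG stratum (see the methods vignette; the
truth-channel estimate printed by step 1 recovers 4.20).

Step 5 summarises selection:

```
Ka and Ks both defined for 76 / 94 pairs
mean Ka 0.0025, mean Ks 0.0166, mean Ka/Ks 0.245
selection bands: 3 positive (>1), 11 relaxed (0.5-1), 62 constrained (<0.5)
```

Equivalently, `run_pipeline(pipeline_config(out_dir, seed = 101))` runs
all five stages in one call and writes `ortholog_pairs.tsv`,
`divergence_table.tsv`, `ratios.tsv`, `kaks_table.tsv`, `scatter.tsv`
and a JSON manifest with the filter-funnel counts; identical seeds give
byte-identical reports.

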