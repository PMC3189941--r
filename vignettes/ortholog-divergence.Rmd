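---
title: "Ortholog divergence and selection scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog divergence and selection scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`orthodiv` compares the transcriptomes of two closely related species —
the motivating case is a pair of cryptic whitefly species whose
assembled transcripts are 80-100% identical — and asks three questions:
which transcripts are orthologous, how diverged they are in different
sequence contexts (untranslated vs coding, CpG vs non-CpG,
nondegenerate vs fourfold-degenerate sites), and which genes show
signatures of positive or relaxed selection in their Ka/Ks ratio. This
vignette documents the models, the tunable parameters, the synthetic
data used to validate every stage, and the design decisions taken where
the procedure was genuinely open.

## The pipeline

1. **Orthology.** All-against-all local alignment between the two
   transcript sets (k-mer seeded, banded Smith-Waterman; see below).
   Pairs that are each other's best hit and align over more than 200 bp
   are putative orthologs. Because de novo assemblies confound members
   of gene families, both members are then compared against a reference
   protein set in all six reading frames; a pair is kept only when both
   map *unambiguously* (unique best hit) to the *same* protein.
2. **Annotation.** The shared protein anchors the reading frame. The
   start codon is the in-frame ATG nearest to the position of the
   protein's first residue, searched within ±30 bp (ties go upstream);
   the stop codon is the nearest in-frame TAA/TAG/TGA within ±30 bp of
   the position following the last residue. If no ATG is found the CDS
   is anchored at the aligned protein start but the pair is excluded
   from 5'UTR statistics; likewise for the stop and the 3'UTR. Pairs
   whose CDS alignments have unequal lengths (an indel or frame
   disagreement), are shorter than 150 bp, or contain an internal stop
   are rejected. UTR alignments are kept only at high stringency
   (>= 40 gap-free columns at >= 90% identity).
3. **Divergence.** Because the species are close, multiple hits at one
   site are rare and divergence is simply substitutions per compared
   site, stratified by region and site class, with the SE taken across
   loci and transitions/transversions tallied per stratum.
4. **Selection.** Ka and Ks per pair by two routes: Nei-Gojobori (1986)
   counting (the transparent oracle) and a Yang-Nielsen (2000)-style
   approximate method (the default), followed by banding at Ka/Ks > 1,
   0.5-1, and < 0.5.

## The synthetic-data generator

No public data are needed to validate the pipeline: the `simulate`
module builds ortholog pairs with complete ground truth. Its defaults
*are* the study conditions the package is designed for; they were fixed
once, from the biology of the motivating system, and are not tuning
knobs.

| parameter | default | rationale |
|---|---|---|
| `n_transcripts` | 100 | enough loci for stable stratified statistics at desk scale |
| `cds_length_range` | 300-900 bp | short assembled transcripts; mean CDS ~500-600 bp |
| `utr5_length_range`, `utr3_length_range` | 30-150, 50-250 bp | transcript-fragment UTRs, 3' longer than 5' |
| `gc_content` | 0.43 | coding GC typical of hemipteran transcriptomes (~42-44%) |
| `cpg_enrichment` | 0.7 | animal transcriptomes are CpG-depleted (observed/expected < 1) |
| `branch_divergence` | 0.01 | ~1% pairwise divergence, i.e. ~99% ortholog identity |
| `cpg_rate_multiplier` | 4 | CpG sites diverge several-fold faster than non-CpG sites |
| `kappa` | 2 | transition bias typical of nuclear sequence |
| `omega` | 0.2 | genome-wide purifying selection; mean Ka/Ks ~0.2 |
| `paralog_fraction` | 0.1 | moderate duplicate contamination of an assembly |
| `paralog_divergence_factor` | 2 | duplicates noticeably older than the speciation event |

**Composition model.** Each ancestor is drawn from a first-order Markov
chain over A/C/G/T constructed so that its stationary distribution is
exactly the target composition (GC split evenly between G and C) and its
CpG dinucleotide frequency is exactly `cpg_enrichment` times the
independence expectation. The construction perturbs only the C row
(P(G|C) = e·pi_G) and rebalances the other rows proportionally, which
keeps the stationary distribution exact for every base; `e = 0`
therefore eliminates CG dinucleotides entirely, and realized GC stays
within sampling error of the target. The CDS is generated codon-wise on
the same chain with stop codons redrawn, which nudges realized GC up by
under a percentage point at GC 0.5 — within the ±2 point tolerance the
generator promises for kilobase-scale sequence.

**Substitution process.** Divergence is applied as independent per-site
Bernoulli draws along the two lineages (rate `branch_divergence/2` per
non-CpG site each), not as a full continuous-time Markov chain; at the
<= 5% divergence scale the probability of two hits at one site is of
order 1e-4 per site and the truth log stays exact. The per-site hazard
is multiplied by `cpg_rate_multiplier` when the site currently sits in a
CG dinucleotide (status evaluated against the mutating sequence at draw
time). The substitute base is a transition with probability
`kappa/(kappa+2)` — the standard rate parameterisation in which kappa is
the transition/transversion *rate* ratio and the expected ts/tv *count*
ratio is kappa/2. Inside the CDS a proposed change is accepted with
probability proportional to omega if nonsynonymous (synonymous changes
are thinned instead when omega > 1, preserving the ratio); changes that
would create an internal stop are redrawn among the remaining bases, so
simulated fixtures deterministically survive the internal-stop filter.
The terminal stop codon may only wander among the three stop codons.
One consequence worth knowing: at stop-adjacent codons the redraw
diverts some probability mass from transitions to transversions, so at
extreme kappa the realized coding ts fraction sits slightly below
kappa/(kappa+2) while UTRs match it exactly.

**Paralogs.** A fraction of ancestors leave an extra descendant in
species A, evolved along an independent lineage twice as long as one
ortholog lineage. The duplicate's own translated CDS joins the
reference protein set under a new id. This creates exactly the failure
modes the shared-protein filter exists for: a duplicate occasionally
out-competes the true ortholog at the reciprocal-best-hit stage, and a
duplicate whose protein happens to be identical to the original makes
the best-hit assignment ambiguous, removing the pair. Both effects
reduce recall by a few percent at the defaults while precision stays at
1.0 — which is the documented, intended trade-off of the "unambiguous
shared protein" rule.

**Seeding.** One master seed; every stochastic operation derives a child
seed deterministically from (master, operation tag), so fixtures are
bit-reproducible regardless of evaluation order, and two pipeline runs
with the same seed produce byte-identical reports.

## Alignment engine

The aligner is a k-mer seeded (word size 11), banded Smith-Waterman
with linear gap penalties (match +2, mismatch -3, gap -5 per column),
implemented in C++ and restricted to ±15 diagonals around the
seed-dominant diagonal. This is appropriate for the >= 80% identity
regime, where the optimal local alignment hugs one diagonal; on
substitution-only pairs the banded score provably equals the exhaustive
dynamic program, and the test suite verifies the equality against an
independent Smith-Waterman implementation. `N` scores as a mismatch
against everything and is excluded from identity denominators.
Tie-breaking everywhere is deterministic: best score, then most
alignment columns, then lexicographically smallest subject id.

Protein comparisons (six-frame translations against the reference set)
use the same engine with BLOSUM62 and a linear gap of -10. BLAST
E-values are not reimplemented; significance is a raw-score cutoff
(default 60) and the UTR "high stringency" gate is >= 40 aligned bp at
>= 0.9 identity. These surrogates are deliberate: at transcript scale a
BLOSUM62 score of ~60 corresponds to matches far beyond chance, and the
UTR gate reproduces the practical effect (few, reliable UTR pairs)
without importing Karlin-Altschul statistics.

## Divergence statistics and the CpG context rule

A compared column is **CpG-context** when its base participates in a CG
dinucleotide in *either* member (the default; a both-member switch
exists). The either rule is the right one for methylation-driven
divergence: deamination converts CG to TG/CA in one lineage, so
requiring both members to retain CG would discard precisely the events
of interest. Its known cost is misattribution in the other direction —
a substitution that *creates* a CG assigns its column (evolved at the
non-CpG rate) to the CpG stratum. At 1% divergence with transition bias
this inflates the measured CpG/non-CpG ratio noticeably above the true
rate ratio. For that reason the *calibration* check of the simulator
(`truth_context_divergence()`) uses the truth channel — substitutions
carrying their draw-time CpG flag over ancestral context counts — which
recovers `cpg_rate_multiplier` directly; the descendant-based table is
reported as what an observer of real data would measure. Passing tests
therefore show that the generator is calibrated *and* that the
measurement behaves as theory predicts, including its bias.

Degeneracy classes (nondegenerate through fourfold) come from the
standard genetic code per codon position and are assigned to a column
only when both members' codons imply the same class; disagreeing
columns stay in the "all" stratum but leave the nd/4d tallies
(conservative). Columns containing `N` are excluded everywhere. The
pooled divergence (substitutions / compared sites) is reported with the
SE of per-locus divergences across loci, which matches how
"mean ± SE over thousands of loci" tables are usually built; the pooled
and per-locus means differ only through locus-length weighting.

## Ka/Ks

**NG86 (oracle).** Per-codon mutational-opportunity site counts with
equal weights (mutations to stop codons excluded and the opportunity
renormalised, so S + N = 3 per codon); substitution counts averaged
with equal weights over all minimal pathways between observed codons,
excluding pathways through stop intermediates (if every pathway is
blocked, all are used); Jukes-Cantor correction applied separately to
the synonymous and nonsynonymous proportions, flagged as undefined at
proportions >= 0.75. The test suite checks the pathway counts against
an independent exhaustive enumeration over the entire codon-pair table.

**YN-style estimator (default).** Three refinements over NG86, in the
spirit of the Yang-Nielsen (2000) approximate method: (i) kappa is
estimated from the K80 transition/transversion distances at sites that
are nondegenerate (resp. fourfold degenerate) in both sequences,
combined by site-count weighting; (ii) site and pathway counts are
weighted by kappa and by F3x4 positional nucleotide frequencies (the
codon-frequency model built from the three codon positions of the data);
(iii) the synonymous and nonsynonymous proportions are corrected with
K80-style formulas using the within-class transition/transversion
split, and omega enters the pathway weights, iterated until its
relative change falls below 1e-6 (at most 100 iterations, flagged
otherwise). With kappa fixed at 1 and uniform frequencies the estimator
reduces to NG86 up to the correction formula, and agrees with it within
5% at <= 5% divergence — a reduction property the tests enforce.

Numerical edge cases are handled explicitly: kappa is capped at 50 when
no transversions are observed in the informative classes (and falls
back to 1 when neither class is informative); omega is floored at 1e-4
inside pathway weights so a nonsynonymous-free iteration cannot lock at
zero; K80 logs with non-positive arguments mark the pair as flagged;
Ks = 0 (or a synonymous opportunity of zero under degenerate F3x4
weights) leaves Ka/Ks undefined, and such pairs are excluded from
ratio-based statistics — mirroring the large fraction of short,
low-divergence ortholog pairs in real data for which only one rate is
computable. Band boundaries are closed into the middle band: Ka/Ks = 1
is *not* positive selection, Ka/Ks = 0.5 is not strong constraint.

Small-sample behaviour worth knowing: per-gene kappa estimates from a
handful of differences are noisy and right-skewed (the cap binds), and
the mean of per-gene Ka/Ks ratios is biased upward by a factor of about
(1 + 1/E[S_sub]) through Jensen's inequality. At the recovery
conditions used in the tests (500-codon genes at 4% divergence) this
predicts a mean near 0.21 for a true omega of 0.2, which is what the
estimator delivers.

## Validation problem sizes

The test suite validates the stack at sizes chosen to make the checks
statistically meaningful while staying desk-scale: composition checks
on ~100 kb of sequence; aligner-vs-oracle on 50 random pairs up to
300 bp; the full codon-pair table (61 x 61) for pathway counting plus
200 random two-codon alignments; CpG-multiplier recovery on 200 loci;
omega recovery on 200 replicates of 500-codon genes at 4% divergence
with kappa = 2 and CpG effects switched off (isolating the codon-level
process); the filter funnel on a 100-gene fixture with a 10% paralog
spike; and byte-level determinism of two full pipeline runs. The omega
experiment uses 4% divergence — the top of the intended regime —
because at 1% a 500-codon gene carries too few synonymous events for a
stable per-gene ratio.

## Known limitations

* Substitution-only evolution: no indels (real pairs with indels are
  filtered, so the simulator models the surviving population), no rate
  heterogeneity across genes beyond CpG and omega, no codon-frequency
  evolution.
* The per-site Bernoulli draw ignores multiple hits within a lineage;
  at 1-5% divergence the resulting downward bias on true distances is
  below the statistical noise of the affected statistics.
* The CpG hazard multiplier is change-agnostic, whereas biological CpG
  hypermutability is transition-specific (deamination); simulated CpG
  strata therefore show less ts/tv elevation than real data.
* The measured CpG/non-CpG fold ratio under the either-member rule
  overshoots the underlying rate ratio through de novo CpG
  misattribution (see above); compare like with like.
* Published tables of per-gene synonymous/nonsynonymous substitution
  *counts* are not always internally consistent with the quoted rates
  (column transpositions are a known hazard); this package treats
  counts as diagnostics and rates as the primary output.
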