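---
title: "dynomine: models, numerical choices and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dynomine: models, numerical choices and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynomine)
```

`dynomine` implements a desk-scale pipeline for discovering dynorphin-like
peptide precursors in nucleotide contigs and for quantifying candidate
peptides pharmacologically at the κ-opioid receptor (KOR). This vignette is
the package's own account of the underlying models, the tunable parameters
and their defaults, what the synthetic-data generators do and do not
emulate, and the numerical decisions a maintainer should know about.

## The mining model

Opioid peptides begin with the invariant Tyr-Gly-Gly-Phe tetrapeptide, and
the mature dynorphin A 1–17 peptide is excised proteolytically from the
preprodynorphin precursor. The mining stage looks for precursor-like
coding regions in assembled transcriptome contigs in four steps.

**Six-frame conceptual translation.** Every contig is translated at all
three offsets on both strands. Translation deliberately runs *through*
stop codons (rendered `*`) with no ORF calling: the downstream filter is a
motif filter on conceptual translations, and imposing ORF structure would
add an assumption the procedure does not need. Codons containing `N`
translate to `X`; trailing 1–2 nucleotides that do not fill a codon are
dropped. Frames are labelled `(strand, offset)` with the offset counted
0-based on the strand being read.

**Motif filter.** A contig is a candidate if at least one of its six frame
translations contains the `YGGF` motif (exact, possibly overlapping
occurrences; `X` never matches). The filter is applied per frame, not per
ORF — consistent with translating through stops.

**Local alignment.** Each motif-bearing frame translation is aligned
against the query precursor by *exact* affine-gap Smith–Waterman — no
heuristic seeding, since candidate sets at desk scale make the full
dynamic program affordable (the DP kernel is C++ via Rcpp, as alignment
inner loops are in any sequence-analysis package). Defaults are the
classic protein-search parameters: BLOSUM62, gap open 11, gap extend 1,
with a gap of length $k$ costing $11 + k$. `X` and `*` score $-4$ against
everything, penalizing ambiguous or stop-containing positions without
aborting. Significance uses the Karlin–Altschul form

$$E = K \, m \, n \, e^{-\lambda S}, \qquad
S' = \frac{\lambda S - \ln K}{\ln 2},$$

with the published gapped-BLOSUM62 pair $\lambda = 0.267$, $K = 0.041$,
query length $m$ and database length $n$ equal to the total residues
across candidate frame translations. No composition-based statistics and
no finite-size (edge-effect) length correction are applied; this is a
deliberate, documented divergence from production BLAST in favour of
simplicity and determinism. Hits require $E \le 10^{-6}$ *and* an aligned
query span overlapping the mature dyn A 1–17 interval by at least 8
residues (configurable); requiring full 17-residue coverage would discard
genuine truncated homologs, while no overlap requirement would admit
alignments entirely outside the mature peptide.

**Extraction, deduplication, profiling.** The mature peptide is read off
the alignment column-wise over the dyn A interval: one character per query
column, `-` where the subject has no aligned residue, subject insertions
dropped. A *unique hit* is a distinct (mature sequence, species) pair —
a novel sequence, or a known sequence in a new species. Unique hits are
clustered by taxonomic group, and sequence-logo matrices report per-column
residue frequencies over non-gap residues with information content

$$R_i = \log_2 20 - (H_i + e_n), \qquad
e_n = \frac{19}{2 \ln(2)\, n_i},$$

clamped at 0, where $H_i$ is the column's Shannon entropy in bits and the
small-sample term $e_n$ (optional, off by default) uses the non-gap count
$n_i$.

### Deterministic tie-breaking, and one known degeneracy

Equal-scoring optimal alignments are resolved deterministically: the best
cell is the one with the smallest subject end coordinate, then the
smallest query end coordinate, and traceback prefers diagonal over
gap-in-subject over gap-in-query. One consequence surfaced by the fixture
tests is worth recording: when both the query and the subject happen to
extend an alignment beyond the planted core, a gap can sit on either side
of a repeated boundary residue at identical total score, and the greedy
diagonal-first traceback may choose the placement that leaves a terminal
core column aligned to a gap. The extracted mature sequence then shows a
terminal `-` even though the residue is present and identical in the
subject. Aligned (non-gap) columns are never wrong; this is purely a
gap-placement degeneracy, shared by any maximal-scoring local aligner, and
the test suite asserts exactly that contract.

Only the single best alignment per candidate frame is evaluated — no
sub-optimal HSPs. A frame containing two separate precursor copies would
therefore yield one hit; that limitation is acceptable because the
generators plant at most one precursor per contig, and is documented here
for real-data use.

## The synthetic transcriptome generator

`make_precursor_set()` builds one precursor per species: the human dyn A
1–17 core `YGGFLRRIRPKLKWDNQ` with positions 5–17 independently
substituted (by one of the 19 *other* residues, so the expected number of
substitutions is exactly $13 \times$ the mutation rate) and the `YGGF`
positions never mutated, flanked by random sequence (N-flank 40–80
residues, C-flank 10–30). `embed_in_contigs()` back-translates each
precursor with uniformly random synonymous codons from the standard
genetic code — real codon-usage bias is irrelevant to a translation-based
pipeline — and plants it at a uniformly random offset, strand and frame in
a random-nucleotide contig of 900–1500 nt; decoys are rejection-sampled
until no frame contains `YGGF`. Every planting is recorded in a manifest,
which is the oracle for recall and false-positive tests.

The query shipped for fixtures, `make_query_precursor()`, is a *synthetic*
80-residue preprodynorphin-like precursor (random flanks, core at residues
41–57); for real analyses the user supplies their precursor of interest,
e.g. human preprodynorphin (UniProt P01213, dyn A at residues 207–223,
which is the config default interval). The fixture geometry was sized from
the closed form: a perfect 17-residue core alignment scores 97, so with an
80-residue query against the ≈20,000 candidate residues of the default
fixture, $E \approx 4 \times 10^{-7}$ — safely below the $10^{-6}$ cutoff,
which is why mutation-free recall is exactly 100%.

What the fixtures do **not** emulate: sequencing error, assembly
artifacts, splice variation, real codon usage, and — importantly — real
flanking homology between query and subject precursors (flanks are
random). Passing tests therefore demonstrate correctness of the pipeline's
logic and statistics, not sensitivity on diverged real precursors, where
flank conservation would only *raise* scores.

## The assay simulators and fitting procedures

### Competition binding

Expected bound radioligand follows monophasic displacement,

$$\mathrm{cpm}(c) = NS + \frac{B_0 - NS}{1 + c/\mathrm{IC}_{50}}, \qquad
\mathrm{IC}_{50} = K_i \left(1 + \frac{[L]}{K_d}\right),$$

with Poisson counting noise on the observed counts (counting statistics
are the natural detector model for cpm). Defaults: $[L] = 1$ nM tracer
with $K_d = 0.87$ nM; total-binding scale $B_0 = 4000$ cpm (a typical
filtration-assay count at this membrane load); nonspecific level
$NS = 0.1\,B_0$, reflecting its operational definition by 10 µM naloxone;
12 logarithmically spaced concentrations over 0.1 nM–30 µM in duplicate.
The calibration constant 38.4 fmol/cpm is stored in the configuration for
reference but is not used to derive $B_0$, because its direction and units
cannot be reconciled with the stated receptor density and membrane amounts
without extra assumptions.

Fits use the three-parameter logistic with Hill slope fixed at 1 — the
"three-parameter" naming means exactly that the slope is not fitted — on
*raw cpm* with the bottom plateau free; the fitted bottom is reported
alongside the experimentally defined nonspecific level so the two can be
compared, and $K_i$ follows from Cheng–Prusoff. (Fitting specific binding,
total minus NS, is the main alternative convention; raw cpm keeps the
noise model honest and both plateaus visible.)

### cAMP inhibition

The generating response, as percent of the reference effect, is
$y(c) = E_{\max} / (1 + \mathrm{EC}_{50}/c)$. The raw scale is defined
*operationally*: the reference ligand's measured response at 10 µM **is**
the 100% point of the normalization, so simulated raw responses are
$y(c)/100$ times the reference effect magnitude plus Gaussian noise (SD
3% of that magnitude), and the published efficacies — already expressed as
percent of the reference — are the exact generating plateaus. This choice
makes noise-free recovery exact rather than exact-up-to-the-reference's
own sub-saturation, which would otherwise contaminate every simulated
plateau by a fraction of a percent. Fits constrain the bottom to 0 (the
normalization defines 0 as no inhibition) and warn, without failing, if
the fitted plateau exceeds 120%. The default grid is 13 points over
0.03 nM–30 µM in triplicate.

### BRET β-arrestin-2 recruitment

Traces are sampled every 60 s from −300 s to 2460 s with ligand addition
at $t = 0$ after the 5-min baseline. The ligand-induced acceptor/donor
ratio rises mono-exponentially,
$\Delta(t) = A\,(1 - e^{-t/\tau})$ for $t > 0$ and 0 before addition, with
$\tau = 300$ s by default (a typical arrestin-recruitment time constant;
the quantification below is insensitive to $\tau$ as long as ligand and
reference kinetics match). The reference amplitude is 0.10 ratio units on
a baseline ratio of 0.6, with Gaussian ratio noise of 3% of the reference
amplitude; the ligand amplitude is the efficacy ratio times the reference
amplitude, 0.7 by default — i.e. a 30% lower recruitment ceiling than the
reference, the blenniorphin-like preset. Quantification takes the
pointwise ligand-minus-vehicle ratio difference, averages it over the
inclusive 311–2411 s window, and divides by the reference's windowed mean;
because the window average of $A(1 - e^{-t/\tau})$ is proportional to $A$
at matched kinetics, the noise-free relative value equals the efficacy
ratio exactly. Unequal time grids are linearly interpolated onto the
ligand grid; extrapolation is refused.

### Nonlinear least squares

All fits run Levenberg–Marquardt (`minpack.lm`) from three deterministic
starts — data-driven plateau estimates with the midpoint concentration,
then $\pm 1$ log-unit shifts of the midpoint — keeping the converged start
with the lowest SSE (relative-SSE tolerance $10^{-10}$, 500 iterations).
Flat data are flagged degenerate with an undefined midpoint rather than
fitted; non-convergence is flagged, never silently replaced. Summaries
across independent experiments report mean and sample SD ($n-1$
denominator), with SD marked unavailable for a single experiment.

## Peptide masses

Monoisotopic masses are residue-table sums plus one water (18.010565 Da),
free N-terminal amine and free C-terminal acid, no modifications; [M+H]⁺
adds one proton (1.007276 Da). Observed MALDI-TOF masses of synthesized
peptides typically sit ≈0.1 Da above these theoretical values, so
comparisons against observed masses use a ±0.15 Da tolerance.

## Problem sizes used by the test suite

The suite exercises: a 50-precursor / 500-decoy fixture for recall and
false-positive properties; 200 random pairs of length ≤ 8 against a
brute-force alignment-enumeration oracle (plus longer pairs against an
independent aligner); 100-seed parameter-recovery studies for the binding
and cAMP fits (median relative error must stay below 10%); and 3–4
replicate simulations per ligand at the published parameter sets. These
sizes are the package's chosen balance between statistical resolution and
a test suite that runs in well under a minute.

## Known limitations

* One best alignment per frame (no sub-optimal HSPs); no composition-based
  statistics or length correction in the E-value.
* The per-frame motif filter cannot find precursors whose `YGGF` spans a
  sequencing gap or `N`-containing codon.
* Binding fits assume pure competitive displacement (monophasic, slope 1);
  two-site or cooperative binding is out of scope.
* BRET quantification assumes matched ligand/reference kinetics within the
  analysis window; strongly mismatched kinetics would bias the windowed
  ratio.
* The simulators model detector noise, not biological replicate
  variability (e.g. day effects, membrane-batch effects), so simulated
  SDs understate real inter-experiment scatter.
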