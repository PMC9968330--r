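---
title: "Methods: lncRNA-derived MHC peptide discovery with lncpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA-derived MHC peptide discovery with lncpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpep)
```

## The problem

Immunopeptidomics identifies MHC class I bound peptides by matching
tandem-MS spectra against a protein database. Peptides translated from
long non-coding RNAs are invisible to a standard proteome database, so the
pipeline's first job is to build a custom search space: the three-frame
translation of every lncRNA transcript expressed at detectable levels.
Its second job is interpretation — deciding which identified peptides are
genuinely lncRNA-derived, which small ORF could have produced them,
whether their source genes look like targets of the E2F1 transcription
factor, and how to package the best peptides into a vectored-vaccine
cassette.

## Translation and ORF model

Translation is sense-strand only, in frames 0/1/2 (the offset in
nucleotides from the transcript 5' end), under the standard genetic code;
the translated products therefore cover "all theoretical ORFs" without
committing to any start-codon model at the database stage. Stops are kept
as `*` at the frame level and database entries are the maximal stop-free
segments of each frame, because search engines require stop-free
sequences. A codon containing `N` translates to `X`, and `X` never
matches a peptide residue, so ambiguous sequence can only lose matches,
never invent them.

ORFs, used for peptide-source assignment and cloning, are defined
strictly: every ATG to its first in-frame stop codon. Nested ORFs sharing
a stop are all reported, since MS evidence cannot distinguish which
methionine initiated translation. Near-cognate (non-ATG) initiation is
deliberately not enumerated by default — start-codon ambiguity in the
field is real but unresolved — and `enumerate_orfs(start_codons = ...)`
exposes the extension for users who want CTG/GTG starts. ORFs running off
the transcript 3' end are excluded by default (`require_stop = TRUE`):
the ORF definition demands a stop, and the cloning design needs one to
remove.

Coordinates are 0-based half-open everywhere inside the package; GTF
(1-based closed) is converted at the parser boundary, BED passes through
unchanged.

## Expression gating

Per-transcript TPM is summarised as the **maximum** across samples —
"detectable in any sample" is the natural reading of detectable-level
gating and is robust to a transcript being switched off in one condition;
`aggregator = "mean"` is available for users who prefer pooled gating.
Bins follow the three stated classes: non-expressed (TPM = 0, with
`zero_eps = 1e-9` absorbing quantifier float noise), low
(0.5 < TPM < 1.0) and high (TPM ≥ 1.0). Two boundary decisions were
genuinely open:

* TPM in (0, 0.5] belongs to no stated bin. These transcripts are
  `unassigned` and excluded from both databases — they are neither
  reliably expressed nor reliably silent, so using them on either side
  would blur the target/decoy contrast.
* TPM exactly 1.0 is assigned to **high**, so the low/high pair tiles
  (0.5, ∞) without orphaning exactly-1.0 transcripts.

Low-bin transcripts are included in the target database by default
(detectable, if weakly), switchable by filtering the binned table before
`build_search_databases()`. The minimum segment length of 7 residues is
the shortest plausible class I ligand; raising it can only shrink the
database (a tested monotonicity property).

## Provenance and precedence

Peptide matching is exact substring search, both against the canonical
proteome and the lncRNA target database. Canonical evidence dominates: a
peptide present in both databases is `shared`, not lncRNA-unique — the
conservative reading of "peptides derived from lncRNA genes". Optional
I/L-collapsed matching (`collapse_il = TRUE`) accounts for MS being blind
to the isoleucine/leucine distinction; it is off by default because the
standard analysis treats sequences literally. Significance calls
(up/down/unchanged) are consumed as input flags — differential-abundance
testing happens upstream in the MS quantification software — and
`summarize_regulation()` only aggregates them.

## Promoter-window classification

The direct-target rule is geometric: the window is
`[tss - 500, tss + 500)`, exactly 1000 nt, and any peak sharing at least
one nucleotide with it scores the gene direct. Half-open intervals make
the boundary behaviour exact and testable: a peak ending at the window
start misses; one nucleotide further in hits. The TSS is strand-aware
(`genomic_start` on `+`, `genomic_end - 1` on `-`) and taken from each
gene's representative transcript. Associated status is strand-blind
overlap or containment within the boundaries of any *direct-scoring* gene
(the reference set is built by applying the same peak rule to all supplied
genes, with `reference_genes` available for screened host annotations);
precedence is direct > associated > none, so a gene is counted once.
Peaks from multiple tracks (cell lines) are simply pooled.

## Cassette and cloning arithmetic

Each cassette segment is the peptide plus up to 24 nt (8 residues) of
natural flanking sequence either side, copied verbatim from the source
transcript so that proteasomal processing context is preserved. Flanks are
bounded by the ORF, not the raw transcript: translation cannot have
produced residues upstream of the initiator methionine or downstream of
the stop, which is why a peptide near an ORF's 3' end carries a truncated
downstream flank. Segments are whole codons, so concatenation preserves
frame; a stop codon can therefore only arise *within* a hand-made segment,
and assembly warns (never edits) if one appears. The leader is Kozak
`GCCACC` plus a standard 23-residue human tPA signal-peptide CDS — both
are configuration, echoed in the design report, since vaccine programmes
vary them. The cloning amplicon is `[max(0, orf_start - 30), orf_end - 3)`
on the transcript: 30 bp of upstream context to retain any endogenous
ribosome binding site, stop removed so a C-terminal tag stays in frame.

Candidate shortlisting (`rank_vaccine_candidates()`) filters on the three
stated criteria — predicted MHC affinity rank, normal-thymus expression of
the source lncRNA, and regulation q-value — then orders lexicographically
with alphabetical tie-breaks for determinism. The thresholds are mandatory
arguments with no defaults: no published cut-offs exist, and silently
assumed ones would masquerade as science.

## What the synthetic data emulates — and what it cannot show

The generators produce uniform-composition background sequence with
planted ATG…stop ORFs of 20–80 residues (the sub-100-residue smORF
regime), TPM tables whose per-transcript maxima land exactly in designed
bins across two conditions with three replicates, peptides drawn 8–11
residues with mode 9 (weights 0.25/0.55/0.15/0.05, mean exactly 9.0),
and peaks placed strictly inside or outside promoter windows. Associated
genes are realised by a synthetic host gene spanning the lncRNA whose own
distant TSS carries the peak — the geometry of an lncRNA inside another
TF-target gene. Genes are spaced (10 kb) so neighbouring windows cannot
interact; the generator audits its own design and rejects infeasible
geometry rather than emitting ambiguous truth.

Passing tests on these data show the pipeline's *logic* is exact:
binning, partition, provenance, window arithmetic and cassette round-trips
recover the manifest at 100%. They do not show robustness to what real
data add: assembly errors and incomplete annotation, TPM uncertainty near
bin boundaries, peptides matching repetitive or paralogous sequence,
fuzzy peak edges, or I/L ambiguity in the MS evidence. Headline dataset
counts from real experiments depend on the deposited RNA-seq,
immunopeptidome and ENCODE data and are outside what synthetic fixtures
can or should reproduce.

Cross-contamination control matters for interpretability: lncRNA-origin
peptides are rejected if they occur in the canonical proteome, canonical
contaminants if they occur in any expressed transcript's translation, and
unmatched peptides if they occur in either — so intended provenance is
unambiguous by construction, and any misclassification is a pipeline
defect, not a fixture accident.

## Numerical and degenerate-input choices

* All generators are deterministic under a fixed seed; the orchestrator
  derives sub-seeds (`seed + k`) so components stay independently
  reproducible.
* Exact class counts (bins, regulation flags, target classes) use
  largest-remainder allocation, so designed proportions are hit exactly
  whenever `n × proportion` sums allow.
* Mean normalisation rejects rows with non-positive means by name instead
  of emitting NaN/Inf.
* An empty database write is a warning plus an empty file (a legitimate
  all-expressed design), and reading it back yields a zero-row table.
* Molecular weight uses standard average residue masses plus one water;
  the empty peptide and any non-standard residue are errors, not zeros.
* Test problem sizes — 200 transcripts for the unit-level ORF oracle,
  1000 for the acceptance-level one, 120-transcript end-to-end datasets,
  1000 peptides for the length-distribution check — were chosen as the
  smallest sets that exercise every code path and make sampling error
  negligible against the asserted tolerances.

## Known limitations

Three-frame (not six-frame) translation is by design: the database models
sense-strand products of the annotated transcript. The pipeline does not
quantify expression, call peaks, match spectra, estimate FDR from search
scores, or predict MHC binding — those live in dedicated upstream tools,
and their outputs enter here as plain tables. Splice-aware genome mapping
of ORFs is out of scope: all ORF coordinates are transcript-relative.
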