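# lncpep

Long non-coding RNAs (lncRNAs) are conventionally annotated as
untranslated, yet many carry small open reading frames (smORFs, typically
under 100 residues) whose products are processed and presented on MHC
class I molecules as 8–11-mer peptides. Such lncRNA-derived ligands are
attractive tumour-vaccine antigens: their source genes are frequently
driven by the E2F1 transcription factor, reshaped by PRMT5 inhibition, and
poorly expressed in normal thymus, so the peptides can escape central
tolerance. `lncpep` is the computational half of that discovery programme,
for proteogenomics and immunopeptidomics analysts:

* **Expression-gated search databases** — every lncRNA transcript is
  translated in all three sense frames, binned on TPM
  (non-expressed: TPM = 0; low: 0.5 < TPM < 1.0; high: TPM ≥ 1.0), and
  split into stop-free segments. Low/high transcripts form the *target*
  FASTA; the identically translated non-expressed set forms the *decoy*
  FASTA used to calibrate false discovery in the MS search.
* **Peptide provenance and ORF assignment** — MS-identified peptides are
  matched by exact substring search against the canonical proteome and the
  lncRNA target database; lncRNA-unique peptides are assigned every
  ATG-to-stop ORF whose polypeptide contains them, with length
  distributions, mean-normalised abundance matrices and regulation
  summaries.
* **TF-target classification** — a gene scores as a potential *direct*
  E2F1 target when a ChIP-seq peak falls in the 1000-bp window centred on
  its TSS (500 bp either side, half-open), and as *associated* when its
  boundaries overlap or lie within a direct-target gene on either strand.
* **Vaccine design** — each selected 9-mer is carried into a poly-antigen
  cassette with 24 bp of natural flanking sequence either side (bounded by
  its source ORF), behind a Kozak sequence and a tPA secretion leader;
  cloning amplicons cover the ORF minus its stop plus 30 bp of upstream
  transcript sequence.
* **Synthetic data with planted truth** — seeded generators emulate the
  transcriptome, TPM table, immunopeptidome, ChIP-seq peaks and canonical
  proteome, with a manifest that predicts every downstream call, so the
  whole pipeline is testable without external downloads.

## Worked example

```r
library(lncpep)

ds <- simulate_lncpep_dataset(seed = 1, n_transcripts = 60,
                              n_lnc = 40, n_canonical = 20, n_unmatched = 5)

binned <- bin_expression(ds$expression$tpm)
table(binned$bin)
#>          high           low non_expressed
#>            30            12            18

db <- build_search_databases(ds$transcriptome$transcripts, binned)
table(db$role)
#>  decoy target
#>    441    899

prov <- classify_peptide_provenance(ds$peptides$sequence, ds$proteome,
                                    db[db$role == "target", ])
table(prov)
#>     canonical lncRNA_unique     unmatched
#>            20            40             5

peptide_length_distribution(ds$peptides$sequence[prov == "lncRNA_unique"])
#> $counts
#>  8  9 10 11
#>  8 21  8  3
#> $mean_length
#> [1] 9.2

calls <- classify_gene_targets(ds$transcriptome$annotation, ds$peaks$peaks,
                               reference_genes = ds$peaks$host_genes)
summarize_target_fractions(calls)
#>        class  n percent
#> 1     direct 48      80
#> 2 associated  6      10
#> 3       none  6      10
```

Sixty synthetic lncRNA transcripts split 30/12/18 across the high/low/
non-expressed TPM bins; the 42 expressed transcripts yield 899 target
segments and the 18 non-expressed ones 441 decoy segments. All 65
simulated MS peptides are returned to their intended origin: 40
lncRNA-unique (mostly 9-mers, mean 9.2 residues — the MHC class I size
signature), 20 canonical-proteome contaminants, 5 unmatched. Peak
classification recovers the designed 80/10/10 split of direct/associated/
non-target genes.

Downstream, `extract_flanked_segment()` / `assemble_cassette()` turn
chosen peptides into the flanked cassette (with `tpa_leader_default()`
and Kozak `GCCACC`), `cloning_amplicon()` produces the ORF-FLAG insert,
and `rank_vaccine_candidates()` shortlists peptides on predicted MHC
affinity rank, thymus expression and regulation q-value.

A command-line front end over the same functions ships in
`inst/cli/lncpep.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lncpep.R", package = "lncpep"))')
Rscript $CLI simulate --seed 3 --out sim --n-transcripts 40
Rscript $CLI builddb --fasta sim/transcripts.fa --tpm sim/tpm.tsv \
    --out target.fa --decoy-out decoy.fa
Rscript $CLI map --peptides sim/peptides.tsv --canonical sim/proteome.fa \
    --lncdb target.fa --fasta sim/transcripts.fa --out report.tsv
```

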