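# vestige

Inference of gene inactivation (pseudogenization) from comparative genomic
loci.

When a lineage loses a trait, the genes serving it decay: frameshifting
indels, premature stop codons, broken splice sites and deleted exons
accumulate once purifying selection stops. The textbook case is the loss of
sebum-producing genes in cetaceans, whose skin lacks sebaceous glands.
`vestige` is for comparative genomicists who want to document such losses
reproducibly: given an intact reference gene model and the orthologous
genomic locus of each target species, it maps the reference exons, calls
ORF-disrupting lesions, classifies each gene's coding status per species,
dates shared losses on the species tree, and weighs genomic and
transcriptomic read evidence.

## The method

For a reference gene with exons $e_1, \dots, e_k$ and a target locus $T$,
each exon is placed by **glocal alignment** (exon global, locus-window
local) under affine gap scoring (match +2, mismatch −3, gap −5 − 2L),
with windows constrained between already-anchored exons so placements stay
colinear. From the per-exon alignments the package emits **lesions**:

| type | signal |
|---|---|
| insertion / deletion | alignment indel, left-normalized; frameshift iff length mod 3 ≠ 0 |
| premature_stop | in-frame stop upstream of the reference stop in the translated virtual CDS |
| splice_donor / splice_acceptor | intron boundary dinucleotide ≠ GT / ≠ AG |
| exon_deletion | exon unplaceable in fully sequenced (non-N) context |

Lesions grade into strong / medium / weak evidence (truncations in the
final 10% of the CDS or the last exon are down-weighted, following the
weaker selective constraint on carboxyl termini), and verdicts follow:
**inactivated** (≥1 strong or ≥2 medium+), **inconclusive**, or **intact**.
Identical lesion signatures across species are single founding mutations:
**Dollo parsimony** places each on the branch above its carriers' MRCA.
Genomic reads validate lesions via exact-matching mutant-allele contexts
(20 nt flanks, ≥2 reads, ≥2 independent read sets when available); RNA
reads are classified mature (exonic / junction-spanning) vs immature
(containing intronic sequence).

A synthetic clade simulator (`make_toy_gene`, `evolve_clade`,
`inject_lesion`, `simulate_reads`) generates worlds with machine-readable
truth tables, so the whole pipeline is testable offline with known answers.

## Worked example

Simulate an 8-species clade at ~5% divergence from the reference, inject a
1-nt deletion on the stem (all species inherit it) and a premature stop on
the (C,D) ancestor, then run the pipeline:

```r
library(vestige)

model <- make_toy_gene(3, c(120, 150, 90), c(200, 200), seed = 1)
tree <- ape::read.tree(text = paste0(
  "(((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3):0.4,",
  "((E:0.3,F:0.3):0.3,(G:0.3,H:0.3):0.3):0.4);"))

clade <- evolve_clade(model, tree, 0.05, seed = 1)
clade <- inject_lesion(clade, tree$tip.label,
                       list(type = "deletion", cds_coord = 60, length = 1))
clade <- inject_lesion(clade, c("C", "D"),
                       list(type = "premature_stop", cds_coord = 12))

ann <- run_annotate(model, clade$loci)
ann$statuses[["C.toyA"]]
#> C / toyA: inactivated (2 lesion(s))

subset(ann$lesions, species == "C",
       select = c(type, exon, cds_coord, length, alt_allele, severity))
#>             type exon cds_coord length alt_allele severity
#> 5 premature_stop    1        12      0        TGA   strong
#> 6       deletion    1        60      1              strong

cmp <- run_compare(ann, tree)
cmp
#> comparison run: 2 signature(s), 2 shared event(s)
#>   toyA premature_stop @12 (2 carriers) -> stem of (C,D) [conserved]
#>   toyA deletion @60 (8 carriers) -> root stem [conserved]
```

Both injected mutations are recovered at their exact normalized CDS
coordinates (0-based, reference frame). The species-C gene carries a strong
frameshifting deletion and a strong early stop, hence `inactivated`. The
deletion, present in all eight species, is dated to the clade's stem
("root stem", conserved across every assayable descendant); the stop is
dated to the (C,D) ancestor — the same logic that dates a gene loss shared
by all cetaceans to the cetacean stem lineage.

Real data enter through `build_gene_model(gff3, fasta, gene_id)` for the
reference and `target_locus()` / `read_fasta()` for per-species loci;
`run_validate()` and `classify_rna_read()` add read evidence;
`write_report()` serializes the full run as JSON.

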