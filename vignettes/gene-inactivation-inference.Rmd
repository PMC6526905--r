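---
title: "Inferring gene inactivation from orthologous genomic loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene inactivation from orthologous genomic loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestige)
```

## The inference problem

When a trait is lost in a lineage — the loss of skin sebaceous glands in
whales and dolphins is a canonical example — the genes serving that trait
stop being maintained by selection and decay into pseudogenes. The decay
leaves diagnostic scars in the genome: frameshifting insertions and
deletions, premature stop codons, degenerate splice-site dinucleotides, and
outright exon deletions. `vestige` codifies the workflow used to document
such losses across a clade:

1. **Exon mapping** — each exon of an intact reference gene model (e.g. the
   cow orthologue) is located inside the orthologous genomic locus of every
   target species by glocal alignment.
2. **Lesion calling** — the per-exon alignments are turned into a list of
   ORF-disrupting lesions with left-normalized coordinates in the reference
   CDS frame.
3. **Status classification** — the lesion list yields a per-species verdict:
   `intact`, `inactivated`, or `inconclusive`.
4. **Comparative placement** — lesions with identical signatures in several
   species are treated as single founding mutations and placed on the
   species tree by Dollo parsimony (one origin, no reversal): the event sits
   on the branch above the carriers' most recent common ancestor.
5. **Read evidence** — genomic reads validate called lesions (a read must
   reproduce the mutant allele with exactly matching flanks), and RNA-seq
   reads are classified as maturely spliced (exonic-only or
   junction-spanning) versus immature (containing intronic sequence).

Orthology is supported independently by flanking-gene synteny
(`check_synteny()`), comparing the ordered gene neighbourhood of the target
locus against the reference locus, orientation-agnostically.

## Alignment model and numerical choices

Exon placement uses an affine-gap aligner (`Biostrings::pairwiseAlignment`,
`type = "global-local"`): the exon is aligned end-to-end while the target
window is free at both flanks. Default scores are match +2, mismatch −3,
gap-open −5, gap-extend −2 (a gap of length L costs `5 + 2L`); IUPAC
ambiguity codes, including N, never match anything, so assembly-gap runs
carry no signal. The aligner's score is verified in the test suite against
an independent brute-force dynamic program on hundreds of random pairs.

Three choices matter for robustness and are worth stating explicitly:

* **What counts as "found".** An exon placement is accepted when identity
  ≥ 0.5 and coverage ≥ 0.5 *and* the alignment score is positive. Identity
  is computed over all alignment columns, with gap columns counting against
  it. Both refinements exist because an optimal glocal alignment against
  completely unrelated sequence still attains a deceptive ~0.52–0.57
  match-per-column fraction by stitching chance 8-mers together with gaps —
  but its score is deeply negative, while a genuine exon even at 25%
  divergence scores well above zero. The thresholds are deliberately
  permissive: reference-to-target divergence in practice (e.g. cow to
  cetaceans) is far below what they tolerate.
* **Boundary anchoring.** Each exon pattern carries up to 10 nt of
  homologous reference intron (or flank) context on each side, trimmed from
  the result after alignment. A boundary-blind aligner otherwise misplaces
  exon ends by 1–2 nt when substitutions fall near them, which fabricates
  indel + splice-lesion pairs. The splice context is nearly conserved, so it
  pins the boundary; when the target truly carries a splice mutation the pad
  simply absorbs one mismatch.
* **Mutation parsimony at equal length.** When the aligner explains a
  same-length target segment with a compensating insertion–deletion pair
  that is only marginally cheaper than plain substitutions (within the two
  gaps' own penalties), the substitution reading is preferred. A run of
  substitutions is the simpler mutational history than two indels that
  exactly restore the length.

Exons are placed in decreasing length order; the search window for each exon
spans between the nearest already-anchored exons, which enforces colinearity
by construction, and placement runs in two passes so an exon evaluated
before its neighbours were anchored gets retried in its final window. An
exon that cannot be placed is reported `missing` — a deletion candidate —
unless ≥ 20% of its search window is N, in which case it is
`gap_unresolved`: with no sequence to inspect, absence of evidence is not
evidence of deletion. This codifies the argument that a fully sequenced,
gap-free region lacking an exon indicates genuine exon loss.

## Lesion calling rules

Indels are emitted from the alignment operations and left-normalized
(VCF-style: shifted to the leftmost equivalent placement), so that the same
historical mutation acquires an identical `(gene, type, coordinate, length,
allele)` signature in every descendant species; the test suite checks the
normalizer against exhaustive enumeration of equivalent placements. The
frameshift flag is exactly `length %% 3 != 0`.

Premature stops are read off the translated virtual CDS (the concatenated
aligned target exons, insertions included, deletions excluded, frame offset
propagated across exon boundaries). Two kinds are distinguished:

* a stop in the *reference* frame created by substitution is a lesion in its
  own right — but only called when the 10 aligned bases on each side reach
  70% identity, suppressing stops hallucinated inside alignment noise;
* the first stop met by the ribosome downstream of a frameshift is reported
  with a `consequence` flag. It is real biology (the frameshift "culminates
  in a stop codon"), but the heritable signature is the frameshift itself:
  consequence stops are excluded from cross-species signature matching and
  are not double-counted in verdicts, because background substitutions make
  the downstream stop position drift between species sharing one frameshift.

Splice sites are checked per intron flanked by two found exons: donor = the
first two intron nucleotides (canonically GT), acceptor = the last two
(canonically AG). Donor lesions are indexed by the exon whose 3' boundary
they disrupt, and reports carry both exon and intron indices to avoid the
ambiguity of "splice site of exon 3". GC is treated as a non-canonical donor
by default but `noncanonical_donors = "GC"` accepts it, since minor-class
GC–AG introns do occur in mammals.

## From lesions to verdicts

The field literature argues case-by-case; `vestige` freezes that reasoning
into an explicit severity scheme so it can be tested. Truncating lesions in
the amino-terminal and internal CDS are the decisive ones, because the
carboxyl terminus is under weaker selection and late frameshifts can be
tolerated:

* **strong** — frameshift indel or premature stop upstream of the terminal
  region (the final 10% of the CDS, `terminal_fraction`) and outside the
  last exon; a premature stop upstream of an annotated critical interval
  (e.g. an active-site motif such as AWAT2's HPHG, supplied per gene as
  `critical_intervals`); deletion of a non-terminal exon.
* **medium** — a non-canonical splice dinucleotide (potentially rescuable by
  cryptic splicing, hence not decisive alone).
* **weak** — truncating lesions confined to the terminal region or last
  exon; in-frame indels.

Verdict: `inactivated` with ≥ 1 strong or ≥ 2 medium-or-strong lesions;
`inconclusive` with exactly one medium lesion, only weak lesions, or only
unresolved assembly gaps; `intact` otherwise. These cut-offs are this
package's codification of published worked cases (a lone acceptor mutation
is "insufficient to determine the coding status"; a 4-nt deletion just
before the stop codon does not establish loss), not a community standard —
they are parameters, and the classification they produce should be read
together with the underlying lesion table, which is always reported.

Dollo placement treats species with a `gap_unresolved` exon at a lesion's
locus as missing data: they join neither the carrier nor the non-carrier
set, and an event is `conserved` only when every assayable leaf under the
assigned branch carries it. Signature matching is exact after
normalization; a configurable ±3 nt fallback (`coord_jitter`) exists but
defaults to off. Genes whose lesions never match across species (the
`Awat2`-like pattern) simply yield no shared event: the package reports
convergence rather than forcing an ancestral branch.

## Read-based evidence

A genomic read supports a lesion when it contains the mutant allele with
≥ 20 exactly matching nucleotides on each side (`min_flank`), and
contradicts it when the reference allele in the same context matches
instead; reads ending inside a flank count in neither bucket, and both read
orientations are searched. Validation needs ≥ 2 supporting reads, and, when
two or more independent read sets are supplied, support from ≥ 2 of them —
mirroring validation against at least two independent sequencing projects.

RNA reads are aligned to both the spliced transcript and the unspliced
locus; a read whose best placement covers ≥ 10 intronic nucleotides
(`min_intronic_overlap`) is immature, one placed at least as well on the
transcript is mature, and reads below an identity floor of 0.8, or tied
placements that overlap introns, are ambiguous. Paralogous reads (the
*Mogat3* / *Mogat3-like* situation) are assigned to the candidate with the
fewest mismatches only when the margin over the runner-up is ≥ 2
mismatches; otherwise they are reported ambiguous and kept out of per-gene
counts.

## The synthetic study system

Because the real inputs of such analyses are genome assemblies and SRA
archives, every stage here is exercised on a fully specified synthetic
world whose truth is known by construction:

* `make_toy_gene()` builds a reference model — by default in the tests, a
  3-exon gene (120/150/90 nt exons, 200 nt introns, 150 nt flanks) whose
  CDS is a run of sense codons ending in a stop, with canonical GT/AG at
  every intron.
* `evolve_clade()` runs neutral point substitutions (equal-rate,
  Jukes–Cantor-like) along an 8-leaf ultrametric tree of unit root-to-leaf
  depth at 0.05 substitutions per site — i.e. ~5% divergence of each leaf
  from the reference, up to ~10% between opposite leaves, a regime
  comparable to intra-artiodactyl coding divergence. Splice dinucleotides,
  start and stop codons are never mutated and substitutions that would
  create an in-frame stop are resampled, so the background is lesion-free
  by construction and every detected lesion is an injected one. The
  background process has no indels; indels exist only as injections.
* `inject_lesion()` places one lesion on a chosen branch; every descendant
  leaf inherits it at the homologous position. All six lesion types are
  supported, plus N-masking to fabricate assembly gaps. Around indel and
  stop injections, 12 nt of flanking context is restored to the reference
  bases in the carriers first — otherwise a background substitution
  directly adjacent to an injected indel can merge with it into a
  different, equally optimal indel representation, and the truth signature
  would be ill-defined. Injections closer than ~30 nt on a shared lineage
  are rejected.
* `simulate_reads()` emits genomic reads (uniform starts, per-base error,
  both strands) or RNA reads drawn from the spliced transcript with
  probability `mature_fraction` and from the pre-mRNA otherwise. Read
  classes are content-defined (immature = contains intronic sequence), so
  immature reads are drawn only from positions covering at least the
  classification threshold of intronic sequence: a pre-mRNA read lying
  wholly inside an exon is indistinguishable from a mature read by any
  content-based rule.

What this world does *not* emulate: rate heterogeneity and GC content
structure, background indels, segmental duplications and rearrangements,
sequencing-error profiles beyond uniform substitutions, and the annotation
noise of real assemblies. Passing the simulated recovery tests therefore
demonstrates the correctness of the inference logic under its stated model,
not performance on arbitrary real genomes; on real data the thresholds
above are the knobs to revisit, and every one of them lives in
`vestige_config()`.

```{r world, eval = FALSE}
model <- make_toy_gene(3, c(120, 150, 90), c(200, 200), seed = 1)
tree <- ape::read.tree(text = paste0(
  "(((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3):0.4,",
  "((E:0.3,F:0.3):0.3,(G:0.3,H:0.3):0.3):0.4);"))
clade <- evolve_clade(model, tree, 0.05, seed = 1)
clade <- inject_lesion(clade, tree$tip.label,
                       list(type = "deletion", cds_coord = 60, length = 1))
ann <- run_annotate(model, clade$loci)
cmp <- run_compare(ann, tree)
cmp$events
```

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
8-leaf, 3-exon world (including 100 lesion-free replicate clades as a
false-positive control), 200 aligner-versus-oracle pairs up to 50 nt, ~150
enumerated indel-normalization cases, and two 500-read RNA mixtures —
sizes chosen so the whole battery completes in a few minutes on one core
while still estimating each rate with useful resolution. All randomness
flows from explicit integer seeds; a fixed seed reproduces every sequence,
read and report byte-for-byte.

## Known limitations

* Exon inversions and translocations are reported as `missing`, not
  recognized as rearrangements (a flagged-but-unresolved situation in real
  data too).
* Regulatory inactivation — an intact ORF that is transcriptionally silent —
  is visible only through the RNA-evidence counts, never through the
  genomic verdict.
* Selection statistics (dN/dS and relatives) are out of scope; the package
  is about presence/absence of ORF integrity, not rate shifts.
* The verdict thresholds codify worked published cases; for a new gene
  family they should be sanity-checked against a few hand-annotated
  species before being trusted wholesale.
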