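---
title: "FGFR2 fusion architecture: annotation model and assay simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FGFR2 fusion architecture: annotation model and assay simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FGFR2fusion)
```

## The biological problem

FGFR2 fusions occur in roughly 10–15% of intrahepatic cholangiocarcinoma
(iCCA) and are druggable with selective FGFR inhibitors, which makes their
reliable detection and interpretation a routine molecular-pathology task.
Structurally these are "type 2" fusions: FGFR2 is invariably the 5' partner,
breakpoints cluster downstream of the tyrosine kinase domain — in exon 17,
intron 17 (most frequently) or the protein-coding part of exon 18 — and the
3' partner is drawn from a long, heterogeneous list of genes. Two activation
mechanisms are recognised:

* **C-terminal truncation** — loss of the FGFR2 C-terminus including the
  YLDL internalisation motif (aa 769–772 on NM_000141.4). This mechanism is
  independent of the reading frame and of any partner contribution; even a
  partnerless rearrangement or an out-of-frame junction activates the
  receptor this way, provided the kinase domain (aa 481–757) survives.
* **Enhanced dimerisation** — an in-frame partner contributes a
  dimerisation/oligomerisation module (coiled-coil, SAM, leucine zipper,
  zinc finger, and related families), making receptor dimerisation
  ligand-independent.

The package implements this interpretive logic per isoform, plus declarative
models of the six assay classes used diagnostically (break-apart and
dual-fusion FISH, 5'/3' expression imbalance, amplicon panels, anchored
single-primer extension, and hybrid capture at DNA and RNA level), so that
any breakpoint or junction can be asked: *would this assay have seen it, and
what could it have reported?*

## The gene model and its fixture

The packaged FGFR2 model (`fgfr2GeneModel()`) encodes the published facts:
minus strand of chr10, locus 123,237,844–123,357,972 (hg19 labels);
NM_000141.4 (IIIc) with 18 exons and an 821-aa protein; NM_022970.3 (IIIb)
differing only by an alternative eighth exon and one extra residue (822 aa);
NM_001144913 (IIIb C3) lacking the first exon and ending in a shorter
alternative last exon, its protein being the IIIb protein without the final
53 aa; domains at the published amino-acid coordinates; 26 described exonic
regions in the extended catalog. Individual exon widths and intron sizes are
synthetic — the published facts, not a base-by-base coordinate table, are
the contract — which keeps the package free of any external download. Exon
labels are parent-relative, so the C3 isoform's first exon is labelled "2"
and shared exons keep their names across isoforms.

Two deliberate consequences of the synthetic layout: every internal exon
boundary is codon-aligned (exon 17 ends at codon 762), so a junction "after
exon 17" retains the complete kinase domain but has already lost YLDL; and
the canonical protein contains exactly one YLDL occurrence, so motif-loss
logic cannot be confounded by spurious matches.

Internally all genomic coordinates are 1-based closed, the native
GenomicRanges convention; BEDPE input/output converts from/to its 0-based
half-open form at the boundary, and cDNA/protein coordinates are 1-based to
match clinical amino-acid numbering.

Eight toy partner genes (real symbols, synthetic coordinates) model the
partner landscape: ATE1 and TACC2 within interphase-FISH resolution of the
locus, BICC1/CCDC6/WAC/AFF3/DBP distant, KCTD1 with three isoforms whose
start codons differ, so one genomic breakpoint can be 5' UTR on the
canonical isoform yet intron 1 — and in-frame — on the alternatives. KCTD1's
BTB/POZ module is explicitly flagged dimerisation-competent even though it
is not in the classical domain-family list, because an in-frame KCTD1 fusion
is interpreted as potentially dimerisation-driven.

## Frame, kinase and mechanism decisions

**Reading frame.** Let `L5` be the retained driver CDS length in
nucleotides and `q` the number of partner CDS nucleotides lost 5' of the
junction. Codon phase is preserved iff `L5 ≡ q (mod 3)`. When the junction
splits a codon, the hybrid codon spanning it can be a stop; `frameStatus()`
checks this against the transcript sequences, so its verdict agrees exactly
with a translation oracle that concatenates the two fragments and translates
them (the test suite enforces this on 1000 random junctions). A junction
upstream of the partner isoform's start codon yields `no_cds_3p`; partner
isoforms that do not carry the junction exon yield `indeterminate` rather
than an error. Everything is evaluated per driver-isoform × partner-isoform
pair and never collapsed: a conflict flag is raised when informative records
disagree, which is precisely the situation of isoform-dependent start codons.

**Kinase retention** is decided by two rules that must agree on the fixture:
the positional rule (exon 17, intron 17, or the CDS of the exon after 17)
and the general rule (the retained prefix translates the full kinase
domain). Breaks inside exon 17 upstream of the kinase C-terminal codon make
the rules disagree; such positions carry a discrepancy warning instead of a
silent guess, since the source material does not define competence there.

**Mechanism.** Without kinase retention there is no mechanism. Otherwise an
in-frame fusion with a fully retained flagged dimerisation domain is
`enhanced_dimerisation`; YLDL loss with no dimerisation gain (or no frame,
or no partner) is `c_terminal_truncation`; a DNA-only event whose partner
content is unknown — a bridged insert mapping to a repeat or a third locus —
is `indeterminate`, unless truncation is forced because there is no partner
at all. Loss of the last 10 aa (GRB2-binding region) is recorded as an
informational flag, not a separate mechanism. `competent` is kinase
retention combined with a non-`none` mechanism; indeterminate mechanisms
remain competent because partnerless FGFR2 rearrangements are clinically
actionable.

## Assay models and their parameters

| design | key parameters (default) | rationale |
|---|---|---|
| BA-FISH | probe footprints flanking the locus; `resolutionBp = 1e6` | no separation figure is published; 1 Mb is a conservative interphase separation scale and reproduces the documented ATE1/TACC2 misses |
| Dual-FISH | designed partner = BICC1 | detection restricted to the exact designed partner |
| Imbalance | 3'/5' molecule-count `ratioThreshold = 0.5` | no published cutoff; half the 5' signal is a conservative call |
| Amplicon | driver primers exons 17/18; per-partner exon lists (CCDC6: 1–2) | closed design; the CCDC6 1–2 choice reproduces the published worked example |
| SPE | driver primers on the design isoform NM_000141.4 | anchored PCR is partner-agnostic but isoform-bound |
| HyCa | DNA: probes tiling exon 17–intron 17–exon 18 end to end; RNA: all described driver exons | intron 17 must be covered in its entire length |

DNA-level hybrid capture identifies the partner only when the non-driver
side maps within an annotated gene; bridged inserts of at least 10 nt that
map elsewhere or only to repeat families leave the event *detected but
unresolved*, reported as a rearrangement rather than a fusion. This is an
intentional asymmetry with the verdict-soundness rule: an undetected verdict
always carries a failure mode, but a detected verdict may carry
`bridged_unresolved`.

## The synthetic cohort

`simulateCohort()` draws event classes with fixed default rates:
bridged/intergenic partnerless 10% and close-proximity partners 4.2% (both
published for the reference cohort), out-of-frame 5%, intragenic 3'
deletions 3%, non-competent upstream breaks 5% — the last three are not
published numbers but plausible minority fractions chosen once. Driver
breakpoints are distributed 0.15/0.70/0.15 over exon 17/intron 17/exon 18
(configurable; the source describes the distribution only qualitatively as
intron-17-dominant). Read counts are Poisson with means proportional to
depth × expression (depth default 200). All randomness flows through the
single seed in `cohortParams()`.

Simplifications worth knowing before extrapolating to real data: breaks
inside coding exons are codon-aligned, so junction phases are controlled by
the partner offset alone; 3' deletions are intragenic (both breakends inside
the locus), matching their DNA-level reporting as FGFR2-internal
rearrangements; bridged events carry either a repeat-derived or a
third-locus insert; there is no sequence-level read simulation, no FFPE
degradation model, no coverage variability, and partner expression is
uniform. Passing tests therefore demonstrate the internal consistency of
the annotation and assay logic under the published architecture, not
performance on raw sequencing data.

The law-of-large-numbers test runs at n = 10,000 events and the
acceptance-style cohort checks at n = 1,000; both finish in seconds to tens
of seconds on one core.

## Reports

RNA reports carry the five mandated items — split/paired read counts, the
fusion-read ratio, gene names with transcript IDs, junction exons, and the
frame plus domain-integrity statement — in machine-readable JSON and
Markdown. DNA reports add breakpoint coordinates, the genome build, an
ISCN-like and an HGVS-style rendering, and phrase the frame/domain estimate
with a mandatory cautious qualifier whenever the mechanism is indeterminate.
The fusion-read ratio denominator includes spanning pairs; the report footer
states this, since the definition is not fixed by any published convention.
The compact junction code (F17A12) uses gene initials; when two symbols
share an initial the first differing letter is appended. Structured
junction coordinates (transcript, exon, offset per side) are emitted as a
JSON block rather than a string, anticipating consensus nomenclature that
was not yet finalised.

## Known limitations

* Fixture coordinates are synthetic; positions cannot be compared with real
  hg19 FGFR2 coordinates base-for-base.
* Competence of breaks inside exon 17 upstream of codon 757 is flagged, not
  decided.
* FISH is modelled geometrically (probe separation distance only); no
  signal-intensity or cell-count modelling.
* Amplicon/SPE primer chemistry is reduced to exon membership;
  primer-to-junction distance limits are out of scope.
* The cohort-level detection percentages published for the original trial
  cohort depend on a non-deposited breakpoint list and are deliberately not
  reproduced; the machinery that would compute them is instead exercised on
  synthetic cohorts and property tests.
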