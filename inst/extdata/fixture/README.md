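# Hand-checkable fixture bundle

A tiny deterministic dataset exercising every pipeline stage, with the
expected outputs under `expected/` computed by hand from the construction
below (independently of the package code). All BED-style coordinates are
0-based half-open; the reference species is `C_niphades`, chromosome
`chrI`, length 2000.

## Catalog stage (`segments.bed`, `annotation.gff3`, `alignment.maf`)

CDS intervals (= gene bodies here): gA [120,200), gB [480,560),
gC [720,730), gD [760,770), gE [1500,1600).

Candidate conserved segments and what the filters do to them:

| segment | interval | after CDS subtraction | after > 10 bp rule |
|---|---|---|---|
| S1 | [100,140) | [100,120) | CNE00001 |
| S2 | [300,308) | unchanged | dropped (8 <= 10) |
| S3 | [400,460) | unchanged | CNE00002 |
| S4 | [500,540) | removed (inside gB) | — |
| S5 | [700,790) | [700,720), [730,760), [770,790) | CNE00003-5 |
| S6 | [900,911) | unchanged | CNE00006 (11 > 10) |

Projection truth from the MAF gap/coordinate structure:

- Block 1 (ref [80,150)) carries a 25-column insertion after ref position
  109 present only in C_inopinata. CNE00001 ([100,120), 20 bp) therefore
  projects to 45 bp in C_inopinata (45 > 2 x 20, `dropped_length_ratio`)
  and to 20 bp in C_elegans / C_briggsae (kept).
- Blocks 4a/4b split ref [695,725) at 710; C_briggsae's row of block 4b
  comes from a distant locus (start 1500), so CNE00003 ([700,720)) maps to
  two disjoint C_briggsae intervals (`dropped_redundant`); C_elegans and
  C_inopinata stay contiguous (kept).
- Block 6 (ref [895,915)) lacks a C_briggsae row: CNE00006 is `unaligned`
  there.
- Everything else is ungapped and in-place: kept.

Nearest genes (gap = bases between; sign: + downstream, - upstream; ties
by leftmost gene start): CNE00001-gA 0 (adjacent), CNE00002-gB +20,
CNE00003-gC 0, CNE00004 ties gC/gD at 0 -> gC, CNE00005-gD 0,
CNE00006-gD -130.

## Diversity stage (`panel.vcf`, `pi_elements.bed`)

8 haploid samples. Per-site contribution 2p(1-p) n/(n-1) with n the
called haplotypes:

- 1005 (E1): 4/8 alt -> 2(.5)(.5)(8/7) = 4/7
- 1050 (E1): 1/8 -> 2(1/8)(7/8)(8/7) = 1/4;  pi(E1) = (4/7 + 1/4)/100 = 0.00821429
- 1250 (E2): 2/8 -> 3/7; 1260 (E2): 3/6 called -> 2(.5)(.5)(6/5) = 0.6;
  1270: 1 called haplotype -> skipped;  pi(E2) = (3/7 + 0.6)/120 = 0.00857143
- 1550 (E4): 1/8 -> 1/4;  pi(E4) = 0.00250000
- 1700 lies outside all elements; 1800 is an indel and is dropped on read.

E3 (40 bp) is excluded by the > 50 bp rule.

## Transition stage (`biascalls_*.tsv`, `orthologs.tsv`, `neighbor_genes.txt`)

12 one-to-one orthologs; neighbors {g1, g2, g11}; cells from the planted
classes. Per-cell 2x2 hypergeometric p-values enumerated by hand, e.g.
(Non, XX-biased): 2 of 2 in-cell genes are neighbors, margins (2, 10; 3):
p = C(2,2)C(10,1)/C(12,3) = 10/220 = 0.04545455; BH over the nine cells
gives q = 9 x p = 0.40909091 for that cell and 1 elsewhere. Sample odds
ratios use the 0.5 correction whenever a cell is zero, e.g.
(2.5 x 9.5)/(0.5 x 1.5) = 31.6667 for (Non, XX-biased).

## Acceleration bundle

Built in code by `makeFixture()` from a fixed internal seed: six
80-column element alignments at conserved scale rho = 0.3, one planted
with lambda = 8 on the three hermaphrodite terminal branches; the planted
element must be called at q < 0.05.
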