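# vhhkit

Tools for single-domain antibody (VHH / nanobody) engineering in R, for
structural bioinformaticians and antibody-library designers.

Camelid VHHs bind antigen with a lone heavy-chain variable domain, and their
third hypervariable loop (CDR3) adopts a small number of gross conformations
relative to framework region 2 (FR2): an extended loop standing away from FR2
(*Upright*), a loop folded back over FR2 (*Roll*), and an intermediate
(*Half-Roll*). The conformation determines how the paratope forms — Upright
domains recruit FR2 residues into the paratope, Roll domains bury FR2 under
the loop — so reproducing it is central to designing synthetic VHH libraries
that behave like camelid antibodies.

## The classification at the core

For a Kabat-numbered domain with CDR3 endpoint *n* = H102, vhhkit computes
two indices from the Cα trace:

- **d** — the distance (Å) between Cα(H46) in FR2 and Cα of residue
  (*n* − 5), five positions before the CDR3 endpoint;
- **θ_base** — the pseudo-dihedral angle (degrees, mapped to [0°, 360°))
  over the Cα atoms of residues (*n* + 1), (*n*), (*n* − 1), (*n* − 2).

The class is assigned by a fixed partition of the (θ, d) plane:

| class     | rule                       |
|-----------|----------------------------|
| Upright   | θ ≥ 140° and d ≥ 15 Å      |
| Roll      | θ < 140° and d < 10 Å      |
| Half-Roll | everything else            |

Loops shorter than five residues are *Indeterminate* (the indices are
undefined; a manual label from visual inspection can be carried through).

Around this core the package provides structure I/O (PDB/mmCIF via bio3d), a
heuristic Kabat numberer with an escape hatch for external numbering tables,
dataset curation filters with class/length statistics, contact-based paratope
mapping, a four-sub-library synthetic VHH library designer (*Upright 6*,
*Upright 12*, *Roll 12*, *Roll 15*) with exact combinatorial diversity
accounting, in-silico sampling, DNA cassette assembly with a restriction
audit, and post-screening triage arithmetic. A seeded fixtures module makes
the whole pipeline runnable and testable with no downloads.

## Worked example

```r
library(vhhkit)

# a synthetic Cα trace built to sit in the Upright region
tr <- make_loop_trace(theta_target = 200, d_target = 18, cdr3_length = 8, seed = 1)
g  <- loop_geometry(tr$chain, tr$numbering)
g
#> <LoopGeometry> d_fr2 = 18 A, theta_base = 200 deg, CDR3 length = 8
classify_loop(g)
#> [1] "Upright"

# the default four-sub-library design and its exact diversity
d <- default_design()
diversity(d)
#>       name               diversity diversity_num
#>   Upright6            257065109850  2.570651e+11
#>  Upright12     6204926826496954650  6.204927e+18
#>     Roll12     6030140155328026350  6.030140e+18
#>     Roll15 29626078583126593457550  2.962608e+22
#> pooled total: 29638313650365483548400 (~2.96e+22)

# sample library members and attribute them back to their origin
sm <- sample_protein(d, "Roll15", n = 3, seed = 42)
sm$cdr3
#> [1] "ITLSKNKSDHENAFL" "FVFGEQFGEHDKYSR" "GEGDAVFFYDHGINL"
attribute_sublibrary(sm$sequence, d)$label
#> [1] "Roll15" "Roll15" "Roll15"
```

The diversity numbers are exact integers: |CDR1| · |CDR2| · 17^L per
sub-library (150 CDR1 sequences; 71 CDR2 of 16 residues for Upright, 69 of
17 residues for Roll; CDR3 randomized over the 17-letter alphabet that
excludes Cys, Met and Pro). The pooled theoretical diversity of the default
design, about 3 × 10^22, comfortably exceeds 10^13. Sampled CDR3s never
contain C/M/P, and unmutated samples are attributed to their sub-library of
origin with 100% recall.

## Command line

A thin wrapper is installed at `inst/cli/vhhkit`:

```sh
Rscript inst/cli/vhhkit classify --input structures/ --out classes.tsv
Rscript inst/cli/vhhkit sample --sublibrary Roll12 --n 1000 --seed 7 --out lib.fasta
Rscript inst/cli/vhhkit triage --clones clones.tsv --out triage.json
```

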