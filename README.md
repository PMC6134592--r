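# exocube

Exometabolomics assertion datacubes, compatibility scores and interaction
webs.

## What this is for

Exometabolomics (metabolite footprinting) experiments compare the
extracellular metabolite pool of an environment — a defined medium, a soil
extract, a root exudate — before and after growth of a microorganism. The
outcome per metabolite is a qualitative assertion: the organism *increased*
it, *decreased* it, left it with *no change*, or the metabolite was *not
investigated*; the uninoculated control pool itself records only whether each
metabolite was *detected* or *not detected*. `exocube` stores these
assertions in a three-dimensional organism × metabolite × environment
datacube and provides the analyses microbial ecologists run on such data:
slicing the cube into two-dimensional tables, drawing the bipartite
organism–metabolite interaction web of an environment, and scoring potential
metabolite competition and exchange between organisms for consortium design.

## The data model and the scores

One **observation** is a unique (metabolite, organism, environment) triple
carrying an action code, an optional log2 fold change
(log2 of spent over control mean abundance), a confidence score
`min(|log2fc|, 5)` used for cell shading (exactly 5 when the metabolite was
detected on only one side, where a fold change against zero is undefined),
an optional p-value and a project tag. The control pool is the reserved
pseudo-organism `"The Environment"`.

The **assertion engine** turns replicate control-vs-spent abundance tables
into observations: metabolites undetected on both sides are not
investigated; otherwise a two-sided test (Welch t by default, Mann–Whitney
optional, Benjamini–Hochberg correction optional per batch) asserts no
change when non-significant, else an increase or decrease by the direction
of the ratio of replicate means.

For organisms cultured in the same environment, with `D_s` / `I_s` the sets
of metabolites organism *s* decreased / increased and `P` the control pool:

- **EUS** (environmental uptake score) `= |D_s ∩ P| / |P|` — the fraction of
  the starting pool the organism consumes;
- **OCS-FMC** (fraction of metabolites under competition)
  `= |D_s ∩ D_r| / |D_s|` for scored organism *s* against reference *r*;
- **OCS-FME** (fraction of metabolites for potential exchange)
  `= |D_s ∩ I_r| / |D_s|` — resources the reference releases and the scored
  organism takes up.

All scores lie in [0, 1]; an empty denominator makes a score undefined
(`NA`, never 0).

## Worked example

The package ships a fixed demonstration cube of two soil isolates
mono-cultured in R2A medium, *Phenylobacterium* sp. GW123-8A04 and
*Pseudomonas* sp. FW300-N2A2 (synthetic metabolite names, set sizes
back-solved from a reference scoring demonstration):

```r
library(exocube)
cube <- worked_example_fixture()
compatibility_table(cube, "R2A", reference = "FW300-N2A2")
#>   kind     scored  reference numerator denominator value
#> 1  FMC GW123-8A04 FW300-N2A2        25          50  0.50
#> 2  FME GW123-8A04 FW300-N2A2         8          50  0.16
compatibility_table(cube, "R2A", reference = "GW123-8A04")
#>   kind     scored  reference numerator denominator     value
#> 1  FMC FW300-N2A2 GW123-8A04        25          26 0.9615385
#> 2  FME FW300-N2A2 GW123-8A04         0          26 0.0000000
```

Read: the two isolates share 25 decreased metabolites. For GW123-8A04 those
are half of the 50 metabolites it consumes (FMC = 0.5); for FW300-N2A2 they
are 25 of its 26 (FMC ≈ 0.96), so FW300-N2A2 would face competition for
nearly everything it uses. FW300-N2A2 releases 8 metabolites that GW123-8A04
consumes (FME = 0.16) while the reverse exchange is empty (FME = 0):
GW123-8A04 is the likely beneficiary of a co-culture.

Other entry points:

```r
one_environment(cube, "R2A")         # heatmap-like slice table
build_web(cube, "R2A")               # bipartite interaction web
#> interaction web (R2A): 105 metabolites (100 in control), 2 organisms, 89 edges
save_db(cube, "isolates.sqlite")          # single-file relational store
```

A thin command-line wrapper (subcommands `score`, `view`, `web`, `simulate`,
`upload`) is installed at `system.file("cli", "exocube", package = "exocube")`.

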