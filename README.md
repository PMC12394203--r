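# cdr3scope

Length-dependent analysis of nanobody (VHH) repertoires and structures.

The CDR3 loop of a camelid single-domain antibody is built by VDJ
recombination and varies from ~5 to 25+ residues — up to a fifth of the
whole domain. `cdr3scope` is for immunologists and antibody engineers who
want to ask, systematically: *what else changes as CDR3 gets longer?* It
covers both sides of that question:

* **Sequences** — ingest IMGT-annotated repertoires (TSV, one row per
  unique read with a position:insertion:residue numbering string), apply
  the standard three-stage filter (read count ≥ 5 → amino-acid
  deduplication → CDR3-length |z| < 2.5), and correlate CDR3 length with
  per-region net charge at pH 7.4 (D,E −1; R,K +1; H +0.1),
  Kyte–Doolittle hydropathy, regional and per-position residue usage, and
  germline length preference (pairwise Mann–Whitney U).
* **Structures** — load VHH–antigen complexes (PDB + a JSON chain map),
  find 4 Å residue contacts, compute the conformation metric
  **FR2_CDR3_Dis** (minimum distance between the centroid of IMGT
  position 42 and trimmed-CDR3 residue centroids), classify bent vs
  extended conformations at the trough of the metric's bimodal density,
  and quantify interfaces by Shrake–Rupley SASA, buried surface area,
  per-segment paratope counts, FR2 involvement, seven-class compositions
  and DSSP secondary-structure usage.

All correlation families report Pearson r with BH-adjusted p-values and
the usual star codes. Outputs are tibbles throughout; results compose with
dplyr/ggplot2, and fitted objects have `tidy()`/`glance()`/`autoplot()`
methods. A synthetic module (`simulate_repertoire()`,
`simulate_structures()`) generates repertoires and pseudo-structures with
the statistical structure the analysis assumes, so the whole pipeline is
testable without SRA or structure-database downloads.

## Worked example

```r
library(cdr3scope)

rep <- simulate_repertoire(repertoire_recipe(n = 2000, seed = 1))
f   <- filter_repertoire(rep)
filter_log(f)
#> # A tibble: 3 × 4
#>   step          parameter                               n_before n_after
#> 1 min_count     count >= 5                                  2110    1535
#> 2 dedup         amino-acid identity, keep highest count     1535    1475
#> 3 cdr3_length_z |z| < 2.5                                   1475    1464

length_summary(f)
#>   count  mean    se median   std
#> 1  1464  15.8 0.120     16  4.58
```

2,110 generated rows (duplicates included) collapse to 1,464 filtered
members whose CDR3 lengths average 15.8 ± 4.6 residues. Running the
repertoire branch and looking at IMGT position 42 — the classic
framework-2 switch position — shows the length-linked Y→F exchange:

```r
out <- run_repertoire_branch(rep, min_position_n = 50)
subset(out$positional_usage, position == 42)
#>   region position residue    n      r        p_adj stars
#> 1    FR2       42       F 1464  0.364 1.16e-45  ****
#> 2    FR2       42       Y 1464 -0.364 1.16e-45  ****
```

F at position 42 becomes more frequent as CDR3 grows (r = 0.36), Y less —
i.e. short-CDR3 VHHs carry Y42, long-CDR3 VHHs carry F42. On the structure
side, the FR2–CDR3 distance separates the two loop conformations:

```r
ss  <- simulate_structures(structure_recipe(n = 60, seed = 7))
dis <- vapply(ss$models, fr2_cdr3_dis, numeric(1))
cls <- classify_conformation(dis)
cls
#> cdr3_conformation: threshold 10.81 A; 31 bent, 29 extended
autoplot(cls)   # density with the trough threshold marked
```

Structures below the 10.8 Å trough have CDR3 bent down toward framework 2;
those above project away from it. `run_structure_branch()` assembles the
full feature table and the length correlations, overall and within the
conformation / FR2-involvement strata.

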