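# abtriage

Experimentally guided triage of computational antibody–antigen binding poses,
with downstream affinity-maturation candidate selection — at toy scale.

## The problem

Computational docking and structure prediction typically return many mutually
incompatible binding poses for an antibody–antigen pair, and scoring functions
alone often cannot tell which (if any) is right. A cheap and decisive source
of truth is mutagenesis: if an alanine substitution abolishes binding at the
bench, a correct pose must predict a binding-energy penalty at that position;
if a substitution leaves binding intact, a correct pose must not predict a
large penalty there. `abtriage` operationalizes this idea as a pipeline:

1. **Fixtures** — build a small synthetic antibody (heavy + light chain) /
   antigen complex with *planted* interactions (salt bridge, hydrogen bond,
   π-cation, hydrophobic contact) whose geometry and energetics are known
   exactly, plus simulated binding phenotypes for an alanine panel.
2. **Dock** — generate rigid-body decoy poses around the antigen (clash-free,
   exact first-contact placement) alongside the true pose.
3. **Scan** — compute an *in silico* alanine scan (ΔΔE of binding) for every
   pose × mutation, using localized recomputation that is exact under the
   rigid-body model.
4. **Triage** — apply a consistency filter (deleterious mutations must have
   ΔΔE ≥ 0; neutral mutations must have ΔΔE ≤ 0.5 AU) and rank surviving
   poses by the partial-knockout margin (reduced-binding mutations should
   hurt less than knockouts).
5. **Design** — propose a minimal validation panel of discriminating
   mutations (unique-contact positions, single discriminators, maximally
   discriminating triples, and per-chain neutral controls).
6. **Mature** — saturation-scan the top pose over CDR and Vernier positions
   in two side-chain accommodation modes (rigid and tolerant), keep
   consensus candidates that improve binding without destabilizing, pool and
   deduplicate across modes, and select a bench panel with per-position caps
   and a neutral control.

Energies are in arbitrary units (AU): each detected interaction contributes
a fixed weight (salt bridge −2.0, hydrogen bond −1.0, π-cation −1.25,
π-stacking −0.75, hydrophobic −0.25) and steric clashes a +5.0 penalty, so
all bookkeeping is exact and checkable by hand.

## Worked example

```r
library(abtriage)

fx <- make_toy_complex(fixture_spec(seed = 1))
detect_interactions(fx$complex)
#>          kind binder_chain binder_pos binder_aa3 target_chain target_pos
#> 1 salt_bridge            H          4        LYS            A          4
#> 2       hbond            H          8        SER            A          8
#> 3   pi_cation            L         11        ARG            A         11
#> 4 hydrophobic            L          2        LEU            A          2
#>   target_aa3 distance angle
#> 1        ASP      3.0    NA
#> 2        SER      3.0    NA
#> 3        TYR      4.9  28.5
#> 4        LEU      4.0    NA

binding_energy(fx$complex)
#> [1] -4.5

alanine_scan(fx$complex, fx$truth$scan_positions)
#>   pose_id mutation  mode ddE_binding ddE_stability
#> 1      NA    H:K4A rigid        2.00             0
#> 2      NA    H:S8A rigid        1.00             0
#> 3      NA   H:A11A rigid        0.00             0
#> 4      NA    L:L2A rigid        0.25             0
#> 5      NA    L:A6A rigid        0.00             0
#> 6      NA   L:R11A rigid        1.25             0
```

Each planted interaction is recovered at its exact specified geometry, and
each alanine ΔΔE equals the weight of the interaction it deletes. Now hide
the true pose (pose id `0`) among 199 decoys and triage:

```r
ps <- make_decoy_set(fx, n_decoys = 199, seed = 1)
m  <- scan_pose_matrix(ps, fx$truth$scan_positions)
ph <- simulate_phenotypes(fx$truth, fx$complex)
fl <- consistency_filter(m, ph)
r  <- rank_partial_knockout(fl$passing, m,
                            names(ph)[ph == "reduced"],
                            names(ph)[ph == "non_binding"])
head(data.frame(pose = as.character(r), margin = attr(r, "margin"),
                strict = attr(r, "strict_partial")), 5)
#>   pose margin strict
#> 1    0  -0.75   TRUE
#> 2    1   0.00  FALSE
#> 3    2   0.00  FALSE
#> 4    3   0.00  FALSE
#> 5    4   0.00  FALSE
```

The true pose ranks first: it is the only pose where the weak hydrophobic
contact (ΔΔE +0.25) is strictly smaller than every knockout penalty, giving a
partial-knockout margin of −0.75 AU; contact-free decoys sit at 0.

## Command-line pipeline

An executable runner is installed under `inst/scripts/abtriage.R`:

```sh
Rscript inst/scripts/abtriage.R all --seed 1 --out run1
Rscript inst/scripts/abtriage.R triage --config config.yaml
```

Stages (`fixtures`, `dock`, `scan`, `triage`, `design`, `mature`, `report`)
read and write deterministic TSV artifacts under `--out`; logs (no
timestamps) go to `out/logs/`. Two runs with the same config and seed are
byte-identical. Defaults live in `default_config()`; a YAML config and
command-line flags override them.

## Testing

```r
testthat::test_dir("tests/testthat", package = "abtriage",
                   load_package = "installed")
```

The suite includes per-module unit and property tests (independent oracles:
`bio3d` for PDB I/O and superposition, closed-form two-sphere SASA,
exhaustive filter enumeration, brute-force clustering and distance censuses)
plus `test-acceptance.R`, one block per acceptance criterion. The full run
takes about eight minutes, dominated by the 20-seed planted-pose recovery
benchmark.

## Reproducing results

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

runs the main computation against the installed package and writes the key
quantities as JSON. With `--seed 1`: true-pose binding energy −4.5 AU,
alanine ΔΔE of 2 / 1 / 1.25 / 0.25 at the four planted positions, true pose
ranked first with margin −0.75 over 199 decoys, and a recovery fraction of
1.0 over ten seeds. All randomness derives from `--seed`; rerunning with the
same seed reproduces the file exactly.
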