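# memsurf

Analysis toolkit for protein–lipid bilayer molecular dynamics
trajectories, built around the amyloid-beta dimer / membrane-surface
use case: how fast does a peptide attach to a bilayer, how does it orient,
how does its secondary structure evolve on the surface, how do its domains
contact each other, which lipids form its annular shell, and how
asymmetric are the two leaflets it sits on.

It is written for structural biophysicists who have trajectories (or want
ground-truthed synthetic stand-ins) and need the standard per-figure
quantities of a membrane-binding study as reproducible numbers rather
than renderings.

## What it computes

* **Binding kinetics** — the protein–lipid minimum distance d(t) per frame
  (exact all-pairs, minimum-image), and the attachment time t_attach
  defined as the intersection of two fitted lines: a least-squares decline
  over samples 1..k and a horizontal plateau over k..n, with the
  breakpoint k chosen by exhaustive search to minimise the total SSE.
* **Orientation** — the angle θ(t) = arccos(v·ẑ/|v|) between a body-fixed
  residue-to-residue vector (e.g. Ala-42 → Lys-28) and the bilayer normal.
* **Secondary structure** — per-residue 9-state codes
  {H, G, I, E, B, T, S, C, X} from Kabsch–Sander backbone hydrogen-bond
  patterns, E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol
  with bonds below −0.5 kcal/mol (X is the chain-separator row), plus
  reduction to the hydrogen-bonded classes BE, GHI, T and their sum
  BEGHIT per N/C-terminal domain.
* **Contact maps and zones** — symmetric residue × residue minimum-distance
  maps (nm), averaged over the trailing 50 ns and across replicates, and
  summarised over the 10 zones pairing the domains N_A, C_A, N_B, C_B
  (means ± SEM across replicates).
* **Annular sorting** — lipids/waters within a lateral (or 3D) cutoff of
  the protein are annular (AL), the rest non-annular (nAL).
* **Leaflet asymmetry** — lipid-number mismatch |n_a−n_b|/max(n_a,n_b)·100
  and the analogous surface-area-per-lipid mismatch; with a shared box
  area the two are identical by algebra.

Seeded generators (`makeBilayer`, `makeBindingTrajectory`,
`makeIdealHelix`, `makeBetaPair`) provide synthetic systems whose correct
answers are known analytically, so every stage is testable without
simulation data.

## Worked example

```r
library(memsurf)

# a 20 ns approach trajectory of the A-beta dimer over a PC-like bilayer,
# true attachment time 4 ns, 1.4 A jitter
spec  <- bindingTraceSpec(t_attach = 4, d0 = 50, plateau = 5,
                          noise_sd = 1.4, t_end = 20, dt = 0.1, seed = 42L)
traj  <- makeBindingTrajectory(spec, bilayerSpec(36L, 36L, seed = 42L),
                               abeta42Sequence())
series <- minDistanceSeries(traj,
                            selectAtoms(traj@system, class = "protein"),
                            selectAtoms(traj@system, chain = "L"))
fit <- detectAttachment(series)
str(fit)
#> List of 5
#>  $ t_attach        : num 3.93
#>  $ decline_slope   : num -11.6
#>  $ plateau_level   : num 4.96
#>  $ breakpoint_index: int 38
#>  $ sse             : num 367
```

The detector recovers the generator's 4 ns attachment time to 0.07 ns
despite the jitter; the decline slope ≈ −11.6 Å/ns matches the
constructed (50 − 5)/4 ≈ −11.3 Å/ns ramp, and the plateau level ≈ 5 Å is
the constructed stabilised distance.

```r
leafletStats(makeBilayer(bilayerSpec(576L, 288L, seed = 1L)))
#> LeafletStats: 576 upper / 288 lower lipids, area 37440.0 A^2
#>   APL upper 65.00, lower 130.00 A^2/lipid
#>   number mismatch 50.00%, SAPL mismatch 50.00%

zoneDirectory(assignDomains(buildDimer(abeta42Sequence()), 17L))
#> ZoneDirectory (10 zones over N_A, C_A, N_B, C_B):
#>  zone domainA domainB
#>     1     N_A     N_A
#>     ...
#>    10     C_A     C_B
```

A 2:1 leaflet imbalance gives a 50% mismatch on both metrics (the two
coincide whenever leaflets share one box area), and the dimer's domain
partition yields the 10 contact zones used to summarise its maps.

## Command line

A thin launcher over the same functions ships in `inst/scripts/memsurf`
(subcommands: fixture, kinetics, attach, orient, ss, ss-reduce, contacts,
zones, annular, asym; TSV/JSON outputs plus a JSON run-manifest with the
configuration and input checksums next to every output):

```sh
memsurf fixture --type binding --seed 7 --out binding.pdb
memsurf kinetics --traj binding.pdb --contact-leaflet upper --out d.tsv
memsurf attach --series d.tsv --out attach.json
```

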