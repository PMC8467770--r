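# loopkin

Binding kinetics of flexible protein loops from molecular dynamics
trajectories.

Some receptor ectodomains carry a short, intrinsically flexible loop that
detaches and rebinds reversibly at more than one intramolecular site —
the thyroglobulin (TY) loop of EpCAM, which competes between a site on
its own domain and a second site on the C-terminal domain, is the
motivating case. On multi-microsecond MD trajectories these events repeat
often enough to estimate rate constants by **direct counting**. `loopkin`
implements that analysis for the two-competing-site case:

* **Contact statistics** — per-residue contact ratios of the loop's
  heavy-atom geometric center (cutoffs 6.5 / 8.0 / 12.0 Å) and
  residue–residue contact maps (any heavy-atom pair within 4.5 Å),
  optionally conditioned on a bound state.
* **Three-state classification** — each frame is OPEN, SITE_A-bound or
  SITE_B-bound; a site is bound when ≥ 3 loop residues are in 4.5 Å
  contact with it.
* **Dwell-time extraction** — maximal constant-state runs per replica,
  with boundary censoring flagged; independent trajectories are never
  joined.
* **Rate constants** — for each site,

  $$k_\mathrm{off} = \frac{1}{\text{mean survival time}},\qquad
    k_\mathrm{on} = \frac{N_\mathrm{Av}\,v_\mathrm{eff}}{t_\mathrm{on}}
    \;\;[\mathrm{M^{-1}s^{-1}}]$$

  with $t_\mathrm{on}$ the mean unbound waiting time behind the site's
  association events and $v_\mathrm{eff}$ the effective volume (box
  minus vdW-voxelised protein volume). Percentile-bootstrap 95% CIs over
  events.
* **Ground-truth validation** — a seeded three-state continuous-time
  Markov chain simulator plus a coordinate-level toy system (PDB + DCD)
  whose loop tracks the chain, so the whole pipeline can be checked
  against known rates.

Input formats: PDB topology, DCD trajectories (via `bio3d`), YAML region
configs (`inst/extdata/human_epcam_regions.yaml` shows the reference
regions: loop 78–98, site A 109–115, site B 219–225).

## Worked example

Generate a study-scale synthetic system (5 × 500 ns at 200 ps, i.e.
12,500 frames) with known rates, then run the estimator on coordinates
alone:

```r
library(loopkin)
spec <- paper_scale_preset(seed = 7)          # truth: k_off 1.6e8 / 2.5e8 s^-1
syn  <- synthesize_ensemble(spec)
reg  <- resolve_regions(syn$ensemble, syn$regions$loop,
                        syn$regions$siteA, syn$regions$siteB)
fit  <- loop_kinetics(syn$ensemble, regions = reg,
                      config = analysis_config(bootstrap_replicates = 2000,
                                               seed = 7))
fit
#> Loop binding kinetics (direct counting)
#>
#>   kind   site     value   units n_events    ci_low   ci_high ci_level
#>  k_off SITE_A 1.542e+08     1/s      168 1.326e+08 1.803e+08     0.95
#>   k_on SITE_A 3.665e+10 1/(M s)      168 3.097e+10 4.375e+10     0.95
#>  k_off SITE_B 2.195e+08     1/s      160 1.928e+08 2.498e+08     0.95
#>   k_on SITE_B 2.920e+10 1/(M s)      160 2.435e+10 3.598e+10     0.95
```

Reading this: the loop bound site A 168 times; the mean bound dwell of
6.5 ns gives `k_off = 1.54e8 s^-1`, and the generative truth (1.6e8) sits
inside the bootstrap CI. Site B unbinds ~1.4× faster, as simulated. The
`k_on` values are scaled by the effective concentration of the single
tethered partner (here `C_eff ≈ 3.2 mM` from the 5.1e-22 L effective
volume), so `k_on * C_eff` recovers the observed pseudo-first-order
association rate. `summary(fit)` adds dwell-time tables; `coef`,
`confint`, `residuals`, `plot` and `simulate` (parametric refit of the
fitted chain) behave as for any fitted model.

File-based workflows use `run_full_pipeline()` or the CLI:

```sh
Rscript inst/scripts/loopkin.R simulate --seed 7 --out-prefix toy
Rscript inst/scripts/loopkin.R run --topology toy.pdb \
    --traj toy_rep1.dcd,toy_rep2.dcd,toy_rep3.dcd,toy_rep4.dcd,toy_rep5.dcd \
    --config toy_config.yaml --box-volume 512000 --out-dir out
```

which writes contact profiles, contact maps, the state sequence, the
dwell table, `kinetics.tsv`/`.json` and a run manifest.

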