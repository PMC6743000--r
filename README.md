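# isofodder

Quantifying seasonal millet foddering of ancient livestock from stable
isotopes and mitochondrial DNA.

Sequentially sampled tooth enamel records a herbivore's diet season by
season: δ13C_apa tracks the proportion of C4 plants (millet, ~−12‰)
versus C3 steppe vegetation (dietary −26 to −22‰), while δ18O_apa cycles
with the seasons. `isofodder` aligns each intra-tooth sequence to the
calendar by fitting a 365-day cosine

    δ18O(x) = M + A·cos(2π(x − x0)/X)

to the δ18O series (day 0 = January 15th, δ18O maximum anchored to
mid-July), converts tissue δ13C to dietary δ13C with diet–tissue spacing
factors (enamel +14.1‰, collagen +5.0‰, hair +3.2‰), and estimates the C4
dietary fraction *p* per two-month interval with a Bayesian two-source
mixing model:

    x_i ~ Normal( p·μ_C4 + (1−p)·μ_C3 ,  p²σ²_C4 + (1−p)²σ²_C3 + σ²_res )
    p ~ U(0,1),   σ_res ~ U(0,5)‰

estimated by random-walk Metropolis (3 chains, split-R̂ and ESS
diagnostics) and cross-checked against a deterministic 401×401 quadrature
engine. The package also quality-screens bone-collagen δ13C/δ15N data
(atomic C:N in [2.9, 3.6], %C/%N ranges), computes the comparative
statistics used in palaeodiet work (Pearson, Mann–Whitney U, group
contrasts, lifetime C4 fractions), and assigns taxa to 110-bp MT-CYB
amplicons by primer trimming and Hamming distance against a labelled
haplotype panel. A forward simulator generates every input with known
ground truth, so the whole pipeline is testable end to end.

It is written for zooarchaeologists and isotope ecologists who want the
inference chain from raw band measurements to credible intervals to be
explicit, configurable and auditable.

## Worked example

Simulate a six-tooth herd winter-foddered at a C4 fraction of 0.5
(mid-November to mid-March), then recover the seasonal diet:

```r
library(isofodder)

set.seed(42)
teeth <- lapply(1:6, function(i) {
  g <- growth_model(crown_length = 36, growth_rate = 0.08 * runif(1, 0.9, 1.1))
  simulate_tooth_series(schedule = fodder_schedule(pulse = 0.5), growth = g,
                        start_day = 90 + round(rnorm(1, 0, 10)),
                        tooth_id = paste0("T", i), seed = 4200 + i)$series
})
enamel <- do.call(rbind, teeth)

obs <- enamel_bimonthly_observations(enamel)   # cosine fit + Julian days + bins
mix <- run_mixing_by_group(obs, default_sources(), engine = "mcmc", seed = 42)
mix[, c("bimonth", "n", "p_mean", "p_lo90", "p_hi90")]
```

Output (posterior C4 dietary fraction per two-month interval):

```
  bimonth n p_mean p_lo90 p_hi90
  Jan-Feb 6  0.463  0.415  0.507
  Jul-Aug 6  0.038  0.003  0.091
  Mar-Apr 6  0.149  0.077  0.213
  May-Jun 6  0.038  0.003  0.091
  Nov-Dec 6  0.346  0.290  0.398
  Sep-Oct 6  0.062  0.009  0.124
```

The winter interval (Jan–Feb) recovers the foddering pulse — its 90%
interval contains the true 0.5 — while summer intervals collapse toward
zero, the C3 grazing baseline. Nov–Dec reads lower (~0.35) than the true
pulse because enamel maturation averages diet over ~90 days: intra-tooth
estimates genuinely understate short pulses, which is why the winter
signal is read from the peak bin.

The same machinery answers single-value questions, e.g. the lifetime C4
intake implied by a collagen δ13C of −16‰:

```r
lifetime_c4_fraction(-16, engine = "grid")
#> C4 dietary fraction [lifetime]: mean 0.301, median 0.272,
#>   90% CI [0.049, 0.662] (n = 1, grid engine)
```

and `sensitivity_scan(-6)` documents how a winter enamel value of −6‰
maps to 24–50% dietary C4 across plausible spacing/source choices.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on simulated data
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # all inputs + ground truth
Rscript analysis/02_seasonality.R  # cosine fits, Julian days, bimonthly bins
Rscript analysis/03_mixing.R       # bimonthly C4 fractions + sensitivity scan
Rscript analysis/04_collagen.R     # QC, d15N contrast, Pearson/Mann-Whitney
Rscript analysis/05_mtdna.R        # primer trimming + taxon assignment
Rscript analysis/06_report.R       # consolidated pipeline report
```

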