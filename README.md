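# ecoevoclim

Spatially explicit eco-evolutionary simulation of ecological communities
responding to climate change.

Theoretical ecologists studying range shifts, community reorganisation and
extinction under warming need models in which ecology (competition,
trophic interactions, dispersal) and evolution (adaptation of thermal
physiology) play out together. `ecoevoclim` implements such a model for
communities of resource and consumer species on a chain of `L` habitat
patches from pole to equator, warmed by a polar-amplified, smoothly ramped
temperature increase.

## The model

Each species `i` in patch `k` has two state variables: density `N_i^k` and
mean temperature optimum `μ_i^k`. Phenotypes are normally distributed with
fixed variance (infinitesimal model), so trait dynamics reduce to the mean:

    dN_i^k/dt = N_i^k ∫ r_i^k(z) p_i^k(z) dz + Σ_l m_i^kl N_i^l − Σ_l m_i^lk N_i^k
    dμ_i^k/dt = h_i² ∫ (z − μ_i^k) r_i^k(z) p_i^k(z) dz
                + h_i² Σ_l m_i^kl (N_i^l/N_i^k)(μ_i^l − μ_i^k)

with per-capita growth

    r_i^k(z) = r_0(z) − Σ_j N_j^k ∫ a_ij(z,z′) p_j^k(z′) dz′
               + Σ_j ε_i F_ij^k − Σ_j N_j^k F_ji^k / N_i^k

where `r_0` is a Gaussian thermal performance curve with a width–height
tradeoff, competition among resources is either constant or declines with
trait distance via the kernel `exp(−(z−z′)²/η²)`, and feeding follows a
Holling type II response on a bipartite web (five prey per consumer).
All phenotype integrals are evaluated in closed form and validated against
an adaptive quadrature oracle in the tests. The factorial experiment of
the model — dispersal high/low × genetic variance high/low × one/two
trophic levels × constant/temperature-dependent competition, 16 scenarios —
is built in, along with the diversity and trait metrics used to summarise
it (local/regional/global richness, range breadth, Bray–Curtis turnover,
community-weighted trait lag and dispersion).

See the methods vignette (`vignettes/eco-evolutionary-model.Rmd`) for the
full account, including parameter defaults and numerical choices.

## A worked example

```r
library(ecoevoclim)

scen <- scenario(dispersal = "high", variance = "high",
                 trophic = "one", competition = "temperature_dependent")
cfg  <- draw_replicate(scen, seed = 1)
traj <- run_replicate(cfg)
traj
#> <ee_trajectory> 66 snapshots over t = -4000..2500; 50 species x 50 patches; 34 global extinction(s)

summarise_realisation(traj)
#> # A tibble: 1 × 7
#>     lag dispersion polar_turnover richness_t0 richness_tE richness_end global_extinctions
#>   <dbl>      <dbl>          <dbl>       <int>       <int>        <int>              <int>
#> 1 0.617       2.98          0.537          18          16           15                 34
```

The run (about six seconds) integrates 50 species on 50 patches from 4000
years before the onset of warming to 2200 years after its end. Under
temperature-dependent competition, similar temperature optima mean strong
competition, so the establishment phase prunes the 50 founders to 18
niche-differentiated survivors (32 of the 34 logged global extinctions
happen before warming starts); warming then thins the community from 18
to 15 species above the presence threshold by `t = 2500`, with two
outright global extinctions — one of them after the climate has already
restabilised, an extinction debt. The surviving community's temperature
optima trail the
warming by 0.62 °C on average over the warming window (`lag`), its
within-patch variation in temperature optima averages 3.0 °C²
(`dispersion`), and the polar third of the landscape ends the simulation
53.7% dissimilar (Bray–Curtis) from its pre-warming composition
(`polar_turnover`).

Plot helpers (`autoplot()` on a trajectory, `plot_richness()`,
`plot_lag_dispersion()`) visualise range shifts, richness trends, and the
lag–dispersion relationship; `fit_lag_dispersion()` with `tidy()` /
`glance()` quantifies the latter.

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ecoevoclim.R", package = "ecoevoclim"))') \
  run --out runs/ --dispersal high --variance low --trophic two --competition constant --seed 7
```

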