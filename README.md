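# plimox

Time-resolved luminescence oximetry in R: decay fitting, Stern–Volmer
oxygen calibration, distribution indicators, and Ward.D2 dendrogram
analysis of lifetime statistics.

## The problem

Long-lived luminescent probes such as dichlorotris(1,10-phenanthroline)-
ruthenium(II) ([Ru(Phen)₃]²⁺) report local oxygenation because molecular
oxygen quenches their emission: the lower the oxygen, the longer the
phosphorescence lifetime. Time-resolved detection — either single-point
gated acquisition in vivo (e.g. on the chicken embryo chorioallantoic
membrane, CAM, inside and outside blood vessels) or per-pixel
phosphorescence lifetime imaging (PLIM) of cell cultures — yields photon-
counting decay traces whose fitted lifetimes must be converted to %O₂,
summarised per experimental condition, and compared across conditions.
Because the lifetime distributions are non-Gaussian, single mean values
are a poor basis for comparison; this package implements the
dendrogram-based workflow that clusters whole distribution summaries
instead.

## The model

Decays are time-binned photon counts fitted by least squares as

- mono-exponential: `I(t) = A·exp(−t/τ) + B`, or
- bi-exponential with a fixed long-lived second component
  (`τ₂ = 20,000 ns` by convention for PLIM maps).

Fitted lifetimes convert to oxygenation through the Stern–Volmer
calibration (τ in seconds)

```
%O₂ in N₂ = (1/τ − a) / b ,   a = 919,155.47 s⁻¹ ,  b = 45,157.84 s⁻¹/%
```

Each condition's lifetime sample is reduced to the six-number summary
`(min, Q1, mean, median, Q3, max)` and to two bespoke indicators:

```
rel_Md = 2 (Median τ − Mean τ) / (Median τ + Mean τ)      # asymmetry
rel_OI = 2 (Mean_out τ − Mean_in τ) / (Mean_out τ + Mean_in τ)  # out-vs-in contrast
```

Conditions are compared by the Minkowski (p = 1) distance between their
six-number vectors and agglomerated with Ward.D2 linkage (Lance–Williams
recurrence on squared distances, heights on the square-root scale, in
ns); cophenetic distances and Newick export support downstream
dendrogram analysis. A synthetic-data module generates per-condition
lifetime samples (shifted-gamma, matching target means and rel_Md) and
two-population lifetime scenes so the entire pipeline is testable
without instrument data.

## Worked example

```r
library(plimox)

# convert measured mean lifetimes to oxygenation
tau_to_oxygen(c(710.8, 650, 800))
#>   tau_ns percent_o2 below_calibration
#> 1  710.8  10.800119             FALSE
#> 2  650.0  13.714254             FALSE
#> 3  800.0   7.326403             FALSE

# generate the 18-condition synthetic CAM study and summarise it
ds  <- generate_dataset(table1_specs(), seed = 1)
tab <- condition_table(ds)
head(tab, 4)
#>   regime time_post_admin location   n mean_tau median_tau rel_md rel_oi
#> 1      0               5       in 500    710.7      732.0  0.030     NA
#> 2      0               5      out 500    730.9      735.4  0.006  0.028
#> 3      0              10       in 500    741.6      750.1  0.011     NA
#> 4      0              10      out 500    766.7      788.4  0.028  0.033
#>   percent_o2_printed
#> 1              10.80
#> 2               9.94
#> 3               9.50
#> 4               8.52
```

The first row reads: intravascular lifetimes 5 min after administration
under the 0 % O₂ regime average 710.7 ns, i.e. 10.80 % O₂ in N₂; the
positive `rel_md` flags a left-skewed distribution, and the `out` row's
`rel_oi = 0.028` quantifies the extravascular-vs-intravascular lifetime
contrast.

```r
# cluster the pooled per-regime summaries and inspect the tree
rv <- condition_summary_vectors(ds, by = "regime")
rd <- ward_d2_linkage(minkowski_distance_matrix(rv, p = 1))
cat(export_newick(rd))
#> (0%:384.463584012,(20%:96.7391966052,10%:96.7391966052):287.724387407);
round(cophenetic_matrix(rd))
#>      0% 10% 20%
#> 0%    0 769 769
#> 10% 769   0 193
#> 20% 769 193   0
```

The 10 % and 20 % regimes join first (cophenetic distance 193 ns) while
the 0 % regime is the outlier branch (769 ns) — hypoxia moves the whole
lifetime distribution, not just its mean. `run_pipeline(run_config(...))`
orchestrates the same stages end to end and writes a reproducible
artifact bundle (condition table, distance matrix, Newick/JSON
dendrograms, logs); `inst/scripts/plimox-run.R` is a thin command-line
wrapper around it.

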