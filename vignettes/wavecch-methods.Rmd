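---
title: "Methods: wavelet analysis of spike-train cross-correlograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet analysis of spike-train cross-correlograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multielectrode arrays record spiking from hundreds of neurons at
sub-millisecond resolution. Pairwise cross-correlation histograms (CCHs) of
such recordings carry structure at very different time scales at once: sharp,
offset peaks a few milliseconds wide that are the classical signature of
synaptic coupling, and broader zero-centred oscillations at gamma, beta and
theta frequencies that reflect shared rhythmic drive. `wavecch` separates
these regimes by wavelet-transforming each CCH, testing the resulting
time-frequency power plane against a Monte-Carlo noise model, and assembling
band-specific binary networks whose graph-theoretic structure can then be
compared under controlled subsampling.

## Cross-correlation histograms

For neurons $I$ and $J$ the CCH is the count correlogram
$C_{IJ}(\tau) = \sum_t i(t)\, j(t+\tau)$, where $i(t)$, $j(t)$ are binary
spike indicators on a time grid of width $\delta t$ (50 µs at analysis scale
1, 500 µs at scale 2). Because the indicators are binary, two spikes of one
neuron falling into the same bin count once (`compute_cch(..., clip = TRUE)`);
at 50 µs this is immaterial for realistic firing rates. Bin centres sit at
integer multiples of $\delta t$ with half-open bins, the zero-lag bin in the
middle, and 2801 centres spanning ±70 ms (scale 1) or ±700 ms (scale 2).
Counts are left unnormalized: the significance test below is calibrated on
correlograms with the same total count, which makes every popular
normalization equivalent.

The lag sign convention is fixed package-wide: positive $\tau$ means $J$
fires after $I$.

When two units sit closer than 180 µm (three inter-electrode distances),
spike-sorting cross-talk can carve a spurious trough, or an ultra-sharp peak,
into the CCH near zero lag. `interpolate_artifact()` replaces the ±1 ms
segment of such pairs with the straight line joining the flank averages over
[−1.5, −1.0] ms and [+1.0, +1.5] ms. The anchor points are placed at the
flank-window centres (±1.25 ms) — the unbiased choice given that only the
flank averages are specified.

## Continuous Morlet wavelet transform

The mother wavelet is the complex Morlet
$\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}$ with
$\omega_0 = 4$. Frequencies map to scales through the Morlet Fourier-period
relation $T = 1/f$ and $s = T\,(\omega_0 + \sqrt{2+\omega_0^2})/(4\pi)$.
Each configuration analyses 101 frequencies spaced evenly in log frequency
(20–1000 Hz at scale 1, 2–100 Hz at scale 2).

Before transforming, both ends of the correlogram are padded with the average
of its 100 edge bins so that the total length is a power of two
(2801 → 4096); the pad is split as evenly as possible (647 left, 648 right).
The transform itself is evaluated in the frequency domain on that padded
grid — the padded series is multiplied, per scale, by the real-valued
Fourier transform of the normalized Morlet
($\sqrt{2\pi s/\delta t}\,\pi^{-1/4} e^{-(s\omega-\omega_0)^2/2}$, sampled on
the signed DFT frequencies) and inverse-transformed. This is the standard
FFT formulation of the continuous wavelet transform with the
$\sqrt{\delta t/s}$ time-domain normalization, and it equals the explicit
convolution with the sampled wavelet to near machine precision: the test
suite checks FFT against a termwise direct-summation oracle at $10^{-6}$
relative tolerance. Only the inner 2801-bin window is kept, so the pad (and
any periodic wrap-around, which is confined to the pad's neighbourhood by
the Gaussian decay of the wavelet) never enters peak detection. Two
numerical details are worth recording: filter values below $10^{-14}$ of the
filter peak are flushed to zero, because the Gaussian tails otherwise
produce subnormal floating-point numbers that slow the FFT loop by an order
of magnitude without affecting any result at the tested tolerance; and the
worked example of a zero-centred Gaussian correlogram with $\sigma = 1$ ms
anchors the frequency–scale convention — its power plane peaks at lag 0 and
≈116 Hz, i.e. the best-matching Fourier period is $T \approx 8.6\sigma$.

## Monte-Carlo significance

The null model is Poisson white noise: a correlogram with the same total
spike count but all structure destroyed, generated by placing each of $n$
spikes uniformly at random over the 2801 bins of the transformed window
(collisions allowed, so each bin is Poisson). For each count on the grid
$10^k$, $k = 0.0, 0.1, \ldots, 6.0$, `calibrate_thresholds()` transforms
`n_reps` such nulls and records, at every frequency, the maximum power over
the *peak-identification* window (±20 ms / ±200 ms). The threshold at level
$p$ is the $(p \cdot n_{\text{reps}})$-th highest of those maxima — at full
fidelity the 100th highest of $10^5$ for $p = 0.001$. Two choices the
procedure leaves open are resolved as follows:

* **Null maxima are taken over the peak window**, not the full transformed
  window, so that the null statistic coincides with the region where peaks
  are accepted and $p$ retains its nominal meaning. A held-out validation
  (fresh null ensemble against an independently calibrated table) confirms
  the empirical exceedance matches $p$ within binomial error.
* **Interpolation between grid counts is linear in $k = \log_{10} n$**,
  matching the geometry of the grid. Lookups never extrapolate.

Raw order statistics are made non-decreasing along the count axis by a
running maximum before storage. The true threshold grows monotonically with
spike count, so this guards the table's monotonicity invariant against
Monte-Carlo noise without biasing any well-sampled entry. Per-grid-count
child seeds are derived from the master seed, so the table is reproducible
and independent of the order in which grid counts are processed.

## Peaks, bands, direction

Significant peaks are strict local maxima over their 8 neighbours in the
discrete power plane, restricted to the peak-identification window, with
power above the threshold for the correlogram's count at that frequency. A
correlogram may carry several peaks; peaks in different bands are different
connections, while multiple peaks of one pair within one band connect the
pair once, keeping the most significant peak's attributes (edges are binary
per pair per band).

Bands follow the standard electrophysiological ranges: HFC 100–1000 Hz
(scale 1), GFC 30–80 Hz, BFC 12–30 Hz, TFC 4–12 Hz (scale 2). Intervals are
treated half-open $[lo, hi)$, with the HFC top closed at 1000 Hz, so border
frequencies are assigned uniquely; frequencies in covered-but-unbanded gaps
(e.g. 80–100 Hz at scale 2) are discarded.

A peak whose lag offset exceeds one quarter of the Fourier period of its
frequency (strictly) is classified as delayed, i.e. a directed connection —
at that shift the primary peak of the wavelet's real part no longer overlaps
zero lag. For a pure Gaussian CCH peak this boundary sits at
$T/(4\sigma) \approx 2.15\sigma \approx 2.2\sigma$, tying the direction rule
to the worked example above. Non-delayed peaks are treated as bidirectional.

## Networks and graph measures

Within a band, connections are ordered by significance (peak power divided
by threshold power, descending; ties broken lexicographically by pair id)
and retained until the target connectivity density — the fraction of
connected unordered pairs — is reached. Networks whose supply runs out first
are kept at their smaller achieved density, and
`match_density_across_bands()` re-truncates all bands of a data set to the
sparsest band's density so measures are compared at equal density. Edges are
binary thereafter; direction is an attribute, not a second edge.

Graph measures use the undirected pair projection (a pair is connected
regardless of direction), since density is pair-based; out-degree is the
one directed quantity reported, with non-delayed edges counting toward both
end nodes. Conventions:

* **Clustering**: local coefficient = realized links among a node's
  neighbours over possible links, averaged over nodes with ≥2 neighbours.
  With no such node the measure is undefined and flagged `NA`. (For an empty
  graph this convention makes clustering undefined rather than zero — the
  $k \ge 2$ rule takes precedence.)
* **Efficiency**: mean inverse shortest path length (hops) over ordered
  pairs, with unreachable pairs contributing 0 — finite on disconnected
  graphs, unlike mean path length.
* **Assortativity**: Newman's edge-list Pearson correlation of end degrees;
  undefined for fewer than two edges or zero degree variance.
* Undefined values propagate to aggregation by exclusion, with the excluded
  count reported.

All measures are validated against independent brute-force oracles
(Floyd–Warshall, explicit triple counting, the doubled-edge-list Pearson
correlation) on every graph of up to 5 nodes plus sampled 6-node graphs, and
against igraph where the conventions coincide.

To compare tissues with different population sizes on an equal footing,
`subsample_metrics()` repeatedly draws 100 neurons without replacement
(100 repeats by default), rebuilds the edge set inside each sample,
truncates to each density in the 0.5–2 % range (grid
{0.5, 1.0, 1.5, 2.0} % — the range endpoints are prescribed, the step is
this package's choice) and reports mean and root-mean-square spread per
measure. Degree distributions are pooled at the 1 % reference density.

Model degree laws for comparison are fully determined by the size $n = 100$
and density $p$: binomial $B(n-1, p)$ for random graphs; a discretized
exponential $P(k) \propto e^{-k/\bar{k}}$ on $k = 0..n-1$ with $\bar{k}$
fixed by matching the mean degree $(n-1)p$ (the mean-matching convention
resolves the otherwise underdetermined parameterization); and, because
subsampling destroys power-law tails, the scale-free reference is the
*empirical* degree law of 100-node uniform subsamples of 1000-node
Barabási–Albert graphs matched to density $p$. The per-node attachment
count $m = p(N_\text{parent}-1)/2$ is generally fractional and is realized
by Bernoulli mixing of $\lfloor m \rfloor$ and $\lceil m \rceil$. The
subsampled law is insensitive to the parent size (500 vs 1000), which the
suite verifies at reduced replicates. Model-observation distances use the
reduced chi-square over bins with defined SEM.

`fit_decay()` bins unordered pairs by inter-neuron distance (50 µm bins),
averages per-bin connection probabilities over networks (mean and SEM), and
fits $P(d) = A e^{-d/\lambda} + C$ by Levenberg–Marquardt least squares with
non-negativity bounds; confidence intervals are Wald intervals from the fit
covariance. Distance-independent wiring leaves $\lambda$ unidentified, which
surfaces as a very wide interval or a non-convergence flag rather than a
silent number.

## The synthetic generator

No public recordings accompany the method, so the package ships a generator
that produces populations with exactly the statistical structure the
pipeline detects, plus exhaustive ground truth:

* **Rates** are drawn log-normally, $10^{-0.16 \pm 0.64}$ Hz by default —
  the cortical firing-rate statistics of organotypic slice cultures; trains
  are (in)homogeneous Poisson processes.
* **Geometry** is a hexagonal 60 µm lattice spanning 0.9 × 1.9 mm with
  < 30 µm uniform scatter, so distance bins are populated distinctly.
* **Synaptic couplings** (`inject_synaptic()`) add, per source spike with
  probability `efficacy`, a target spike at `delay_ms` plus Gaussian jitter,
  producing the offset high-frequency CCH peak.
* **Common drive** (`inject_common_drive()`) regenerates member trains as
  inhomogeneous Poisson processes sharing a sinusoidal rate modulation with
  a random common phase — a phenomenological stand-in for rhythmic field
  coupling that produces zero-centred oscillatory CCHs at the set frequency.
  An explicit field simulation is deliberately avoided: the analysis treats
  oscillatory correlograms phenomenologically, and nothing downstream
  depends on their biophysical origin.
* **Network bursts** can be emulated as population-wide rate-multiplier
  epochs, but default off; no operation requires burst statistics, and no
  quantitative description of them constrains the generator.

All generators are seed-deterministic, and no pairwise dependence exists
beyond the recorded ground truth. What passing recovery tests therefore
show is that the pipeline detects the *mechanisms it models* — delayed
point-process couplings and shared sinusoidal modulation — under realistic
rates and geometry. They do not show robustness to everything real tissue
adds: strong non-stationary bursting, inhibitory suppression (troughs are
observed in real data but not used for network construction), overlapping
mechanisms on one pair, or spike-sorting errors beyond the near-electrode
artifact that the interpolation rule addresses.

## Validation problem sizes

The shipped tests and the acceptance script favour problem sizes that keep
a complete run in minutes on one core while preserving each statistical
guarantee: threshold calibration at $10^4$ replicates with the 10th-highest
order statistic (the same $p = 0.001$ as the full-fidelity 100th of $10^5$),
held-out validation on an independent $10^4$ ensemble, coupling recovery on
a 60-neuron hour-long population with 20 known synapses (precision ≥ 80 %
at matched edge count, and ≥ 90 % of high-frequency detections destroyed by
50 ms jitter at unchanged thresholds), and decay fits pooled over ten
300-node networks. The full-fidelity settings ($10^5$ replicates, the
complete $k = 0.0..6.0$ count grid, 100 × 100 subsampling) remain available
through the ordinary function arguments.

## Known limitations

* Detection is peak-based: long-lasting inhibition (CCH troughs) is not a
  connection class.
* The direction rule is a binary quarter-period criterion; no latency or
  strength estimation beyond the stored peak attributes is attempted.
* Thresholds assume the transformed window dominates the correlogram's
  count statistics; extremely sparse correlograms (n below the calibrated
  grid) are rejected rather than extrapolated.
* Graph measures are computed on the undirected projection except for
  out-degree; directed variants of clustering/efficiency/assortativity are
  not implemented.
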