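---
title: "Preparing coordinate-based meta-analysis datasets with cbmaprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing coordinate-based meta-analysis datasets with cbmaprep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmaprep)
```

## The problem

Coordinate-based meta-analysis (CBMA) synthesizes neuroimaging findings
from the peak coordinates ("foci") that studies report, rather than from
their full statistical maps. Before any consensus estimate — typically an
activation likelihood estimation (ALE) map — can be computed, the dataset
has to be assembled, checked and filtered, and afterwards the result is
usually stress-tested by re-running the analysis on partitions of the
dataset (leave-one-experiment-out, split-half, subset analyses). These
preparation steps are mechanical but error-prone when done by hand;
`cbmaprep` automates them as small, composable, seeded operations around
the Sleuth-compatible foci text format used by the BrainMap ecosystem.

The unit of analysis throughout is the *experiment*: one contrast
contributing an author-year key, a subject count (`Subjects=`) and an
ordered list of (x, y, z) stereotactic coordinates in mm. A *dataset* is an
ordered list of experiments; order is preserved from the source file by
every operation.

## The file dialects

`parse_foci_text()` and `load_foci()` accept two dialects. The strict
dialect is the bare layout: `//` metadata lines, `author,yyyy:` first,
`Subjects=<n>` last, foci as three space-separated numbers with `.` as
decimal separator, a blank line between experiments, no header. The lenient
dialect (the default) additionally consumes a single leading
`// Reference=<space>` line — the header Sleuth exports — and tolerates
case and spacing variations of the `Subjects=` line, because real exports
vary. The parser never *requires* the header; `write_foci_file()` emits it
only on request. Output always uses `\n` endings and UTF-8, and coordinate
serialization uses the shortest decimal string that parses back to exactly
the same double, so a write/parse round trip is lossless.

Duplicate experiments (the same study exported twice) are removed at load
time. Two experiments are duplicates only when their whole metadata blocks
are identical after whitespace trimming — including the subject count — and
they report the same foci. Foci are compared as a multiset of exact
coordinate triples: listing order is irrelevant, but no numeric tolerance
is applied, so near-duplicates are never silently merged, and a coordinate
listed twice within one experiment is preserved and only matches another
experiment that also lists it twice.

## Independence, tissue and ROI filtering

`remove_multiple()` enforces the assumption that experiments draw on
independent samples: experiments sharing an author-year key (compared
case-insensitively; free text after the colon is ignored) are treated as
one paper, and a single member is retained — the largest sample with
`mode = 1` (ties broken at random), or a uniformly random member with
`mode = 2`. A trailing letter after the year (`AndersonT,2023a` vs
`AndersonT,2023b`) splits a paper into groups known to be independent.
All random selection runs through R's RNG in a local scope: a supplied
`seed` makes the selection exactly reproducible, an omitted seed is drawn
fresh and reported so the run can be replayed, and the caller's global RNG
state is never disturbed. Bit-compatibility with other tools' generators is
deliberately not promised — reproducibility is defined within this package.

`filter_by_tissue()` keeps, within each experiment, only foci inside a
binary mask (typically a gray- or white-matter template), dropping
experiments left without foci; `prepare_macm()` instead keeps an
experiment's *complete* focus list whenever at least one focus hits a
region of interest, because meta-analytic connectivity modeling interprets
all peaks co-reported with an ROI hit as coactivation. The distinction —
focus-level versus experiment-level selection — is the tested invariant
separating the two.

Masks are NIfTI volumes read with `read_mask()`. Non-binary input is
binarized with a strict `value > 0` rule. The affine is taken from the file
header rather than assuming a fixed bounding box; the expected Talairach
2 x 2 x 2 mm grid is enforced only as a warning so user-defined masks on
other grids still work. A focus belongs to the voxel nearest to it: the
inverse affine is applied and each continuous index is rounded to the
nearest integer, ties rounded *half away from zero*. This rule is
arbitrary on exact midplane coordinates but deterministic and covered by a
dedicated tie test; agreement with other implementations on boundary foci
is not guaranteed, which on a 2 mm grid affects only foci placed exactly
1 mm off a voxel center. No interpolation is used. Conversion between MNI
and Talairach space is out of scope; inputs are assumed to already share
the mask's space (foci files carry no reliable space tag, so this cannot
be checked mechanically — the command-line interface prints a reminder).

## Resampling for post hoc validation

`create_loeo()` implements the jackknife: n subsamples each omitting one
experiment (`add = FALSE`), or the incremental variant (`add = TRUE`) where
iteration k omits the first k experiments in file order. The incremental
scheme stops after n − 1 iterations: the n-th would produce an empty file,
which is suppressed — so `p = n - 1` and the last subsample contains a
single experiment.

`create_subsets()` covers split-half and bootstrap-style designs. With
`rep = TRUE` each of `ns` subsamples is an independent uniform draw of
`nexp` *distinct* experiments; overlap is allowed across subsamples only.
With `rep = FALSE` a random permutation of the experiments is cut into
`ns` disjoint subsamples of equal size; when `ns * nexp` does not match n
the size is adjusted to `floor(n / ns)`, and a remainder subsample holds
whatever is left, so `p` is `ns` or `ns + 1`. Partitioning the permuted
order (rather than file order) was chosen because the design is explicitly
a random selection process. Within each subsample, experiments are written
in their original file order. `write_subsamples()` emits `LOEO_<k>.txt` or
`sub_sample_<k>.txt` plus a plain-text manifest (scheme, seed, per-file
source keys), so any run is auditable and, given its seed, byte-identical
on repetition.

## Diagnostics

`dataset_stats()` reports the mean sample size and the median publication
year (extracted from the key; the independence letter is ignored). The
median uses midpoint interpolation for an even number of experiments — the
standard convention, documented here because year data make the case
visible. `dataset_hist()` renders the sample-size distribution three ways
— automatic binning on top (Freedman–Diaconis, falling back to Sturges
when the interquartile range degenerates), exactly `sbins` bins in the
middle (`sbins = 0` for automatic), and one bin per distinct sample-size
value at the bottom — bracketing coarse and maximally detailed views, each
with a red line at the mean. The year histogram uses one bin per calendar
year (not user-configurable) with a red line at the median. Bin *counts*
are the tested surface; visual parity with any other tool's automatic
binning is a non-goal. Images are JPEG by default to honor the
conventional `sample_size.jpg` / `year_of_publication.jpg` names, with
`format = "png"` for lossless output.

## The ALE extension and the robustness index

`ma_map()` builds one modeled-activation (MA) map per experiment: each
focus contributes an isotropic 3-D Gaussian whose full width at half
maximum (FWHM) depends on the experiment's sample size, truncated at
3 x FWHM to bound compute. The kernel is *pluggable* via `kernel_spec()`
because the mapping from subject count to spatial uncertainty is a
modeling choice with several published variants; the packaged default,
`FWHM(n) = sqrt(5.7^2 + 11.6^2 / n)` mm, is a smooth, strictly decreasing
stand-in on a realistic scale (about 7 mm at n = 10, flattening toward
5.7 mm for large samples) and is not a replica of any specific ALE
implementation — supply your own `fwhm` function for exact parity with one.
Kernels are peak-normalized (value 1 at the focus) rather than
mass-normalized, and foci of the same experiment combine by the per-voxel
maximum rather than by summation: both choices keep MA values
interpretable as activation probabilities in [0, 1], matching the union
semantics of the next step. `ale_union()` combines MA maps as independent
probabilities, `1 - prod(1 - MA_i)`.

Statistical thresholding of ALE maps is intentionally out of scope — it is
a separate inference problem with its own established tools.
`robustness_index()` therefore consumes externally thresholded *binary*
significance maps, one per validation run, and counts per voxel in how
many runs the effect was significant. Higher counts mean stronger
replicability across subsamples; with no agreed gold standard for judging
post hoc validation results, the index is a descriptive summary, not a
test.

## Synthetic data and what it does (and does not) show

All tests run on data built in code. `generate_dataset()` emulates the
structure that matters to the preparation steps: author-year keys with
same-paper groups and exact duplicate pairs, subject counts in 5–160,
years in 1995–2020, 3–12 foci per experiment, and a controllable fraction
of foci placed *exactly at voxel centers* of a companion mask so that
in/out membership is unambiguous under any reasonable rounding rule
(`boundary_foci()` separately emits midplane coordinates to pin down the
tie rule). `synthetic_example_dataset()` is a deterministic stand-in for a
typical published example: 34 experiments from 30 papers (one paper with
three experiments, two with two), seven papers without gray-matter foci,
sample sizes averaging 25 with one 160-subject outlier, publication years
with median 2007, and five papers hitting a small ROI sphere — so the
canonical pipeline (load 34 → independence filter 30 → tissue filter 23 →
MACM 5) is reproducible by construction, whichever seed drives the random
within-paper selection.

What passing tests show: the file grammar, the filtering semantics, the
partition algebra and the map algebra are implemented exactly as
specified, verified against brute-force oracles (exhaustive nearest-voxel
search, per-voxel loops, closed-form Gaussians). What they do not show:
behavior on the messiness of real exports (inconsistent author spellings
across databases, MNI coordinates mislabeled as Talairach, masks on
non-standard grids) — the first two are out of scope by design, the last
is accepted with a warning. Synthetic foci are placed at voxel centers, so
the tests deliberately do not probe rounding of generic real-world
coordinates beyond the dedicated midplane cases.

## Numerical and sizing choices

Coordinates are compared exactly (no tolerance) in deduplication;
mask membership uses half-away-from-zero rounding; the MA kernel oracle is
checked to 1e-6, far above the truncation error at 3 x FWHM
(exp(-36 ln 2), about 1.5e-11 of peak height). Example and test volumes are 24^3 or smaller at 2 mm — large
enough to hold a 16 mm "gray matter" sphere and a separated ROI, small
enough that exhaustive per-voxel oracles stay instant; the property suite
runs 500 round-trip datasets and 25 full filter/partition rounds in a few
seconds. Degenerate inputs are defined, not accidental: single-experiment
datasets render histograms with the mean line on the single bar;
leave-one-out requires n >= 2; zero-focus experiments may exist in memory
(as transient filter output) but can never be written to disk.

## Known limitations

* No MNI/Talairach transformation, no BrainMap database access, no GUI.
* No statistical thresholding of ALE maps; the robustness index requires
  binary maps thresholded elsewhere.
* The default kernel is a documented stand-in; results depending on exact
  kernel shape require a user-supplied `fwhm`.
* Selection among same-paper experiments by diagnosis or task is not
  automated (those criteria are not mechanically standardizable); the
  trailing-letter escape exists for manually screened cases.
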