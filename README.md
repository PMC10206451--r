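# fishwolf

Tools for detecting and quantifying **pulsed fishing behaviour by grey
wolves** from GPS telemetry and camera traps. In boreal lake country,
wolves exploit the brief spring spawning run of white suckers by
ambushing fish at night in shallow creek reaches, often just below
beaver dams. The behaviour lasts days to a few weeks per wolf per year,
which makes it invisible to most diet methods; this package implements
the analysis chain that makes it measurable from standard field
instruments. It is written for movement ecologists and carnivore
researchers working with collar fixes, cluster ground searches and
camera records.

## What it computes

* **GPS clusters** (`detect_clusters`): a cluster is ≥ 2 *consecutive*
  fixes within *r* = 200 m of the first fix (the anchor), with a
  configurable bound on the time gap between consecutive members
  (default 3 × the nominal fix interval). Greedy left-to-right scan;
  disjoint clusters; verified against a by-definition reference
  enumeration.
* **Fishing-site classification** (`is_fishing_cluster`): a cluster is
  a fishing site iff the ground search found *fresh* fish remains ∧
  abundant wolf sign ∧ ¬ other-predator sign ∧ ¬ old remains.
* **Camera events** (`segment_events`): maximal runs of records at one
  camera with inter-record gaps ≤ 10 min; each event gets the
  highest-precedence behaviour present from a closed seven-code
  ethogram (on creek bank, wading, successful / failed / unknown
  fishing attempt, carrying fish, caching fish).
* **Fishing periods** (`infer_fishing_period`): per wolf-year,
  `[min date, max date]` of pooled evidence (clusters, cameras, camera
  collar, field observation), with inclusive length
  `(end − start) + 1` days.
* **Buffer occupancy** (`buffer_occupancy`, `phase_comparison`): hours
  per day within 20 m (actively hunting) and 500 m (hunting +
  handling) of a fishing water source, each in-buffer fix weighted by
  its fix interval, compared across equal-length *before / during /
  after* windows; hourly and seasonal histograms and a nocturnality
  share (20:00–06:00 local) via `activity_profiles`.
* **A seeded synthetic study system** (`sim_config`,
  `simulate_trajectory`, `simulate_camera_records`,
  `simulate_annotations`): a two-state movement model (home-centred
  correlated random walk + nocturnal dam-side fishing bouts) with
  camera triggering and cluster annotations, emitting the exact file
  formats the readers consume plus ground truth for validation.

## Worked example

The `analysis/` scripts run the whole workflow over a simulated season
(package functions do all the work; the scripts are thin drivers):

```sh
Rscript analysis/01_simulate.R          # writes results/dataset/
Rscript analysis/02_analyze.R           # clusters, events, periods, occupancy
Rscript analysis/03_validate.R          # recovery vs. ground truth
Rscript analysis/04_cohort_summaries.R  # desk arithmetic from the cohort table
Rscript analysis/05_figures.R           # histogram figures
```

Output of steps 2–4 for seed 1:

```
clusters: 1595 detected, 15 classified as fishing
camera: 1146 records, 62 events
fishing periods inferred: 2 (mean 12.0 d, max 20 d)
  500 m occupancy before: 0.10 h/day
  500 m occupancy during: 3.73 h/day
  500 m occupancy after : 0.12 h/day
night share of active-hunting (20 m) fixes: 1.00

period endpoint error (days): start +0, end +1
fishing-cluster precision 1.00, recall 1.00 (15 predicted / 15 expected)
camera event partition agreement: 1.000

period lengths (days): 31, 28, 7, 17, 10, 18, 23, 11, 9, 24, 8, 43
mean 19.1 d, sd 10.6 (population) / 11.1 (sample), max 43 d
10 collared wolves at 4 waterways; 34% of the 29 collared wolves
remote-camera events: 59; collared 37%; wading 34%; on-bank 53%
camera collar: 18 fishing-behaviour videos, 42% of hunting/eating footage
```

Reading: the simulated wolf's 15 fishing clusters recover its bout
schedule exactly at the start and to one day at the end (a camera
record after midnight correctly documents fishing on the next calendar
date); occupancy within 500 m of the creek is ~30× higher during the
fishing period than in the equal-length windows before and after; and
all in-buffer activity is nocturnal, as simulated. The cohort block
reproduces the recorded field seasons' arithmetic from the bundled
period table (`inst/extdata/gve_fishing_periods.csv`).

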