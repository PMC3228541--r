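---
title: "Planning and simulating elastic sequence-search pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and simulating elastic sequence-search pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastiseq)
```

`elastiseq` models the execution of a partitioned sequence-search workload
on an elastic cloud cluster. This vignette is the package's account of the
science inside it: the models, the tunable parameters and their defaults,
the numerical choices, what the synthetic data does and does not emulate,
and where the design was genuinely open.

## 1. The runtime model

### Representation: k-mer profiles

A workload is summarised as the multiset of its length-k words. For DNA the
reverse-complemented strand is counted as well, because a search engine
scans both strands: the profile of a sequence then equals the profile of
its reverse complement, and `kmer_profile()` is tested for exactly that
strand symmetry. Defaults are k = 11 for DNA and k = 3 for protein — the
word sizes at which seeded search tools anchor alignments, which is what
makes word-content a good runtime covariate.

Windows containing ambiguity codes (N for DNA, X for protein) are
*skipped*, not expanded: expansion would multiply one uncertain observation
into up to 4^k phantom words and make counts depend on an arbitrary
expansion convention. Sequences shorter than k contribute nothing.

### The overlap statistic and the linear law

The estimator compares the query profile with a pre-calculated reference
profile. How to compare is a genuine design choice; the package uses the
simplest statistic that is linear and monotone in the query:

$$x \;=\; \sum_w c_q(w)\, \omega_{\mathrm{ref}}(w),$$

the dot product of query counts with per-word reference weights, with the
weights defaulting to the reference profile's relative frequencies
(`reference_weights()`). Predicted CPU-hours are

$$T \;=\; \alpha + \beta x, \qquad \alpha \ge 0,$$

with `(α, β)` estimated by ordinary least squares from timed calibration
runs (`fit_runtime_model()`). The choice is deliberately swappable: a
`runtime_model` is an ordinary object holding `k`, weights and two
coefficients, and anything that produces the same surface (e.g. a coverage
statistic, or per-word costs learned from timings) can stand behind it.
Linearity buys two testable properties for free: doubling every query
count doubles the overlap term exactly, and predictions are monotone
non-decreasing in every count.

**Numerical choices.** A fitted intercept below zero means the calibration
data cannot distinguish a small fixed cost from none; since a negative
fixed cost is meaningless, α is clamped to 0 and β refit through the
origin. Calibration requires at least two runs with distinct x (the design
matrix is otherwise singular). The package's tests recover a known
(α = 0.5, β = 2.0) law exactly from noiseless runs and to within
0.1 / 0.05 from 50 runs with Gaussian timing noise (σ = 0.05 h) at a fixed
seed.

## 2. Partition planning

Given the total estimate T and the preferred per-partition execution time
R (default **2 hours**), the planner chooses the number of sequences per
work unit. Two interpretations are implemented:

* **corrected** (default): `n_parts = max(1, ceil(T/R))`,
  `p_size = ceil(N_q/n_parts)` — equivalently `P = N_q·R/T`. Each
  partition's expected runtime is then ≈ R, which is R's stated purpose.
* **literal**: `P = N_q·T/R`, rounded and clamped. This is the historical
  printed form of the sizing rule; note it is dimensionally inconsistent
  with the goal (partition size *grows* with total runtime, producing
  fewer, longer partitions for bigger jobs). It is retained behind
  `mode = "literal"` for fidelity and comparison, with the corrected form
  as the default.

Both modes clamp `p_size` to `[1, N_q]`, so there is always at least one
partition and never more partitions than sequences — over-partitioning
produces many very short jobs whose scheduling and invocation overhead
degrades throughput. Rounding is always `ceiling` (a partial partition is
still a partition). Assignment to partitions is contiguous in input order:
deterministic, and concatenating the partition files reproduces the input
record set exactly, which the suite asserts for 1, 2, 5 and 17 partitions.

Load-balancing by sequence *length* rather than count is a documented
non-goal: with the uniform-length synthetic workloads used here the two
coincide, and count-based splitting keeps the arithmetic exact.

## 3. Provisioning policy

`plan_provisioning()` applies a three-level hierarchy, in order:

1. **Hard-coded resource rules.** A `microbe` run tagged
   `illumina-assembly` gets exactly one high-memory `m2.xlarge`
   (17.1 GB RAM) — short-read assembly is memory-bound, not CPU-bound.
   Search-backed protocols never start below the policy floor of
   **5 instances** (40 CPUs with the default 8-CPU `c1.xlarge`).
2. **Estimate-based sizing.** Above the floor,
   `count = ceil(T / (R · cpus))`: each CPU processes about one R-hour
   partition, tying cluster size to the same target that sized the
   partitions. The formula is this package's own, chosen for that
   consistency; the hierarchy's inputs (estimate, floor, caps, R) are the
   policy's fixed points.
3. **Caps.** The provider's per-account limit (default **20**) and an
   optional user-configured limit. An explicit user cap is never exceeded,
   even by the floor: a user bound is a promise about spend.

The default catalog prices `c1.xlarge` at 0.675 currency-units/hour so
that a 160-instance cluster — 1,280 virtual CPUs — bills ≈ 108/hour; the
price is used for cost reporting only. The `m2.xlarge` CPU count (2) and
the zero cost of the academic `medium` type are package choices where the
policy source is silent.

Idle workers are terminated on an hourly timer: billing accrues per
started hour, so a jobless node is shut down within a window (default
**0.1 h**) before its next whole-hour uptime boundary
(`idle_termination_due()`). The window approximates
"terminate just before the next billing boundary" without claiming a
particular scheduler cadence.

## 4. The simulated cloud and cluster

The backend (`cloud_sim()`) exposes exactly three provider calls — run,
terminate, describe — and an append-only call log; the orchestration layer
is tested never to use anything else. Time is a virtual clock in hours: no
wall-clock sleeps, so a 160-instance scale-out study runs in milliseconds
and is bit-reproducible from a seed.

* **Boot latency** defaults to 0.02 h plus uniform jitter up to 0.01 h per
  instance, drawn from a private seeded stream: batches come online
  staggered, which matters for mirroring (below). The values reproduce the
  *regime* (staggered, minutes-scale boots), not any measured
  distribution.
* **Billing** is `max(1, ceiling(uptime))` instance-hours.
* **Links** have a point-to-point bandwidth of 40 MB/s between instances
  and a slower 10 MB/s desktop↔cloud link, the two knobs the transfer
  model needs; latency and congestion are not modelled.

Clusters have a single master (the first instance launched) and workers
that register as they boot; each cluster carries an opaque random keypair
token (no real cryptography). Queues follow the Grid-Engine pattern:
`exec.q` with one slot per worker CPU, and `staging.q` / `harvesting.q`
whose per-host slots (default 2) bound how many simultaneous prolog/epilog
transfers the master serves. The job engine (`run_queue()`) is a
discrete-event scheduler; its event log is asserted, at every event
instant, never to exceed any queue's slot limit. Jobs are assigned to the
least-loaded booted worker at prolog start, ties to the lowest instance
id — chosen for determinism and balance, as any tie-break must be.

### Peer-to-peer staging

Reference data needed on every instance is mirrored from a staging
directory. Initially only the master can serve; a worker that completes
its copy immediately becomes an additional source (joins `stagingsub.q`).
Transfers are non-preemptive whole-payload copies — directory-rsync
semantics, not chunked swarming — and no source exceeds its per-host
outbound limit. With uniform links, simultaneous boots and unit
concurrency the number of sources doubles each round, so n workers
complete in `ceil(log2(n+1))` rounds; the suite pins `mirror_staging()` to
that closed form (7 workers → exactly 3 rounds) and verifies that
peer-to-peer completion strictly beats the master-only baseline from 4
workers up, with strictly higher peak aggregate throughput. Epilog
(output) transfers are deliberately master-directed only — outputs funnel
to one place for download, so peer relay would buy nothing.

## 5. The seven-phase wrapper pipeline

`run_pipeline()` executes: (1) validation, (2) start cluster, (3) upload,
(4) execute, (5) monitor, (6) download, (7) post-process. Phases 2, 3
and 6 are skipped in local mode, which runs the worker on the local CPU
slots and produces byte-identical merged output — the mode switch is one
configuration key. Failure semantics: a validation failure halts the run
before any backend call; any later failure still ends in cluster teardown,
and at terminal state no instance is left running. Monitoring (phase 5)
takes snapshots at a fixed 0.05-h virtual interval — fine enough to
resolve the scale-out/teardown profile, coarse enough to keep logs small —
scales the cluster to the estimate-based plan before the parallel stage
(cap refusals are recorded and the run continues with what it has), and
terminates idle workers on the hourly timer afterwards while the master
persists for the download.

The shipped worker is a **toy seed-match counter**: per query, the number
of its k-mer windows present in the reference word set. It is per-query
independent (hence merged output is provably partition-invariant) and its
simulated CPU cost follows the *same* linear law the estimator assumes,
with the configured (α, β). That circularity is intentional and stated
plainly: it makes the estimator→partitioner→provisioner chain testable
end-to-end (the parallel-stage makespan lands within 25% of R when the
plan is uncapped), but it says nothing about how well a linear overlap law
fits any real search engine. One consequence visible in traces: α is
incurred once per *partition*, so heavily partitioned runs carry
`(n_parts − 1)·α` more simulated cost than the single-shot estimate.

Every output dataset records its producer: pipeline id, protocol id and
version, and the full parameter snapshot — enough to re-run the analysis
from the registry alone.

## 6. Synthetic data: what it does and does not emulate

`generate_synthetic()` draws sequence lengths uniformly on
`[min_len, max_len]` and residues i.i.d. uniformly over the unambiguous
alphabet, from a fixed seed (byte-identical regeneration). That gives the
tests exactly what they need — known window counts, near-uniform k-mer
content, reproducibility — and the defaults used across the suite
(queries of 40–1,000 sequences × 80–400 nt, references of 10–30 sequences
× 200–400 nt, k ∈ {2, …, 11}) keep the whole test run under half a minute
on one CPU; the largest integration case is 1,000 × 400-nt queries.

What it does **not** emulate: real base composition bias, repeats and
low-complexity tracts, ambiguity codes, read-length distributions, or any
homology structure between query and reference. Passing tests therefore
demonstrate the *mechanics* — counting, planning, scheduling,
conservation, determinism — not that the runtime model's fit carries over
to real data, which requires calibration on real timed searches.

## 7. Degenerate inputs and tie-breaks, collected

* Empty record set: valid; empty profile (total 0); prediction = α.
* Sequences shorter than k: contribute no windows.
* Empty FASTA file, FASTQ input, out-of-alphabet residues: validation
  errors naming the offender; FASTQ/SFF/QUAL are out of scope by design.
* `T ≤ R`: one partition containing everything.
* Re-terminating instances, clusters, or re-transferring unchanged
  datasets: idempotent no-ops (transfers move 0 bytes when checksums
  match).
* Scheduling ties everywhere break by lowest identifier; all event
  comparisons use a 1e-12 slack so equal virtual times are processed
  together.
* Boundary test `idle_termination_due(1.9, window = 0.1)` sits exactly on
  the window edge; the comparison carries a 1e-9 tolerance so binary
  representation of 0.9 does not flip it.

## 8. Known limitations

* The linear overlap law is an assumption, not a finding; the model object
  is the seam for replacing it.
* Transfers are bandwidth-only (no latency, no contention beyond slot
  limits); chunked/pipelined dissemination would beat the
  `ceil(log2(n+1))` schedule and is intentionally not modelled.
* One instance type per cluster; no spot pricing; no mid-stage downscaling
  other than idle termination.
* The `microbe`, `sixteen_s` and `metagenomics` protocols are registry
  entries with provisioning rules only; `search` is the one with a
  shipped worker.
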