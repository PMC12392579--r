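---
title: "Assigning long RNA-seq reads to transcripts with alignment-guided EM"
author: "lrassign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning long RNA-seq reads to transcripts with alignment-guided EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrassign)
```

## The problem

A long RNA-seq read should, in principle, identify the transcript it was
sequenced from: it can span the whole molecule. In practice reads are
truncated (direct RNA reads are strongly 3′-biased), error-prone, and many
isoforms of a gene share most of their sequence, so a read aligned against
a transcriptome typically has one primary alignment and a tail of secondary
alignments with similar scores. `lrassign` resolves this ambiguity with an
expectation–maximization (EM) algorithm whose E-step is *guided* by
alignment-derived priors, and reports both fractional read-to-transcript
assignments and per-transcript abundances.

## The generative model and the likelihood

Each read is modeled as arising from three latent choices: a transcript
(with probability equal to its relative abundance $\rho_t$), a 5′ end and a
3′ end position on it. Approximating the end-position and sequence
likelihoods with quantities observable in the alignments gives the working
likelihood

$$\mathcal{L}(\rho) = \prod_{r}\sum_{t \in T_r}
  \rho_t\,\upsilon_{rt}\,\omega_{rt}\,f_\eta(r,t)\,\sigma_{rt},$$

where $T_r$ is the set of transcripts read $r$ aligns to. The four factors
multiplying $\rho_t$ are fixed before the EM and stored in a sparse
compatibility matrix $X$; only $\rho$ is updated across iterations.

### Score decay $\sigma$

$\sigma_{rt} = \exp(-(\max_k x_{rk} - x_{rt})/\lambda)$ with the alignment
score $x_{rt}$ (minimap2's `ms` tag, `AS` as fallback; if a pair aligns
multiple times only the maximum-score alignment is kept). The read's
best-scoring transcript always gets 1; a score gap of $\lambda$ costs one
e-fold. The default $\lambda = 5$ works on the scale of minimap2 match
scores, where a handful of score points separates near-identical candidate
isoforms from genuinely worse ones. $\sigma$ depends only on score *gaps*:
adding a constant to all of a read's scores changes nothing.

The maximum is taken over the read's aligned transcripts — scores for
unaligned pairs do not exist, so no other reading is computable.

### End filters $\upsilon, \omega$ (optional)

For an alignment spanning $[i, j)$ on a transcript of length $|t|$, the end
distances are $\delta_s = i$ and $\delta_e = |t| - j$. A candidate
alignment passes a filter when its end distance exceeds that of the read's
*primary* alignment by at most a tolerance:
$\delta^{rt} - \delta^{rt'} \le |\beta|$. Because the threshold is relative
to the primary alignment, the primary always passes and no read can be
filtered out entirely. Setting $\beta = -\infty$ disables a filter, and
both are disabled by default: useful tolerances depend on the library
protocol. `compat_preset()` exposes recommended values
(`ont-drna`: $\beta_s = -800$, 3′ filter off; `ont-cdna`/`pacbio`:
$\beta_s = -600$, $\beta_e = -500$).

The tolerance is deliberately one-sided: it bounds *how much greater* a
candidate's end distance may be than the primary's, never penalizing
candidates whose ends sit closer to the transcript ends than the primary's
do. A symmetric band around the primary's end distance would reject such
candidates and, with a tight tolerance, could leave a read with no
compatible transcript at all; the one-sided form is the only one under
which the relative-thresholding guarantee — each read always keeps at
least its primary — holds by construction.

### Position-specific weights $f_\eta$ (optional, `psw`)

With `psw = TRUE`, per-base coverage $c^t_k$ (reads overlapping base $k$)
and per-transcript coverage $c^t$ (aligned bases divided by length) are
tallied once from all deduplicated alignments. Differences
$\eta_k = c^t - c^t_k$ are shifted nonnegative by $|\min_z \eta_z|$ and
normalized to sum to one, and $f_\eta(r,t)$ sums these weights over the
aligned interval. Alignments covering sparsely covered positions are thus
up-weighted. The shift $\eta_k + |\min_z \eta_z|$ is the smallest
translation making every weight nonnegative while preserving the
positional contrasts that carry the signal: a larger constant would
compress the contrast after normalization, and clamping negatives at zero
would discard the ordering among over-covered positions. Uniformly
covered transcripts make every shifted difference
zero; their weights are flagged degenerate and $f_\eta$ reverts to 1.

A second degeneracy arises for reads whose aligned positions all carry
near-zero weight (typical on lowly expressed transcripts): their whole row
of $f_\eta \sigma$ products vanishes. Such rows are rebuilt with
$f_\eta = 1$, so coverage weighting can only ever act through the defined
pathway and no read is silently unassigned. The number of rescued reads is
reported (`n_psw_fallback`).

## The EM, drop and push

$\rho$ initializes uniformly over the transcripts with at least one
alignment. The E-step computes
$\alpha_{rt} = \rho_t X_{rt} / \sum_{t'} \rho_{t'} X_{rt'}$; the M-step
sets $\rho_t$ to the column sums of $\alpha$ divided by the fixed read
total $N$.

**Drop.** Immediately after the first E-step — and only then — entries with
$\alpha_{rt} < \tau'_r = (1 + f)/|T_r|$ are zeroed in $X$ (default
$f = 0.1$), discarding alignments that even a uniform prior considers
implausible; a fresh E-step follows. Zeroed entries are absorbing: every
later $\alpha_{rt}$ is a multiple of $X_{rt}$. The rule as stated can zero
an entire row (an evenly split read has all $\alpha = 1/|T_r| < \tau'_r$
whenever $f > 0$), so the implementation always retains the row's largest
entry, breaking ties toward the lowest transcript index. This guard is a
deliberate design choice: the method's own guarantee is that each read
stays compatible with at least one transcript.

**Convergence** is declared when the L1 distance between successive
read-count vectors (the "total change in read counts"; the norm is our
choice, as only the quantity is named) falls below the threshold, default
10 reads — an *absolute* criterion calibrated for experiments with
millions of reads, where it permits iterations in the hundreds. On small
instances the first comparison (against the zero vector) is already below
10, so tests and small analyses should pass a tighter threshold such as
`1e-6`. Iteration order is deterministic (sorted read and transcript
indices), so results are bit-reproducible run to run.

**Push.** Fractional assignments are the primary output; `--push` samples
each read's hard transcript from its $\alpha$ row. Sampling perturbs
abundance estimates far less than assigning each read to its argmax
transcript (the acceptance script quantifies both deltas); the argmax
strategy remains available for comparison. All sampling flows from a
single seed, default 0, and the caller's RNG state is left untouched.

## What the synthetic fixtures emulate

`sim_config()` generates: a transcriptome of `n_loci` loci whose isoforms
share a 3′ suffix (`shared_suffix`, default 400 nt) behind
isoform-specific random 5′ extensions (multiples of `unique_step`,
default 150 nt); reads whose origins are multinomial in a Dirichlet-drawn
abundance vector, with lengths uniform between 30% and 100% of the origin
and 3′-anchored ends (direct-RNA-like; `three_prime_frac < 1` emulates
cDNA); and alignment records derived from the known overlap geometry, with
scores `2·overlap − 4·Binomial(overlap, 0.02)` and secondary records
emitted for locus siblings overlapping the read by ≥ 25 nt. These defaults
were chosen once as a realistic desk-scale caricature of a nanopore
experiment: heavy within-locus multi-mapping (a 3′-anchored read shorter
than the shared suffix is sequence-identical across all isoforms of its
locus), score gaps on the minimap2 scale, and a long-tailed abundance
distribution.

The simulated aligner is score-faithful, not sequence-faithful: it computes
scores from overlap geometry instead of re-running dynamic programming,
because the tests target the compatibility and EM arithmetic, not
alignment. Consequently passing tests demonstrate correct inference *given
aligner-like inputs*; they do not exercise basecalling error profiles,
chimeric reads, inter-locus sequence similarity, or annotation
incompleteness, all of which affect real accuracy. The fixture writers
(`write_fixture_files()`) emit real FASTA/FASTQ/SAM, and the same pipeline
run on genuine minimap2 alignments of the fixture reads gives closely
matching results.

Default problem sizes — 50 transcripts, 10,000 reads for the ambiguous
parameter-recovery fixture; 15 transcripts, 500 reads for the unambiguous
exact-recovery fixture; instances of ≤ 20 reads × ≤ 5 transcripts for the
per-iteration oracle comparisons — keep the full suite and the acceptance
script in the minutes range while still exercising every code path at
realistic ambiguity levels.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open on the transcript everywhere inside
  the package; SAM's 1-based inclusive positions and PAF's half-open ones
  are converted at the parsing boundary, and round-trips are exact.
- Per-pair dedup ties (equal scores) break by smaller start, then smaller
  end; if a read's flagged primary loses its pair's dedup, the top-score
  survivor is promoted so each read keeps exactly one primary.
- Reverse-strand transcriptomic hits are dropped by default (reads come
  from the sense strand); `keep_reverse = TRUE` retains them.
- Supplementary alignments are treated exactly as secondary alignments.
- Tolerances: $\alpha$ row sums and $\sum\rho$ hold to 1e-9, read-count
  conservation to 1e-6, position-weight normalization to 1e-12.
- Transcripts in the annotation with no alignments are reported with zero
  counts rather than omitted.
- An empty alignment file, a missing score tag on every record, an
  unknown reference name, or an interval exceeding the transcript length
  are hard errors; score tags missing on only some records skip those
  records with a count.

## Known limitations

Abundance priors shared across a locus mean structurally identical reads
are split by expression, not evidence; truly indistinguishable isoforms
get proportional fractions. The drop step is greedy and one-shot — a
compatibility discarded at iteration one cannot return. CPM here equals
TPM only because each long read represents one molecule; no
effective-length correction is applied. Evaluation assumes estimated and
true transcripts share identifiers (no intron-chain matching of novel
isoforms). Hard assignments are stochastic by design; bootstrap or
ensemble summaries over push seeds are left to the user.
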