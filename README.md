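# lrassign

Assignment of long RNA-seq reads (ONT direct RNA, ONT cDNA, PacBio) to the
transcripts of a user-supplied transcriptome, with transcript abundance
estimation. Unlike assembly-first pipelines, `lrassign` treats read-to-
transcript assignment itself as the primary output: every read receives
either a fractional assignment distribution over compatible transcripts or
a sampled hard 1-to-1 assignment, so downstream analyses can inspect
read-level support for any transcript.

## The model

Reads are assumed to be generated by picking a transcript `t` with
probability `ρ_t`, then picking 5′ and 3′ end positions on it. Given
non-spliced alignments of the reads against the transcript sequences
(minimap2, keeping many secondary alignments), each read–transcript pair
`(r, t)` gets a precomputed compatibility score

    X_rt = υ_rt · ω_rt · f_η(r,t) · σ_rt

where

- `σ_rt = exp(−(max_k x_rk − x_rt)/λ)` is an exponential decay in the gap
  between the pair's alignment score `x_rt` and the read's best score
  (default λ = 5);
- `υ_rt, ω_rt ∈ {0,1}` are optional 5′/3′ end-distance filters: a
  candidate alignment passes when its end distance exceeds the read's
  primary alignment's end distance by at most `|β|` (off by default;
  protocol presets available);
- `f_η(r,t)` (optional, `psw = TRUE`) sums per-base weights
  `η″_k ∝ (c^t − c_k^t) + |min_z (c^t − c_z^t)|` over the aligned interval,
  up-weighting alignments that cover sparsely covered transcript positions.

An EM algorithm then maximizes `L(ρ) = Π_r Σ_t ρ_t X_rt`: the E-step
computes read fractions `α_rt = ρ_t X_rt / Σ_{t′} ρ_{t′} X_{rt′}`, the
M-step sets `ρ_t` to the normalized column sums of `α`. Right after the
first E-step, a one-shot *drop* step zeroes entries with
`α_rt < (1 + f)/|T_r|` (default `f = 0.1`), permanently discarding weak
compatibilities. Iterations stop when the total absolute change in read
counts falls below a threshold (default 10 reads). A final *push* step can
sample each read's hard assignment from its `α` row.

Outputs per transcript: read count `rc_t = Σ_r α_rt`, relative abundance
`ρ_t`, `CPM_t = rc_t/l · 10⁶` (`l` = aligned reads), and coverage
`λ_t = Σ_r α_rt·l(r) / l(t)`.

## Worked example

The package ships a synthetic fixture generator producing a multi-isoform
transcriptome (isoforms of a locus share their 3′ suffix, so 3′-truncated
reads multi-map), seeded reads with known origins, and aligner-like scored
alignment records:

```r
library(lrassign)

ds  <- simulate_dataset(sim_config())   # 10 loci x 5 isoforms, 10,000 reads
res <- quantify_reads(ds$records, ds$index)
res
#> lrassign_result: 10000 reads assigned across 50 of 50 transcripts in 4 EM iterations

head(res$report, 3)
#>   transcript_id read_count      cpm coverage
#> 1          L1.1   30.28521 3028.521 21.25994
#> 2          L1.2   44.93338 4493.338 31.90413
#> 3          L1.3   32.39148 3239.148 19.26675

truth <- true_read_counts(ds$sim, ds$index)
est   <- setNames(res$report$read_count, res$report$transcript_id)
abundance_metrics(est, truth)[c("scc", "pcc_log", "rmse")]
#> $scc      [1] 0.9553357
#> $pcc_log  [1] 0.9447376
#> $rmse     [1] 58.92851
```

`read_count` is the expected number of reads from each transcript, `cpm`
its library-size-normalized version, and `coverage` the expected read bases
per transcript base. With position-specific weights
(`compat = compat_config(psw = TRUE)`) the same fixture yields SCC 0.96 /
PCC 0.97 / RMSE 41.3 — coverage weighting sharpens the estimates exactly as
intended. `push_assignments(res$fit$alpha, seed = 0)` converts fractions to
hard assignments at a small accuracy cost (SCC drop ≈ 0.004 here).

Real data enter through `read_transcriptome()` (FASTA) or
`read_transcriptome_gtf()` plus `parse_alignments()` (SAM/BAM/PAF with
`ms`/`AS` score tags), or `run_aligner()` when minimap2 is on the PATH. A
command-line front end is installed at
`system.file("scripts", "lrassign.R", package = "lrassign")`:

```sh
Rscript lrassign.R --alignments aln.bam --transcriptome tx.fa \
    --out-dir results --psw --push
```

Evaluation helpers (`assignment_confusion()`, `precision_recall_f1()`,
`abundance_metrics()`, `sequin_cpm()`) score assignments and abundances
against known read origins or spike-in concentrations.

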