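---
title: "Mapping point mutations without alignment: the count-shift method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping point mutations without alignment: the count-shift method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpshift)
```

## The problem

A chemically mutagenized line differs from its isogenic wild type by a
handful of point mutations; one of them causes the phenotype. When RNA-seq
data exist for both genotypes, the causal candidates can be found without
any read alignment: every position of the reference transcriptome is
represented by a 22-mer starting there, and a homozygous SNP at that
position makes mutant reads stop matching the reference 22-mer and start
matching exactly one of its three first-position substitution variants.
`snpshift` implements that idea end to end — variant database construction,
exact closed-set k-mer counting, count-shift calling, coding-effect
annotation — together with the downstream statistics such a mapping study
typically needs (gene-list overlap enrichment, segregation chi-square,
vitamer fold-change arithmetic) and a seeded simulator that generates every
input, so the whole pipeline is testable without external data.

## The model and its assumptions

For a transcript of length $L$ and k-mer length $k$ (default 22), reference
k-mers are taken at positions $1 \ldots L-k+1$. Each reference k-mer is
paired with its three first-position substitution variants, so each covered
position contributes four database records. A SNP at position $p$ moves the
read k-mers starting at $p$ from the reference record to exactly one variant
record — the *count shift*. The method is sound when:

* **mutations are sparse** — no two SNPs within $k$ bases of each other,
  otherwise a mutant read k-mer can differ from the reference at two
  positions and match nothing. EMS mutagenesis, with a genome-wide density
  far below one mutation per 22 bases, satisfies this comfortably;
* **the mutation is homozygous** in the sequenced material, so essentially
  all mutant reads at the site carry the variant;
* **the k-mer is unique**. Database keys that occur at more than one
  (transcript, position), collide between reference and variant roles, or
  (in canonical mode) collide with a reverse complement, are *masked* with a
  reason code and excluded from calling. Masking is deliberately
  conservative: an ambiguous k-mer is dropped, never silently kept.

Two blind spots are inherent and reported rather than patched: the final
$k-1$ positions of a transcript start no k-mer (`db$uncovered` lists the
interval), and positions whose k-mer is masked are uncalled.

### Strand handling

RNA-seq library strandedness is often unknown, so the database defaults to
*canonical* mode: a k-mer and its reverse complement form one key, and every
read window increments exactly one counter regardless of the strand the
read came from. This costs a small number of extra maskings (cross-strand
key collisions) and is correct for both stranded and unstranded protocols.
Forward-only matching is available with `canonical = FALSE`.

## Calling policy

The count-shift criterion — variant present in all mutant replicates,
absent from wild type — is qualitative; `calling_policy()` makes it
operational for error-bearing reads:

| parameter | default | meaning |
|---|---|---|
| `min_ref_count_wt` | 5 | coverage floor per wild-type replicate |
| `max_alt_fraction_wt` | 0.05 | tolerated wild-type alt fraction (sequencing error) |
| `min_alt_count_mut` | 3 | variant k-mer count floor per mutant replicate |
| `min_alt_fraction_mut` | 0.8 | homozygous expectation per mutant replicate |
| `require_all_mut_replicates` | TRUE | all (vs strict majority) mutant replicates must pass |

"Absent from wild type" is interpreted as alt fraction at or below
`max_alt_fraction_wt` rather than strictly zero: at high depth a few
error-derived variant k-mers are expected even at true-negative sites.
Positions with zero wild-type coverage can never PASS (`NO_WT_COVERAGE`) —
without a baseline, no shift can be established. If two alt alleles at one
position both qualify (unexpected under EMS), both are emitted flagged
`MULTIALLELIC` instead of being resolved silently. Tightening any single
threshold can only shrink the PASS set; the test suite checks this
monotonicity property.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the scaled-down study design used throughout
the tests: 20 transcripts of 1.0–1.2 kb, 5 planted EMS transitions, three
replicates per genotype, 50,000 single-end 75 nt reads per replicate, and a
0.5% uniform per-base substitution error rate (read length, depth and error
behaviour of the original instrument run are not published, so these are
configurable package choices at desk scale). Per-transcript abundance
weights are log-uniform over one order of magnitude — a realistic expression
spread that still leaves the least-expressed transcript at roughly 30-fold
k-mer window coverage under the defaults, matching the depth regime in which
the default policy is meant to operate. Planted mutations are exclusively
G→A or C→T on the transcript strand, the canonical EMS spectrum.

Planted SNPs are restricted to the *well-covered core* of each transcript:
positions within one read length of a transcript end are started by only a
handful of read positions, so a SNP planted there is undetectable at any
realistic depth — not because the caller is weak, but because almost no
k-mer windows over it exist. The pipeline driver passes
`margin = read_length - k` to `apply_ems_mutations()` accordingly; the
margin is a study-design property, not a caller parameter.

Generated coding sequences start with ATG, end with a stop codon, and have
internal stop codons recoded GC-neutrally (TAA→TAT, TAG→TAC, TGA→TGT) so
planted ORFs are open without biasing the configured GC content.

The simulator deliberately omits: splicing and intron retention, paired-end
reads, position- or quality-dependent error models, indels, PCR duplicates,
and coverage bias along transcripts. Passing tests therefore demonstrate the
correctness of the counting and calling logic under uniform substitution
noise — they do not certify performance on real libraries with structured
error or coverage artefacts, where the policy thresholds may need
adjustment.

## Fold-change overlap and the enrichment null

`threshold_genes()` uses the exact $\log_2(\text{fold})$ cutoff with strict
inequality ($\log_2 1.5 \approx 0.58496$). Published analyses sometimes
print a rounded constant (e.g. 0.587); the `cutoff` argument accepts such a
literal value for replication. The overlap p-value follows a binomial
statistic — the upper-tail probability of at least the observed
intersection in $|A|$ trials with success probability $|B|/|U|$, computed by
exact summation — with a hypergeometric (both-margins-fixed) alternative
behind the `null` argument, since the two nulls differ for small universes
and published figure legends rarely say which was used. The universe
defaults to the genes present in both tables: an overlap is only defined on
jointly assayed genes. `set_enrichment()` applies the same statistic per
term of a user-supplied gene→term map with Benjamini–Hochberg adjustment
across terms; it does not query any live annotation database.

The planted-table generator needs the sizes of the second contrast's gene
sets, which the motivating study never states (only the first contrast's
set sizes and the intersections are printed); the defaults of 1,200 up- and
800 down-regulated genes are a plausible scale for a strong perturbation
and affect nothing but the Venn margins.

## Vitamer arithmetic

Fold changes between growth conditions are ratios of arithmetic replicate
means (measurements are reported as mean ± SEM of three replicates), with a
delta-method standard error; the test suite checks it against a parametric
bootstrap. Group comparisons use Welch's unequal-variance t-test — the safer
default when only "t-test" is specified — with the conventional star labels.
The free-pool amplification identity
$(F - b)/(1 - b)$ follows from holding the enzyme-bound amount constant
while the total pool changes $F$-fold: with the control total normalized to
1, free changes from $1-b$ to $F-b$. With $F = 2.5$ and $b = 0.9$ the free
pool rises 16-fold — a modest total-pool change conceals an
order-of-magnitude change in free cofactor. The function rejects $F < b$,
where the fixed bound pool would exceed the new total.

The default planted vitamer scenario embeds a 2.6-fold (wild type) and
2.3-fold (mutant) ThDP increase under 30 nM supplementation with free
thiamin at 14% and 11% of the summed pool, at a 10% coefficient of
variation — typical reproducibility for HPLC-based vitamer quantification
with three biological replicates.

## Numerical and degenerate-input choices

* Counting uses a rolling 2-bit encoding (A<C<G<T matches lexicographic
  order, so the canonical key is `min(code, rc_code)`); `k` is limited to
  8–32. Only database k-mers are stored, so memory is proportional to the
  database, not the read set. Counting is single-threaded; it is exactly
  associative over file splits (tested), so coarse parallelism over files
  reproduces identical results.
* Windows containing any non-ACGT character are skipped in both database
  construction and counting.
* All coordinates in files and interfaces are 1-based inclusive on the cDNA;
  `hgvs_c` shorthand is cDNA-numbered (`c.1278G>A` means cDNA position
  1278), matching the coordinate the pipeline reports, rather than
  CDS-numbered as in strict HGVS.
* Start-codon disruptions are classed `start_loss` (ATG is the only Met
  codon, so any change there alters initiation) and stop-codon losses
  `stop_loss`, rather than folding either into missense.
* `alt_fraction` is NA where ref + alt = 0; such sites surface as
  `NO_WT_COVERAGE`, never as calls.
* A fixed seed makes every output byte-identical across runs, including
  gzip FASTQ.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 42)       # the scaled-down study design above
res <- run_snp_pipeline(cfg)
res$evaluation
#> $n_truth        [1] 5
#> $n_pass         [1] 5
#> $n_recovered    [1] 5
#> $recall         [1] 1
#> $false_positives[1] 0

ann <- summarize_effects(annotate_effects(res$calls, res$tx))
ann[, c("transcript_id", "position", "effect_class", "hgvs_c", "hgvs_p")]
```

At this scale (about 24,000 database positions, 300,000 reads) a run takes
a few seconds; the acceptance script repeats it over 20 seeds at a 0.5%
error rate and reports aggregate recall and false-positive counts.

## Known limitations

* Transcript-level only: no genome-scale scan with introns; restricting a
  scan to a chromosome or gene subset is done by pre-filtering the FASTA.
* No heterozygote model: the policy encodes the homozygous-mutant
  expectation; a 50% alt fraction fails the default `min_alt_fraction_mut`.
* No indels, and no splice-aware coordinates.
* The binomial overlap null treats draws as independent; for small
  universes the hypergeometric option is the better-calibrated choice.
* Enrichment p-values depend strongly on the universe definition, which is
  the caller's responsibility to choose honestly.
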