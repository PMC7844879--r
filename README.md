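# chimloci

Chimeric read analysis for RNA–RNA interactome and structurome data.

RNA–RNA contact protocols — CLASH and CLEAR-CLIP for miRNA–target
chimeras, PARIS/SPLASH/LIGR-Seq for structure-derived duplexes — sequence
*chimeric reads* in which two RNA fragments are ligated into one molecule.
The two arms of such a read are short (often 10–25 nt) and therefore
multi-map across paralogs, gene families and isoforms; discarding or
arbitrarily placing multi-mapped arms loses or mislocates exactly the
family-borne interactions these experiments are run for.

`chimloci` resolves multi-mapped chimeric arms **by expression**:

1. reads are UMI-aware deduplicated (exact `(sequence, UMI)` identity;
   `< 10` nt discarded);
2. alignments (external 2-pass `bwa mem`, pre-made SAM, or the built-in
   exact toy mapper) are post-processed: sense-strand only, best-read-
   coverage XA alternatives, cross-pass dedup;
3. alignments merge into **expressed loci** (reciprocal overlap > 70%),
   optionally after lifting transcript coordinates to the genome through a
   GTF;
4. loci sharing multi-mapped read segments group into **common read loci
   (CRLs)** by single-linkage clustering on the Jaccard index (J > 0.7),
   an annotation-free stand-in for paralog/family structure;
5. CRL abundances ρ are estimated by **expectation-maximization** on the
   likelihood L(ρ) = ∏ₛ Σ_c y₍s,c₎ ρ_c, where y₍s,c₎ = 1 iff segment *s*
   maps to CRL *c* (E-step: Pr(z₍s,c₎=1) = ρ_c / Σ_{c'} y₍s,c'₎ ρ_{c'};
   M-step: ρ_c = Σₛ E[z₍s,c₎]/N; stop at Σ|Δρ| ≤ 1e−5); abundances are
   reported as TPM = ρ·10⁶;
6. each read's two most probable arms are extracted and scored with
   Pr[(s,s′) ∈ c↔c′] = Pr(z₍s,c₎=1)·Pr(z₍s′,c′₎=1), annotated
   (gene, biotype, 5′UTR/CDS/3′UTR) and written as a tab-separated
   interaction table.

A benchmark simulator (paralogous split references, fused-arm reads with
per-read ground truth, optional 5-nt inserts) and a seven-category
evaluator (perfect / partial_multi / both_multi / partial_wrong /
both_wrong / partial_miss / both_miss, with ≥ 80% overlap defining an
"agreed" arm) make every stage testable offline. CRL coherence is
validated by average pairwise sequence identity (APSI: LCS length over
mean sequence length) against a size-matched random baseline.

## Worked example

```r
library(chimloci)
library(dplyr)

refs    <- make_reference(n_families = 20, family_size = 3,
                          divergence = 0.03, seed = 1)
sim     <- make_chimeric_reads(refs, 1000, arm_length = 18, seed = 1)
singles <- make_singleton_reads(refs, 600, read_length = 25, seed = 1)

res <- chim_run(bind_rows(sim$reads, singles), refs = refs,
                config = chim_config(seed = 1))

glance(res$fit)
#>   n_segments n_crls n_iterations converged epsilon logLik
#> 1       2283    398           43 TRUE      0.00001 -11699.

tidy(res$fit) |> arrange(desc(tpm)) |> head(3)
#>   crl_id      rho    tpm n_segments
#> 1 CRL00001 0.0263 26281.         60
#> 2 CRL00002 0.0254 25405.         58
#> 3 CRL00003 0.0250 24967.         57

head(res$interactions |> select(read_id, arm1_ref_id, arm2_ref_id, score), 3)
#>   read_id       arm1_ref_id arm2_ref_id score
#> 1 simread000001 mir004_c1   tgt007_c1       1
#> 2 simread000002 mir007_c2   tgt019_c1       1
#> 3 simread000003 mir001_c3   tgt007_c1       1
```

The 1,600 simulated reads (1,000 chimeric + 600 expression-marking
singletons) map into 646 expressed loci grouped into 398 CRLs; the EM
converges in 43 iterations. Every interaction row carries, per arm, the
reference, locus, CRL, coordinates, CIGAR, posterior and CRL TPM; `score`
is the product of the two arm posteriors. Evaluating against the simulated
truth:

```r
counts <- categorize_reads(
  chira_predictions(semi_join(res$interactions, sim$truth, by = "read_id")),
  sim$truth)
counts
#>   category          n
#> 1 perfect         578
#> 2 partial_multi     0
#> 3 both_multi        0
#> 4 partial_wrong   410
#> 5 both_wrong        0
#> 6 partial_miss      0
#> 7 both_miss        12
```

Here 57.8% of reads have both arms uniquely and correctly placed; the
`partial_wrong` remainder is dominated by family windows that are
sequence-identical across all three paralog copies, where no read evidence
can single out the expressed copy (see the methods vignette,
`vignettes/chimeric-read-quantification.Rmd`). The naive longest-hit
baseline on the same alignments (`naive_predictions()`) reaches ~25%
perfect — the CRL+EM machinery roughly doubles correct placements.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch: it simulates the benchmark world at the given seed, executes the
full dedup → map → loci → CRL → EM → extraction workflow, evaluates the
result against the simulated truth, and writes its JSON report to the
path given with `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
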