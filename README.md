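# viroblock

Biologically informed block-sparse attention for whole viral proteomes, in R.

Viral genomes are compact arrays of co-evolving proteins, but protein language
models either see one protein at a time or pay the quadratic cost of dense
attention over the whole proteome. `viroblock` implements a two-stage method
around that obstacle:

1. **Infer putative protein–protein interactions (PPIs) from attention maps.**
   Given per-(layer, head) attention matrices $M$ over a multi-protein genome
   fragment, each matrix is corrected with Average Product Correction and
   symmetrized,

   $$N = \tfrac12\left[(M - \mathrm{APC}) + (M - \mathrm{APC})^\top\right],
   \qquad \mathrm{APC}_{ij} = \frac{(\sum_l M_{il})(\sum_k M_{kj})}{\sum_{kl} M_{kl}},$$

   reduced across heads, and thresholded at the upper $t\%$ nearest-rank
   quantile into a cell set $S$ (strict inequality). Min–max–normalized cell
   scores aggregate to a pair statistic
   $A_{P_I,P_J} = \sum_{(i,j)\in S} \mathrm{score}(i,j) / (n_I n_J)$,
   and the top-50 non-adjacent pairs by $A$ become the interaction set.

2. **Compute attention only where biology allows it.** Each protein is padded
   to a multiple of the block size $B = 32$ and the mask admits three block
   origins — intra-protein, adjacent proteins, inferred PPI pairs — stored in
   Block Sparse Row (BSR) layout. `block_sparse_attention()` runs masked
   multi-head scaled-dot-product attention (optional ALiBi bias) per block
   row, never materializing an $L' \times L'$ matrix, and is verified against
   a dense masked-softmax oracle to $10^{-5}$, with an analytic backward pass
   checked against finite differences.

The package also ships seeded fixture generators (planted-interaction
attention stacks, a partner-dependent masked-token task), a miniature
masked-language-model encoder built on the sparse kernel, distance-stratified
attention analysis, benchmarking against reference interaction labels
(F1/accuracy/AUC with bootstrap CI), and embedding metrics (perplexity,
silhouette, stratified k-fold linear classification).

## Worked example

Generate a 20-protein genome with five planted non-adjacent interacting
pairs, infer interactions from the planted attention stack, and build the
sparse mask:

```r
library(viroblock)

g <- make_synthetic_genome(20, c(20, 40), seed = 1, genome_id = "demo")
planted <- rbind(c(2L, 11L), c(0L, 5L), c(7L, 18L), c(4L, 13L), c(9L, 16L))
stack <- plant_attention(g, planted, snr = 5, n_layers = 4, n_heads = 4,
                         seed = 2)

fit <- infer_interactions(stack, g, t = 10, agg = "mean", k = 10)
print(fit)
#> ppi_fit for genome 'demo'
#>   190 protein pairs scored; t = 10%, aggregation = mean
#>   35880 selected cells above threshold 0.0003664
#>   top-10 non-adjacent interactions selected (10 found)

head(fit$selected, 5)
#>   I  J         A rank
#> 1 2 11 0.5076247    1
#> 2 0  5 0.4948294    2
#> 3 4 13 0.4818122    3
#> 4 7 18 0.4805551    4
#> 5 9 16 0.4487446    5
```

All five planted pairs rank 1–5 of 190 scored pairs: the APC + quantile +
aggregation pipeline isolates the planted signal. The interaction set then
drives the sparse mask:

```r
layout <- segment_genome(g, 32)
mask <- build_block_mask(layout, fit$selected)
sparsity_stats(mask, layout)$fraction
#> [1] 0.1964286   # stored blocks as a fraction of the dense block grid

inputs <- make_qkv(layout$padded_length, d_k = 16, n_heads = 4, seed = 3)
out <- block_sparse_attention(inputs, mask, layout, alibi_slopes(4))
dim(remove_padding(out, layout))
#> [1]   4 599  16   # heads x residues x d_k, padding stripped
```

On a synthetic 61,000-aa genome (150 proteins, 50 interactions) the stored
fraction drops to ~2.4% and a forward pass runs on one CPU.

The command-line surface wraps the same functions
(`Rscript inst/cli/viroblock.R infer-ppi --attention DIR --genome FASTA ...`);
see `run_cli(character(0))` for the subcommand list.

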