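#!/usr/bin/env Rscript
# Stage 3: subsample ranking of regions by affected-voxel burden. 100
# stratified 60% subsamples are each analyzed with the voxel-wise GLM
# plus cluster-extent filter; regions are ranked per iteration by the
# proportion of surviving voxels and aggregated by mean rank; the top
# ten become the per-region phenotypes for the genetic stages.

source(file.path("analysis", "_common.R"))
inp <- load_inputs()

ranking <- run_ba_ranking(inp$images, inp$cohort, inp$atlas,
                          n_iter = 100, fraction = 0.6, k = 10,
                          seed = substream_seed(seed, "ranking"))
write_ranking_tsv(ranking, file.path(out_dir, "ranking"))

cat("aggregate ranking (mean rank over 100 iterations of 60% subsamples):\n")
print(ranking$aggregate)
cat(sprintf("selected top-10 regions: %s\n",
            paste(sort(ranking$top_k), collapse = ", ")))
planted <- sim$affected_regions
cat(sprintf("planted deficit regions recovered: %d of %d\n",
            length(intersect(ranking$top_k, planted)), length(planted)))
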