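#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study - a parcellated gray-matter
# phantom with deficits planted in regions 1..10, Hardy-Weinberg
# genotypes with per-region causal SNPs and a 200-SNP polygenic
# architecture, noisy discovery summary statistics, a synthetic gene
# annotation, and developmental expression fixtures. Everything is
# written to results/analysis/data in standard formats.

source(file.path("analysis", "_common.R"))

atlas <- generate_phantom_atlas(sim)
cohort <- generate_cohort(sim)
genotypes <- generate_genotypes(sim, cohort)
cohort <- plant_ba_phenotypes(sim, cohort, genotypes)
images <- generate_gm_images(sim, cohort, atlas)
sumstats <- generate_discovery_sumstats(sim, genotypes)
annotation <- generate_gene_annotation(sim)
fixtures <- generate_expression_fixtures(sim)

write_label_volume_nifti(atlas, file.path(data_dir, "atlas.nii.gz"))
write_cohort_tsv(cohort, file.path(data_dir, "cohort.tsv"))
write_gm_images_nifti(images, file.path(data_dir, "gm"))
write_genotypes_vcf(genotypes, file.path(data_dir, "genotypes.vcf.gz"))
write_sumstats_tsv(sumstats, file.path(data_dir, "discovery_sumstats.tsv"))
write.table(data.frame(chrom = paste0("chr", annotation$chrom),
                       start = annotation$start - 1L,
                       end = annotation$end,
                       name = annotation$name),
            file.path(data_dir, "genes.bed"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
write_expression_matrix(fixtures$expression,
                        file.path(data_dir, "counts.tsv"),
                        file.path(data_dir, "cells.tsv"))
write_ish_tsv(fixtures$ish, file.path(data_dir, "ish.tsv"))

counts <- attr(cohort, "case_counts")
cat(sprintf("simulated %d subjects (%d HC / %d SCZ) on a %s grid, %d regions\n",
            nrow(cohort$subjects), sum(cohort$subjects$group == "HC"),
            sum(cohort$subjects$group == "SCZ"),
            paste(sim$grid_shape, collapse = "x"), sim$n_regions))
cat(sprintf("genotypes: %d SNPs; planted per-region case counts: %s\n",
            ncol(genotypes$dosage), paste(counts, collapse = ", ")))
cat(sprintf("gene annotation: %d synthetic genes; expression: %d genes x %d cells\n",
            nrow(annotation), nrow(fixtures$expression$counts),
            ncol(fixtures$expression$counts)))
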