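# Shared setup for the analysis scripts. Run every script from the
# repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_vbm.R
#   ...
# All scripts accept an optional --seed <int> (default 1).

suppressPackageStartupMessages(library(areascan))

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L
if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])

data_dir <- file.path("results", "analysis", "data")
out_dir <- file.path("results", "analysis")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

# the study conditions of the whole workflow: desk-scale phantom with
# deficits planted in regions 1..10 of 20
sim <- sim_config(seed = seed)

load_inputs <- function() {
  atlas <- read_label_volume_nifti(file.path(data_dir, "atlas.nii.gz"))
  subjects <- read_cohort_tsv(file.path(data_dir, "cohort.tsv"))
  cohort <- cohort_from_table(subjects, sim$n_regions)
  images <- read_gm_images_nifti(file.path(data_dir, "gm"),
                                 ids = subjects$id)
  list(atlas = atlas, cohort = cohort, images = images)
}
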