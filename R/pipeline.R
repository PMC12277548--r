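# End-to-end orchestration of the analysis workflow: simulate ->
# whole-brain comparison -> voxel-wise GLM with cluster FWE ->
# subsample ranking -> per-region phenotypes -> genotype QC ->
# association scans -> SNP sharing and gene mapping -> PRS ->
# clinical correlations -> expression statistics.

#' Pipeline configuration
#'
#' Bundles the simulation configuration with the analysis parameters
#' and an output directory. All stage randomness derives from the
#' simulation root seed via named substreams, so individual stages are
#' re-runnable in isolation and a re-run with the same configuration
#' reproduces byte-identical tables.
#'
#' @param simulation a [sim_config()].
#' @param out_dir output directory.
#' @param p_voxel voxel-level threshold for cluster extraction.
#' @param min_size minimum cluster extent (voxels).
#' @param fraction subsample fraction for the ranking procedure.
#' @param n_iterations number of ranking subsamples.
#' @param k number of top regions to select.
#' @param n_perm permutations for cluster-level FWE.
#' @param alpha_case one-sided threshold for per-region case selection.
#' @param gwas_threshold association significance threshold.
#' @param prs_grid PRS p-value threshold grid.
#' @param delta high/low margin for areal pattern labels.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            out_dir = "results/pipeline",
                            p_voxel = 0.001, min_size = 100L,
                            fraction = 0.6, n_iterations = 100L,
                            k = 10L, n_perm = 200L, alpha_case = 0.05,
                            gwas_threshold = 5e-6,
                            prs_grid = PRS_DEFAULT_GRID, delta = 0.1) {
  if (p_voxel <= 0 || p_voxel >= 1) stop_config("p_voxel must be in (0,1)")
  if (fraction <= 0 || fraction > 1) stop_config("fraction must be in (0,1]")
  if (k > simulation$n_regions) stop_config("k exceeds n_regions")
  structure(list(simulation = simulation, out_dir = out_dir,
                 p_voxel = p_voxel, min_size = as.integer(min_size),
                 fraction = fraction, n_iterations = as.integer(n_iterations),
                 k = as.integer(k), n_perm = as.integer(n_perm),
                 alpha_case = alpha_case, gwas_threshold = gwas_threshold,
                 prs_grid = prs_grid, delta = delta),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `simulation` (passed to [sim_config()]) and
#' `analysis` (passed to [pipeline_config()]), plus `out_dir`.
#'
#' @param path YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- do.call(sim_config, cfg$simulation %||% list())
  args <- cfg$analysis %||% list()
  args$simulation <- sim
  if (!is.null(cfg$out_dir)) args$out_dir <- cfg$out_dir
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes every stage over a synthetic cohort and writes
#' self-describing TSV outputs plus a JSON manifest (per-stage status,
#' seeds and row counts; no timestamps, so re-runs are byte-identical).
#' Any stage failure halts with the stage name; partial outputs are
#' retained.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every stage's in-memory result and
#'   the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulation
  manifest <- list(seed = sim$seed,
                   package_version = as.character(utils::packageVersion("areascan")),
                   stages = list())
  say <- function(...) if (!quiet) message(sprintf(...))
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c("areascan_stage_error", "areascan_error")))
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), attr(res, "manifest"))
    res
  }
  with_manifest <- function(x, ...) {
    attr(x, "manifest") <- list(...)
    x
  }

  say("stage: simulate")
  state <- run_stage("simulate", function() {
    atlas <- generate_phantom_atlas(sim)
    cohort <- generate_cohort(sim)
    genotypes <- generate_genotypes(sim, cohort)
    cohort <- plant_ba_phenotypes(sim, cohort, genotypes)
    images <- generate_gm_images(sim, cohort, atlas)
    sumstats <- generate_discovery_sumstats(sim, genotypes)
    expr <- generate_expression_fixtures(sim)
    write_cohort_tsv(cohort, file.path(config$out_dir, "cohort.tsv"))
    write_sumstats_tsv(sumstats, file.path(config$out_dir, "discovery_sumstats.tsv"))
    with_manifest(list(atlas = atlas, cohort = cohort, genotypes = genotypes,
                       images = images, sumstats = sumstats, expr = expr),
                  n_subjects = nrow(cohort$subjects),
                  n_snps = ncol(genotypes$dosage),
                  n_regions = sim$n_regions)
  })

  say("stage: whole-brain comparison")
  whole <- run_stage("whole_brain", function() {
    v <- whole_brain_volume(state$images, state$atlas)
    grp <- state$cohort$subjects$group
    test <- welch_t(v[grp == "HC"], v[grp == "SCZ"])
    df <- data.frame(group = c("HC", "SCZ"),
                     n = c(sum(grp == "HC"), sum(grp == "SCZ")),
                     mean_cm3 = c(mean(v[grp == "HC"]), mean(v[grp == "SCZ"])),
                     sd_cm3 = c(sd(v[grp == "HC"]), sd(v[grp == "SCZ"])))
    write_tsv_schema(df, file.path(config$out_dir, "whole_brain.tsv"))
    with_manifest(list(volumes = v, test = test, summary = df),
                  p = test$p)
  })

  say("stage: voxel-wise GLM with cluster FWE")
  vbm <- run_stage("vbm", function() {
    clusters <- cluster_fwe_permutation(
      state$images, state$cohort, state$atlas,
      p_voxel = config$p_voxel, min_size = config$min_size,
      n_perm = config$n_perm,
      seed = substream_seed(sim$seed, "fwe_permutation"))
    write_cluster_table(clusters, file.path(config$out_dir, "clusters.tsv"))
    with_manifest(clusters, n_clusters = nrow(clusters$clusters),
                  n_significant = sum(clusters$clusters$significant %||% FALSE))
  })

  say("stage: subsample ranking (%d x %.0f%%)", config$n_iterations,
      100 * config$fraction)
  ranking <- run_stage("rank_ba", function() {
    r <- run_ba_ranking(state$images, state$cohort, state$atlas,
                        n_iter = config$n_iterations,
                        fraction = config$fraction, k = config$k,
                        p_voxel = config$p_voxel, min_size = config$min_size,
                        seed = substream_seed(sim$seed, "ranking"))
    write_ranking_tsv(r, file.path(config$out_dir, "ranking"))
    with_manifest(r, top_k = paste(r$top_k, collapse = ","),
                  n_iterations = nrow(r$proportions))
  })

  say("stage: regional volumes and clinical correlations")
  volumes <- run_stage("volumes", function() {
    tab <- region_volume_table(state$images, state$atlas)
    write_tsv_schema(tab, file.path(config$out_dir, "region_volumes.tsv"))
    with_manifest(tab, n_rows = nrow(tab))
  })
  clinical <- run_stage("clinical", function() {
    subj <- state$cohort$subjects
    scz <- subj[subj$group == "SCZ", ]
    whole_scz <- whole$volumes[scz$id]
    targets <- c(list(whole_brain = whole_scz),
                 setNames(lapply(ranking$top_k, function(r) {
                   v <- volumes[volumes$region == r, ]
                   setNames(v$volume_cm3, v$id)[scz$id]
                 }), paste0("region_", ranking$top_k)))
    rows <- list()
    for (nm in names(targets)) {
      for (covar in c("duration", "mmse")) {
        ct <- pearson_corr(targets[[nm]], scz[[covar]])
        rows[[paste(nm, covar)]] <- data.frame(
          target = nm, covariate = covar, r = ct$r, p = ct$test$p)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    write_tsv_schema(tab, file.path(config$out_dir, "clinical_correlations.tsv"))
    with_manifest(tab, n_rows = nrow(tab))
  })

  say("stage: genotype QC")
  qc <- run_stage("qc", function() {
    res <- qc_genotypes(state$genotypes, state$cohort)
    write_tsv_schema(res$report, file.path(config$out_dir, "qc_report.tsv"))
    with_manifest(res, n_snps_kept = ncol(res$genotypes$dosage))
  })

  say("stage: per-region association scans")
  assoc <- run_stage("assoc", function() {
    tables <- list()
    for (r in ranking$top_k) {
      phen <- derive_ba_phenotype(volumes, state$cohort, r,
                                  alpha = config$alpha_case)
      if (length(phen$case_ids) == 0) {
        warning(sprintf("region %d: no cases selected; scan skipped", r))
        next
      }
      tab <- assoc_scan(qc$genotypes, phen, threshold = config$gwas_threshold)
      write_assoc_tsv(tab, file.path(config$out_dir,
                                     sprintf("assoc_region_%02d.tsv", r)))
      tables[[as.character(r)]] <- tab
    }
    shared <- shared_snp_table(tables)
    write_tsv_schema(shared, file.path(config$out_dir, "shared_snps.tsv"))

    # positional SNP-to-gene mapping of every significant SNP
    annotation <- generate_gene_annotation(sim)
    sig <- do.call(rbind, lapply(tables, function(t) {
      t[t$SIGNIFICANT, c("SNP", "CHR", "BP"), drop = FALSE]
    }))
    mapping <- if (!is.null(sig) && nrow(sig)) {
      map_snps_to_genes(unique(sig), annotation, window_kb = 10,
                        significant_only = FALSE)
    } else {
      list(mapped = data.frame(SNP = character(0), CHR = integer(0),
                               BP = integer(0), gene = character(0)),
           unmapped = character(0))
    }
    write_tsv_schema(mapping$mapped,
                     file.path(config$out_dir, "mapped_genes.tsv"))
    with_manifest(list(tables = tables, shared = shared,
                       mapping = mapping, annotation = annotation),
                  n_regions_scanned = length(tables),
                  n_significant_snps = nrow(shared),
                  n_mapped_genes = length(unique(mapping$mapped$gene)))
  })

  say("stage: PRS per region")
  prs <- run_stage("prs", function() {
    prepared <- prepare_sumstats(state$sumstats, qc$genotypes)
    clumped <- ld_clump(prepared, qc$genotypes)
    results <- list()
    rows <- list()
    for (r in ranking$top_k) {
      phen <- derive_ba_phenotype(volumes, state$cohort, r,
                                  alpha = config$alpha_case)
      ids <- c(phen$case_ids, phen$control_ids)
      ids <- intersect(ids, rownames(qc$genotypes$dosage))
      y <- setNames(as.numeric(ids %in% phen$case_ids), ids)
      if (length(unique(y)) < 2) next
      res <- prs_scan(qc$genotypes, clumped, y, grid = config$prs_grid)
      cmp <- tryCatch(compare_groups(res), areascan_error = function(e) NULL)
      results[[as.character(r)]] <- list(scan = res, comparison = cmp)
      write_prs_tsv(res, file.path(config$out_dir, sprintf("prs_region_%02d", r)))
      rows[[as.character(r)]] <- data.frame(
        region = r, best_threshold = res$best_threshold, r2 = res$best_r2,
        n_cases = sum(y == 1), n_controls = sum(y == 0),
        welch_p = if (is.null(cmp)) NA_real_ else cmp$p)
    }
    summary <- do.call(rbind, rows)
    rownames(summary) <- NULL
    write_tsv_schema(summary, file.path(config$out_dir, "prs_summary.tsv"))
    with_manifest(list(results = results, summary = summary,
                       clumped = clumped),
                  n_regions = length(results),
                  mean_r2 = mean(summary$r2))
  })

  say("stage: expression statistics")
  expr <- run_stage("expression", function() {
    fx <- state$expr
    ratios <- positive_cell_ratio(fx$expression,
                                  rownames(fx$expression$counts))
    ratio_df <- data.frame(gene = rownames(ratios), ratios,
                           check.names = FALSE)
    write_tsv_schema(ratio_df, file.path(config$out_dir,
                                         "positive_cell_ratios.tsv"))
    patterns <- classify_ish_panel(fx$ish, delta = config$delta)
    write_tsv_schema(patterns, file.path(config$out_dir, "ish_patterns.tsv"))
    recovery <- mean(patterns$pattern == fx$design$ish_truth$pattern)
    with_manifest(list(ratios = ratios, patterns = patterns,
                       recovery = recovery),
                  pattern_recovery = recovery)
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: %s", config$out_dir)
  invisible(list(state = state, whole_brain = whole, vbm = vbm,
                 ranking = ranking, volumes = volumes, clinical = clinical,
                 qc = qc, assoc = assoc, prs = prs, expression = expr,
                 manifest = manifest))
}
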