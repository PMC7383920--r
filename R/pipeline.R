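#' Pipeline configuration
#'
#' Collects every stage's tuning parameter with defaults equal to the
#' conventional settings of this analysis: 1 cM scan step, PIN 0.001,
#' LOD threshold 2.5, 1000 permutations, replicate support 2 of 3,
#' 10 cM hotspot bins at genome-wide P = 0.01, network P < 0.01,
#' 10-fold cross-validation.
#'
#' @param ... Overrides of the defaults (unknown names are an error).
#'   `config` may also be a YAML file path via [read_pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preset = "paper",        # synthetic preset when no input paths given
    out_dir = NULL,
    seed = 1,
    scan_step = 1,
    pin = 0.001,
    lod_threshold = 2.5,
    cofactor_window_cM = 10,
    n_perm = 1000,
    min_support = 2,
    hotspot_bin_cM = 10,
    hotspot_alpha = 0.01,
    network_p = 0.01,
    cv_folds = 10,
    stages = c("simulate", "stats", "scan", "consolidate", "hotspots",
               "coloc", "predict")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys are config fields.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# scan every column of a lines x traits matrix and call QTL
scan_trait_set <- function(genotypes, map, Y, genoprob, cfg,
                           label = colnames(Y)) {
  recs <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- stats::setNames(Y[, j], rownames(Y))
    cof <- select_cofactors(genotypes, y, pin = cfg$pin)
    prof <- icim_scan(genotypes, map, y, cofactors = cof,
                      step = cfg$scan_step,
                      window_cM = cfg$cofactor_window_cM,
                      genoprob = genoprob)
    recs[[j]] <- call_qtl(prof, map, lod_threshold = cfg$lod_threshold,
                          trait_id = label[j])
  }
  qtl_table(do.call(rbind, lapply(recs, as.data.frame)))
}

#' Run the full mQTL analysis pipeline
#'
#' Orchestrates simulate -> descriptive stats -> per-replicate ICIM
#' scans -> replicate consolidation -> hotspot permutation test ->
#' mQTL-pQTL colocalization with correlation cross-referencing ->
#' BLUP/LASSO trait prediction, under one master seed with per-stage
#' substreams. When `config$out_dir` is set, every table is written
#' there as TSV together with a machine-readable `summary.json` and the
#' serialized config; re-running with the same config and seed
#' reproduces the outputs.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]).
#' @param data Optional pre-built study list as returned by
#'   [sim_ril_study()] (fields `map`, `genotypes`, `metabolome`,
#'   `agronomic`, optionally truth tables); when NULL the `simulate`
#'   stage generates one from `config$preset`.
#' @return Invisibly, a list with every stage output plus `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "pipeline_config"))
  res <- list(config = cfg)
  if (is.null(data)) {
    if (!"simulate" %in% cfg$stages)
      stop("stage 'simulate' disabled but no input data supplied")
    message("stage simulate: preset '", cfg$preset, "'")
    data <- sim_ril_study(cfg$preset, seed = cfg$seed)
  }
  res$data <- data
  map <- data$map; geno <- data$genotypes
  met_log <- log2_transform(data$metabolome)
  agro_mat <- trait_matrix(data$agronomic)
  met_mat_log <- trait_matrix(met_log)

  if ("stats" %in% cfg$stages) {
    message("stage stats: CV, H2, correlation network")
    res$cv <- coefficient_of_variation(data$metabolome)
    res$h2 <- broad_sense_heritability(met_log)
    res$edges <- pairwise_correlation(met_mat_log, agro_mat,
                                      method = "pearson")
    res$network <- build_network(res$edges, p_threshold = cfg$network_p)
  }

  if (any(c("scan", "consolidate", "hotspots", "coloc") %in% cfg$stages)) {
    gp <- scan_genoprob(geno, map, step = cfg$scan_step)
    reps <- sort(unique(met_log$replicate_id))
    message("stage scan: ", length(unique(met_log$trait_id)),
            " metabolites x ", length(reps), " replicates")
    res$mqtl_by_replicate <- lapply(reps, function(r)
      scan_trait_set(geno, map, trait_matrix(met_log, replicate = r),
                     gp, cfg))
    message("stage scan: ", ncol(agro_mat), " agronomic traits")
    res$pqtl <- scan_trait_set(geno, map, agro_mat, gp, cfg)
  }

  if (any(c("consolidate", "hotspots", "coloc") %in% cfg$stages)) {
    res$mqtl <- consolidate_replicates(res$mqtl_by_replicate,
                                       min_support = cfg$min_support)
    message("stage consolidate: ", nrow(res$mqtl), " reproducible mQTL")
    if (nrow(res$mqtl) >= 2)
      res$chrom_test <- tryCatch(
        chromosome_distribution_test(res$mqtl, map), error = function(e) NULL)
  }

  if ("hotspots" %in% cfg$stages) {
    bins <- genome_bins(map, cfg$hotspot_bin_cM)
    res$hotspot_cutoff <- if (nrow(res$mqtl))
      hotspot_cutoff(nrow(res$mqtl), bins, n_perm = cfg$n_perm,
                     alpha = cfg$hotspot_alpha,
                     seed = stage_seed(cfg$seed, "permutation")) else NA
    res$hotspots <- if (nrow(res$mqtl))
      call_hotspots(res$mqtl, map, cfg$hotspot_bin_cM, res$hotspot_cutoff)
      else bins[0, ]
    message("stage hotspots: cutoff ", as.integer(res$hotspot_cutoff),
            ", ", nrow(res$hotspots), " hotspot bin(s)")
  }

  if ("coloc" %in% cfg$stages) {
    if (is.null(res$edges))
      res$edges <- pairwise_correlation(met_mat_log, agro_mat,
                                        method = "pearson")
    res$coloc <- colocalize(res$mqtl, res$pqtl)
    res$coloc <- cross_reference(res$coloc, res$edges,
                                 p_threshold = cfg$network_p)
    message("stage coloc: ", nrow(res$coloc), " pair(s), ",
            sum(res$coloc$correlated), " correlated")
  }

  if ("predict" %in% cfg$stages) {
    message("stage predict: BLUP/LASSO, ", cfg$cv_folds, "-fold CV")
    K <- build_kernel(met_mat_log)
    fold_seed <- stage_seed(cfg$seed, "folds")
    res$predictions <- do.call(rbind, lapply(colnames(agro_mat), function(tr) {
      y <- stats::setNames(agro_mat[, tr], rownames(agro_mat))
      b <- blup_cv(K, y, k_folds = cfg$cv_folds, seed = fold_seed,
                   trait_id = tr)
      l <- lasso_cv(met_mat_log, y, k_folds = cfg$cv_folds,
                    seed = fold_seed, trait_id = tr)
      data.frame(trait_id = tr, blup = b$predictability,
                 lasso = l$predictability,
                 lasso_n_features = nrow(l$selected_features),
                 stringsAsFactors = FALSE)
    }))
  }

  res$summary <- pipeline_summary(res)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  invisible(res)
}

pipeline_summary <- function(res) {
  s <- list(seed = res$config$seed, preset = res$config$preset)
  if (!is.null(res$h2)) {
    s$n_metabolites <- length(res$h2)
    s$mean_h2 <- mean(res$h2)
    s$mean_cv_percent <- mean(res$cv, na.rm = TRUE)
    s$n_network_edges <- nrow(res$network$edges)
  }
  if (!is.null(res$mqtl)) {
    s$n_mqtl <- nrow(res$mqtl)
    s$mean_mqtl_pve <- if (nrow(res$mqtl)) mean(res$mqtl$PVE) else NA
    s$n_major_mqtl <- sum(res$mqtl$is_major)
  }
  if (!is.null(res$pqtl)) s$n_pqtl <- nrow(res$pqtl)
  if (!is.null(res$hotspots)) {
    s$hotspot_cutoff <- as.integer(res$hotspot_cutoff)
    s$n_hotspots <- nrow(res$hotspots)
  }
  if (!is.null(res$coloc)) {
    s$n_coloc_pairs <- nrow(res$coloc)
    s$n_coloc_correlated <- sum(res$coloc$correlated)
  }
  if (!is.null(res$predictions)) {
    s$mean_predictability_blup <- mean(res$predictions$blup)
    s$mean_predictability_lasso <- mean(res$predictions$lasso)
  }
  s
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  cfg <- res$config
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   fp("config.yaml"))
  write_genotypes(res$data$genotypes, res$data$map, fp("genotypes.tsv"))
  write_traits(res$data$metabolome, fp("metabolome.tsv"))
  write_traits(res$data$agronomic, fp("agronomic.tsv"))
  if (!is.null(res$data$truth_metabolome))
    utils::write.table(res$data$truth_metabolome$planted_qtl,
                       fp("truth_planted_mqtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$h2)) {
    utils::write.table(
      data.frame(trait_id = names(res$h2), H2 = res$h2,
                 CV_percent = res$cv[names(res$h2)], row.names = NULL),
      fp("trait_stats.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_network_sif(res$network$edges, fp("network.sif"))
  }
  if (!is.null(res$mqtl)) write_qtl_table(res$mqtl, fp("mqtl.tsv"))
  if (!is.null(res$pqtl)) write_qtl_table(res$pqtl, fp("pqtl.tsv"))
  if (!is.null(res$hotspots))
    utils::write.table(res$hotspots, fp("hotspots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$coloc))
    utils::write.table(res$coloc, fp("coloc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$predictions))
    utils::write.table(res$predictions, fp("predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
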