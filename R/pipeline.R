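# Pipeline orchestration: configuration, report writers with atomic
# temp-then-rename output, a machine-readable run manifest, and the
# subcommand entry points binding the stages end to end.

#' Build a pipeline configuration
#'
#' All analysis thresholds are configuration keys defaulting to the audit's
#' standard values: the 1,000,000-occurrence class-inclusion cutoff
#' (scalable for synthetic runs), the 20-occurrence "decent sampling" rule,
#' the 0.5% ventilation threshold, the 5% significance threshold and the
#' Q3 + 4 IQR outlier rule.
#'
#' @param occurrences,backbone,covariates input file paths (occurrence and
#'   backbone dialects of [read_occurrences()] / [read_backbone()]).
#' @param out_dir output directory for reports and the manifest.
#' @param min_class_occ minimum occurrences for a class to enter the audit.
#' @param export_year snapshot year for the temporal analysis.
#' @param checkpoints decadal checkpoint years.
#' @param distinct_threshold occurrences needed for "decent" sampling.
#' @param cell_size equal-area grid cell edge (m).
#' @param mca_sample_size,mca_seed MCA subsample controls.
#' @param ventilation_threshold rare-category share for [ventilate()].
#' @param glm_n_target,glm_seed,glm_transform,outlier_multiplier model-stage
#'   controls.
#' @param seed master seed recorded in the manifest and used by
#'   [run_simulate()].
#' @param synth a [synth_config()] for [run_simulate()] (built from `seed`
#'   when omitted).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    occurrences = NULL, backbone = NULL, covariates = NULL,
    out_dir = tempfile("occbias_out_"),
    min_class_occ = 1e6, export_year = 2016L,
    checkpoints = seq(1956L, 2006L, by = 10L),
    distinct_threshold = 20L, cell_size = 10000,
    mca_sample_size = NULL, mca_seed = 1L,
    ventilation_threshold = 0.005,
    glm_n_target = 1000L, glm_seed = 1L, glm_transform = "log1p",
    outlier_multiplier = 4, seed = 1L, synth = NULL) {
  if (export_year < max(checkpoints)) {
    stop("export_year must be >= the last checkpoint")
  }
  cfg <- list(
    occurrences = occurrences, backbone = backbone, covariates = covariates,
    out_dir = out_dir, min_class_occ = min_class_occ,
    export_year = as.integer(export_year),
    checkpoints = as.integer(checkpoints),
    distinct_threshold = as.integer(distinct_threshold),
    cell_size = cell_size, mca_sample_size = mca_sample_size,
    mca_seed = as.integer(mca_seed),
    ventilation_threshold = ventilation_threshold,
    glm_n_target = as.integer(glm_n_target),
    glm_seed = as.integer(glm_seed), glm_transform = glm_transform,
    outlier_multiplier = outlier_multiplier, seed = as.integer(seed),
    synth = if (is.null(synth)) synth_config(seed = seed) else synth
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# Atomic CSV write: temp file in the target directory, then rename, so no
# report exists in a half-written state.
write_atomic <- function(dt, path) {
  tmp <- tempfile("part_", dirname(path), fileext = ".tmp")
  fwrite(as.data.table(dt), tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE); unlink(tmp)
  }
  invisible(path)
}

write_manifest <- function(cfg, extra, path) {
  keep <- cfg[setdiff(names(cfg), "synth")]
  keep <- keep[!vapply(keep, is.null, TRUE)]
  manifest <- c(
    keep,
    list(config_hash = sum(utf8ToInt(paste(
      utils::capture.output(utils::str(keep)), collapse = ""))) %% 1e9),
    extra
  )
  tmp <- tempfile("manifest_", dirname(path))
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Generate synthetic fixtures on disk
#'
#' Writes a backbone, an occurrence table and a coupled covariate table in
#' the pipeline dialects under `cfg$out_dir`, plus a manifest recording the
#' seed and configuration.
#'
#' @param cfg a [pipeline_config()].
#' @return named paths of the written files, invisibly.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message("simulate: seed ", cfg$synth$seed)
  bb <- gen_backbone(cfg$synth)
  occ <- gen_occurrences(cfg$synth, bb)
  cov <- gen_covariates(cfg$synth, bb, mode = "coupled")
  paths <- c(
    backbone = file.path(cfg$out_dir, "backbone.tsv"),
    occurrences = file.path(cfg$out_dir, "occurrences.tsv"),
    covariates = file.path(cfg$out_dir, "covariates.tsv")
  )
  write_backbone(bb, paths["backbone"])
  write_occurrences(occ, paths["occurrences"])
  write_covariates(cov, paths["covariates"])
  write_manifest(cfg, list(
    stage = "simulate", n_records = nrow(occ),
    truth = as.data.frame(attr(occ, "truth"))
  ), file.path(cfg$out_dir, "manifest_simulate.json"))
  invisible(paths)
}

# Shared loader with the class-inclusion filter applied; returns records,
# backbone and the excluded-class tally.
.load_inputs <- function(cfg) {
  if (is.null(cfg$occurrences) || is.null(cfg$backbone)) {
    stop("configuration error: 'occurrences' and 'backbone' paths are required")
  }
  records <- read_occurrences(cfg$occurrences)
  backbone <- read_backbone(cfg$backbone)
  sizes <- records[nzchar(class_name), .N, by = class_name]
  keep <- sizes$class_name[sizes$N >= cfg$min_class_occ]
  excluded <- sizes[!class_name %in% keep]
  list(
    records = records[class_name %in% keep],
    backbone = backbone[class_name %in% keep],
    excluded = excluded,
    tallies = attr(records, "tallies")
  )
}

#' Run the occurrence audit stage
#'
#' Produces the per-class (and optionally per-order) summary reports, the
#' temporal deviations report, the species occurrence-count histogram, and
#' a manifest with seeds and row tallies.  Classes below the inclusion
#' threshold are excluded and listed in the manifest.
#'
#' @param cfg a [pipeline_config()].
#' @param order_classes classes for which order-level summaries are also
#'   computed (default none).
#' @return list with `class_summary`, `order_summary`, `deviations`,
#'   `histogram`, invisibly; reports are written under `cfg$out_dir`.
#' @export
run_audit <- function(cfg, order_classes = character()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(cfg)
  message("audit: ", nrow(inp$records), " records in ",
          length(unique(inp$records$class_name)), " classes")
  summ <- summarize_taxa(inp$records, inp$backbone, level = "class",
                         cell_size = cfg$cell_size,
                         distinct_threshold = cfg$distinct_threshold)
  dev <- temporal_deviations(inp$records, inp$backbone,
                             checkpoints = cfg$checkpoints,
                             export_year = cfg$export_year)
  per_sp <- inp$records[nzchar(species), .N, by = species]
  hist <- occurrence_class_histogram(per_sp$N)
  hist_dt <- data.table(bin = names(hist), share = as.numeric(hist))
  ord <- NULL
  if (length(order_classes)) {
    ord <- summarize_taxa(
      inp$records[class_name %in% order_classes],
      inp$backbone[class_name %in% order_classes],
      level = "order", cell_size = cfg$cell_size,
      distinct_threshold = cfg$distinct_threshold
    )
  }
  write_atomic(summ, file.path(cfg$out_dir, "class_summary.csv"))
  write_atomic(dev, file.path(cfg$out_dir, "deviations.csv"))
  write_atomic(hist_dt, file.path(cfg$out_dir, "histogram.csv"))
  if (!is.null(ord)) {
    write_atomic(ord, file.path(cfg$out_dir, "order_summary.csv"))
  }
  write_manifest(cfg, list(
    stage = "audit", n_records = nrow(inp$records),
    skip_tallies = as.list(inp$tallies),
    excluded_classes = as.data.frame(inp$excluded)
  ), file.path(cfg$out_dir, "manifest_audit.json"))
  invisible(list(class_summary = summ, order_summary = ord,
                 deviations = dev, histogram = hist))
}

#' Run the record-quality MCA stage
#'
#' Builds the categorical table (class, year bin, origin, completeness),
#' runs the analysis once as-is and once after rare-category ventilation,
#' and writes eigenvalue, category-coordinate and class-barycentre reports
#' for both runs.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `raw` and `ventilated` fits plus barycentres,
#'   invisibly.
#' @export
run_mca <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(cfg)
  tab <- mca_table(inp$records, sample_size = cfg$mca_sample_size,
                   seed = cfg$mca_seed)
  message("mca: ", nrow(tab), " rows")
  res <- list()
  for (variant in c("raw", "ventilated")) {
    vt <- if (variant == "ventilated") {
      ventilate(tab, threshold = cfg$ventilation_threshold,
                seed = cfg$mca_seed)
    } else tab
    fit <- fit_mca(vt)
    bary <- class_barycentres(fit, vt$class)
    coords <- data.table(category = rownames(fit$col_coords),
                         fit$col_coords[, 1:min(2, ncol(fit$col_coords)),
                                        drop = FALSE])
    setnames(coords, c("category", paste0("axis", seq_len(ncol(coords) - 1))))
    write_atomic(
      data.table(axis = seq_along(fit$eigenvalues),
                 eigenvalue = fit$eigenvalues,
                 inertia_share = fit$inertia_share),
      file.path(cfg$out_dir, paste0("mca_eigenvalues_", variant, ".csv"))
    )
    write_atomic(coords,
                 file.path(cfg$out_dir, paste0("mca_categories_", variant, ".csv")))
    write_atomic(bary,
                 file.path(cfg$out_dir, paste0("mca_barycentres_", variant, ".csv")))
    res[[variant]] <- list(fit = fit, barycentres = bary)
  }
  write_manifest(cfg, list(stage = "mca", n_rows = nrow(tab)),
                 file.path(cfg$out_dir, "manifest_mca.json"))
  invisible(res)
}

#' Run the covariate model stage
#'
#' Fits the per-class negative-binomial battery on the covariate table and
#' writes the model report (one row per class and selection).
#'
#' @param cfg a [pipeline_config()]; `covariates` must point to a table in
#'   the [write_covariates()] dialect.
#' @return the [glm_battery()] result, invisibly.
#' @export
run_glm <- function(cfg) {
  if (is.null(cfg$covariates)) {
    stop("configuration error: 'covariates' path is required for the model stage")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cov <- read_covariates(cfg$covariates)
  message("glm: ", nrow(cov), " species in ",
          length(unique(cov$class_name)), " classes")
  res <- glm_battery(cov, n_target = cfg$glm_n_target, seed = cfg$glm_seed,
                     transform = cfg$glm_transform,
                     multiplier = cfg$outlier_multiplier)
  write_atomic(res$table, file.path(cfg$out_dir, "glm_results.csv"))
  write_manifest(cfg, list(stage = "glm", n_species = nrow(cov)),
                 file.path(cfg$out_dir, "manifest_glm.json"))
  invisible(res)
}

#' Run every stage end to end
#'
#' simulate (when no input paths are configured), then audit, MCA and the
#' model battery, sharing one output directory.
#'
#' @param cfg a [pipeline_config()].
#' @return list of stage results, invisibly.
#' @export
report_all <- function(cfg) {
  if (is.null(cfg$occurrences)) {
    paths <- run_simulate(cfg)
    cfg$occurrences <- unname(paths["occurrences"])
    cfg$backbone <- unname(paths["backbone"])
    cfg$covariates <- unname(paths["covariates"])
  }
  invisible(list(
    audit = run_audit(cfg),
    mca = run_mca(cfg),
    glm = run_glm(cfg)
  ))
}

#' Command-line entry point
#'
#' Usage: `Rscript -e 'occbias::occbias_main()' <subcommand> [--key value ...]`
#' with subcommands `simulate`, `audit`, `mca`, `glm`, `report-all`.
#' Recognized flags: `--occurrences`, `--backbone`, `--covariates`, `--out`,
#' `--seed`, `--min-class-occ`, `--mca-sample-size`, `--glm-n-target`.
#'
#' @param args character vector (default: the command line).
#' @return exit status 0 invisibly; configuration errors stop.
#' @export
occbias_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: occbias <simulate|audit|mca|glm|report-all> [--key value ...]")
  }
  cmd <- args[1]
  kv <- list()
  rest <- args[-1]
  while (length(rest) >= 2L) {
    if (!startsWith(rest[1], "--")) stop("unexpected argument: ", rest[1])
    kv[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  cfg <- pipeline_config(
    occurrences = kv[["occurrences"]], backbone = kv[["backbone"]],
    covariates = kv[["covariates"]],
    out_dir = if (is.null(kv[["out"]])) "occbias_out" else kv[["out"]],
    min_class_occ = if (is.null(kv[["min-class-occ"]])) 1e6
      else num(kv[["min-class-occ"]]),
    mca_sample_size = num(kv[["mca-sample-size"]]),
    glm_n_target = if (is.null(kv[["glm-n-target"]])) 1000L
      else as.integer(kv[["glm-n-target"]]),
    seed = if (is.null(kv[["seed"]])) 1L else as.integer(kv[["seed"]])
  )
  switch(
    cmd,
    "simulate" = run_simulate(cfg),
    "audit" = run_audit(cfg),
    "mca" = run_mca(cfg),
    "glm" = run_glm(cfg),
    "report-all" = report_all(cfg),
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

#' Load the packaged snapshot-level class summary table
#'
#' A transcription of published summary statistics for the 24 taxonomic
#' classes holding at least one million occurrences in the June 2016 GBIF
#' snapshot: per class, total occurrences (millions), recorded species
#' (thousands), median and raw MAD of occurrences per species, and
#' taxonomic precision.  Used to reproduce portal-scale headline statistics
#' without the 626-million-record download.
#'
#' @return list with `classes` (per-class `data.table`, including absolute
#'   `nb_occ` and `n_sp` columns) and `globals` (named vector: portal
#'   totals and the species occurrence-count tallies).
#' @export
gbif2016_snapshot <- function() {
  cls <- fread(system.file("extdata", "gbif2016_class_summary.tsv",
                           package = "occbias"), sep = "\t")
  cls[, taxon := class]
  cls[, nb_occ := nb_occ_millions * 1e6]
  cls[, n_sp := n_sp_thousands * 1e3]
  gl <- fread(system.file("extdata", "gbif2016_global_counts.tsv",
                          package = "occbias"), sep = "\t")
  list(classes = cls[], globals = setNames(gl$value, gl$key))
}
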