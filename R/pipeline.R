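#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end meta-analysis: input paths,
#' contrast definition, normalization parameters, the absence filter
#' threshold, meta-analysis significance settings, ORA bounds and network
#' parameters. `config` may be written to / read from a flat YAML file.
#'
#' @param array_expression,rnaseq_expression paths to the two expression
#'   TSVs.
#' @param metadata path to the pooled sample-metadata TSV.
#' @param array_idmap,rnaseq_idmap optional probe/transcript-to-gene map
#'   TSVs; when `NULL` the matrix is assumed gene-keyed already.
#' @param gmt optional GMT gene-set file for ORA.
#' @param edges optional PPI edge-list TSV.
#' @param region which region's samples enter the contrast.
#' @param case_label,control_label group labels defining the contrast.
#' @param absent_threshold pooled absence fraction above which a gene is
#'   removed.
#' @param normalization a [normalization_config()].
#' @param meta_alpha meta-gene significance threshold.
#' @param meta_use_adjusted apply `meta_alpha` to BH-adjusted combined p.
#' @param ora_size_range within-universe set-size bounds for ORA.
#' @param network_order `"zero"` or `"first"` order subnetwork.
#' @param rwr_restart restart probability of the random-walk ranking.
#' @param top_k rows kept in the top-gene / top-pathway report.
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(array_expression, rnaseq_expression, metadata,
                            array_idmap = NULL, rnaseq_idmap = NULL,
                            gmt = NULL, edges = NULL,
                            region = "macular",
                            case_label = "case", control_label = "control",
                            absent_threshold = 0.8,
                            normalization = normalization_config(),
                            meta_alpha = 0.05, meta_use_adjusted = TRUE,
                            ora_size_range = c(5, 2000),
                            network_order = "zero", rwr_restart = 0.5,
                            top_k = 20, outdir = "transmeta_out",
                            seed = 1L) {
  if (meta_alpha <= 0 || meta_alpha >= 1) stop("meta_alpha must be in (0, 1)")
  cfg <- list(array_expression = array_expression,
              rnaseq_expression = rnaseq_expression, metadata = metadata,
              array_idmap = array_idmap, rnaseq_idmap = rnaseq_idmap,
              gmt = gmt, edges = edges, region = region,
              case_label = case_label, control_label = control_label,
              absent_threshold = absent_threshold,
              normalization = normalization,
              meta_alpha = meta_alpha,
              meta_use_adjusted = meta_use_adjusted,
              ora_size_range = ora_size_range,
              network_order = network_order, rwr_restart = rwr_restart,
              top_k = top_k, outdir = outdir, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  norm <- do.call(normalization_config, y$normalization %||% list())
  y$normalization <- NULL
  do.call(pipeline_config, c(y, list(normalization = norm)))
}

#' @rdname read_pipeline_config
#' @param config a `PipelineConfig` to write.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$normalization <- unclass(y$normalization)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## rolling polynomial hash of the serialized configuration (provenance tag);
## outdir is excluded so reruns into different directories share a hash
config_hash <- function(config) {
  u <- unclass(config)
  u$outdir <- NULL
  s <- paste(deparse(u), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

subset_region <- function(study, region) {
  keep <- study$samples$region == region
  if (sum(keep) < 4) stop("fewer than 4 samples in region '", region, "'")
  study$values <- study$values[, keep, drop = FALSE]
  study$samples <- study$samples[keep, , drop = FALSE]
  study
}

relabel_groups <- function(study, case_label, control_label) {
  grp <- study$samples$group
  if (!all(grp %in% c(case_label, control_label)))
    stop("unexpected group label(s): ",
         paste(setdiff(unique(grp), c(case_label, control_label)),
               collapse = ", "))
  study$samples$group <- ifelse(grp == case_label, "case", "control")
  study
}

#' Run the full cross-platform meta-analysis pipeline
#'
#' harmonize -> absence filter -> platform-specific normalization ->
#' per-study moderated-t DE -> ComBat merge with PCA diagnostics ->
#' Fisher meta-analysis with BH adjustment -> overlap accounting ->
#' optional ORA and PPI hub ranking. All stage outputs are written under
#' `config$outdir` together with a JSON manifest (parameters, per-stage
#' gene/sample counts, wall times) and a plain-text report.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  hash <- config_hash(config)
  manifest <- list(package_version = as.character(utils::packageVersion("transmeta")),
                   config_hash = hash, seed = config$seed,
                   parameters = list(alpha = config$meta_alpha,
                                     use_adjusted = config$meta_use_adjusted,
                                     absent_threshold = config$absent_threshold,
                                     region = config$region),
                   stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- c(manifest$stages[[name]],
                                  list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    res
  }
  log_msg <- function(...) message("[transmeta] ", ...)

  md <- read_sample_metadata(config$metadata)
  md_for <- function(path) {
    ids <- scan_header(path)
    miss <- setdiff(ids, md$sample)
    if (length(miss)) stop("samples missing from metadata: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    md[match(ids, md$sample), , drop = FALSE]
  }
  arr <- stage("read", read_expression(config$array_expression, "microarray",
                                       md_for(config$array_expression)))
  rna <- read_expression(config$rnaseq_expression, "rnaseq",
                         md_for(config$rnaseq_expression))
  arr <- subset_region(relabel_groups(arr, config$case_label,
                                      config$control_label), config$region)
  rna <- subset_region(relabel_groups(rna, config$case_label,
                                      config$control_label), config$region)

  harmonized <- stage("harmonize", {
    if (!is.null(config$array_idmap))
      arr <- collapse_to_genes(arr, read_id_map(config$array_idmap))
    if (!is.null(config$rnaseq_idmap))
      rna <- collapse_to_genes(rna, read_id_map(config$rnaseq_idmap))
    intersect_universe(arr, rna)
  })
  manifest$stages$harmonize$genes <- nrow(harmonized$a$values)

  filtered <- stage("filter_absent",
                    filter_absent(harmonized$a, harmonized$b,
                                  config$absent_threshold))
  manifest$stages$filter_absent$removed <- length(filtered$removed)
  manifest$stages$filter_absent$genes <- nrow(filtered$a$values)
  log_msg(length(filtered$removed), " gene(s) removed by the absence filter")

  norm <- stage("normalize", list(
    array = vst_array(filtered$a, config$normalization),
    rnaseq = log_cpm(filtered$b, config$normalization)))
  write_expression(norm$array,
                   file.path(config$outdir, "array_normalized.tsv"),
                   comments = c(paste("config", hash),
                                attr(norm$array, "method")))
  write_expression(norm$rnaseq,
                   file.path(config$outdir, "rnaseq_logcpm.tsv"),
                   comments = c(paste("config", hash),
                                attr(norm$rnaseq, "method")))

  de <- stage("de", list(array = run_de(norm$array),
                         rnaseq = run_de(norm$rnaseq)))
  write_de(de$array, file.path(config$outdir, "de_array.tsv"))
  write_de(de$rnaseq, file.path(config$outdir, "de_rnaseq.tsv"))
  manifest$stages$de$genes <- nrow(de$array)
  manifest$stages$de$sig_array <- sum(de$array$p_adj < config$meta_alpha)
  manifest$stages$de$sig_rnaseq <- sum(de$rnaseq$p_adj < config$meta_alpha)

  diag <- stage("batch_adjust", {
    merged <- merge_studies(norm$array, norm$rnaseq)
    before <- pca_report(merged$values, merged$samples$study)
    cb <- combat_adjust(merged)
    after <- pca_report(cb$adjusted$values, merged$samples$study)
    write_expression(cb$adjusted,
                     file.path(config$outdir, "merged_combat.tsv"),
                     comments = paste("config", hash))
    list(before = before, after = after)
  })
  manifest$stages$batch_adjust$silhouette_before <- diag$before$silhouette
  manifest$stages$batch_adjust$silhouette_after <- diag$after$silhouette
  jsonlite::write_json(
    list(var_explained = diag$after$var_explained[1:5],
         silhouette_before = diag$before$silhouette,
         silhouette_after = diag$after$silhouette),
    file.path(config$outdir, "pca_summary.json"), auto_unbox = TRUE,
    digits = NA)

  meta <- stage("meta_fisher", meta_records(de$array, de$rnaseq))
  sig <- call_meta_genes(meta, config$meta_alpha, config$meta_use_adjusted)
  sig <- sig[sig$effect != "ambiguous", , drop = FALSE]
  write_meta_table(meta, file.path(config$outdir, "meta_genes_all.tsv"),
                   comments = paste("config", hash))
  write_meta_table(sig, file.path(config$outdir, "meta_genes_significant.tsv"),
                   comments = paste("config", hash))
  manifest$stages$meta_fisher$genes <- nrow(meta)
  manifest$stages$meta_fisher$significant <- nrow(sig)
  manifest$stages$meta_fisher$up <- sum(sig$effect == "Up-regulated")
  manifest$stages$meta_fisher$down <- sum(sig$effect == "Down-regulated")

  vc <- venn_counts(de$array$gene[de$array$p_adj < config$meta_alpha],
                    de$rnaseq$gene[de$rnaseq$p_adj < config$meta_alpha],
                    sig$gene)
  jsonlite::write_json(unclass(vc),
                       file.path(config$outdir, "venn_counts.json"),
                       auto_unbox = TRUE)
  manifest$stages$meta_fisher$newly_detected <- vc$newly_detected

  if (!is.null(config$gmt)) {
    ora <- stage("ora", {
      coll <- read_gmt(config$gmt, universe = meta$gene)
      ora_test(sig$gene, coll, size_range = config$ora_size_range)
    })
    write_ora(ora, file.path(config$outdir, "ora_results.tsv"),
              comments = c(paste("config", hash),
                           sprintf("size_range %d..%d",
                                   config$ora_size_range[1],
                                   config$ora_size_range[2])))
    manifest$stages$ora$sets_tested <- nrow(ora)
    manifest$stages$ora$sets_fdr05 <- sum(ora$fdr < 0.05)
  }

  if (!is.null(config$edges)) {
    hubs <- stage("network", {
      ref <- read_edge_list(config$edges)
      sub <- build_subnetwork(sig$gene, ref, config$network_order)
      if (length(sub$nodes) == 0) NULL else {
        st <- node_stats(sub, seeds = intersect(sig$gene, sub$nodes),
                         restart = config$rwr_restart)
        write_edge_list(sub, file.path(config$outdir, "subnetwork_edges.tsv"))
        rank_hubs(st)
      }
    })
    if (!is.null(hubs)) {
      utils::write.table(hubs, file.path(config$outdir, "node_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$network$nodes <- nrow(hubs)
    } else manifest$stages$network$nodes <- 0L
  }

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_report(config, manifest, sig, de, config$outdir)
  invisible(manifest)
}

scan_header <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[!startsWith(lines, "#")]
  strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
}

write_report <- function(config, manifest, sig, de, outdir) {
  con <- file(file.path(outdir, "report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("transmeta run report (config %s, seed %d)", manifest$config_hash,
    config$seed)
  w("region: %s; alpha: %g (%s combined p)", config$region,
    config$meta_alpha,
    if (config$meta_use_adjusted) "BH-adjusted" else "raw")
  w("genes analyzed: %d; removed by absence filter: %d",
    manifest$stages$meta_fisher$genes,
    manifest$stages$filter_absent$removed)
  w("per-study DE (adjusted p < %g): array %d, rnaseq %d",
    config$meta_alpha, manifest$stages$de$sig_array,
    manifest$stages$de$sig_rnaseq)
  w("meta-genes: %d (%d up, %d down); newly detected: %d",
    manifest$stages$meta_fisher$significant,
    manifest$stages$meta_fisher$up, manifest$stages$meta_fisher$down,
    manifest$stages$meta_fisher$newly_detected)
  w("batch silhouette before/after ComBat: %.3f / %.3f",
    manifest$stages$batch_adjust$silhouette_before,
    manifest$stages$batch_adjust$silhouette_after)
  w("")
  w("top meta-genes:")
  top <- utils::head(sig, config$top_k)
  for (i in seq_len(nrow(top)))
    w("  %-12s F_g=%9.3f  p_adj=%.3g  %s", top$gene[i], top$F_g[i],
      top$p_comb_adj[i], top$effect[i])
  invisible(NULL)
}
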