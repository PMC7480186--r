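#' Configuration for the dual-platform simulator
#'
#' Defines the study conditions emulated by [generate_dual_study()]: a
#' microarray-type case/control study and an RNA-seq-type case/control study
#' of the same tissue contrast, sharing one gene universe and one
#' differential-expression truth. Defaults mirror the structure of the
#' published AMD RPE/choroid macular contrast this pipeline was designed
#' around: ~18,000 genes, 41 vs 50 array samples and 26 vs 105 RNA-seq
#' samples.
#'
#' @param n_genes number of genes in the shared universe.
#' @param group_sizes integer vector of length 4: array cases, array
#'   controls, RNA-seq cases, RNA-seq controls.
#' @param de_fraction expected proportion of genes that are truly
#'   differentially expressed.
#' @param lfc_mean,lfc_sd mean and sd (log2 units) of the absolute true
#'   log-fold-change of DE genes.
#' @param discordant_fraction proportion of DE genes whose direction is
#'   flipped on the RNA-seq platform relative to the array platform.
#' @param array_noise_sd residual sd of log2 array intensities.
#' @param nb_dispersion negative-binomial dispersion of RNA-seq counts
#'   (variance = mu + dispersion * mu^2).
#' @param batch_shift_sd sd (log2 units) of the gene-wise between-study
#'   offset applied to all samples of the RNA-seq study.
#' @param dropout_fraction proportion of genes forced to zero in a random
#'   >80% subset of all samples (exercises the absence filter).
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return a validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 18000,
                              group_sizes = c(41, 50, 26, 105),
                              de_fraction = 0.05,
                              lfc_mean = 1.0,
                              lfc_sd = 0.4,
                              discordant_fraction = 0.05,
                              array_noise_sd = 0.7,
                              nb_dispersion = 0.1,
                              batch_shift_sd = 0.5,
                              dropout_fraction = 0.01,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              group_sizes = as.integer(group_sizes),
              de_fraction = de_fraction, lfc_mean = lfc_mean,
              lfc_sd = lfc_sd, discordant_fraction = discordant_fraction,
              array_noise_sd = array_noise_sd, nb_dispersion = nb_dispersion,
              batch_shift_sd = batch_shift_sd,
              dropout_fraction = dropout_fraction, seed = as.integer(seed))
  nums <- unlist(cfg[setdiff(names(cfg), "group_sizes")])
  if (any(!is.finite(nums)) || any(!is.finite(cfg$group_sizes)))
    stop("simulation parameters must be finite")
  props <- c(cfg$de_fraction, cfg$discordant_fraction, cfg$dropout_fraction)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]")
  if (cfg$n_genes < 1L || any(cfg$group_sizes < 2L))
    stop("n_genes must be positive and every group must have >= 2 samples")
  if (length(cfg$group_sizes) != 4L)
    stop("group_sizes must have length 4")
  if (cfg$array_noise_sd <= 0 || cfg$nb_dispersion <= 0 ||
      cfg$lfc_sd < 0 || cfg$batch_shift_sd < 0)
    stop("scale parameters must be positive")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a paired microarray and RNA-seq study with known DE truth
#'
#' Draws one shared truth table (which genes are differentially expressed,
#' in which direction, and with what log2 fold change on each platform),
#' then emits: a continuous-intensity array study with log-normal noise
#' around log-uniform gene baselines, and an integer-count RNA-seq study
#' with negative-binomial noise, uniformly varying library sizes (up to
#' 3-fold either way) and a gene-wise between-study batch offset. A small
#' configured fraction of genes is zeroed in a random >80% subset of all
#' samples of both studies so that the downstream absence filter has work
#' to do.
#'
#' @param config a [simulation_config()].
#' @param region region label written into the sample metadata.
#' @return list with elements `array` and `rnaseq` (two
#'   [expression_study()] objects over the same gene universe) and `truth`
#'   (data frame: `gene`, `is_de`, `true_direction`, `true_lfc_array`,
#'   `true_lfc_rnaseq`).
#' @export
generate_dual_study <- function(config = simulation_config(),
                                region = "macular") {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))

  ## shared truth
  is_de <- stats::runif(n) < config$de_fraction
  dir_arr <- ifelse(stats::runif(n) < 0.5, 1, -1)
  mag <- abs(stats::rnorm(n, config$lfc_mean, config$lfc_sd))
  lfc_arr <- ifelse(is_de, dir_arr * mag, 0)
  flip <- is_de & (stats::runif(n) < config$discordant_fraction)
  lfc_rna <- ifelse(flip, -lfc_arr, lfc_arr)
  truth <- data.frame(
    gene = genes, is_de = is_de,
    true_direction = ifelse(!is_de, "none",
                            ifelse(lfc_arr > 0, "up", "down")),
    true_lfc_array = lfc_arr, true_lfc_rnaseq = lfc_rna,
    stringsAsFactors = FALSE)

  gs <- config$group_sizes
  baseline <- stats::runif(n, 4, 14)            # log2 scale
  batch <- stats::rnorm(n, 0, config$batch_shift_sd)

  ## microarray: natural-scale intensities exp2(baseline + effect + noise)
  n_arr <- gs[1] + gs[2]
  grp_arr <- rep(c("case", "control"), c(gs[1], gs[2]))
  mu_arr <- outer(lfc_arr, as.numeric(grp_arr == "case")) + baseline
  arr <- 2^(mu_arr + matrix(stats::rnorm(n * n_arr, 0, config$array_noise_sd),
                            n, n_arr))
  colnames(arr) <- sprintf("A%03d", seq_len(n_arr))
  rownames(arr) <- genes

  ## rnaseq: negative-binomial counts, library factor log-uniform in [1/3, 3]
  n_rna <- gs[3] + gs[4]
  grp_rna <- rep(c("case", "control"), c(gs[3], gs[4]))
  libf <- 2^stats::runif(n_rna, -log2(3), log2(3))
  mu_rna <- 2^(baseline + batch +
                 outer(lfc_rna, as.numeric(grp_rna == "case")))
  mu_rna <- sweep(mu_rna, 2, libf, `*`)
  cnt <- matrix(stats::rnbinom(n * n_rna, mu = mu_rna,
                               size = 1 / config$nb_dispersion),
                n, n_rna)
  colnames(cnt) <- sprintf("R%03d", seq_len(n_rna))
  rownames(cnt) <- genes

  ## dropout genes: zero in a random >80% subset of pooled samples
  n_drop <- round(n * config$dropout_fraction)
  if (n_drop > 0) {
    drop_genes <- sample.int(n, n_drop)
    n_tot <- n_arr + n_rna
    for (g in drop_genes) {
      frac <- stats::runif(1, 0.82, 0.95)
      z <- sample.int(n_tot, ceiling(frac * n_tot))
      za <- z[z <= n_arr]
      zr <- z[z > n_arr] - n_arr
      arr[g, za] <- 0
      cnt[g, zr] <- 0
    }
  }

  meta_arr <- data.frame(sample = colnames(arr), study = "array_study",
                         group = grp_arr, region = region,
                         stringsAsFactors = FALSE)
  meta_rna <- data.frame(sample = colnames(cnt), study = "rnaseq_study",
                         group = grp_rna, region = region,
                         stringsAsFactors = FALSE)
  list(array = expression_study(arr, "microarray", meta_arr),
       rnaseq = expression_study(cnt, "rnaseq", meta_rna),
       truth = truth)
}

#' Simulate a GMT-style gene-set collection with planted enrichment
#'
#' Designated "enriched" sets draw their members with odds
#' `enrichment_odds` : 1 in favour of true-DE genes; remaining sets draw
#' uniformly from the universe.
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of sets to emit.
#' @param set_size_range length-2 integer vector, inclusive bounds on set
#'   size.
#' @param enrich_truth truth table from [generate_dual_study()] (or any
#'   data frame with columns `gene` and `is_de`).
#' @param enriched_sets how many of the sets are enriched for DE genes.
#' @param enrichment_odds sampling odds of a DE gene relative to a non-DE
#'   gene within enriched sets; must be > 0.
#' @param seed integer seed.
#' @return a `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
generate_gene_sets <- function(universe, n_sets = 50,
                               set_size_range = c(10, 200),
                               enrich_truth = NULL, enriched_sets = 0,
                               enrichment_odds = 1, seed = 1L) {
  if (length(universe) == 0) stop("empty universe")
  if (enrichment_odds <= 0) stop("enrichment_odds must be > 0")
  if (max(set_size_range) > length(universe))
    stop("set sizes exceed universe size")
  if (enriched_sets > 0 && is.null(enrich_truth))
    stop("enriched sets requested but no truth table supplied")
  set.seed(seed)
  w <- rep(1, length(universe))
  if (!is.null(enrich_truth)) {
    de <- enrich_truth$gene[enrich_truth$is_de]
    w[universe %in% de] <- enrichment_odds
  }
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    k <- if (set_size_range[1] == set_size_range[2]) set_size_range[1]
         else sample(seq(set_size_range[1], set_size_range[2]), 1)
    prob <- if (i <= enriched_sets) w else NULL
    sets[[i]] <- sort(sample(universe, k, prob = prob))
  }
  names(sets) <- sprintf("SET%03d%s", seq_len(n_sets),
                         ifelse(seq_len(n_sets) <= enriched_sets,
                                "_ENR", ""))
  gene_set_collection(sets, universe)
}

#' Simulate a scale-free protein-protein interaction network
#'
#' Preferential-attachment (Barabasi-Albert) graph over the gene universe:
#' connected, undirected, no self-loops or duplicate edges, heavy-tailed
#' degree distribution. Gene ids are assigned to vertices in random order
#' so degree is independent of DE status.
#'
#' @param universe character vector of gene ids (length > `attachment`).
#' @param attachment number of edges each incoming node attaches with
#'   (>= 1); `attachment = 1` yields a tree.
#' @param seed integer seed.
#' @return an [interaction_network()].
#' @export
generate_ppi <- function(universe, attachment = 2, seed = 1L) {
  if (length(universe) == 0) stop("empty universe")
  if (attachment < 1) stop("attachment must be >= 1")
  if (length(universe) <= attachment)
    stop("universe must be larger than 'attachment'")
  set.seed(seed)
  g <- igraph::sample_pa(length(universe), m = attachment, directed = FALSE)
  igraph::V(g)$name <- sample(universe)
  el <- igraph::as_edgelist(g)
  interaction_network(data.frame(from = el[, 1], to = el[, 2],
                                 stringsAsFactors = FALSE))
}
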