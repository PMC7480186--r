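#' Merge two normalized studies into one matrix with batch labels
#'
#' Genes must already be harmonized to a shared universe; columns are the
#' concatenated samples, and the per-sample `study` annotation becomes the
#' batch label.
#'
#' @param a,b normalized [expression_study()] objects over identical genes.
#' @return an `ExpressionStudy` with platform `"microarray"` placeholder
#'   semantics removed: values are merged log2-scale expression; `samples`
#'   carries the original study ids as batch labels.
#' @export
merge_studies <- function(a, b) {
  stopifnot(identical(gene_ids(a), gene_ids(b)))
  vals <- cbind(a$values, b$values)
  samples <- rbind(a$samples, b$samples)
  structure(list(values = vals, platform = "merged", samples = samples),
            class = "ExpressionStudy")
}

#' Parametric empirical-Bayes batch adjustment (ComBat)
#'
#' Removes additive and multiplicative between-batch effects gene by gene
#' while protecting the case/control contrast: each gene is standardized
#' against its grand mean plus covariate fit, per-batch location and scale
#' effects are estimated, shrunk toward batch-level normal /
#' inverse-gamma priors by the standard EB fixed-point iteration
#' (convergence `max |delta| < 1e-6`, at most 500 sweeps), and the data are
#' back-transformed.
#'
#' @param merged an `ExpressionStudy` from [merge_studies()]; the `study`
#'   annotation defines the batches.
#' @param covariate name of the `samples` column to protect (default
#'   `"group"`); set `NULL` for no covariate.
#' @return list with `adjusted` (the batch-corrected `ExpressionStudy`) and
#'   `model` (a `BatchModel`: per-batch `gamma_star`, `delta2_star`,
#'   hyperparameters, per-gene `grand` and `sigma2`).
#' @export
combat_adjust <- function(merged, covariate = "group") {
  stopifnot(inherits(merged, "ExpressionStudy"))
  dat <- merged$values
  batch <- factor(merged$samples$study)
  if (nlevels(batch) < 2) {
    ## nothing to remove
    return(list(adjusted = merged,
                model = structure(list(n_batch = 1L), class = "BatchModel")))
  }
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  batchmod <- stats::model.matrix(~ -1 + batch)
  mod <- NULL
  if (!is.null(covariate)) {
    cv <- factor(merged$samples[[covariate]])
    if (nlevels(cv) > 1)
      mod <- stats::model.matrix(~ cv)[, -1, drop = FALSE]
  }
  design <- cbind(batchmod, mod)
  if (qr(design)$rank < ncol(design))
    stop("batch is confounded with the protected covariate; ",
         "the batch effect cannot be separated from the group effect")
  n_array <- ncol(dat)
  n_batches <- as.vector(table(batch))
  n_batch <- nlevels(batch)

  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(n_batches / n_array,
                          B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowSums((dat - t(design %*% B_hat))^2) / n_array
  if (any(var_pooled <= 0))
    stop("gene(s) with zero pooled variance cannot be standardized: ",
         paste(utils::head(rownames(dat)[var_pooled <= 0], 5),
               collapse = ", "))

  stand_mean <- matrix(grand_mean, nrow(dat), n_array)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  batches <- lapply(levels(batch), function(b) which(batch == b))
  gamma_hat <- t(vapply(batches, function(ix)
    rowMeans(s_data[, ix, drop = FALSE]), numeric(nrow(dat))))
  delta_hat <- t(vapply(batches, function(ix) {
    xs <- s_data[, ix, drop = FALSE]
    rowSums((xs - rowMeans(xs))^2) / (length(ix) - 1)
  }, numeric(nrow(dat))))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  aprior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); v <- stats::var(d); (2 * v + m^2) / v
  })
  bprior <- apply(delta_hat, 1, function(d) {
    m <- mean(d); v <- stats::var(d); (m * v + m^3) / v
  })

  gamma_star <- gamma_hat
  delta2_star <- delta_hat
  for (i in seq_len(n_batch)) {
    ix <- batches[[i]]
    n <- length(ix)
    g_old <- gamma_hat[i, ]
    d_old <- delta_hat[i, ]
    sdat <- s_data[, ix, drop = FALSE]
    for (iter in seq_len(500)) {
      g_new <- (t2[i] * n * rowMeans(sdat) + d_old * gamma_bar[i]) /
        (t2[i] * n + d_old)
      sum2 <- rowSums((sdat - g_new)^2)
      d_new <- (0.5 * sum2 + bprior[i]) / (n / 2 + aprior[i] - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < 1e-6) break
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
  }

  bayes <- s_data
  for (i in seq_len(n_batch)) {
    ix <- batches[[i]]
    bayes[, ix] <- (s_data[, ix, drop = FALSE] - gamma_star[i, ]) /
      sqrt(delta2_star[i, ])
  }
  adjusted <- bayes * sqrt(var_pooled) + stand_mean

  out <- merged
  out$values <- adjusted
  model <- structure(list(
    n_batch = n_batch, batches = levels(batch),
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    grand = as.vector(grand_mean), sigma2 = var_pooled,
    hyper = list(gamma_bar = gamma_bar, t2 = t2,
                 lambda = aprior, theta = bprior)),
    class = "BatchModel")
  list(adjusted = out, model = model)
}

#' PCA diagnostics with a batch-separation score
#'
#' Centers each gene, decomposes the sample cloud by SVD, and reports
#' per-sample component scores, variance-explained fractions and the mean
#' silhouette width of the batch labels in the PC1-PC2 plane (near zero
#' when batches are well mixed).
#'
#' @param x numeric matrix, genes x samples.
#' @param labels batch label per sample (length `ncol(x)`).
#' @param n_components number of components to retain in the score table.
#' @return list of class `PCAReport`: `scores` (samples x components),
#'   `var_explained`, `silhouette`.
#' @export
pca_report <- function(x, labels, n_components = 10) {
  if (ncol(x) < 3) stop("need >= 3 samples")
  if (length(labels) != ncol(x)) stop("one label per sample required")
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-300)) stop("constant matrix has no principal components")
  sv <- La.svd(t(xc))  # samples x genes
  d2 <- sv$d^2
  var_explained <- d2 / sum(d2)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  lab <- as.integer(factor(labels))
  sil <- if (length(unique(lab)) < 2) NA_real_ else {
    s <- cluster::silhouette(lab, stats::dist(scores[, 1:2, drop = FALSE]))
    mean(s[, "sil_width"])
  }
  structure(list(scores = scores, var_explained = var_explained,
                 silhouette = sil),
            class = "PCAReport")
}
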