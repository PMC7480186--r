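# Small simulation settings reused where the full study sizes are not the
# point of the test.
small_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 2000, group_sizes = c(8, 10, 8, 12), seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Manual ExpressionStudy over a plain matrix (all samples one study/region).
make_study <- function(values, platform = "microarray", groups = NULL,
                       study = "s1") {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(groups)) groups <- rep("control", ncol(values))
  expression_study(values, platform,
                   data.frame(sample = colnames(values), study = study,
                              group = groups, region = "macular",
                              stringsAsFactors = FALSE))
}
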