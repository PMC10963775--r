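#' Run the full surprisal / state-transition pipeline
#'
#' Chains every stage of the analysis on one cohort: log transform,
#' surprisal decomposition, stable-transcript noise estimate, amplitude
#' thresholds, significant-process count, state-space construction,
#' k-means + Boltzmann-ratio estimation of the critical points (on
#' coordinates rescaled to the unit interval, where the default potential
#' scale 64 gives a unit symmetric barrier), critical-point assignment,
#' FEC, PaSSS barcodes and the FEC-by-critical-point comparison.
#'
#' @param expression Expression matrix (linear scale, genes x samples).
#' @param meta Sample table covering all samples.
#' @param pseudocount Pseudocount of the log transform.
#' @param n_surrogates Surrogates for the amplitude thresholds.
#' @param scale Potential scaling coefficient (unit-interval coordinates).
#' @param select_genes Run MI feature selection before building the
#'   state-space (default `FALSE`: all genes, which is also the fallback
#'   whenever selection does not separate the clusters).
#' @param seed Seed driving every stochastic stage.
#' @return List with the intermediate objects of every stage: `log_matrix`,
#'   `decomposition`, `noise`, `state_space`, `selected_genes`,
#'   `coordinates` (raw), `u` (unit-interval coordinates), `clusters`,
#'   `model` ([potential_model()]), `c2_fit`, `assignments`, `fec`,
#'   `barcodes`, `passs_catalog`, `fec_anova`.
#' @export
run_pipeline <- function(expression, meta, pseudocount = 1,
                         n_surrogates = 100L, scale = 64,
                         select_genes = FALSE, seed = 1L) {
  meta <- validate_sample_table(meta)
  L <- log_transform(expression, pseudocount)
  d <- sa_decompose(L)
  noise <- estimate_noise_sigma(L)
  d$thresholds <- compute_amplitude_thresholds(d, noise,
                                               n_surrogates = n_surrogates,
                                               seed = seed)
  d$n_significant <- count_significant_processes(d, noise,
                                                 thresholds = d$thresholds)

  selected <- NULL
  L_space <- L
  if (select_genes) {
    selected <- select_features(L, meta, jitter_seed = seed)
    if (selected$separated)
      L_space <- L[selected$selected_gene_ids, , drop = FALSE]
  }
  ss <- build_state_space(L_space, meta)
  coords <- ss$coordinates

  cl <- estimate_c1_c3(coords, meta, seed = seed)
  u <- rescale_coordinates(coords, cl$c1, cl$c3)
  c2_fit <- estimate_c2(0, 1, cl$observed_ratio, scale = scale)
  beta_inv <- estimate_beta_inv(0, c2_fit$c2, 1, scale,
                                u[cl$cluster == "c1"])
  model <- potential_model(0, c2_fit$c2, 1, scale = scale,
                           beta_inv = max(beta_inv, 1e-8))
  assignments <- assign_critical_points(u, model)

  fec <- compute_fec(expression, d)
  barcodes <- make_barcodes(d)
  passs_catalog <- catalog_passs(barcodes)
  fec_anova <- tryCatch(fec_by_critical_point(fec, assignments),
                        error = function(e) NULL)

  list(log_matrix = L, decomposition = d, noise = noise,
       state_space = ss, selected_genes = selected,
       coordinates = coords, u = u, clusters = cl,
       model = model, c2_fit = c2_fit, assignments = assignments,
       fec = fec, barcodes = barcodes, passs_catalog = passs_catalog,
       fec_anova = fec_anova)
}

#' Write the pipeline's result tables
#'
#' Emits the standard TSV outputs of a run (amplitudes, gene weights,
#' thresholds, noise estimate, state-space coordinates, critical points,
#' assignments, FEC, barcodes, PaSSS catalogue) plus a JSON run manifest.
#'
#' @param res A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest.
#' @return The directory, invisibly.
#' @export
write_pipeline_results <- function(res, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  d <- res$decomposition
  tsv(data.frame(sample_id = d$sample_ids, d$lambda, check.names = FALSE), "lambda.tsv")
  tsv(data.frame(gene_id = d$gene_ids, d$G, check.names = FALSE), "gene_weights.tsv")
  tsv(data.frame(alpha = names(d$thresholds), threshold = unname(d$thresholds)),
      "thresholds.tsv")
  tsv(data.frame(sigma = res$noise$sigma, fraction = res$noise$fraction,
                 stable_genes = paste(res$noise$stable_gene_ids, collapse = ",")),
      "noise.tsv")
  tsv(data.frame(sample_id = names(res$coordinates),
                 coordinate = unname(res$coordinates),
                 u = unname(res$u),
                 cluster = as.character(res$clusters$cluster)),
      "state_space.tsv")
  m <- res$model
  tsv(data.frame(c1 = m$c1, c2 = m$c2, c3 = m$c3, scale = m$scale,
                 beta_inv = m$beta_inv, c2_residual = res$c2_fit$residual),
      "critical_points.tsv")
  tsv(res$assignments, "assignments.tsv")
  tsv(res$fec, "fec.tsv")
  tsv(res$barcodes[, c("sample_id", "code")], "barcodes.tsv")
  tsv(res$passs_catalog, "passs_catalog.tsv")
  write_run_manifest(file.path(dir, "run_manifest.json"),
                     seed = seed,
                     pseudocount = attr(res$log_matrix, "pseudocount"),
                     n_significant = d$n_significant,
                     noise_sigma = res$noise$sigma,
                     scale = m$scale, beta_inv = m$beta_inv,
                     c1 = m$c1, c2 = m$c2, c3 = m$c3)
  invisible(dir)
}
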