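#' Separation between the normal and leukemia clusters on one coordinate
#'
#' After orienting the coordinate so that the AML mean exceeds the normal
#' mean, returns `min(AML) - max(normal)`: positive exactly when the two
#' clusters are perfectly separated, negative when they overlap. Invariant
#' to a global sign flip of the coordinates.
#'
#' @param coords Named (or column-ordered) per-sample coordinates.
#' @param labels Sample table or label vector (see [rank_genes_by_mi()]).
#' @return The signed separation distance.
#' @export
cluster_separation <- function(coords, labels) {
  y <- label_vector(labels, names(coords) %||% seq_along(coords))
  if (!any(y == 1L) || !any(y == 0L)) stop("both groups must be present")
  if (mean(coords[y == 1L]) < mean(coords[y == 0L])) coords <- -coords
  min(coords[y == 1L]) - max(coords[y == 0L])
}

#' Build the 1-D transcriptome state-space
#'
#' Mean-centres each gene across the training samples, computes the SVD
#' `X_hat = U Sigma V*` of the samples x genes matrix, and models the
#' state-space with the principal components `PC = U Sigma`. The component
#' giving the greatest normal-vs-AML cluster separation is chosen (ties go
#' to the lower index) and oriented so that AML coordinates exceed normal
#' ones. The columns of `V` are the eigengenes used to project held-out
#' samples.
#'
#' @param L Log-expression matrix (genes x samples) of the training set
#'   (normal + primary AML samples).
#' @param labels Sample table or label vector.
#' @return Object of class `state_space`: `eigengenes` (genes x r),
#'   `mean_vector`, `pcs` (samples x r), `chosen_component`, `orientation`,
#'   `separations` (per component), `gene_ids`, `sample_ids`,
#'   `coordinates` (oriented training coordinates on the chosen component).
#' @export
build_state_space <- function(L, labels) {
  if (ncol(L) < 3L) stop("need at least 3 training samples")
  y <- label_vector(labels, colnames(L))
  if (!any(y == 1L) || !any(y == 0L)) stop("both groups must be present")
  X <- t(L)                                  # samples x genes
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc)
  pcs <- s$u %*% diag(s$d, length(s$d))
  seps <- vapply(seq_len(ncol(pcs)), function(j)
    cluster_separation(stats::setNames(pcs[, j], colnames(L)), y), numeric(1))
  chosen <- which.max(seps)                  # which.max takes the first max
  orientation <- if (mean(pcs[y == 1L, chosen]) >= mean(pcs[y == 0L, chosen])) 1 else -1
  coords <- stats::setNames(orientation * pcs[, chosen], colnames(L))
  structure(list(eigengenes = s$v, mean_vector = mu, pcs = pcs,
                 chosen_component = chosen, orientation = orientation,
                 separations = seps, gene_ids = rownames(L),
                 sample_ids = colnames(L), coordinates = coords),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("Transcriptome state-space:", length(x$gene_ids), "genes,",
      length(x$sample_ids), "training samples\n")
  cat("  chosen component:", x$chosen_component,
      " separation:", signif(x$separations[x$chosen_component], 4), "\n")
  invisible(x)
}

#' Project samples into an existing state-space
#'
#' Subtracts the stored training mean and multiplies by the eigengenes,
#' returning the oriented coordinate on the chosen component:
#' `PC_m = (X_m - X_bar) V`.
#'
#' @param ss A [build_state_space()] result.
#' @param L_new Log-expression matrix of the new samples; must contain
#'   every state-space gene.
#' @return Named vector of state-space coordinates.
#' @export
project_samples <- function(ss, L_new) {
  stopifnot(inherits(ss, "state_space"))
  miss <- setdiff(ss$gene_ids, rownames(L_new))
  if (length(miss))
    stop("genes missing from the new matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(" (and %d more)", length(miss) - 5L))
  X <- t(L_new[ss$gene_ids, , drop = FALSE])
  Xc <- sweep(X, 2L, ss$mean_vector)
  pc <- Xc %*% ss$eigengenes[, ss$chosen_component]
  stats::setNames(ss$orientation * as.vector(pc), colnames(L_new))
}

#' Mutual-information feature selection for the state-space
#'
#' Ranks genes by MI against the disease label, then iteratively drops the
#' lowest-MI genes and rebuilds the state-space until the normal and AML
#' clusters separate on the chosen component (separation > 0), or the gene
#' count reaches `floor_genes`. When the floor is reached without
#' separation the retained set is flagged unseparated and all genes of the
#' final iteration are returned -- on some cohorts gene selection does not
#' improve separation, in which case the full transcriptome is the right
#' state-space basis.
#'
#' @param L Log-expression matrix (genes x samples).
#' @param labels Sample table or label vector.
#' @param k Neighbour count for the MI estimator.
#' @param batch_step Genes removed per iteration (1 reproduces the
#'   one-at-a-time scheme; larger values trade SVD count for granularity --
#'   the returned set is always re-checked as-is, so the separated/
#'   unseparated flag does not depend on the step).
#' @param floor_genes Minimum number of genes to retain.
#' @param jitter_seed Seed for the MI estimator jitter.
#' @return List with `selected_gene_ids`, `separated` (logical),
#'   `separation` (final value), `ranking` (the [rank_genes_by_mi()]
#'   table) and `trace` (data.frame of gene count vs separation per
#'   iteration).
#' @export
select_features <- function(L, labels, k = 3L, batch_step = 1L,
                            floor_genes = 10L, jitter_seed = 1L) {
  if (nrow(L) < 2L) stop("need at least 2 genes")
  ranking <- rank_genes_by_mi(L, labels, k = k, jitter_seed = jitter_seed)
  genes <- ranking$gene_id                    # best first
  trace <- list()
  repeat {
    ss <- build_state_space(L[genes, , drop = FALSE], labels)
    sep <- ss$separations[ss$chosen_component]
    trace[[length(trace) + 1L]] <- data.frame(n_genes = length(genes),
                                              separation = sep)
    if (sep > 0 || length(genes) <= floor_genes) break
    drop_n <- min(batch_step, length(genes) - floor_genes)
    genes <- genes[seq_len(length(genes) - drop_n)]
  }
  list(selected_gene_ids = genes, separated = sep > 0, separation = sep,
       ranking = ranking, trace = do.call(rbind, trace))
}
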