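#' Specify a synthetic transcriptome cohort
#'
#' Describes a cohort with a dominant shared steady state, a configurable
#' number of planted unbalanced processes active in sample subsets,
#' log-additive Gaussian noise, a low-variance stable-transcript subset, a
#' three-stage latent structure (normal / transition / AML) separable along
#' one coordinate, and a designated pseudotime marker gene.
#'
#' Defaults encode the study conditions used throughout the package's tests:
#' 1000 genes x 120 samples in three equal stage groups, three planted
#' processes whose amplitudes are 20x the log-scale noise SD, and 1% stable
#' transcripts.
#'
#' @param n_genes,n_samples Matrix dimensions (genes >= samples required by
#'   the decomposition).
#' @param n_processes Number of planted unbalanced processes (>= 0).
#' @param steady_state_amplitude Constant planted steady-state amplitude
#'   \eqn{\lambda_0(k)} (log-expression units).
#' @param noise_sd SD of the i.i.d. Gaussian noise added on the log scale.
#' @param process_amplitudes Per-process amplitude scale of the planted
#'   \eqn{\lambda_\alpha(k)} entries; default `20 * noise_sd` for every
#'   process.
#' @param active_fraction Per-process fraction of samples in which the
#'   process is active. Defaults place process 1 in all transition + AML
#'   samples and give later processes geometrically shrinking subsets.
#' @param stable_fraction Fraction of genes designated stable transcripts:
#'   they carry no process loadings, so their across-sample SD is the noise
#'   floor.
#' @param group_fractions Proportions of the normal / transition / AML
#'   stages (must sum to 1).
#' @param marker_gene_index Index of the pseudotime marker gene, forced to
#'   load positively and strongly on the state-axis process (process 1).
#'   `NULL` picks the first non-stable gene.
#' @param seed Integer seed; the whole construction is deterministic given
#'   the spec.
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000L, n_samples = 120L, n_processes = 3L,
                           steady_state_amplitude = 100,
                           noise_sd = 0.25,
                           process_amplitudes = NULL,
                           active_fraction = NULL,
                           stable_fraction = 0.01,
                           group_fractions = c(normal = 1/3, transition = 1/3, AML = 1/3),
                           marker_gene_index = NULL,
                           seed = 1L) {
  chk <- function(ok, field, why) if (!ok) stop("invalid synthetic spec field '",
                                                field, "': ", why)
  chk(n_genes >= 2, "n_genes", "need at least 2 genes")
  chk(n_samples >= 2, "n_samples", "need at least 2 samples")
  chk(n_processes >= 0, "n_processes", "must be >= 0")
  chk(n_processes < min(n_genes, n_samples), "n_processes",
      "must be < min(n_genes, n_samples)")
  chk(noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(steady_state_amplitude > 0, "steady_state_amplitude", "must be > 0")
  chk(stable_fraction >= 0 && stable_fraction < 1, "stable_fraction",
      "must be in [0, 1)")
  chk(length(group_fractions) == 3L, "group_fractions",
      "need proportions for normal / transition / AML")
  chk(abs(sum(group_fractions) - 1) < 1e-9, "group_fractions", "must sum to 1")
  if (is.null(process_amplitudes))
    process_amplitudes <- rep(20 * max(noise_sd, 0.01), n_processes)
  process_amplitudes <- rep_len(process_amplitudes, max(n_processes, 0L))
  chk(all(process_amplitudes > 0) || n_processes == 0L, "process_amplitudes",
      "must be positive")
  if (is.null(active_fraction) && n_processes > 0L) {
    gf <- group_fractions
    active_fraction <- c(gf[2] + gf[3],
                         if (n_processes > 1L) gf[2] * 0.7,
                         if (n_processes > 2L) gf[2] * 0.3 * 2^-(seq_len(n_processes - 2L) - 1L))
  }
  active_fraction <- rep_len(active_fraction %||% numeric(0), max(n_processes, 0L))
  chk(all(active_fraction > 0 & active_fraction <= 1) || n_processes == 0L,
      "active_fraction", "fractions must lie in (0, 1]")
  spec <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
               n_processes = as.integer(n_processes),
               steady_state_amplitude = steady_state_amplitude,
               noise_sd = noise_sd,
               process_amplitudes = process_amplitudes,
               active_fraction = active_fraction,
               stable_fraction = stable_fraction,
               group_fractions = group_fractions,
               marker_gene_index = marker_gene_index,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a seeded Gaussian noise matrix
#'
#' @param n_genes,n_samples Dimensions.
#' @param sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An `n_genes x n_samples` matrix of i.i.d. Gaussian(0, sd) values.
#' @export
generate_noise_matrix <- function(n_genes, n_samples, sd, seed = 1L) {
  if (sd < 0) stop("noise sd must be >= 0")
  with_seed(seed, matrix(stats::rnorm(n_genes * n_samples, 0, sd), n_genes, n_samples))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Constructs `ln X = G %*% t(lambda) + E` where the columns of the planted
#' gene-weight matrix `G` are orthonormal, `lambda[, 1]` is the constant
#' steady-state amplitude, and `lambda[, 1 + alpha]` holds the amplitude of
#' planted process `alpha`, zero outside its active sample set. Expression
#' is returned on the linear scale as `exp(ln X)`.
#'
#' Construction details that make the cohort a useful test bed:
#' * Process 1 is the state axis: active in every transition and AML sample
#'   with amplitude proportional to the latent state coordinate, so
#'   transition samples sit between normal and AML along it.
#' * Processes `alpha >= 2` receive balanced +/- amplitude signs stratified
#'   by the sign pattern of previously planted processes, which makes the
#'   planted amplitude columns pairwise orthogonal and hence identifiable by
#'   the decomposition up to sign.
#' * Transition samples are active in every process, so they carry the most
#'   simultaneously active processes (and, downstream, the largest free
#'   energy change).
#' * Stable transcripts load on the steady state only; with every other
#'   gene given an equal share of process variance they are identifiable as
#'   the lowest-SD genes, and their SD is the noise floor.
#' * The marker gene loads large and positive on process 1, so its
#'   expression increases monotonically along the state axis.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expression` (linear-scale matrix, genes x samples),
#'   `meta` (sample table; transition samples are labelled `AML` since the
#'   binary group label tracks disease status), and `truth` (planted `G`,
#'   `lambda`, `state_coordinate`, three-level `stage`, `active_sets`,
#'   `stable_gene_ids`, `marker_gene_id`, `noise_sd`).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  with_seed(spec$seed, {
    ng <- spec$n_genes; ns <- spec$n_samples; P <- spec$n_processes
    gene_ids <- sprintf("g%0*d", nchar(ng), seq_len(ng))
    sample_ids <- sprintf("s%0*d", nchar(ns), seq_len(ns))

    sizes <- round(spec$group_fractions * ns)
    sizes[3] <- ns - sizes[1] - sizes[2]
    stage <- rep(c("normal", "transition", "AML"), times = sizes)
    coord <- stats::rnorm(ns, rep(c(0, 0.5, 1), times = sizes), 0.04)
    tr <- which(stage == "transition"); am <- which(stage == "AML")

    n_stable <- max(1L, ceiling(spec$stable_fraction * ng))
    stable_idx <- sort(sample.int(ng, n_stable))
    marker <- spec$marker_gene_index %||% setdiff(seq_len(ng), stable_idx)[1L]
    if (marker %in% stable_idx) stop("marker gene cannot be a stable transcript")

    ## planted amplitudes
    lambda <- matrix(0, ns, 1L + P,
                     dimnames = list(sample_ids, c("lambda0", if (P > 0) paste0("lambda", seq_len(P)))))
    lambda[, 1L] <- spec$steady_state_amplitude
    active_sets <- vector("list", P)
    if (P > 0L) {
      amp <- spec$process_amplitudes
      ## process 1, the state axis: amplitude grades with the latent
      ## coordinate (0.8x the scale in transition, 1.6x in AML), placing
      ## transition samples mid-interval in the state-space while keeping
      ## every active amplitude well above the noise floor of the
      ## decomposition.
      act1 <- c(tr, am)
      n1 <- min(length(act1), max(2L, round(spec$active_fraction[1] * ns)))
      act1 <- sort(act1[seq_len(n1)])
      lambda[act1, 2L] <- amp[1] * 1.6 * pmax(coord[act1], 0.5)
      active_sets[[1L]] <- sample_ids[act1]
      ## later processes: supports drawn pairwise from strata of the
      ## previously planted sign patterns, with balanced +/- signs inside
      ## each stratum, so the planted amplitude columns are pairwise
      ## orthogonal (and orthogonal to the constant steady state).
      pool <- c(tr, sample(am))
      for (a in seq_len(P)[-1L]) {
        n_act <- max(4L, round(spec$active_fraction[a] * ns))
        n_act <- 2L * (n_act %/% 2L)            # even, so signs can balance
        n_act <- min(n_act, 2L * (length(pool) %/% 2L))
        key <- paste(stage[pool],
                     apply(sign(lambda[pool, 2:a, drop = FALSE]), 1L,
                           paste, collapse = "/"))
        cells <- split(pool, key)
        ## exhaust transition strata first so transition samples stay the
        ## group with the most simultaneously active processes
        tiers <- list(cells[grepl("^transition", names(cells))],
                      cells[!grepl("^transition", names(cells))])
        support <- integer(0)
        for (tier in tiers) {
          repeat {
            grew <- FALSE
            for (cell in tier) {
              avail <- setdiff(cell, support)
              if (length(avail) >= 2L && length(support) < n_act) {
                support <- c(support, avail[1:2]); grew <- TRUE
              }
            }
            if (!grew || length(support) >= n_act) break
          }
          if (length(support) >= n_act) break
        }
        key_s <- key[match(support, pool)]
        signs <- numeric(length(support))
        for (cell in split(seq_along(support), key_s)) {
          s <- rep(c(1, -1), length.out = length(cell))
          signs[cell] <- sample(s)
        }
        lambda[support, 1L + a] <- amp[a] * signs
        active_sets[[a]] <- sample_ids[sort(support)]
      }
      names(active_sets) <- paste0("process", seq_len(P))
    }

    ## planted gene weights: steady-state profile plus process loadings
    B <- matrix(stats::rnorm(ng * (1L + P)), ng, 1L + P)
    B[, 1L] <- 0.8 + abs(B[, 1L])             # positive expression profile
    if (P > 0L) {
      B[stable_idx, -1L] <- 0
      ## give every non-stable gene (marker aside) an equal share of
      ## process variance, so the stable transcripts are identifiable as
      ## the lowest-SD genes and their SD estimates the noise floor
      v_lambda <- apply(lambda[, -1L, drop = FALSE], 2L, stats::var)
      ordinary <- setdiff(seq_len(ng), c(stable_idx, marker))
      v_bar <- sum(v_lambda) / length(ordinary)
      for (i in ordinary) {
        u <- B[i, -1L]
        vi <- sum(u^2 * v_lambda)
        if (vi > 0) B[i, -1L] <- u * sqrt(v_bar / vi)
      }
      ## marker gene: all of its (3x typical) process variance loads
      ## positively on the state axis, so its expression grades with
      ## disease progression
      B[marker, -1L] <- 0
      B[marker, 2L] <- 3 * sqrt(v_bar / v_lambda[1L])
    }
    qrB <- qr(B)
    G <- qr.Q(qrB)
    G <- sweep(G, 2L, sign(diag(qr.R(qrB))), "*")
    dimnames(G) <- list(gene_ids, colnames(lambda))

    E <- matrix(stats::rnorm(ng * ns, 0, spec$noise_sd), ng, ns)
    L <- G %*% t(lambda) + E
    ## the planted log matrix uses the same pseudocount-1 convention as the
    ## default log transform, so log_transform(expression, 1) recovers it
    ## exactly (planted log values are comfortably positive by design)
    expression <- pmax(exp(L) - 1, 0)
    dimnames(expression) <- list(gene_ids, sample_ids)

    meta <- data.frame(sample_id = sample_ids,
                       group = ifelse(stage == "normal", "normal", "AML"),
                       patient_id = sample_ids, tissue = NA_character_,
                       stringsAsFactors = FALSE)
    ## Expected barcodes in the canonical (decomposition) frame: the SVD
    ## defines the steady state, so the cohort mean of each planted
    ## amplitude column is absorbed into it and a process's observable
    ## amplitude is the centred part. Entries within half the process
    ## scale of zero discretize to 0.
    expected_codes <- NULL
    if (P > 0L) {
      cmat <- vapply(seq_len(P), function(a) {
        lam_c <- lambda[, 1L + a] - mean(lambda[, 1L + a])
        ifelse(abs(lam_c) > amp[a] / 2, sign(lam_c), 0)
      }, numeric(ns))
      expected_codes <- apply(cmat, 1L, paste, collapse = ",")
      names(expected_codes) <- sample_ids
    }
    truth <- list(G = G, lambda = lambda,
                  state_coordinate = stats::setNames(coord, sample_ids),
                  stage = stats::setNames(stage, sample_ids),
                  active_sets = active_sets,
                  stable_gene_ids = gene_ids[stable_idx],
                  marker_gene_id = gene_ids[marker],
                  expected_codes = expected_codes,
                  noise_sd = spec$noise_sd, pseudocount = 1)
    list(expression = expression, meta = meta, truth = truth)
  })
}
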