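#' Free-energy change of samples relative to the steady state
#'
#' For sample `k`, `FEC/RT = sum_i X_i(k) * sum_alpha G_i_alpha *
#' lambda_alpha(k)`, where `X_i(k)` is the linear-scale expression of gene
#' `i` and the inner sum runs over the *active* processes of the sample:
#' those with `|lambda_alpha(k)| > threshold_alpha`, restricted by default
#' to the significant processes `alpha = 1..n_significant` of the
#' decomposition. FEC is dimensionless (units of RT); a sample with no
#' active process has FEC exactly 0.
#'
#' @param m Expression matrix (linear scale) whose axes match the
#'   decomposition.
#' @param d A [sa_decompose()] result with `thresholds` filled (see
#'   [compute_amplitude_thresholds()]); `n_significant` is used when
#'   present.
#' @param sample_id Samples to evaluate (default all).
#' @param processes Integer vector of candidate process indices
#'   (`alpha >= 1`); default `1..n_significant`, or all processes when the
#'   count has not been set.
#' @return data.frame (class `fec_table`) with `sample_id`, `fec_signed`,
#'   `fec_abs`, `n_active_processes`.
#' @export
compute_fec <- function(m, d, sample_id = NULL, processes = NULL) {
  stopifnot(inherits(d, "surprisal_decomposition"))
  if (is.null(d$thresholds)) stop("thresholds not computed; run compute_amplitude_thresholds()")
  if (!identical(rownames(m), d$gene_ids) || !identical(colnames(m), d$sample_ids))
    stop("expression matrix axes do not match the decomposition")
  r <- length(d$singular_values)
  if (is.null(processes)) {
    processes <- if (!is.null(d$n_significant)) seq_len(d$n_significant)
    else seq_len(r - 1L)
  }
  if (length(processes) && (min(processes) < 1L || max(processes) > r - 1L))
    stop("process indices out of range")
  sample_id <- sample_id %||% d$sample_ids
  ks <- match(sample_id, d$sample_ids)
  if (anyNA(ks)) stop("unknown sample: ", sample_id[which(is.na(ks))[1L]])
  fec <- numeric(length(ks)); n_act <- integer(length(ks))
  cols <- processes + 1L                      # lambda column 1 is the steady state
  for (j in seq_along(ks)) {
    k <- ks[j]
    active <- cols[abs(d$lambda[k, cols]) > d$thresholds[cols]]
    n_act[j] <- length(active)
    if (length(active)) {
      dev <- as.vector(d$G[, active, drop = FALSE] %*% d$lambda[k, active])
      fec[j] <- sum(m[, k] * dev)
    }
  }
  out <- data.frame(sample_id = sample_id, fec_signed = fec, fec_abs = abs(fec),
                    n_active_processes = n_act, stringsAsFactors = FALSE)
  class(out) <- c("fec_table", class(out))
  out
}

#' Ternary PaSSS barcodes
#'
#' Discretizes each sample's process amplitudes against the noise
#' thresholds ("error limits"): `+1` when `lambda_alpha(k) >
#' threshold_alpha`, `-1` when `lambda_alpha(k) < -threshold_alpha`, else
#' `0` (strict inequalities, so an amplitude exactly at the limit is 0).
#' The barcode spans the significant processes `alpha = 1..n_significant`;
#' the set of nonzero positions is the sample's patient-specific signaling
#' signature (PaSSS).
#'
#' @param d A [sa_decompose()] result with `thresholds` and
#'   `n_significant` filled.
#' @return data.frame (class `barcode_table`) with `sample_id`, `code`
#'   (comma-separated ternary string) and `passs` (active process indices,
#'   list column); the ternary matrix is kept in attribute `code_matrix`.
#' @export
make_barcodes <- function(d) {
  stopifnot(inherits(d, "surprisal_decomposition"))
  if (is.null(d$thresholds)) stop("thresholds not computed; run compute_amplitude_thresholds()")
  if (is.null(d$n_significant)) stop("n_significant not set; run count_significant_processes()")
  n <- d$n_significant
  ns <- length(d$sample_ids)
  code <- matrix(0L, ns, max(n, 0L),
                 dimnames = list(d$sample_ids,
                                 if (n > 0) paste0("process", seq_len(n))))
  for (a in seq_len(n)) {
    lam <- d$lambda[, a + 1L]; thr <- d$thresholds[a + 1L]
    code[, a] <- ifelse(lam > thr, 1L, ifelse(lam < -thr, -1L, 0L))
  }
  out <- data.frame(sample_id = d$sample_ids,
                    code = apply(code, 1L, paste, collapse = ","),
                    stringsAsFactors = FALSE)
  out$passs <- lapply(seq_len(ns), function(i) which(code[i, ] != 0L))
  attr(out, "code_matrix") <- code
  class(out) <- c("barcode_table", class(out))
  out
}

#' Catalogue of distinct PaSSS barcodes
#'
#' Groups samples by exact ternary-code equality and counts each distinct
#' barcode, sorted by decreasing count then lexicographically.
#'
#' @param barcodes A [make_barcodes()] table.
#' @return data.frame with `code` and `n_samples`; counts sum to the
#'   number of samples.
#' @export
catalog_passs <- function(barcodes) {
  if (nrow(barcodes) == 0L) stop("empty barcode table")
  tab <- table(barcodes$code)
  out <- data.frame(code = names(tab), n_samples = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_samples, out$code), ]
  rownames(out) <- NULL
  out
}

#' FEC statistics by critical point
#'
#' Summarizes the absolute free-energy changes of the samples assigned to
#' each critical point and tests for differences: one-way ANOVA across
#' groups on `|FEC|`, plus pairwise Welch t-tests (raw and Holm-adjusted
#' p-values). Groups with fewer than 2 samples are excluded with a
#' warning.
#'
#' @param fec A [compute_fec()] table.
#' @param assignments An [assign_critical_points()] table for the same
#'   samples.
#' @return List with `summary` (per-group n / mean / sd of `|FEC|`),
#'   `anova` (`F`, `df`, `p_value`) and `pairwise` (data.frame of Welch
#'   comparisons).
#' @export
fec_by_critical_point <- function(fec, assignments) {
  df <- merge(fec, assignments[, c("sample_id", "assigned")], by = "sample_id")
  if (nrow(df) == 0L) stop("no overlapping samples between FEC table and assignments")
  counts <- table(df$assigned)
  small <- names(counts)[counts > 0 & counts < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ", paste(small, collapse = ", "))
    df <- df[!df$assigned %in% small, ]
  }
  df$assigned <- droplevels(df$assigned)
  if (nlevels(df$assigned) < 2L) stop("fewer than 2 groups with >= 2 samples")
  smry <- do.call(rbind, lapply(split(df$fec_abs, df$assigned), function(v)
    data.frame(n = length(v), mean_abs_fec = mean(v), sd_abs_fec = stats::sd(v))))
  smry <- data.frame(critical_point = rownames(smry), smry, row.names = NULL)
  if (stats::var(df$fec_abs) == 0) {            # identical values in all groups
    anova_res <- list(F = 0, df = c(nlevels(df$assigned) - 1L,
                                    nrow(df) - nlevels(df$assigned)),
                      p_value = 1)
  } else {
    fit <- stats::aov(fec_abs ~ assigned, data = df)
    at <- summary(fit)[[1L]]
    anova_res <- list(F = at[["F value"]][1L],
                      df = c(at[["Df"]][1L], at[["Df"]][2L]),
                      p_value = at[["Pr(>F)"]][1L])
  }
  lv <- levels(df$assigned)
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- df$fec_abs[df$assigned == pr[1L]]
    b <- df$fec_abs[df$assigned == pr[2L]]
    tt <- tryCatch(stats::t.test(a, b),
                   error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    data.frame(group1 = pr[1L], group2 = pr[2L],
               mean1 = mean(a), mean2 = mean(b),
               t = unname(tt$statistic), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_holm <- stats::p.adjust(pw$p_raw, method = "holm")
  list(summary = smry, anova = anova_res, pairwise = pw)
}
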