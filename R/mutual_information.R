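#' Mutual information between a continuous and a binary variable
#'
#' k-nearest-neighbour estimator for mixed discrete/continuous pairs: for
#' each point the distance to its k-th nearest neighbour *within the same
#' class* defines a radius, the number of points of any class inside that
#' radius enters a digamma average, and
#' `I = psi(N) - <psi(N_y)> + psi(k) - <psi(m)>` (nats). Rank-based, hence
#' invariant under strictly monotone transforms of `x` up to estimator
#' noise. Exact ties are broken by an infinitesimal seeded jitter.
#'
#' @param x Continuous vector.
#' @param y Binary vector (exactly two distinct values), same length as
#'   `x`, at least 10 points.
#' @param k Number of neighbours (default 3); must be smaller than the
#'   smallest class.
#' @param jitter_seed Seed for the tie-breaking jitter.
#' @return Estimated mutual information in nats, clipped at 0; the raw
#'   (possibly slightly negative) estimate is kept in attribute `raw`.
#' @export
mutual_information_mixed <- function(x, y, k = 3L, jitter_seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 10L) stop("need at least 10 points")
  uy <- unique(y)
  if (length(uy) < 2L) stop("y has a single class; MI undefined")
  if (length(uy) > 2L) stop("y must be binary")
  if (k >= min(table(y))) stop("k must be smaller than the smallest class")
  x <- with_seed(jitter_seed, x + stats::rnorm(n, 0, 1e-10) * (1 + abs(x)))
  xs <- sort(x)
  psi_sum <- 0
  for (cl in uy) {
    idx <- which(y == cl)
    Ny <- length(idx)
    xc <- sort(x[idx])
    for (i in idx) {
      pos <- findInterval(x[i], xc)
      lo <- max(1L, pos - k - 1L); hi <- min(Ny, pos + k + 1L)
      d <- sort(abs(xc[lo:hi] - x[i]))
      rho <- d[k + 1L]                       # d[1] is the self-distance 0
      m <- findInterval(x[i] + rho, xs) -
        findInterval(x[i] - rho, xs, left.open = TRUE) - 1L
      psi_sum <- psi_sum + digamma(Ny) + digamma(max(m, 1L))
    }
  }
  raw <- digamma(n) + digamma(k) - psi_sum / n
  structure(max(raw, 0), raw = raw)
}

#' Rank genes by mutual information with the disease label
#'
#' Computes, for every gene, the mutual information between its log
#' expression across samples and the binary normal/AML indicator, and sorts
#' genes by decreasing MI (ties broken by gene id).
#'
#' @param L Log-expression matrix (genes x samples).
#' @param labels Sample table (or a vector of `"normal"`/`"AML"` labels in
#'   column order).
#' @param k Neighbour count for [mutual_information_mixed()].
#' @param jitter_seed Seed for the estimator's tie-breaking jitter.
#' @return Object of class `mi_ranking`: data.frame with `gene_id`, `mi`
#'   (clipped, nats), `mi_raw`, sorted by decreasing `mi`; attribute
#'   `k_neighbors`.
#' @export
rank_genes_by_mi <- function(L, labels, k = 3L, jitter_seed = 1L) {
  y <- label_vector(labels, colnames(L))
  mi <- numeric(nrow(L)); raw <- numeric(nrow(L))
  for (i in seq_len(nrow(L))) {
    v <- mutual_information_mixed(L[i, ], y, k = k,
                                  jitter_seed = jitter_seed + i)
    mi[i] <- as.numeric(v); raw[i] <- attr(v, "raw")
  }
  out <- data.frame(gene_id = rownames(L), mi = mi, mi_raw = raw,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mi, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "k_neighbors") <- k
  class(out) <- c("mi_ranking", class(out))
  out
}

# Resolve labels (sample table or bare vector) to 0/1 in sample order.
label_vector <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    labels <- validate_sample_table(labels)
    miss <- setdiff(sample_ids, labels$sample_id)
    if (length(miss)) stop("labels missing for sample(s): ",
                           paste(miss, collapse = ", "))
    g <- labels$group[match(sample_ids, labels$sample_id)]
  } else {
    if (length(labels) != length(sample_ids))
      stop("label vector length does not match sample count")
    if (is.numeric(labels) && all(labels %in% c(0, 1)))
      return(as.integer(labels))
    g <- as.character(labels)
  }
  if (!all(g %in% c("normal", "AML")))
    stop("labels must be 'normal'/'AML' (or a 0/1 vector)")
  as.integer(g == "AML")
}
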