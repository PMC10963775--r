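test_that("a rank-1 matrix decomposes into a pure steady state", {
  L <- matrix(c(1, 2, 1, 2, 1, 2), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  d <- sa_decompose(L)
  expect_equal(sum(d$singular_values > 1e-10), 1L)
  expect_equal(unname(d$lambda[, 1]), rep(sqrt(5), 3))
  expect_equal(unname(d$G[, 1]), c(1, 2) / sqrt(5))
  expect_lt(max(abs(d$lambda[, -1])), 1e-10)
  # rank-1 input: all deviations are zero
  expect_lt(max(abs(deviation_terms(d, "s2"))), 1e-10)
  # steady-state-only reconstruction is already exact
  expect_equal(sa_reconstruct(d, 0), L, ignore_attr = TRUE)
})

test_that("the full decomposition reconstructs any matrix to 1e-8", {
  set.seed(31)
  for (dims in list(c(50, 10), c(12, 30))) {
    L <- matrix(rnorm(prod(dims), 5, 1), dims[1], dims[2],
                dimnames = list(paste0("g", 1:dims[1]), paste0("s", 1:dims[2])))
    d <- sa_decompose(L)
    expect_lt(max(abs(d$G %*% t(d$lambda) - L)), 1e-8)
    # gene-weight columns orthonormal; amplitude norms = singular values
    expect_lt(max(abs(crossprod(d$G) - diag(ncol(d$G)))), 1e-8)
    expect_equal(sqrt(colSums(d$lambda^2)), d$singular_values,
                 ignore_attr = TRUE)
    # truncation error (Frobenius) is nonincreasing in the process count
    errs <- vapply(0:(length(d$singular_values) - 1), function(m)
      sqrt(sum((sa_reconstruct(d, m) - L)^2)), numeric(1))
    expect_true(all(diff(errs) < 1e-8))
  }
  expect_error(sa_reconstruct(d, length(d$singular_values)), "must lie in")
})

test_that("degenerate inputs are rejected", {
  expect_error(sa_decompose(matrix(1:4, 4, 1)), "2 samples")
  bad <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(sa_decompose(bad), "non-finite")
})

test_that("noise sigma comes from the most stable transcripts", {
  set.seed(8)
  L <- rbind(matrix(rnorm(2 * 50, 5, 0.01), 2),
             matrix(rnorm(98 * 50, 5, 1), 98))
  rownames(L) <- paste0("g", 1:100); colnames(L) <- paste0("s", 1:50)
  noise <- estimate_noise_sigma(L, fraction = 0.02)
  expect_equal(noise$sigma, 0.01, tolerance = 0.5)
  expect_setequal(noise$stable_gene_ids, c("g1", "g2"))
  # fraction 1 averages every gene's SD
  expect_equal(estimate_noise_sigma(L, 1)$sigma, mean(apply(L, 1, sd)))
  # degenerate: constant matrix
  cst <- matrix(3, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_warning(n0 <- estimate_noise_sigma(cst), "constant")
  expect_identical(n0$sigma, 0)
  expect_true(n0$degenerate)
  expect_error(estimate_noise_sigma(L[, 1, drop = FALSE]), "single sample")
})

test_that("amplitude thresholds scale linearly with the noise SD", {
  set.seed(21)
  L <- matrix(rnorm(200 * 30, 4, 0.5), 200, 30,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:30)))
  d <- sa_decompose(L)
  t1 <- compute_amplitude_thresholds(d, structure(list(sigma = 0.2), class = "noise_estimate"),
                                     n_surrogates = 60, seed = 4)
  t2 <- compute_amplitude_thresholds(d, structure(list(sigma = 0.4), class = "noise_estimate"),
                                     n_surrogates = 60, seed = 4)
  expect_equal(unname(t2 / t1), rep(2, length(t1)), tolerance = 0.05)
  expect_true(all(t1 > 0))
  expect_warning(t0 <- compute_amplitude_thresholds(d, structure(list(sigma = 0), class = "noise_estimate")),
                 "floor")
  expect_true(all(t0 == .Machine$double.eps))
})

test_that("planted amplitudes far above the noise floor exceed thresholds", {
  for (seed in 1:5) {
    spec <- synthetic_spec(n_genes = 300, n_samples = 60, n_processes = 1,
                           noise_sd = 0.25,
                           process_amplitudes = 50 * 0.25, seed = seed)
    gen <- generate_dataset(spec)
    L <- log_transform(gen$expression, 1)
    d <- sa_decompose(L)
    noise <- estimate_noise_sigma(L)
    thr <- compute_amplitude_thresholds(d, noise, n_surrogates = 40, seed = seed)
    expect_gt(max(abs(d$lambda[, 2])), thr[2])
  }
})

test_that("the significant-process count matches the planted dimension", {
  # pure noise at a known SD: nothing beyond the steady state
  set.seed(17)
  L <- matrix(rnorm(400 * 50, 5, 0.3), 400, 50,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:50)))
  d <- sa_decompose(L)
  noise <- structure(list(sigma = 0.3), class = "noise_estimate")
  expect_equal(count_significant_processes(d, noise, seed = 2), 0L)

  # noise-free with three planted processes: both methods return 3
  gen0 <- generate_dataset(synthetic_spec(n_genes = 200, n_samples = 40,
                                          n_processes = 3, noise_sd = 0, seed = 6))
  L0 <- log_transform(gen0$expression, 1)
  d0 <- sa_decompose(L0)
  n0 <- suppressWarnings(estimate_noise_sigma(L0))
  suppressWarnings({
    expect_equal(count_significant_processes(d0, n0), 3L)
    expect_equal(count_significant_processes(d0, n0, method = "reconstruction"), 3L)
  })

  # sigma = 0 with a full-rank input: nothing short of full rank reproduces it
  set.seed(18)
  Lf <- matrix(rnorm(30 * 10, 5, 1), 30, 10,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  df <- sa_decompose(Lf)
  zero <- structure(list(sigma = 0), class = "noise_estimate")
  suppressWarnings({
    expect_equal(count_significant_processes(df, zero), 9L)
    expect_equal(count_significant_processes(df, zero, method = "reconstruction"), 9L)
  })
})

test_that("deviation terms reproduce the documented 2-gene example", {
  # steady state along (0.8, 0.6); one process along (0.6, -0.8) with
  # amplitudes (0.5, -0.5, 0)
  G <- cbind(c(0.8, 0.6), c(0.6, -0.8))
  lam <- cbind(rep(10, 3), c(0.5, -0.5, 0))
  L <- G %*% t(lam)
  dimnames(L) <- list(c("g1", "g2"), c("s1", "s2", "s3"))
  d <- sa_decompose(L)
  expect_equal(unname(deviation_terms(d, "s1")), c(0.3, -0.4), tolerance = 1e-10)
  expect_lt(max(abs(deviation_terms(d, "s3"))), 1e-10)
  # partition: steady state + deviations = log expression, exactly
  steady <- d$G[, 1] * d$lambda["s2", 1]
  expect_equal(steady + deviation_terms(d, "s2"), L[, "s2"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(deviation_terms(d, "nope"), "unknown sample")
})

test_that("steady state dominates and is invariant on the study cohort", {
  d <- default_cohort()$res$decomposition
  lam0 <- d$lambda[, 1]
  expect_true(all(lam0 > 0))
  expect_lt(sd(lam0) / mean(lam0), 0.01)
  expect_gt(min(lam0), max(abs(d$lambda[, -1])))
})

test_that("planted amplitudes are recovered with |r| >= 0.95 at 20x sigma", {
  co <- default_cohort()
  d <- co$res$decomposition
  lam_p <- co$gen$truth$lambda
  for (a in 1:3) {
    r <- max(abs(cor(lam_p[, 1 + a], d$lambda[, 2:6])))
    expect_gt(r, 0.95)
  }
})
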