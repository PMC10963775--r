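test_that("FEC reproduces the two-gene worked example exactly", {
  G <- cbind(alpha0 = c(0.8, 0.6), alpha1 = c(0.6, -0.8))
  rownames(G) <- c("g1", "g2")
  lam <- cbind(alpha0 = 10, alpha1 = 0.5)
  rownames(lam) <- "s1"
  X <- matrix(c(10, 5), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  d <- toy_decomposition(G, lam, thresholds = c(alpha0 = 0, alpha1 = 0.3),
                         n_significant = 1L)
  fec <- compute_fec(X, d)
  expect_equal(fec$fec_signed, 1.0)
  expect_equal(fec$fec_abs, 1.0)
  expect_equal(fec$n_active_processes, 1L)
  # doubling the amplitude doubles FEC (thresholds and X fixed)
  d2 <- d; d2$lambda[, 2] <- 1.0
  expect_equal(compute_fec(X, d2)$fec_signed, 2.0)
  # below threshold: the sum is empty and FEC is exactly zero
  d0 <- d; d0$thresholds <- c(alpha0 = 0, alpha1 = 0.6)
  f0 <- compute_fec(X, d0)
  expect_identical(f0$fec_signed, 0)
  expect_identical(f0$n_active_processes, 0L)
  # an amplitude exactly at the error limit is not active (strict rule)
  dq <- d; dq$thresholds <- c(alpha0 = 0, alpha1 = 0.5)
  expect_identical(compute_fec(X, dq)$n_active_processes, 0L)
  # axis mismatch is an error
  Xbad <- X; rownames(Xbad) <- c("g1", "gX")
  expect_error(compute_fec(Xbad, d), "axes")
})

test_that("FEC is additive over the active processes", {
  set.seed(51)
  G <- qr.Q(qr(matrix(rnorm(15), 5, 3)))
  dimnames(G) <- list(paste0("g", 1:5), paste0("alpha", 0:2))
  lam <- cbind(alpha0 = c(8, 8), alpha1 = c(1.2, -0.4), alpha2 = c(-0.9, 2))
  rownames(lam) <- c("s1", "s2")
  X <- matrix(rexp(10, 0.1), 5, 2, dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  d <- toy_decomposition(G, lam, thresholds = c(alpha0 = 0, alpha1 = 0.3, alpha2 = 0.3),
                         n_significant = 2L)
  whole <- compute_fec(X, d)
  p1 <- compute_fec(X, d, processes = 1L)
  p2 <- compute_fec(X, d, processes = 2L)
  expect_equal(whole$fec_signed, p1$fec_signed + p2$fec_signed)
})

test_that("barcodes discretize amplitudes against the error limits", {
  G <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  dimnames(G) <- list(paste0("g", 1:4), paste0("alpha", 0:3))
  lam <- rbind(s1 = c(9, 2.0, -1.5, 0.1),
               s2 = c(9, 0.5, 0.2, -0.1),
               s3 = c(9, 1.0, 1.5, 0.9))
  colnames(lam) <- paste0("alpha", 0:3)
  d <- toy_decomposition(G, lam, thresholds = c(alpha0 = 0, alpha1 = 1,
                                                alpha2 = 1, alpha3 = 1),
                         n_significant = 3L)
  bc <- make_barcodes(d)
  expect_equal(bc$code, c("1,-1,0", "0,0,0", "0,1,0"))
  expect_equal(lapply(bc$passs, unname), list(c(1L, 2L), integer(0), 2L))
  # the amplitude exactly at the limit (|1.0|) discretizes to 0
  expect_equal(attr(bc, "code_matrix")["s3", "process1"], 0L)
  dna <- d; dna$thresholds <- NULL
  expect_error(make_barcodes(dna), "thresholds")
})

test_that("the PaSSS catalogue counts distinct codes", {
  bc <- data.frame(sample_id = c("a", "b", "c"),
                   code = c("1,0", "1,0", "0,1"), stringsAsFactors = FALSE)
  cat1 <- catalog_passs(bc)
  expect_equal(nrow(cat1), 2L)
  expect_equal(cat1$code, c("1,0", "0,1"))
  expect_equal(cat1$n_samples, c(2L, 1L))
  expect_equal(sum(cat1$n_samples), 3L)
  same <- data.frame(sample_id = letters[1:4], code = rep("1,1", 4))
  expect_equal(nrow(catalog_passs(same)), 1L)
})

test_that("FEC group statistics handle degenerate layouts", {
  fec <- data.frame(sample_id = paste0("s", 1:9),
                    fec_signed = rep(2, 9), fec_abs = rep(2, 9),
                    n_active_processes = 1L)
  asn <- data.frame(sample_id = paste0("s", 1:9),
                    assigned = factor(rep(c("c1", "c2", "c3"), each = 3),
                                      levels = c("c1", "c2", "c3")))
  res <- fec_by_critical_point(fec, asn)
  expect_equal(res$anova$F, 0)           # identical values in every group
  # a singleton group is excluded with a warning
  asn2 <- asn; asn2$assigned[1:3] <- c("c1", "c2", "c2")
  fec2 <- fec; fec2$fec_abs <- rnorm(9, 5)
  expect_warning(r2 <- fec_by_critical_point(fec2, asn2), "excluding")
  expect_setequal(r2$summary$critical_point, c("c2", "c3"))
  # fewer than two usable groups is an error
  asn3 <- data.frame(sample_id = paste0("s", 1:3),
                     assigned = factor(c("c1", "c1", "c2"), levels = c("c1", "c2", "c3")))
  expect_error(suppressWarnings(fec_by_critical_point(fec[1:3, ], asn3)), "2 groups")
})

test_that("|FEC| grows with the number of active processes", {
  co <- sparse_cohort()
  fec <- co$res$fec
  expect_gt(cor(fec$fec_abs, fec$n_active_processes, method = "spearman"), 0.6)
})

test_that("steady-state samples carry no more FEC than a noise-only null", {
  co <- default_cohort()
  # null: a cohort with no planted processes, same shape and noise
  null <- cached("fec_null", function() {
    gen0 <- generate_dataset(synthetic_spec(n_processes = 0, seed = 137))
    L0 <- log_transform(gen0$expression, 1)
    d0 <- sa_decompose(L0)
    n0 <- estimate_noise_sigma(L0)
    d0$thresholds <- compute_amplitude_thresholds(d0, n0, n_surrogates = 60,
                                                  seed = 137)
    compute_fec(gen0$expression, d0, processes = 1:3)
  })
  bound <- quantile(null$fec_abs, 0.99)
  steady <- co$gen$truth$expected_codes == "0,0,0"
  expect_true(any(steady))
  expect_true(all(co$res$fec$fec_abs[steady] <= bound))
})
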