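test_that("the quartic potential integrates the cubic gradient", {
  m <- potential_model(0, 0.5, 1, scale = 64)
  # symmetric barrier height at the default scale is exactly 1
  expect_equal(potential_value(m, 0.5), 1)
  expect_equal(potential_value(m, 0), 0)
  expect_equal(potential_value(m, 1), 0)   # symmetric wells at equal depth
  # gradient vanishes at the critical points
  expect_lt(max(abs(potential_gradient(m, c(0, 0.5, 1)))), 1e-10)
  # numerical derivative matches the cubic everywhere
  xs <- seq(-0.3, 1.3, length.out = 1000)
  h <- 1e-6
  num <- (potential_value(m, xs + h) - potential_value(m, xs - h)) / (2 * h)
  expect_lt(max(abs(num - potential_gradient(m, xs))), 1e-6)
  # asymmetric case keeps U(c1) = 0 as the reference
  ma <- potential_model(-1, 0.2, 2, scale = 3)
  expect_equal(potential_value(ma, -1), 0)
  expect_lt(max(abs(potential_gradient(ma, c(-1, 0.2, 2)))), 1e-10)
  expect_error(potential_model(1, 0.5, 0), "c1 < c2 < c3")
})

test_that("k-means recovers the stable wells from the coordinates", {
  set.seed(41)
  coords <- c(rnorm(200, 0, 0.1), rnorm(200, 10, 0.1))
  names(coords) <- paste0("s", 1:400)
  labels <- rep(c("normal", "AML"), each = 200)
  cl <- estimate_c1_c3(coords, labels, seed = 5)
  expect_true(cl$c1 > -0.1 && cl$c1 < 0.1)
  expect_true(cl$c3 > 9.9 && cl$c3 < 10.1)
  expect_equal(cl$observed_ratio, 1)
  # exact point masses
  pm <- c(rep(0, 5), rep(5, 5)); names(pm) <- paste0("s", 1:10)
  lp <- rep(c("normal", "AML"), each = 5)
  cle <- estimate_c1_c3(pm, lp, seed = 1)
  expect_equal(cle$c1, 0)
  expect_equal(cle$c3, 5)
  # flipping every label swaps the designation
  clf <- estimate_c1_c3(pm, rev(lp), seed = 1)
  expect_equal(clf$c1, 5)
  expect_equal(clf$c3, 0)
  expect_error(estimate_c1_c3(rep(1, 5), lp[1:5]), "distinct")
})

test_that("c2 matches the Boltzmann occupancy ratio", {
  # equal occupancy: symmetric potential, c2 at the midpoint
  f1 <- estimate_c2(0, 1, observed_ratio = 1, scale = 64)
  expect_equal(f1$c2, 0.5, tolerance = 1e-3)
  # closed form at scale 6: U(c1) - U(c3) = c2 - 1/2, so c2 = 1/2 + ln r
  f2 <- estimate_c2(0, 1, observed_ratio = exp(0.2), scale = 6)
  expect_equal(f2$c2, 0.3, tolerance = 1e-3)
  f3 <- estimate_c2(0, 1, observed_ratio = exp(-0.1), scale = 6)
  expect_equal(f3$c2, 0.6, tolerance = 1e-3)
  expect_true(f2$converged && f3$converged)
  expect_error(estimate_c2(0, 1, observed_ratio = -2), "positive")
  # an unmatchable ratio warns and reports its residual
  expect_warning(bad <- estimate_c2(0, 1, observed_ratio = exp(50), scale = 6),
                 "no interior c2")
  expect_false(bad$converged)
})

test_that("c2 decreases monotonically in the observed ratio", {
  ratios <- exp(seq(-0.4, 0.4, length.out = 9))
  c2s <- vapply(ratios, function(r) estimate_c2(0, 1, r, scale = 6)$c2, numeric(1))
  expect_true(all(diff(c2s) < 0))
})

test_that("samples attach to the nearest critical point, ties to c2", {
  m <- potential_model(0, 1, 2, scale = 4)
  a <- assign_critical_points(c(s1 = 1, s2 = 0.4, s3 = 0.5, s4 = 1.9), m)
  expect_equal(as.character(a$assigned), c("c2", "c1", "c2", "c3"))
  expect_equal(a$distance, c(0, 0.4, 0.5, 0.1))
})

test_that("the diffusion coefficient follows the harmonic well relation", {
  # kappa = scale * (c1-c2)(c1-c3); Gaussian well samples with known var
  set.seed(43)
  kappa <- 64 * (0 - 0.5) * (0 - 1)
  x <- rnorm(5000, 0, sqrt(0.1 / kappa))
  b <- estimate_beta_inv(0, 0.5, 1, 64, x)
  expect_equal(b, 0.1, tolerance = 0.05)
})

test_that("pseudotime is the rescaled marker rank", {
  m <- matrix(c(1, 5, 3), 1, dimnames = list("KITlike", c("a", "b", "c")))
  y <- c("normal", "AML", "AML")
  pt <- suppressWarnings(pseudotime_from_marker(m, "KITlike", y))
  expect_equal(unname(pt$pseudotime), c(0, 1, 0.5))
  # monotone transforms leave the ordering untouched
  pt2 <- suppressWarnings(pseudotime_from_marker(exp(m), "KITlike", y))
  expect_equal(pt$pseudotime, pt2$pseudotime)
  # ties share midranks
  mt <- matrix(c(2, 2, 7, 9), 1, dimnames = list("g", letters[1:4]))
  pt3 <- suppressWarnings(pseudotime_from_marker(mt, "g", c("normal", "normal", "AML", "AML")))
  expect_equal(unname(pt3$pseudotime), c(0.5, 0.5, 2, 3) / 3)
  # a constant marker is unusable
  mc <- matrix(1, 1, 4, dimnames = list("g", letters[1:4]))
  expect_error(pseudotime_from_marker(mc, "g", c("normal", "normal", "AML", "AML")),
               "constant")
  # an uninformative marker only warns
  set.seed(44)
  mu <- matrix(rnorm(40, 10), 1, dimnames = list("g", paste0("s", 1:40)))
  expect_warning(pseudotime_from_marker(mu, "g", rep(c("normal", "AML"), 20)),
                 "does not differ")
})

test_that("the cohort marker grades with disease stage", {
  co <- default_cohort()
  pt <- pseudotime_from_marker(co$gen$expression, co$gen$truth$marker_gene_id,
                               co$gen$meta)
  expect_true(pt$significant)
  stage_num <- as.numeric(factor(co$gen$truth$stage,
                                 c("normal", "transition", "AML")))
  expect_gt(cor(pt$pseudotime, stage_num, method = "spearman"), 0.7)
})

test_that("noise-free Langevin motion is gradient descent into the wells", {
  m <- potential_model(0, 0.5, 1, scale = 64, beta_inv = 0)
  traj <- simulate_langevin(m, x0 = 0.99, t_end = 5, dt = 0.002)
  expect_lt(abs(traj[length(traj)] - 1), 1e-4)
  # the unstable point is stationary
  stay <- simulate_langevin(m, x0 = 0.5, t_end = 1, dt = 0.002)
  expect_true(all(stay == 0.5))
  # starting left of the barrier flows to the normal well
  down <- simulate_langevin(m, x0 = 0.45, t_end = 5, dt = 0.002)
  expect_lt(abs(down[length(down)]), 1e-4)
  expect_error(simulate_langevin(m, 0.5, 1, dt = 0.1), "unstable")
})

test_that("lowering the barrier accelerates first passage out of the well", {
  high <- potential_model(0, 0.5, 1, scale = 64, beta_inv = 0.25)
  low <- potential_model(0, 0.5, 1, scale = 24, beta_inv = 0.25)
  crossed <- function(m, seed) {
    traj <- simulate_langevin(m, x0 = rep(0, 60), t_end = 6, dt = 0.002,
                              seed = seed)
    mean(apply(traj > m$c2, 2, any))
  }
  expect_gt(crossed(low, 9), crossed(high, 9))
})
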