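test_that("phantom atlas matches its specification", {
  atlas <- build_phantom_atlas(phantom_spec())
  expect_equal(nrow(atlas$parcels), 100L)
  sizes <- table(atlas$parcels$network)
  expect_equal(sizes[["frontoparietal"]], 4L)
  expect_equal(sizes[["visual"]], 13L)
  expect_equal(sizes[["somatomotor"]], 14L)
  expect_equal(sizes[["dorsal_attention"]], 13L)
  expect_equal(sizes[["ventral_attention"]], 14L)
  expect_equal(sizes[["limbic"]], 5L)
  expect_equal(sizes[["control"]], 16L)
  expect_equal(sizes[["default_mode"]], 21L)
  counts <- tabulate(atlas$labels, 100L)
  expect_true(all(counts == 800L))
})

test_that("tiny phantom atlas lays out labels and background exactly", {
  spec <- phantom_spec(volume_shape = c(4L, 4L, 4L), parcel_voxels = 10L,
                       network_sizes = c(a = 1L, b = 1L))
  atlas <- build_phantom_atlas(spec)
  expect_equal(sum(atlas$labels == 1L), 10L)
  expect_equal(sum(atlas$labels == 2L), 10L)
  expect_equal(sum(atlas$labels == 0L), 44L)
})

test_that("atlas construction fails when the volume is too small", {
  spec <- phantom_spec(volume_shape = c(4L, 4L, 4L), parcel_voxels = 40L,
                       network_sizes = c(a = 1L, b = 1L))
  expect_error(build_phantom_atlas(spec), "volume holds")
})

test_that("cohort age sampling respects range, determinism and errors", {
  a <- sample_cohort_ages(67, c(20, 82), seed = 11)
  expect_length(a, 67L)
  expect_true(all(a >= 20 & a <= 82))
  expect_identical(a, sample_cohort_ages(67, c(20, 82), seed = 11))
  expect_equal(sample_cohort_ages(1, c(50, 50), seed = 1), 50)
  expect_error(sample_cohort_ages(5, c(60, 40)), "empty age range")
  expect_error(sample_cohort_ages(0, c(20, 82)), "n must be")
})

test_that("analytic Gaussian KLS oracle matches closed forms and quadrature", {
  expect_equal(analytic_kls_gaussian(0, 1, 0, 1), 1.0)
  expect_equal(analytic_kls_gaussian(1.0, 0.1, 1.1, 0.1), exp(-1), tolerance = 1e-12)
  # unequal variances against direct numerical integration of the integrand
  num <- integrate(function(x) {
    p <- dnorm(x, 0, 1); q <- dnorm(x, 0, 2)
    p * log(p / q) + q * log(q / p)
  }, -30, 30, rel.tol = 1e-10)$value
  expect_equal(analytic_kls_gaussian(0, 1, 0, 2), exp(-num), tolerance = 1e-6)
  expect_error(analytic_kls_gaussian(0, -1, 0, 1), "positive")
})

test_that("subject simulation is reproducible and recentred", {
  atlas <- small_atlas()
  eff <- age_effect_model(unique(atlas$parcels$network))
  s1 <- simulate_subject(atlas, 40, eff, seed = 5)
  s2 <- simulate_subject(atlas, 40, eff, seed = 5)
  expect_identical(s1$volume, s2$volume)
  lab <- atlas$labels > 0
  expect_equal(mean(s1$volume[lab]), 1, tolerance = 1e-12)
  expect_true(all(s1$volume[lab] >= 0))
  expect_true(all(s1$volume[!lab] == 0))
  bad <- atlas
  bad$parcels$sigma[1] <- -1
  expect_error(simulate_subject(bad, 40, eff, seed = 1), "sigma")
})

test_that("null effects leave expected parcel means age-invariant", {
  atlas <- small_atlas()
  eff <- age_effect_model(unique(atlas$parcels$network))  # all "none"
  # average parcel sample means over seeds at two ages: differences are
  # noise-level only
  mean_at <- function(age) {
    ms <- replicate(8, {
      s <- simulate_subject(atlas, age, eff,
                            seed = sample.int(1e6, 1), subject_sd = 0.008)
      smp <- extract_parcel_samples(s$volume, atlas, min_voxels = 800L)
      vapply(smp$samples, mean, numeric(1))
    })
    rowMeans(ms)
  }
  set.seed(123)
  m25 <- mean_at(25); m75 <- mean_at(75)
  expect_equal(m25, m75, tolerance = 0.02)
})

test_that("linear dispersion growth lowers network KLS monotonically with age", {
  atlas <- small_atlas(sizes = c(net_a = 6L, net_b = 6L))
  eff <- age_effect_model(c("net_a", "net_b"),
                          list(net_a = age_effect_linear(change = 0.5)))
  mean_kls_at <- function(age, seeds) {
    mean(vapply(seeds, function(sd) {
      s <- simulate_subject(atlas, age, eff, seed = sd)
      m <- subject_matrix(s$volume, atlas)
      ids <- as.character(atlas$parcels$parcel_id[atlas$parcels$network == "net_a"])
      mean_strength(m, ids)
    }, numeric(1)))
  }
  seeds <- 1:20
  kls <- vapply(c(25, 50, 75), mean_kls_at, numeric(1), seeds = seeds)
  expect_true(kls[1] > kls[2])
  expect_true(kls[2] > kls[3])
})

test_that("two-parcel phantom reproduces the analytic Gaussian edge weight", {
  # parcels 1 sigma apart in mean: generating distributions N(1.0, 0.1) and
  # N(1.1, 0.1); analytic symmetric KL = (0.1/0.1)^2 = 1, edge = exp(-1).
  spec <- phantom_spec(volume_shape = c(30L, 30L, 12L), parcel_voxels = 5000L,
                       network_sizes = c(a = 1L, b = 1L),
                       delta = c(0, 0.1), sigma = 0.1)
  atlas <- build_phantom_atlas(spec)
  eff <- age_effect_model(c("a", "b"))
  w <- mean(vapply(1:10, function(sd) {
    s <- simulate_subject(atlas, 50, eff, seed = sd, subject_sd = 0)
    m <- subject_matrix(s$volume, atlas, min_voxels = 5000L)
    m$weights[1, 2]
  }, numeric(1)))
  expect_equal(w, exp(-1), tolerance = 0.05)
})

test_that("null cohorts rarely show a significant strength-age slope", {
  # type-I behaviour of the full pipeline: with every network flat in age,
  # the whole-matrix mean-strength regression should stay non-significant in
  # at least 90% of cohorts (nominal rate 95%). Atlas reduced to 16 parcels
  # to keep 50 cohorts of n = 67 affordable.
  atlas <- small_atlas(sizes = c(net_a = 8L, net_b = 8L), seed = 6)
  eff <- age_effect_model(c("net_a", "net_b"))
  nonsig <- vapply(1:50, function(cc) {
    coh <- simulate_cohort(atlas, n = 67, effects = eff, seed = 7000L + cc)
    y <- vapply(coh$subjects, function(s)
      mean_strength(subject_matrix(s$volume, atlas)), numeric(1))
    fit_age_models(y, coh$cohort$age)$linear$p >= 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.9)
})

test_that("dispersion scaling forms honour the effect-kind invariants", {
  e0 <- age_effect("none")
  expect_equal(scaling_at(e0, 20), scaling_at(e0, 80))
  el <- age_effect_linear(change = 0.3, age_range = c(20, 82))
  expect_equal(scaling_at(el, 20), 1)
  expect_equal(scaling_at(el, 82), 1.3)
  eq <- age_effect_quadratic(change = 0.3, age_range = c(20, 82))
  expect_equal(scaling_at(eq, 20), 1)
  expect_equal(scaling_at(eq, 82), 1.3)
  # quadratic: flat near the young end, accelerating later
  expect_lt(scaling_at(eq, 30) - scaling_at(eq, 20),
            scaling_at(eq, 82) - scaling_at(eq, 72))
})
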