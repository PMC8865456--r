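#' Age-dependent dispersion scaling for one network
#'
#' The phantom generator models aging as a growth of the dispersion of parcel
#' mean uptake within a network: voxel intensities of parcel p in a subject
#' of a given age are drawn from `N(1 + delta_p * s(age), sigma_p)` where
#' `s(age)` is the network's dispersion scaling. A growing `s` pulls parcel
#' means apart, increases the pairwise divergence of their intensity
#' densities, and therefore lowers KLS connectivity strength — the mechanism
#' by which the phantom emulates an age-related loss of metabolic
#' connectivity.
#'
#' @param kind One of `"none"` (constant `s`), `"linear"`
#'   (`s = a + b*age`) or `"quadratic"` (`s = a + b*age + c*age^2`).
#' @param a,b,c Polynomial coefficients of `s(age)`.
#' @return Object of class `age_effect`.
#' @seealso [age_effect_linear()], [age_effect_quadratic()]
#' @export
age_effect <- function(kind = c("none", "linear", "quadratic"),
                       a = 1, b = 0, c = 0) {
  kind <- match.arg(kind)
  if (kind == "none") { b <- 0; c <- 0 }
  if (kind == "linear") c <- 0
  structure(list(kind = kind, a = a, b = b, c = c), class = "age_effect")
}

#' Linearly growing dispersion effect
#'
#' Convenience constructor: `s(age)` rises linearly from 1 at `age_range[1]`
#' to `1 + change` at `age_range[2]`.
#'
#' @param change Total increase of the dispersion scaling over the age range
#'   (default 0.3, i.e. parcel-mean dispersion grows by 30% across the
#'   lifespan).
#' @param age_range Ages at which `s` equals 1 and `1 + change`.
#' @export
age_effect_linear <- function(change = 0.3, age_range = c(20, 82)) {
  b <- change / diff(age_range)
  age_effect("linear", a = 1 - b * age_range[1], b = b)
}

#' Quadratically growing dispersion effect
#'
#' `s(age) = 1 + k (age - age_range[1])^2`, reaching `1 + change` at
#' `age_range[2]`: dispersion is flat in young adulthood and accelerates in
#' the elderly.
#'
#' @inheritParams age_effect_linear
#' @export
age_effect_quadratic <- function(change = 0.3, age_range = c(20, 82)) {
  k <- change / diff(age_range)^2
  a0 <- age_range[1]
  age_effect("quadratic", a = 1 + k * a0^2, b = -2 * k * a0, c = k)
}

#' Evaluate an age effect's dispersion scaling
#' @param effect An [age_effect()].
#' @param age Age(s) in years.
#' @return `s(age)`.
#' @export
scaling_at <- function(effect, age) {
  stopifnot(inherits(effect, "age_effect"))
  effect$a + effect$b * age + effect$c * age^2
}

#' Per-network age effect model
#'
#' Assigns one [age_effect()] per functional network. Networks not listed get
#' the null effect (`"none"`). The default emulates the age structure
#' observed in healthy-aging metabolic connectivity cohorts: a linear
#' dispersion growth in the default mode, control, dorsal attention and
#' ventral attention networks, a quadratic (accelerating) growth in the
#' frontoparietal network, and no effect in the somatomotor, limbic and
#' visual networks.
#'
#' @param networks Character vector of all network names in the atlas.
#' @param effects Named list of [age_effect()] objects, one per affected
#'   network.
#' @return Object of class `age_effect_model`: a named list of `age_effect`s
#'   covering every network.
#' @export
age_effect_model <- function(networks, effects = list()) {
  if (!all(names(effects) %in% networks))
    stop("age_effect_model: effects name networks absent from the atlas", call. = FALSE)
  out <- setNames(rep(list(age_effect("none")), length(networks)), networks)
  for (nm in names(effects)) {
    stopifnot(inherits(effects[[nm]], "age_effect"))
    out[[nm]] <- effects[[nm]]
  }
  structure(out, class = "age_effect_model")
}

#' @rdname age_effect_model
#' @export
default_age_effects <- function(networks = names(default_network_sizes())) {
  lin <- c("default_mode", "control", "dorsal_attention", "ventral_attention")
  eff <- setNames(rep(list(age_effect_linear()), length(lin)), lin)
  if ("frontoparietal" %in% networks)
    eff$frontoparietal <- age_effect_quadratic()
  age_effect_model(networks, eff[names(eff) %in% networks])
}

#' Sample cohort ages
#'
#' @param n Number of subjects (>= 1).
#' @param age_range Closed interval of ages in years.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Numeric vector of `n` ages drawn uniformly over `age_range`.
#' @export
sample_cohort_ages <- function(n, age_range = c(20, 82), seed = NULL) {
  if (n < 1) stop("sample_cohort_ages: n must be >= 1", call. = FALSE)
  if (length(age_range) != 2L || age_range[2] < age_range[1])
    stop("sample_cohort_ages: empty age range", call. = FALSE)
  with_seed(seed, runif(n, age_range[1], age_range[2]))
}

#' Simulate one subject's intensity volume
#'
#' Voxel intensities of each parcel are drawn from a Gaussian truncated at 0
#' (negative draws are redrawn, keeping the density smooth) with mean
#' `1 + (delta_p + eps_p) * s_g(age)` and standard deviation `sigma_p`, where
#' `s_g` is the age effect of the parcel's network and `eps_p` is a
#' subject-specific perturbation of the parcel offset
#' (`eps_p ~ N(0, subject_sd)`) providing inter-subject variability of the
#' regional uptake pattern. The labelled voxels are then recentred so their
#' global mean is exactly 1. Background voxels are 0.
#'
#' @param atlas A phantom [parcellation_atlas()] carrying `delta` and `sigma`
#'   columns in its parcel table.
#' @param age Subject age in years.
#' @param effects An [age_effect_model()] covering the atlas networks.
#' @param seed Integer seed for this subject's draws.
#' @param subject_sd Standard deviation of the subject-level offset
#'   perturbation (default 0.008).
#' @return List of class `synthetic_subject` with elements `age`, `seed` and
#'   `volume` (numeric array shaped like the atlas labels).
#' @export
simulate_subject <- function(atlas, age, effects, seed = NULL,
                             subject_sd = 0.008) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  pt <- atlas$parcels
  if (is.null(pt$delta) || is.null(pt$sigma))
    stop("simulate_subject: atlas parcel table lacks delta/sigma (not a phantom atlas?)",
         call. = FALSE)
  if (any(pt$sigma <= 0))
    stop("simulate_subject: sigma must be positive", call. = FALSE)
  nets <- unique(pt$network)
  if (!all(nets %in% names(effects)))
    stop("simulate_subject: effects missing for some networks", call. = FALSE)
  s <- vapply(pt$network, function(g) scaling_at(effects[[g]], age), numeric(1))
  vol <- with_seed(seed, {
    eps <- rnorm(nrow(pt), 0, subject_sd)
    mu <- 1 + (pt$delta + eps) * s
    v <- numeric(length(atlas$labels))
    lab <- as.integer(atlas$labels)
    idx <- which(lab > 0L)
    p_of_vox <- lab[idx]
    x <- rnorm(length(idx), mu[p_of_vox], pt$sigma[p_of_vox])
    bad <- which(x < 0)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mu[p_of_vox[bad]], pt$sigma[p_of_vox[bad]])
      bad <- bad[x[bad] < 0]
    }
    v[idx] <- x / mean(x)  # recentre: global labelled mean = 1
    array(v, dim = dim(atlas$labels))
  })
  structure(list(age = age, seed = seed, volume = vol),
            class = "synthetic_subject")
}

#' Simulate a phantom cohort
#'
#' @param atlas Phantom atlas from [build_phantom_atlas()].
#' @param n Number of subjects (default 67).
#' @param age_range Age range in years (default 20 to 82).
#' @param effects [age_effect_model()]; defaults to [default_age_effects()]
#'   over the atlas networks.
#' @param seed Master seed; ages and per-subject seeds derive from it.
#' @param subject_sd Passed to [simulate_subject()].
#' @return List of class `synthetic_cohort` with `cohort` (data frame:
#'   `subject_id`, `age`, `seed`) and `subjects` (list of volumes).
#' @export
simulate_cohort <- function(atlas, n = 67L, age_range = c(20, 82),
                            effects = NULL, seed = 1L, subject_sd = 0.008) {
  if (is.null(effects))
    effects <- default_age_effects(unique(atlas$parcels$network))
  ages <- sample_cohort_ages(n, age_range, seed = seed)
  sub_seeds <- with_seed(seed + 1L, sample.int(.Machine$integer.max - 1L, n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulate_subject(atlas, ages[i], effects,
                                      seed = sub_seeds[i],
                                      subject_sd = subject_sd)
  }
  structure(
    list(cohort = data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                             age = ages, seed = sub_seeds,
                             stringsAsFactors = FALSE),
         subjects = subjects, effects = effects),
    class = "synthetic_cohort"
  )
}

#' Closed-form Gaussian KL similarity (test oracle)
#'
#' Analytic KLS between two univariate Gaussians,
#' `exp(-(KL(P||Q) + KL(Q||P)))` with the closed-form Gaussian KL divergence.
#' Used as an independent oracle for the grid-based divergence computation:
#' for equal standard deviations the symmetric divergence reduces to
#' `(mu1 - mu2)^2 / sd^2`.
#'
#' @param mu1,sd1,mu2,sd2 Means and standard deviations (`sd > 0`).
#' @return Similarity in (0, 1].
#' @examples
#' analytic_kls_gaussian(1.0, 0.1, 1.1, 0.1)  # exp(-1)
#' @export
analytic_kls_gaussian <- function(mu1, sd1, mu2, sd2) {
  if (any(c(sd1, sd2) <= 0))
    stop("analytic_kls_gaussian: standard deviations must be positive", call. = FALSE)
  kl <- function(m1, s1, m2, s2)
    log(s2 / s1) + (s1^2 + (m1 - m2)^2) / (2 * s2^2) - 0.5
  exp(-(kl(mu1, sd1, mu2, sd2) + kl(mu2, sd2, mu1, sd1)))
}
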