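#' Fit linear and quadratic age models to a metric
#'
#' Ordinary least squares fits of `y = b0 + b1*age` and
#' `y = b0 + b1*age + b2*age^2`. Each fit reports its coefficients, error and
#' total sums of squares, the overall regression p-value (F test against the
#' intercept-only model) and the coefficient of multiple correlation
#' `r = sqrt(1 - SSE/SST)`.
#'
#' @param values Metric value per subject.
#' @param ages Subject ages in years (not all equal; n >= 4).
#' @return List with elements `linear` and `quadratic`, each a list
#'   `coef`, `sse`, `sst`, `p`, `r`, `n`, `df_model`.
#' @export
fit_age_models <- function(values, ages) {
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  n <- length(values)
  if (n < 4L) stop("fit_age_models: need at least 4 subjects", call. = FALSE)
  if (length(unique(ages)) < 3L)
    stop("fit_age_models: ages are (nearly) all equal", call. = FALSE)
  sst <- sum((values - mean(values))^2)
  one <- function(fit, df_model) {
    sse <- sum(stats::residuals(fit)^2)
    f <- if (sse <= 0 && sst <= 0) NA_real_
         else ((sst - sse) / df_model) / (sse / (n - df_model - 1L))
    p <- if (is.na(f)) NA_real_ else pf(f, df_model, n - df_model - 1L,
                                        lower.tail = FALSE)
    r2 <- if (sst > 0) max(0, 1 - sse / sst) else 0
    list(coef = unname(coef(fit)), sse = sse, sst = sst, p = p,
         r = sqrt(r2), n = n, df_model = df_model)
  }
  lin <- stats::lm(values ~ ages)
  quad <- stats::lm(values ~ ages + I(ages^2))
  list(linear = one(lin, 1L), quadratic = one(quad, 2L))
}

#' Select between the linear and quadratic age model
#'
#' Extra-sum-of-squares F test for the quadratic term:
#' `F = (SSE_lin - SSE_quad) / (SSE_quad / (n - 3))` with 1 and n-3 degrees
#' of freedom. The quadratic model is chosen iff the added term is
#' significant at `alpha`; when both models interpolate exactly (both SSE
#' zero) the simpler linear model is retained. The chosen fit is flagged
#' non-significant when its own overall p-value is at or above `alpha`
#' (reported as "/" in the text report).
#'
#' @param fits Result of [fit_age_models()].
#' @param alpha Significance level (default 0.05).
#' @return List of class `age_model_fit`: `kind` ("linear"/"quadratic"),
#'   `coef` (b0, b1 and, for quadratic, b2), `p`, `r`, `n`, `significant`,
#'   `f_quad`, `p_quad`.
#' @export
select_model <- function(fits, alpha = 0.05) {
  lin <- fits$linear; quad <- fits$quadratic
  n <- lin$n
  if (n <= 3L) stop("select_model: insufficient data", call. = FALSE)
  delta <- max(lin$sse - quad$sse, 0)
  if (quad$sse <= 0) {
    if (delta <= 0) {  # both interpolate: keep the simpler model
      f_quad <- NA_real_; p_quad <- NA_real_; use_quad <- FALSE
    } else {
      f_quad <- Inf; p_quad <- 0; use_quad <- TRUE
    }
  } else {
    f_quad <- delta / (quad$sse / (n - 3L))
    p_quad <- pf(f_quad, 1L, n - 3L, lower.tail = FALSE)
    use_quad <- is.finite(p_quad) && p_quad < alpha
  }
  chosen <- if (use_quad) quad else lin
  structure(
    list(kind = if (use_quad) "quadratic" else "linear",
         coef = chosen$coef, p = chosen$p, r = chosen$r, n = n,
         significant = is.finite(chosen$p) && chosen$p < alpha,
         f_quad = f_quad, p_quad = p_quad),
    class = "age_model_fit"
  )
}

#' Construct an age model fit from known coefficients
#'
#' Builds an `age_model_fit` directly from published or externally estimated
#' coefficients, e.g. to recompute predicted values from a reported
#' regression table.
#'
#' @param coef Numeric coefficients `(b0, b1)` or `(b0, b1, b2)`.
#' @param kind `"linear"` or `"quadratic"`; inferred from the length of
#'   `coef` when omitted.
#' @export
age_model_from_coef <- function(coef, kind = NULL) {
  if (is.null(kind)) kind <- if (length(coef) >= 3L) "quadratic" else "linear"
  structure(list(kind = kind, coef = coef, p = NA_real_, r = NA_real_,
                 n = NA_integer_, significant = NA, f_quad = NA_real_,
                 p_quad = NA_real_),
            class = "age_model_fit")
}

#' Predicted metric values at two ages and the lifespan change
#'
#' Evaluates the chosen model at `age_low` and `age_high` (defaults 20 and
#' 80 years) and reports the percent difference
#' `100 * (Y(high) - Y(low)) / Y(low)`. Reported values are additionally
#' rounded the way results tables print them — predictions to 2 decimals,
#' percent difference to 1 decimal, halves away from zero — while the `raw`
#' element keeps full precision.
#'
#' @param fit An `age_model_fit`.
#' @param age_low,age_high Ages to compare (defaults 20 and 80).
#' @return List with `raw` (`pred_low`, `pred_high`, `pct_diff` at full
#'   precision) and `reported` (rounded values).
#' @export
predict_and_diff <- function(fit, age_low = 20, age_high = 80) {
  stopifnot(inherits(fit, "age_model_fit"))
  yhat <- function(a) {
    b <- fit$coef
    b[1L] + b[2L] * a + if (length(b) >= 3L) b[3L] * a^2 else 0
  }
  lo <- yhat(age_low); hi <- yhat(age_high)
  pct <- 100 * (hi - lo) / lo
  list(raw = list(pred_low = lo, pred_high = hi, pct_diff = pct),
       reported = list(pred_low = round_half_up(lo, 2),
                       pred_high = round_half_up(hi, 2),
                       pct_diff = round_half_up(pct, 1)))
}

#' Split a cohort into age tertile groups
#'
#' Age-sorted split into young / middle-aged / old groups with sizes as
#' equal as possible; any remainder is assigned from the oldest group down
#' (n = 67 gives 22/22/23). Ties in age are broken by subject order.
#'
#' @param ages Subject ages.
#' @return Factor with levels `young`, `middle`, `old`, one per subject, in
#'   input order.
#' @export
tertile_groups <- function(ages) {
  n <- length(ages)
  if (n < 3L) stop("tertile_groups: need at least 3 subjects", call. = FALSE)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(young = base, middle = base, old = base)
  if (rem >= 1L) sizes["old"] <- sizes["old"] + 1L
  if (rem == 2L) sizes["middle"] <- sizes["middle"] + 1L
  ord <- order(ages, seq_len(n))
  grp <- rep(factor(c("young", "middle", "old"),
                    levels = c("young", "middle", "old")), times = sizes)
  out <- factor(rep(NA_character_, n), levels = levels(grp))
  out[ord] <- grp
  out
}

#' Group-wise mean and coefficient-of-variation matrices
#'
#' Elementwise mean and coefficient of variation (sample sd / mean) of the
#' connectivity matrices of each group — the group-level summary of the
#' individual networks.
#'
#' @param matrices List of `connectivity_matrix` objects or weight matrices
#'   with identical node sets.
#' @param groups Factor with one level per group, same length as
#'   `matrices`.
#' @return Named list per group, each with `mean` and `cov` matrices and
#'   `n`.
#' @export
group_matrix_summary <- function(matrices, groups) {
  ws <- lapply(matrices, as_weights)
  ids <- rownames(ws[[1L]])
  if (!all(vapply(ws, function(w) identical(rownames(w), ids), logical(1))))
    stop("group_matrix_summary: matrices have differing node sets", call. = FALSE)
  groups <- as.factor(groups)
  out <- list()
  for (g in levels(groups)) {
    sel <- ws[groups == g]
    if (length(sel) < 2L)
      stop("group_matrix_summary: need at least 2 matrices per group", call. = FALSE)
    arr <- simplify2array(sel)
    mu <- apply(arr, c(1L, 2L), mean)
    sdv <- apply(arr, c(1L, 2L), sd)
    out[[g]] <- list(mean = mu, cov = sdv / mu, n = length(sel))
  }
  out
}

#' Age regression report across metrics and scopes
#'
#' For every metric in every scope of a per-subject [network_summary()]
#' stack (whole brain, each functional network, and between-network strength
#' pairs), fits linear and quadratic age models, selects one by the
#' extra-sum-of-squares F test, and reports the chosen model with its
#' p-value, r, coefficients, predictions at 20 and 80 years and the lifespan
#' percent difference. Rows whose overall p-value is at or above `alpha` are
#' marked non-significant (`model = "/"` in the printed table convention)
#' and their predictions are withheld.
#'
#' @param summaries List of per-subject data frames from
#'   [network_summary()], one per subject.
#' @param ages Subject ages, same order.
#' @param alpha Significance level (default 0.05).
#' @param age_low,age_high Comparison ages (defaults 20/80).
#' @return Data frame with one row per metric x scope: `metric`, `scope`,
#'   `model`, `p`, `r`, `b0`, `b1`, `b2`, `pred20`, `pred80`, `pct_diff`,
#'   `significant`.
#' @export
age_regression_report <- function(summaries, ages, alpha = 0.05,
                                  age_low = 20, age_high = 80) {
  stopifnot(length(summaries) == length(ages))
  proto <- summaries[[1L]]
  metric_cols <- c("strength", "path_length", "clustering", "local_efficiency")
  rows <- list()
  for (s in seq_len(nrow(proto))) {
    for (mc in metric_cols) {
      vals <- vapply(summaries, function(df) df[[mc]][s], numeric(1))
      if (all(is.na(vals))) next
      fits <- fit_age_models(vals, ages)
      fit <- select_model(fits, alpha)
      pr <- predict_and_diff(fit, age_low, age_high)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mc, scope = proto$scope[s], scope_type = proto$type[s],
        model = if (fit$significant) fit$kind else "/",
        p = fit$p, r = if (fit$significant) fit$r else NA_real_,
        b0 = if (fit$significant) fit$coef[1L] else NA_real_,
        b1 = if (fit$significant) fit$coef[2L] else NA_real_,
        b2 = if (fit$significant && length(fit$coef) >= 3L) fit$coef[3L] else NA_real_,
        pred20 = if (fit$significant) pr$reported$pred_low else NA_real_,
        pred80 = if (fit$significant) pr$reported$pred_high else NA_real_,
        pct_diff = if (fit$significant) pr$reported$pct_diff else NA_real_,
        significant = fit$significant,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Full cohort analysis
#'
#' Ties the per-subject stages together for a cohort of connectivity
#' matrices: per-subject scope summaries, the age regression report, hub
#' identification with per-group hub-count summaries (median and IQR for the
#' whole cohort and the age tertiles), and group-wise mean /
#' coefficient-of-variation matrices.
#'
#' @param matrices List of `connectivity_matrix` objects, one per subject.
#' @param parcels Parcel table (columns `parcel_id`, `network`).
#' @param ages Subject ages, same order as `matrices`.
#' @param alpha Significance level for model selection and reporting.
#' @param top_fraction Hub criterion fraction (default 0.20).
#' @param include_pairs Analyze between-network strength pairs.
#' @param metrics Metrics to include (reducing this skips expensive scopes).
#' @param group_matrices Also compute group mean/CoV matrices (default
#'   FALSE; they are large).
#' @return List with `report` (age regression table), `hub_counts`
#'   (median/IQR per scope per group), `summaries`, `hubs`, `groups` and
#'   optionally `group_matrices`.
#' @export
run_full_analysis <- function(matrices, parcels, ages, alpha = 0.05,
                              top_fraction = 0.20, include_pairs = TRUE,
                              metrics = c("strength", "path_length",
                                          "clustering", "local_efficiency"),
                              group_matrices = FALSE) {
  if (length(matrices) < 4L)
    stop("run_full_analysis: need at least 4 subjects", call. = FALSE)
  summaries <- lapply(matrices, network_summary, parcels = parcels,
                      include_pairs = include_pairs, metrics = metrics)
  report <- age_regression_report(summaries, ages, alpha)
  hubs <- lapply(matrices, function(m)
    identify_hubs(nodal_metrics(m), top_fraction))
  counts <- lapply(hubs, count_hubs_by_scope, parcels = parcels)
  groups <- tertile_groups(ages)
  scopes <- counts[[1L]]$scope
  hub_rows <- list()
  med_iqr <- function(x)
    sprintf("%g (%g-%g)", median(x),
            quantile(x, 0.25, type = 1), quantile(x, 0.75, type = 1))
  for (s in seq_along(scopes)) {
    cnt <- vapply(counts, function(df) df$n_hubs[s], numeric(1))
    hub_rows[[s]] <- data.frame(
      scope = scopes[s],
      all = med_iqr(cnt),
      young = med_iqr(cnt[groups == "young"]),
      middle = med_iqr(cnt[groups == "middle"]),
      old = med_iqr(cnt[groups == "old"]),
      median_all = median(cnt),
      stringsAsFactors = FALSE
    )
  }
  out <- list(report = report, hub_counts = do.call(rbind, hub_rows),
              summaries = summaries, hubs = hubs, groups = groups)
  if (group_matrices)
    out$group_matrices <- group_matrix_summary(matrices, groups)
  out
}
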