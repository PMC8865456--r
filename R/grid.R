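#' Standardized histogram grid
#'
#' All parcel densities within one analysis are evaluated on a single shared
#' grid (fixed range, fixed bin size) so that densities of different parcels
#' and different subjects are directly comparable. The default range of
#' \[0, 3\] in grey-matter-normalized uptake units with 256 points covers the
#' plausible span of normalized uptake values.
#'
#' @param lower,upper Grid range in normalized-uptake units (`upper > lower`).
#' @param bins Number of grid points (>= 2).
#' @return An object of class `standard_grid` with elements `lower`, `upper`,
#'   `bins`, `points` (the grid point locations) and `step` (the spacing).
#' @examples
#' g <- standard_grid()
#' length(g$points)
#' @export
standard_grid <- function(lower = 0, upper = 3, bins = 256L) {
  if (!is.numeric(lower) || !is.numeric(upper) || upper <= lower)
    stop("standard_grid: need upper > lower", call. = FALSE)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L)
    stop("standard_grid: need at least 2 bins", call. = FALSE)
  pts <- seq(lower, upper, length.out = bins)
  structure(
    list(lower = lower, upper = upper, bins = bins,
         points = pts, step = pts[2L] - pts[1L]),
    class = "standard_grid"
  )
}

#' @export
print.standard_grid <- function(x, ...) {
  cat(sprintf("<standard_grid> [%g, %g], %d points (step %.5g)\n",
              x$lower, x$upper, x$bins, x$step))
  invisible(x)
}

grid_equal <- function(a, b) {
  inherits(a, "standard_grid") && inherits(b, "standard_grid") &&
    isTRUE(a$lower == b$lower) && isTRUE(a$upper == b$upper) &&
    isTRUE(a$bins == b$bins)
}

# trapezoidal quadrature weights of a grid
trapz_weights <- function(grid) {
  w <- rep(grid$step, grid$bins)
  w[c(1L, grid$bins)] <- grid$step / 2
  w
}

# trapezoidal integral of values sampled on the grid
trapz <- function(y, grid) sum(y * trapz_weights(grid))

# round half away from zero, the convention used for reported tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run code with an isolated RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
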