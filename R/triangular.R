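#' Triangular distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter triangular distribution on `[min, max]` with
#' most-probable value `mode`. The degenerate case `min == mode == max` is a
#' point mass, used for cost cells supported by a single observation (or an
#' imputed value).
#'
#' Random generation uses the closed-form inverse CDF, so draws are fully
#' reproducible under R's seeded RNG stream.
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param min,mode,max Distribution parameters, `min <= mode <= max`.
#' @return Numeric vector.
#' @name triangular
NULL

check_tri <- function(min, mode, max) {
  if (!(min <= mode && mode <= max)) {
    abort("Triangular parameters must satisfy min <= mode <= max",
          class = "coi_config_error")
  }
}

#' @rdname triangular
#' @export
dtriangular <- function(x, min, mode, max) {
  check_tri(min, mode, max)
  if (min == max) return(ifelse(x == min, Inf, 0))
  ifelse(x < min | x > max, 0,
         ifelse(x < mode, 2 * (x - min) / ((max - min) * (mode - min)),
                ifelse(x == mode, 2 / (max - min),
                       2 * (max - x) / ((max - min) * (max - mode)))))
}

#' @rdname triangular
#' @export
ptriangular <- function(q, min, mode, max) {
  check_tri(min, mode, max)
  if (min == max) return(as.numeric(q >= min))
  ifelse(q <= min, 0,
         ifelse(q >= max, 1,
                ifelse(q <= mode,
                       (q - min)^2 / ((max - min) * (mode - min)),
                       1 - (max - q)^2 / ((max - min) * (max - mode)))))
}

#' @rdname triangular
#' @export
qtriangular <- function(p, min, mode, max) {
  check_tri(min, mode, max)
  stopifnot(all(p >= 0 & p <= 1))
  if (min == max) return(rep(min, length(p)))
  fc <- (mode - min) / (max - min)
  ifelse(p < fc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

#' @rdname triangular
#' @export
rtriangular <- function(n, min, mode, max) {
  qtriangular(runif(n), min, mode, max)
}

#' Fit a triangular distribution to article-level cost values
#'
#' Bounds at the lowest and highest cost provided by any article; the most
#' probable value is the un-weighted article mean (or median, see
#' `mode_stat`), clamped into the bounds. A single value yields a degenerate
#' point mass.
#'
#' @param values Harmonized per-patient amounts across articles (length
#'   >= 1).
#' @param mode_stat `"mean"` (default) or `"median"`.
#' @return A list of class `coi_triangular` with `min`, `mode`, `max`,
#'   `degenerate`, `n_values`.
#' @examples
#' fit_triangular(c(2, 3, 7)) # min 2, mode 4, max 7
#' @export
fit_triangular <- function(values, mode_stat = c("mean", "median")) {
  mode_stat <- match.arg(mode_stat)
  values <- values[!is.na(values)]
  if (!length(values)) {
    abort("fit_triangular() needs at least one value",
          class = "coi_validation_error")
  }
  lo <- min(values)
  hi <- max(values)
  m <- if (mode_stat == "mean") mean(values) else median(values)
  structure(list(min = lo, mode = min(max(m, lo), hi), max = hi,
                 degenerate = lo == hi, n_values = length(values)),
            class = "coi_triangular")
}

# analytic mean (min + mode + max) / 3; the point mass returns its value
triangular_mean <- function(tri) {
  if (tri$degenerate) tri$min else (tri$min + tri$mode + tri$max) / 3
}

degenerate_triangular <- function(value) {
  structure(list(min = value, mode = value, max = value, degenerate = TRUE,
                 n_values = 0L),
            class = "coi_triangular")
}

#' @export
print.coi_triangular <- function(x, ...) {
  if (x$degenerate) {
    cat("<triangular> point mass at", format(x$min), "\n")
  } else {
    cat("<triangular> min", format(x$min), "mode", format(x$mode),
        "max", format(x$max), "\n")
  }
  invisible(x)
}
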