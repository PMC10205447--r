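# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific 32-bit seed from a base seed. Offsets keep the
# pipeline stages on independent, reproducible streams.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% .Machine$integer.max)
}

#' Truncated normal draws via inverse-CDF
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Vectorised weighted categorical draw: one draw per row of `prob` (rows need
# not be normalised). Returns integer column indices.
sample_rows <- function(prob) {
  n <- nrow(prob)
  cs <- prob / pmax(rowSums(prob), .Machine$double.xmin)
  cum <- t(apply(cs, 1L, cumsum))
  u <- stats::runif(n)
  idx <- rowSums(cum < u) + 1L
  pmin(idx, ncol(prob))
}

#' Age-band labels for a set of breaks
#'
#' Breaks are lower bounds; the last band is open-ended ("95+").
#' @noRd
age_band_labels <- function(breaks) {
  k <- length(breaks)
  c(paste0(breaks[-k], "-", breaks[-1L] - 1L), paste0(breaks[k], "+"))
}

age_band_of <- function(age, breaks) {
  labs <- age_band_labels(breaks)
  labs[findInterval(age, breaks) ]
}

# Integer age range covered by a band label, intersected with [lo, hi].
band_age_range <- function(band, breaks, lo = 0L, hi = 110L) {
  labs <- age_band_labels(breaks)
  i <- match(band, labs)
  if (is.na(i)) stop("unknown age band: ", band)
  a <- breaks[i]
  b <- if (i < length(breaks)) breaks[i + 1L] - 1L else hi
  c(max(a, lo), min(b, hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

euclid_km <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2) / 1000

# Pairwise centroid distance matrix (km) for a zones table.
zone_distance_matrix <- function(zones) {
  d <- as.matrix(stats::dist(cbind(zones$centroid_x, zones$centroid_y))) / 1000
  dimnames(d) <- list(zones$zone_id, zones$zone_id)
  d
}

stopf <- function(fmt, ..., class = "actipop_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "actipop_error")))
}

warnf <- function(fmt, ..., class = "actipop_warning") {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "actipop_warning")))
}
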