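# Evaluation metrics: Jensen-Shannon distance and marginal percentage
# differences against the zone-level controls.

#' Jensen-Shannon distance between two discrete distributions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the distance lies in [0, 1]: 0 iff the distributions are identical, 1 for
#' disjoint supports.
#'
#' @param p,q Probability vectors of equal length (each summing to 1).
#' @return A number in [0, 1].
#' @examples
#' js_distance(c(1, 0), c(0, 1))  # 1
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stopf("p and q must have equal length", class = "actipop_input_error")
  }
  if (any(p < 0) || any(q < 0)) {
    stopf("probability vectors must be non-negative",
          class = "actipop_input_error")
  }
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stopf("probability vectors must sum to 1 (got %.12f and %.12f)",
          sum(p), sum(q), class = "actipop_input_error")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d2 <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(d2, 0))
}

#' Histogram-based Jensen-Shannon distance between two samples
#'
#' Bins both samples on a common grid and compares the resulting discrete
#' distributions.
#' @param x,y Numeric samples.
#' @param breaks Bin edges (default hourly bins over [0, 24]).
#' @return A number in [0, 1].
#' @export
js_distance_samples <- function(x, y, breaks = 0:24) {
  px <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), length(breaks) - 1)
  py <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), length(breaks) - 1)
  js_distance(px / sum(px), py / sum(py))
}

#' Marginal percentage differences against zone controls
#'
#' For every zone and controlled attribute category, reports
#' `(synthetic - target) / target * 100`, plus a summary of the share of
#' zone-attribute cells falling inside the +/-0.5% and +/-1% bands.
#'
#' @param persons Synthesized persons (with `zone`, `gender`, `age_group`,
#'   `employment`, `studenthood`).
#' @param world The `actipop_world` carrying the controls.
#' @return list of class `marginal_report`: `detail` (one row per zone,
#'   attribute, category) and `summary` (per attribute: share of finite
#'   cells within the bands). Zones absent from `persons` are reported with
#'   `missing = TRUE`, not as an error.
#' @export
marginal_diff_report <- function(persons, world) {
  zm <- world$zone_marginals
  rows <- list()
  add <- function(zone, attribute, category, target, synth, missing = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      zone_id = zone, attribute = attribute, category = category,
      target = target, synthetic = synth,
      pct_diff = if (target > 0) (synth - target) / target * 100 else
        ifelse(synth == 0, 0, Inf),
      missing = missing, stringsAsFactors = FALSE)
  }
  for (zid in world$zones$zone_id) {
    pz <- persons[persons$zone == zid, , drop = FALSE]
    miss <- nrow(pz) == 0
    mz <- zm[zm$zone_id == zid, ]
    gt <- tapply(mz$count, mz$gender, sum)
    for (g in names(gt)) {
      add(zid, "gender", g, gt[[g]], sum(pz$gender == g), miss)
    }
    at <- tapply(mz$count, mz$age_group, sum)
    for (a in names(at)) {
      add(zid, "age_group", a, at[[a]], sum(pz$age_group == a), miss)
    }
    zrow <- world$zones[world$zones$zone_id == zid, ]
    if (!is.null(persons$employment) && !all(is.na(persons$employment))) {
      add(zid, "employment", "total", zrow$n_employees,
          sum(pz$employment, na.rm = TRUE), miss)
      add(zid, "studenthood", "total", zrow$n_students,
          sum(pz$studenthood, na.rm = TRUE), miss)
    }
  }
  detail <- do.call(rbind, rows)
  fin <- detail[is.finite(detail$pct_diff) & !detail$missing, ]
  summary <- do.call(rbind, lapply(split(fin, fin$attribute), function(d) {
    data.frame(attribute = d$attribute[1], n_cells = nrow(d),
               share_within_0.5 = mean(abs(d$pct_diff) <= 0.5),
               share_within_1 = mean(abs(d$pct_diff) <= 1),
               max_abs_pct = max(abs(d$pct_diff)), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(detail = detail, summary = summary),
            class = "marginal_report")
}

#' @export
print.marginal_report <- function(x, ...) {
  cat("Marginal agreement with zone controls:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
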