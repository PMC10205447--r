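#' Iterative proportional fitting of a K-way table to axis marginals
#'
#' Alternately rescales the slices of a non-negative array so that every
#' one-dimensional marginal matches its target vector, while preserving the
#' interaction (cross-product ratio) structure of the seed where the seed is
#' positive. Structural zeros in the seed remain zero.
#'
#' @param seed_table Non-negative numeric array (a plain vector counts as a
#'   one-axis table).
#' @param marginals List of target vectors, one per axis of `seed_table`, in
#'   axis order. All targets must sum to the same grand total.
#' @param tol Convergence tolerance on the maximum absolute marginal residual.
#' @param max_iter Maximum number of full sweeps over the axes.
#' @return An object of class `ipf_fit`: a list with elements `table` (the
#'   fitted array), `iterations`, and `residual` (max absolute marginal
#'   deviation at exit).
#' @examples
#' fit <- ipf_fit(matrix(1, 2, 2), list(c(10, 30), c(20, 20)))
#' fit$table
#' @export
ipf_fit <- function(seed_table, marginals, tol = 1e-6, max_iter = 1000L) {
  x <- as.array(seed_table)
  if (any(x < 0)) stopf("seed table has negative cells", class = "actipop_input_error")
  dims <- dim(x)
  K <- length(dims)
  if (!is.list(marginals) || length(marginals) != K) {
    stopf("need one marginal target per axis (%d axes, %d targets given)",
          K, length(marginals), class = "actipop_input_error")
  }
  for (k in seq_len(K)) {
    if (length(marginals[[k]]) != dims[k]) {
      stopf("marginal %d has length %d, axis has extent %d",
            k, length(marginals[[k]]), dims[k], class = "actipop_input_error")
    }
    if (any(marginals[[k]] < 0)) {
      stopf("marginal %d has negative entries", k, class = "actipop_input_error")
    }
  }
  totals <- vapply(marginals, sum, numeric(1))
  grand <- totals[1]
  if (max(abs(totals - grand)) > 1e-6 * max(1, abs(grand))) {
    stopf("marginal grand totals disagree (%s): IPF requires consistent totals",
          paste(format(totals), collapse = ", "), class = "actipop_input_error")
  }
  # A slice that is identically zero in the seed cannot absorb positive
  # target mass; fail fast rather than spin to max_iter.
  for (k in seq_len(K)) {
    cur <- apply(x, k, sum)
    dead <- cur == 0 & marginals[[k]] > 0
    if (any(dead)) {
      stopf("axis %d: all-zero seed slice(s) %s carry positive target mass",
            k, paste(which(dead), collapse = ","), class = "actipop_input_error")
    }
  }
  if (grand == 0) {
    return(structure(list(table = x * 0, iterations = 0L, residual = 0),
                     class = "ipf_fit"))
  }

  resid <- function(x) {
    max(vapply(seq_len(K), function(k) {
      max(abs(apply(x, k, sum) - marginals[[k]]))
    }, numeric(1)))
  }

  it <- 0L
  repeat {
    it <- it + 1L
    for (k in seq_len(K)) {
      cur <- apply(x, k, sum)
      fac <- ifelse(cur > 0, marginals[[k]] / cur, 0)
      x <- sweep(x, k, fac, `*`)
    }
    r <- resid(x)
    if (r <= tol) {
      return(structure(list(table = x, iterations = it, residual = r),
                       class = "ipf_fit"))
    }
    if (it >= max_iter) {
      stopf("IPF did not converge in %d iterations (residual %.3g)",
            max_iter, r, class = "actipop_convergence_error")
    }
  }
}

#' @export
print.ipf_fit <- function(x, ...) {
  cat(sprintf("IPF fit: %s table, %d iteration(s), residual %.3g\n",
              paste(dim(x$table), collapse = "x"), x$iterations, x$residual))
  invisible(x)
}

#' Integerize a fractional table by truncate-replicate-sample
#'
#' Floors every cell and then allocates the remaining units (rounded total
#' minus the floor sum) one at a time by sampling cells without replacement
#' with probability proportional to their fractional parts. The output total
#' equals `round(sum(x))` and no cell moves by one or more except through the
#' stochastic remainder allocation.
#'
#' @param x Non-negative numeric vector, matrix, or array.
#' @param seed Optional integer seed for the remainder draw.
#' @return Integer array of the same shape.
#' @export
integerize <- function(x, seed = NULL) {
  if (any(x < 0)) stopf("cells must be non-negative", class = "actipop_input_error")
  with_seed(seed, {
    fl <- floor(x + 1e-9)                    # guard against 2.9999999994
    total <- round(sum(x))
    k <- as.integer(total - sum(fl))
    out <- fl
    if (k > 0) {
      frac <- pmax(x - fl, 0)
      if (sum(frac) <= 0) frac <- rep(1, length(x))
      idx <- sample.int(length(x), size = k, replace = FALSE, prob = frac)
      out[idx] <- out[idx] + 1
    }
    storage.mode(out) <- "integer"
    out
  })
}
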