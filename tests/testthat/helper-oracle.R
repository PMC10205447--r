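# Independent reference implementations used as oracles. Deliberately
# written in a different style from the package code (per-axis loops over
# margin tables, no shared helpers) so agreement is evidence, not tautology.

# Alternating-scaling IPF reference: rescale axis by axis until every
# one-dimensional margin matches its target.
oracle_ipf <- function(seed_table, marginals, tol = 1e-10, max_iter = 10000L) {
  x <- as.array(seed_table)
  nd <- length(dim(x))
  for (it in seq_len(max_iter)) {
    for (k in seq_len(nd)) {
      cur <- apply(x, k, sum)
      fac <- marginals[[k]] / cur
      fac[!is.finite(fac)] <- 0
      x <- sweep(x, k, fac, `*`)
    }
    worst <- 0
    for (k in seq_len(nd)) {
      worst <- max(worst, max(abs(apply(x, k, sum) - marginals[[k]])))
    }
    if (worst <= tol) break
  }
  x
}

# Direct textbook evaluation of the Jensen-Shannon distance (base-2 logs).
oracle_js <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}
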