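# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# Floyd-Warshall all-pairs shortest paths from the bond list
floyd_warshall_oracle <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    D[i, j] <- D[j, i] <- 1
  }
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  D
}

# Brute-force leave-one-out PRESS by refitting n times with lm()
loo_press_oracle <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    d <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    m <- stats::lm(y ~ ., d)
    yhat <- stats::predict(m, newdata = data.frame(X[i, , drop = FALSE]))
    press <- press + (y[i] - unname(yhat))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Exhaustive best subset (by LOO Q2) up to size cap
exhaustive_best_subset <- function(X, y, cap) {
  m <- ncol(X)
  best <- -Inf; best_sub <- NULL
  for (k in seq_len(cap)) {
    cmb <- utils::combn(m, k)
    for (c in seq_len(ncol(cmb))) {
      idx <- cmb[, c]
      q2 <- tryCatch(loo_q2(X[, idx, drop = FALSE], y),
                     error = function(e) -Inf)
      if (q2 > best) { best <- q2; best_sub <- idx }
    }
  }
  list(subset = sort(best_sub), q2 = best)
}

# linear path graph with n sp3 carbons, built without the SMILES parser
path_graph <- function(n) {
  bonds <- if (n > 1)
    data.frame(i = seq_len(n - 1), j = 2:n, order = 1L, aromatic = FALSE)
  else data.frame(i = integer(0), j = integer(0), order = integer(0),
                  aromatic = logical(0))
  terpQSAR:::new_molgraph(rep("C", n), rep(FALSE, n), rep(0L, n),
                          c(3L, rep(2L, max(0, n - 2)), 3L)[seq_len(n)], bonds)
}

ring_graph <- function(n) {
  bonds <- data.frame(i = seq_len(n), j = c(2:n, 1L), order = 1L,
                      aromatic = FALSE)
  terpQSAR:::new_molgraph(rep("C", n), rep(FALSE, n), rep(0L, n),
                          rep(2L, n), bonds)
}

graphs_isomorphic <- function(g1, g2) {
  skip_if_not_installed("igraph")
  to_ig <- function(g) {
    ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("i", "j")]),
                                      directed = FALSE)
    ig
  }
  col <- function(g) as.integer(factor(paste(g$element, g$hcount, g$aromatic),
    levels = sort(unique(c(paste(g1$element, g1$hcount, g1$aromatic),
                           paste(g2$element, g2$hcount, g2$aromatic))))))
  igraph::isomorphic(to_ig(g1), to_ig(g2),
                     method = "vf2",
                     vertex.color1 = col(g1), vertex.color2 = col(g2))
}
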