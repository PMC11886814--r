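# Independent oracles and fixture builders used across the test suite.

# Explicit 256-term pattern-probability enumeration for the quartet tree
# ((A,B),(C,D)): matrix exponentials via Matrix::expm and plain nested
# loops over root/internal states -- deliberately independent of the
# package's pruning/eigen implementation.
oracle_probs <- function(bl, pi = rep(0.25, 4), exch = rep(1, 6),
                         alpha = 1, ncat = 1L) {
  Q <- matrix(0, 4, 4)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in 1:6) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Q[i, j] <- exch[p] * pi[j]
    Q[j, i] <- exch[p] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))
  rates <- if (ncat > 1L) {
    r <- qgamma((seq_len(ncat) - 0.5) / ncat, shape = alpha, rate = alpha)
    r / mean(r)
  } else 1
  probs <- numeric(256)
  for (k in seq_along(rates)) {
    P <- lapply(bl, function(t) as.matrix(Matrix::expm(Q * t * rates[k])))
    for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
      s <- 0
      for (u in 1:4) for (v in 1:4)
        s <- s + pi[u] * P[[1]][u, a] * P[[2]][u, b] * P[[5]][u, v] *
          P[[3]][v, cc] * P[[4]][v, d]
      idx <- 64 * (a - 1) + 16 * (b - 1) + 4 * (cc - 1) + d
      probs[idx] <- probs[idx] + s / length(rates)
    }
  }
  probs
}

# decode 1-based pattern index -> states 0..3 (role order O, x1, x2, x3)
oracle_decode <- function(idx) {
  r <- idx - 1L
  c(r %/% 64L, (r %/% 16L) %% 4L, (r %/% 4L) %% 4L, r %% 4L)
}

# exhaustive grid-search optimum of the RISK threshold objective on the
# 1e-3 grid, ties resolved toward the larger threshold
oracle_grid_risk <- function(ratios, n_total = length(ratios),
                             objective = polarquart::riskObjective) {
  grid <- seq(0.001, 1, by = 0.001)
  f <- vapply(grid, objective, numeric(1), ratios = ratios[is.finite(ratios)],
              n_total = n_total)
  best <- max(f)
  max(grid[abs(f - best) <= 1e-15])
}

# tiny in-memory alignment from named sequence strings
make_aln <- function(...) {
  seqs <- c(...)
  do.call(rbind, lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])) ->
    m
  rownames(m) <- names(seqs)
  m
}

# random GTR-ish parameter set for oracle fixtures
random_model_params <- function() {
  pi <- rgamma(4, 5, 1); pi <- pi / sum(pi)
  list(bl = runif(5, 0.01, 1), pi = pi, exch = runif(6, 0.2, 5),
       alpha = runif(1, 0.2, 2), ncat = sample(c(1L, 4L), 1))
}

# clade map over synthetic taxa with the given clade sizes
make_clade_map <- function(sizes, outgroup = "O") {
  clades <- lapply(names(sizes), function(code)
    paste0(code, "_", seq_len(sizes[[code]])))
  names(clades) <- names(sizes)
  polarquart::cladeMap(clades, outgroup)
}

# deterministic scoring-table stub for filter/aggregation tests
make_scores_stub <- function(R, ratio_best, clade_quartet = "CDOP",
                             usable = TRUE, no_signal = FALSE) {
  n <- nrow(R)
  data.frame(
    quartet_id = seq_len(n), clade_quartet = clade_quartet,
    o = paste0("O_", seq_len(n)), t1 = "x1", t2 = "x2", t3 = "x3",
    n_sites = 100L, usable = usable,
    Na1 = NA_real_, Na2 = NA_real_, Na3 = NA_real_,
    Nc1 = NA_real_, Nc2 = NA_real_, Nc3 = NA_real_,
    S1 = R[, 1], S2 = R[, 2], S3 = R[, 3],
    R1 = R[, 1], R2 = R[, 2], R3 = R[, 3],
    best = max.col(R, ties.method = "first"),
    ratio_best = ratio_best,
    sd12 = apply(R, 1, function(r) {
      sr <- sort(r, decreasing = TRUE); sr[1] - sr[2]
    }),
    no_signal = no_signal, converged = TRUE,
    stringsAsFactors = FALSE)
}
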