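# Sequence simulation on rooted trees with branch lengths: GTR(+Gamma4)
# substitutions via matrix-exponential transition probabilities, and
# optional Lavalette-distributed insertions/deletions producing pre-aligned
# (gapped) output.

#' Lavalette-distributed indel lengths
#'
#' Bounded heavy-tailed discrete length law used for insertion/deletion
#' lengths: \code{P(L = k) \eqn{\propto} ((k*M)/(M-k+1))^(-alpha)} for
#' \code{k = 1..M}.
#'
#' @param n number of draws.
#' @param alpha shape parameter (> 1), default 2.4.
#' @param M maximum length, default 400.
#' @return integer vector of lengths in \code{1..M}.
#' @export
sampleLavalette <- function(n, alpha = 2.4, M = 400L) {
  stopifnot(alpha > 1, M >= 1)
  p <- lavalettePmf(alpha, M)
  sample.int(M, n, replace = TRUE, prob = p)
}

#' @rdname sampleLavalette
#' @return \code{lavalettePmf}: the normalized probability mass function
#'   over \code{1..M}.
#' @export
lavalettePmf <- function(alpha = 2.4, M = 400L) {
  k <- seq_len(M)
  w <- ((k * M) / (M - k + 1))^(-alpha)
  w / sum(w)
}

#' Default indel model
#'
#' @param alpha Lavalette shape (default 2.4).
#' @param rate indel events per site per unit branch length, relative to
#'   the substitution rate (default 0.01747).
#' @param maxLen maximum indel length (default 400).
#' @param insProb probability that an event is an insertion (default 0.5,
#'   i.e. insertion:deletion 1:1).
#' @return list usable as the \code{indels} argument of
#'   [simulateAlignment()].
#' @export
indelModel <- function(alpha = 2.4, rate = 0.01747, maxLen = 400L,
                       insProb = 0.5) {
  stopifnot(alpha > 1, rate >= 0, maxLen >= 1, insProb >= 0, insProb <= 1)
  list(alpha = alpha, rate = rate, maxLen = as.integer(maxLen),
       insProb = insProb)
}

# default GTR+Gamma parameter set used when the caller gives only a model
# name: mildly AT-rich composition, transition/transversion bias, moderate
# among-site rate variation
.defaultSimModel <- function(model = "GTR+G") {
  ms <- .parseModelSpec(model)
  if (startsWith(ms$name, "JC")) {
    pi <- rep(0.25, 4); exch <- rep(1, 6)
  } else {
    pi <- c(0.28, 0.22, 0.22, 0.28)
    exch <- c(1, 4, 1, 1, 4, 1)
  }
  list(pi = pi, exch = exch, gamma = ms$gamma,
       alpha = if (ms$gamma) 0.5 else NA_real_,
       ncat = ms$ncat, name = ms$name)
}

#' Simulate a nucleotide alignment on a rooted tree
#'
#' The root sequence is drawn from the stationary frequencies and evolved
#' branch-wise using matrix-exponential transition probabilities of a
#' rate-normalized GTR(+Gamma4) model; discrete gamma rate categories are
#' drawn i.i.d. per site.  With indels enabled, events are placed along
#' each branch at the given rate per site per unit branch length
#' (insertion:deletion 1:1 by default) with Lavalette-distributed lengths,
#' and the output is pre-aligned: insertions create columns gapped in all
#' non-descendants, deletions write gaps in descendants.  Runs are
#' bit-identical for a fixed seed.
#'
#' @param tree an \pkg{ape} \code{phylo} object, a Newick string, or a path
#'   to a Newick file; branch lengths are required.
#' @param nSites root sequence length.
#' @param model model name (\code{"JC"}, \code{"JC+G"}, \code{"GTR"},
#'   \code{"GTR+G"}) or a list with \code{pi}, \code{exch}, \code{gamma},
#'   \code{alpha}, \code{ncat}.
#' @param indels \code{NULL}/\code{FALSE} for none, \code{TRUE} for the
#'   default [indelModel()], or an [indelModel()] list.
#' @param seed optional integer seed (determinism contract).
#' @return character matrix alignment (rows = taxa, gaps as \code{"-"})
#'   with attribute \code{"truth"}: a list with the tree (Newick), model
#'   parameters and seed.
#' @export
simulateAlignment <- function(tree, nSites, model = "GTR+G", indels = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(tree, "phylo")) {
    txt <- if (length(tree) == 1L && file.exists(tree))
      paste(readLines(tree), collapse = "") else tree
    tree <- ape::read.tree(text = txt)
  }
  if (is.null(tree$edge.length))
    stop("simulation requires branch lengths on every branch")
  if (is.character(model) || !is.list(model)) model <- .defaultSimModel(model)
  stopifnot(abs(sum(model$pi) - 1) < 1e-6, all(tree$edge.length >= 0))
  im <- if (isTRUE(indels)) indelModel() else if (is.list(indels)) indels
  ncat <- if (isTRUE(model$gamma)) model$ncat %||% 4L else 1L
  cat_rates <- if (ncat > 1L) {
    r <- qgamma((seq_len(ncat) - 0.5) / ncat, shape = model$alpha,
                rate = model$alpha)
    r / mean(r)
  } else 1

  # eigen system of the rate-normalized GTR generator (R side, used by the
  # simulator only; the likelihood kernel has its own)
  eg <- .gtrEigenR(model$pi, model$exch)

  state <- new.env(parent = emptyenv())
  state$next_id <- nSites + 1L
  state$key <- as.numeric(seq_len(nSites))       # id -> sort key
  state$leaf_ids <- list(); state$leaf_states <- list()

  root_states <- sample.int(4L, nSites, replace = TRUE, prob = model$pi)
  root_cats <- sample.int(ncat, nSites, replace = TRUE)
  root_ids <- seq_len(nSites)

  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  recurse <- function(node, ids, states, cats) {
    if (node <= ntip) {
      lbl <- tree$tip.label[node]
      state$leaf_ids[[lbl]] <- ids
      state$leaf_states[[lbl]] <- states
      return(invisible())
    }
    for (ei in kids[[as.character(node)]]) {
      child <- tree$edge[ei, 2]
      bl <- tree$edge.length[ei]
      r <- .evolveBranch(ids, states, cats, bl, eg, model, cat_rates, im,
                         state)
      recurse(child, r$ids, r$states, r$cats)
    }
  }
  recurse(ntip + 1L, root_ids, root_states, root_cats)

  all_ids <- seq_len(state$next_id - 1L)
  ord <- all_ids[order(state$key)]
  taxa <- tree$tip.label
  mat <- matrix("-", nrow = length(taxa), ncol = length(ord),
                dimnames = list(taxa, NULL))
  for (tx in taxa) {
    pos <- match(state$leaf_ids[[tx]], ord)
    st <- state$leaf_states[[tx]]
    chr <- ifelse(st == 0L, "-", NUC_STATES[pmax(st, 1L)])
    mat[tx, pos] <- chr
  }
  attr(mat, "truth") <- list(
    tree = ape::write.tree(tree), n_sites = nSites, model = model$name,
    pi = model$pi, exch = model$exch,
    alpha = if (ncat > 1L) model$alpha else NA_real_,
    indels = im, seed = seed)
  mat
}

.gtrEigenR <- function(pi, exch) {
  Q <- matrix(0, 4, 4)
  pair <- 1L
  for (i in 1:3) for (j in (i + 1):4) {
    Q[i, j] <- exch[pair] * pi[j]
    Q[j, i] <- exch[pair] * pi[i]
    pair <- pair + 1L
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, sp = sp)
}

.pmatR <- function(eg, t) {
  P <- diag(1 / eg$sp) %*% eg$U %*% diag(exp(eg$lambda * t)) %*%
    t(eg$U) %*% diag(eg$sp)
  P[P < 0] <- 0
  P / rowSums(P)
}

# evolve one branch: substitutions at per-category scaled lengths, then
# indel events (expected count = rate * branch length * current length)
.evolveBranch <- function(ids, states, cats, bl, eg, model, cat_rates, im,
                          state) {
  ncat <- length(cat_rates)
  alive <- states > 0L
  new_states <- states
  for (k in seq_len(ncat)) {
    P <- .pmatR(eg, bl * cat_rates[k])
    for (s in 1:4) {
      sel <- which(alive & cats == k & states == s)
      if (length(sel))
        new_states[sel] <- sample.int(4L, length(sel), replace = TRUE,
                                      prob = P[s, ])
    }
  }
  states <- new_states

  if (!is.null(im) && im$rate > 0) {
    n_alive <- sum(states > 0L)
    n_events <- rpois(1L, im$rate * bl * n_alive)
    for (ev in seq_len(n_events)) {
      alive_idx <- which(states > 0L)
      n_alive <- length(alive_idx)
      if (n_alive == 0L) break
      len <- sampleLavalette(1L, im$alpha, im$maxLen)
      if (runif(1) < im$insProb) {
        # insertion after a uniformly chosen slot (0 = before first site)
        slot <- sample.int(n_alive + 1L, 1L) - 1L
        lo_key <- if (slot == 0L) min(state$key[ids]) - 1
          else state$key[ids[alive_idx[slot]]]
        hi_key <- if (slot == n_alive) max(state$key[ids]) + 1
          else state$key[ids[alive_idx[slot + 1L]]]
        new_ids <- state$next_id + seq_len(len) - 1L
        state$next_id <- state$next_id + len
        state$key[new_ids] <- lo_key + (hi_key - lo_key) *
          seq_len(len) / (len + 1)
        ins_states <- sample.int(4L, len, replace = TRUE, prob = model$pi)
        ins_cats <- sample.int(ncat, len, replace = TRUE)
        at <- if (slot == 0L) 0L else alive_idx[slot]
        ids <- append(ids, new_ids, after = at)
        states <- append(states, ins_states, after = at)
        cats <- append(cats, ins_cats, after = at)
      } else {
        start <- sample.int(n_alive, 1L)
        del <- alive_idx[start:min(start + len - 1L, n_alive)]
        states[del] <- 0L
      }
    }
  }
  list(ids = ids, states = states, cats = cats)
}
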