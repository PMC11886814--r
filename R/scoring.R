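# Species-quartet scoring: polarized site-pattern counts (Na), expected
# convergent counts (Nc) from quartet ML fits, and normalized supports (R).

# 256 x 4 matrix of decoded states (0..3) in role order (O, x1, x2, x3),
# row r+1 is pattern index r = 64*o + 16*s1 + 4*s2 + s3.
.PATTERN_STATES <- {
  r <- 0:255
  cbind(o = r %/% 64L, s1 = (r %/% 16L) %% 4L,
        s2 = (r %/% 4L) %% 4L, s3 = r %% 4L)
}

#' Classify a site pattern by the rooted topology it supports
#'
#' A pattern in role order (outgroup O, ingroups x1, x2, x3) supports rooted
#' topology \code{k} -- \code{(O,(xk,(xi,xj)))} -- when the two non-basal
#' ingroup taxa xi and xj share a state that differs from the outgroup state
#' (so the shared state is potentially derived rather than a retained
#' plesiomorphy).  Under the default \code{"relaxed"} rule the shared state
#' must also differ from xk's state; the \code{"strict"} rule additionally
#' requires the outgroup and xk to agree.  A pattern supports at most one
#' topology; everything else is uninformative (class 0).
#'
#' @param states vector of 4 states (characters among A,C,G,T or integers
#'   0-3) in role order.
#' @param rule \code{"relaxed"} (default) or \code{"strict"}.
#' @return integer in 0:3 (0 = uninformative, k = supports topology k).
#' @export
classifySitePattern <- function(states, rule = c("relaxed", "strict")) {
  rule <- match.arg(rule)
  if (is.character(states)) {
    states <- match(toupper(states), NUC_STATES) - 1L
    if (anyNA(states)) stop("states must be among A,C,G,T")
  }
  stopifnot(length(states) == 4L, all(states %in% 0:3))
  o <- states[1]; x <- states[2:4]
  for (k in 1:3) {
    ij <- setdiff(1:3, k)
    shared <- x[ij[1]]
    if (x[ij[1]] == x[ij[2]] && shared != o &&
        (if (rule == "strict") o == x[k] else shared != x[k]))
      return(k)
  }
  0L
}

# classification of all 256 patterns, memoized per rule
.patternClassTable <- local({
  cache <- list()
  function(rule = "relaxed") {
    if (is.null(cache[[rule]])) {
      cache[[rule]] <<- vapply(seq_len(256L), function(i) {
        classifySitePattern(.PATTERN_STATES[i, ], rule)
      }, integer(1))
    }
    cache[[rule]]
  }
})

#' Count split-supporting sites per rooted topology
#'
#' @param counts integer vector of 256 pattern counts in role order, as
#'   produced by [extractQuartetColumns()].
#' @param rule pattern rule, see [classifySitePattern()].
#' @return integer vector \code{c(Na1, Na2, Na3)}.
#' @export
countNa <- function(counts, rule = "relaxed") {
  cls <- .patternClassTable(rule)
  vapply(1:3, function(k) sum(counts[cls == k]), numeric(1))
}

# ---- substitution models ---------------------------------------------------

#' @keywords internal
.parseModelSpec <- function(model) {
  if (is.list(model)) return(model)
  parts <- strsplit(toupper(model), "+", fixed = TRUE)[[1]]
  base <- parts[1]
  gamma <- length(parts) > 1L && parts[2] %in% c("G", "G4")
  if (!base %in% c("JC", "GTR"))
    stop("unknown model '", model, "' (use JC, JC+G, GTR or GTR+G)")
  list(name = paste0(base, if (gamma) "+G"),
       fit_exch = base == "GTR", fit_freq = base == "GTR",
       gamma = gamma, ncat = if (gamma) 4L else 1L)
}

# role-order (O,x1,x2,x3) -> tree-order (O,xk,xi,xj) pattern index map for
# topology k; m[r+1] gives the 1-based tree-order index of role pattern r.
.topologyIndexMap <- function(k) {
  ij <- setdiff(1:3, k)
  st <- .PATTERN_STATES
  64L * st[, 1] + 16L * st[, 1 + k] + 4L * st[, 1 + ij[1]] +
    st[, 1 + ij[2]] + 1L
}

#' Pattern probabilities and log-likelihood of a quartet tree
#'
#' \code{quartetPatternProbs} returns the probabilities of all 256 site
#' patterns on the quartet tree \code{((A,B),(C,D))} (pattern index
#' \code{64*a + 16*b + 4*c + d + 1}, states 0..3 = A,C,G,T) under a
#' reversible GTR(+Gamma4) model, computed by the pruning algorithm with the
#' root placed on the internal branch.  \code{quartetLoglik} is the
#' corresponding log-likelihood of observed pattern counts.
#'
#' @param bl branch lengths \code{c(tA, tB, tC, tD, tInternal)} in expected
#'   substitutions per site.
#' @param pi stationary frequencies (A,C,G,T), summing to 1.
#' @param exch GTR exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param alpha gamma shape (ignored when \code{ncat = 1}).
#' @param ncat number of discrete gamma categories (1 = rate homogeneity).
#' @return numeric vector of 256 probabilities summing to 1, or a scalar
#'   log-likelihood.
#' @export
quartetPatternProbs <- function(bl, pi = rep(0.25, 4), exch = rep(1, 6),
                                alpha = 1, ncat = 1L) {
  stopifnot(length(bl) == 5L, length(pi) == 4L, length(exch) == 6L)
  .quartetPatternProbsCpp(as.numeric(bl), as.numeric(pi / sum(pi)),
                          as.numeric(exch), alpha, as.integer(ncat))
}

#' @rdname quartetPatternProbs
#' @param counts 256 pattern counts in the same tree order.
#' @export
quartetLoglik <- function(counts, bl, pi = rep(0.25, 4), exch = rep(1, 6),
                          alpha = 1, ncat = 1L) {
  .quartetLoglikCpp(as.numeric(counts), as.numeric(bl),
                    as.numeric(pi / sum(pi)), as.numeric(exch), alpha,
                    as.integer(ncat))
}

#' Fit the quartet maximum-likelihood model for one rooted topology
#'
#' Maximizes the likelihood of the pattern counts on the quartet tree of
#' topology \code{k} (\code{(O,(xk,(xi,xj)))}, five branch lengths) under
#' the chosen substitution model.  Optimization is a deterministic
#' coordinate-wise bounded line search run from two starts (equal branch
#' lengths 0.1, and distance-scaled lengths derived from the pattern
#' counts); the better optimum is kept.
#'
#' @param counts 256 pattern counts in role order (O, x1, x2, x3).
#' @param topology topology index in 1:3.
#' @param model \code{"JC"}, \code{"JC+G"}, \code{"GTR"} or \code{"GTR+G"}.
#' @param rule pattern rule used for the distance-scaled start.
#' @param control list with \code{tol} (log-likelihood convergence
#'   tolerance, default 1e-6) and \code{max_sweeps} (default 200).
#' @return list with \code{loglik}, \code{bl} (tree order: O, xk, xi, xj,
#'   internal), \code{pi}, \code{exch}, \code{alpha}, \code{converged}, and
#'   \code{probs} -- the 256 fitted pattern probabilities in role order.
#' @export
fitQuartetML <- function(counts, topology, model = "GTR+G",
                         rule = "relaxed", control = list()) {
  ms <- .parseModelSpec(model)
  tol <- control$tol %||% 1e-6
  max_sweeps <- control$max_sweeps %||% 200L
  n <- sum(counts)
  stopifnot(n >= 1)
  m <- .topologyIndexMap(topology)
  tcounts <- numeric(256); tcounts[m] <- counts

  pi0 <- if (ms$fit_freq) .empiricalFreqs(counts) else rep(0.25, 4)
  exch0 <- rep(1, 6)
  alpha0 <- 1

  starts <- list(rep(0.1, 5), .distanceStart(counts, topology, rule))
  best <- NULL
  for (bl0 in starts) {
    fit <- .fitQuartetCpp(tcounts, bl0, pi0, exch0, alpha0,
                          ms$fit_exch, ms$fit_freq, ms$gamma,
                          ms$ncat, tol, as.integer(max_sweeps))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  probs_role <- best$probs[m]
  list(topology = topology, loglik = best$loglik, bl = best$bl,
       pi = best$pi, exch = best$exch,
       alpha = if (ms$gamma) best$alpha else NA_real_,
       ncat = ms$ncat, converged = best$converged, probs = probs_role)
}

.empiricalFreqs <- function(counts) {
  st <- .PATTERN_STATES
  f <- numeric(4)
  for (col in 1:4)
    f <- f + vapply(0:3, function(s) sum(counts[st[, col] == s]), numeric(1))
  f <- f + 1  # pseudocount keeps frequencies off the boundary
  f / sum(f)
}

# distance-scaled starting branch lengths (tree order) from pattern counts
.distanceStart <- function(counts, topology, rule) {
  st <- .PATTERN_STATES
  n <- sum(counts)
  ij <- setdiff(1:3, topology)
  ord <- c(1L, 1L + topology, 1L + ij)  # columns in tree order
  d <- function(a, b) sum(counts[st[, a] != st[, b]]) / n
  term <- vapply(ord, function(a) {
    mean(vapply(setdiff(ord, a), function(b) d(a, b), numeric(1))) / 2
  }, numeric(1))
  internal <- countNa(counts, rule)[topology] / n
  pmin(pmax(c(term, internal), 1e-3), 5)
}

#' Expected convergent supporting-site counts (Nc)
#'
#' For target topology \code{i}, the expectation under each alternative
#' topology's fitted model of the number of sites whose pattern supports
#' \code{i} is computed exactly by summing the fitted pattern probabilities
#' over the supporting pattern class; \code{Nc_i} is the arithmetic mean of
#' the two alternative-topology expectations.
#'
#' @param fits list of three fits from [fitQuartetML()] (topologies 1..3,
#'   fitted on the same columns).
#' @param n_sites number of retained sites.
#' @param rule pattern rule, see [classifySitePattern()].
#' @return numeric vector \code{c(Nc1, Nc2, Nc3)}.
#' @export
estimateNc <- function(fits, n_sites, rule = "relaxed") {
  cls <- .patternClassTable(rule)
  vapply(1:3, function(i) {
    alt <- setdiff(1:3, i)
    e <- vapply(alt, function(j) {
      n_sites * sum(fits[[j]]$probs[cls == i])
    }, numeric(1))
    mean(e)
  }, numeric(1))
}

#' Normalize topology supports of a species-quartet
#'
#' The score of topology \code{k} is the excess of observed over
#' chance-expected supporting sites, \code{S_k = max(Na_k - Nc_k, 0)}
#' (\code{score = "excess"}, default; \code{Na_k > Nc_k} is the positivity
#' condition), or \code{S_k = max(1 - Nc_k/Na_k, 0)}
#' (\code{score = "ratio"}).  Scores are normalized to relative supports
#' \code{R_k = S_k / (S_1+S_2+S_3)}.  When all scores vanish the quartet
#' carries no usable signal: \code{R = (1/3, 1/3, 1/3)} and it is flagged
#' \code{no_signal} (such quartets never pass the filters).
#'
#' @param na,nc numeric vectors of length 3.
#' @param score \code{"excess"} or \code{"ratio"}.
#' @return list with \code{S}, \code{R}, \code{best} (argmax of R, ties to
#'   the lowest index), \code{ratio} (\code{Nc/Na}, \code{Inf} when
#'   \code{Na = 0}), \code{sd12} (best minus second-best R) and
#'   \code{no_signal}.
#' @export
normalizeSupport <- function(na, nc, score = c("excess", "ratio")) {
  score <- match.arg(score)
  stopifnot(length(na) == 3L, length(nc) == 3L)
  S <- switch(score,
              excess = pmax(na - nc, 0),
              ratio = ifelse(na > 0, pmax(1 - nc / na, 0), 0))
  tot <- sum(S)
  no_signal <- tot <= 0
  R <- if (no_signal) rep(1 / 3, 3) else S / tot
  ratio <- ifelse(na > 0, nc / na, Inf)
  sr <- sort(R, decreasing = TRUE)
  list(S = S, R = R, best = which.max(R), ratio = ratio,
       sd12 = sr[1] - sr[2], no_signal = no_signal)
}

#' Score all species-quartets of a clade map
#'
#' Runs the full per-quartet analysis: missing-data-free column extraction,
#' Na counting, the three topology ML fits, Nc estimation and support
#' normalization.
#'
#' @param aln alignment matrix.
#' @param cmap a \linkS4class{CladeMap}.
#' @param model substitution model for the ML stage (see [fitQuartetML()]).
#' @param rule pattern rule (see [classifySitePattern()]).
#' @param score score rule (see [normalizeSupport()]).
#' @param control optimizer control (see [fitQuartetML()]).
#' @param verbose print progress per clade-quartet.
#' @return data.frame, one row per species-quartet, with taxa, site counts,
#'   \code{Na*}, \code{Nc*}, \code{S*}, \code{R*}, \code{best},
#'   \code{ratio_best}, \code{sd12} and flags.  Quartets with no usable
#'   columns are kept with \code{usable = FALSE} and NA scores.
#' @export
scoreSpeciesQuartets <- function(aln, cmap, model = "GTR+G",
                                 rule = "relaxed", score = "excess",
                                 control = list(), verbose = FALSE) {
  cqs <- enumerateCladeQuartets(cmap)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(cqs))) {
    cq <- cqs[i, ]
    sq <- enumerateSpeciesQuartets(cq, cmap)
    if (verbose)
      message("scoring ", cq$name, ": ", nrow(sq), " species-quartets")
    for (j in seq_len(nrow(sq))) {
      taxa <- unlist(sq[j, ], use.names = FALSE)
      qc <- extractQuartetColumns(aln, taxa)
      base <- data.frame(clade_quartet = cq$name, o = taxa[1],
                         t1 = taxa[2], t2 = taxa[3], t3 = taxa[4],
                         n_sites = qc$n_sites, usable = qc$usable,
                         stringsAsFactors = FALSE)
      if (!qc$usable) {
        warning("species-quartet (", paste(taxa, collapse = ","),
                ") has no usable columns; skipped")
        rows[[length(rows) + 1L]] <-
          cbind(base, .naScoreRow())
        next
      }
      na <- countNa(qc$counts, rule)
      fits <- lapply(1:3, function(k) {
        fitQuartetML(qc$counts, k, model, rule, control)
      })
      nc <- estimateNc(fits, qc$n_sites, rule)
      ns <- normalizeSupport(na, nc, score)
      rows[[length(rows) + 1L]] <- cbind(base, data.frame(
        Na1 = na[1], Na2 = na[2], Na3 = na[3],
        Nc1 = nc[1], Nc2 = nc[2], Nc3 = nc[3],
        S1 = ns$S[1], S2 = ns$S[2], S3 = ns$S[3],
        R1 = ns$R[1], R2 = ns$R[2], R3 = ns$R[3],
        best = ns$best, ratio_best = ns$ratio[ns$best],
        sd12 = ns$sd12, no_signal = ns$no_signal,
        converged = all(vapply(fits, `[[`, logical(1), "converged"))))
    }
  }
  res <- do.call(rbind, rows)
  res$quartet_id <- seq_len(nrow(res))
  res[, c("quartet_id", setdiff(names(res), "quartet_id"))]
}

.naScoreRow <- function() {
  data.frame(Na1 = NA_real_, Na2 = NA_real_, Na3 = NA_real_,
             Nc1 = NA_real_, Nc2 = NA_real_, Nc3 = NA_real_,
             S1 = NA_real_, S2 = NA_real_, S3 = NA_real_,
             R1 = NA_real_, R2 = NA_real_, R3 = NA_real_,
             best = NA_integer_, ratio_best = NA_real_,
             sd12 = NA_real_, no_signal = NA, converged = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
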