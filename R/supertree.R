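# Supertree stage: enumerate all rooted trees of the ingroup clades, build
# the pairwise-compatibility support matrix from clade-quartet medians, and
# rank trees by their accumulated induced-quartet support.

#' Enumerate all rooted binary trees on a set of clade codes
#'
#' Recursive leaf insertion: the trees on n leaves arise by attaching the
#' n-th leaf to every branch (including the root branch) of every tree on
#' n-1 leaves, giving (2n-3)!! distinct canonical trees.
#'
#' @param codes character vector of (ingroup) clade codes, n >= 2.
#' @param limit refuse enumeration above this many leaves (double-factorial
#'   growth); default 9.
#' @return list of \linkS4class{RootedCladeTree}, sorted by canonical
#'   Newick string.
#' @export
enumerateRootedCladeTrees <- function(codes, limit = 9L) {
  codes <- sort(unique(as.character(codes)))
  n <- length(codes)
  if (n < 2L) stop("need at least 2 clades")
  if (n > limit)
    stop(n, " clades exceed the enumeration limit (", limit,
         "); constrain the clade set or raise `limit`")
  trees <- list(list(codes[1], codes[2]))
  for (i in seq_len(n - 2L) + 2L) {
    leaf <- codes[i]
    trees <- unlist(lapply(trees, .insertLeafEverywhere, leaf = leaf),
                    recursive = FALSE)
  }
  out <- lapply(trees, .rootedCladeTree)
  nwk <- vapply(out, writeNewick, character(1))
  out[order(nwk)]
}

# all trees obtained by attaching `leaf` to each branch of `node`,
# including above the root
.insertLeafEverywhere <- function(node, leaf) {
  res <- list(list(node, leaf))  # attach above the root
  if (is.character(node)) return(res)
  for (ci in 1:2) {
    sub <- .insertLeafEverywhere(node[[ci]], leaf)
    for (s in sub) {
      nn <- node
      nn[[ci]] <- s
      res[[length(res) + 1L]] <- nn
    }
  }
  res
}

#' Clade-quartet topologies induced by a rooted clade tree
#'
#' Restricting a rooted clade tree to any three ingroup clades (rooted by
#' the implicit outgroup) yields one of the three rooted quartet
#' topologies: the basal clade of the restriction is the one whose two
#' companions have a more recent common ancestor.
#'
#' @param tree a \linkS4class{RootedCladeTree} on the ingroup clades.
#' @param outgroup outgroup clade code (used only for quartet naming).
#' @return data.frame with one row per 3-subset: \code{clade_quartet}
#'   (sorted 4-code name), \code{basal} (earliest-diverging ingroup clade)
#'   and \code{topology} (index of the basal clade among the sorted
#'   triplet).
#' @export
inducedCladeQuartets <- function(tree, outgroup) {
  stopifnot(is(tree, "RootedCladeTree"))
  tips <- tree@tips
  if (length(tips) < 3L) stop("tree must have at least 3 leaves")
  # depth of the MRCA of each leaf pair
  depth <- .pairMrcaDepths(tree@node, 0L)
  trips <- combn(tips, 3L)
  rows <- apply(trips, 2, function(tr) {
    tr <- sort(tr)
    d <- c(depth[paste(tr[2], tr[3])], depth[paste(tr[1], tr[3])],
           depth[paste(tr[1], tr[2])])
    basal_idx <- which.max(d)  # pair with deepest MRCA is the derived pair
    data.frame(
      clade_quartet = paste(sort(c(outgroup, tr)), collapse = ""),
      basal = tr[basal_idx], topology = basal_idx,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# named vector "a b" -> depth of MRCA(a,b), leaves sorted within the name
.pairMrcaDepths <- function(node, d) {
  if (is.character(node)) return(setNames(numeric(0), character(0)))
  left <- .treeTips(node[[1]]); right <- .treeTips(node[[2]])
  cross <- expand.grid(a = left, b = right, stringsAsFactors = FALSE)
  nm <- ifelse(cross$a < cross$b, paste(cross$a, cross$b),
               paste(cross$b, cross$a))
  out <- setNames(rep(d, nrow(cross)), nm)
  c(out, .pairMrcaDepths(node[[1]], d + 1L), .pairMrcaDepths(node[[2]], d + 1L))
}

#' Build the pairwise-compatibility support matrix
#'
#' Every rooted clade-quartet topology \code{(O,(A,(B,C)))} with median
#' support omega contributes omega to the relation cells
#' \code{Precedes(A -> B)}, \code{Precedes(A -> C)} ("A diverges closer to
#' the root than B/C") and \code{DerivedPair\{B,C\}}.  Clade-quartets with
#' missing medians (empty after filtering) contribute 0 with a warning.
#'
#' @param supports data.frame from [medianSupport()].
#' @param cmap the \linkS4class{CladeMap} (supplies clade codes).
#' @return list with matrices \code{precedes} (directed) and
#'   \code{derivedPair} (symmetric), a long-format \code{cells}
#'   data.frame, and \code{omega}, the per clade-quartet/topology medians
#'   used (named list).
#' @export
buildSupportMatrix <- function(supports, cmap) {
  ing <- ingroupCodes(cmap)
  P <- matrix(0, length(ing), length(ing), dimnames = list(ing, ing))
  DP <- P
  omega <- list()
  cqs <- enumerateCladeQuartets(cmap)
  for (i in seq_len(nrow(cqs))) {
    cq <- cqs[i, ]
    row <- supports[supports$clade_quartet == cq$name, , drop = FALSE]
    om <- if (nrow(row) == 0L || isTRUE(row$empty[1])) {
      warning("no median support for clade-quartet ", cq$name,
              "; contributes 0")
      c(0, 0, 0)
    } else unlist(row[1, c("omega1", "omega2", "omega3")], use.names = FALSE)
    omega[[cq$name]] <- om
    trip <- c(cq$x1, cq$x2, cq$x3)
    for (k in 1:3) {
      basal <- trip[k]; pair <- trip[-k]
      P[basal, pair[1]] <- P[basal, pair[1]] + om[k]
      P[basal, pair[2]] <- P[basal, pair[2]] + om[k]
      DP[pair[1], pair[2]] <- DP[pair[1], pair[2]] + om[k]
      DP[pair[2], pair[1]] <- DP[pair[2], pair[1]] + om[k]
    }
  }
  cells <- rbind(
    data.frame(relation = "precedes",
               a = rep(ing, times = length(ing)),
               b = rep(ing, each = length(ing)),
               weight = as.vector(P), stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(ing), function(i) {
      if (i == length(ing)) return(NULL)
      data.frame(relation = "derived_pair", a = ing[i],
                 b = ing[(i + 1):length(ing)],
                 weight = DP[i, (i + 1):length(ing)],
                 stringsAsFactors = FALSE)
    })))
  cells <- cells[cells$a != cells$b, , drop = FALSE]
  list(precedes = P, derivedPair = DP, cells = cells, omega = omega)
}

#' Score a rooted clade tree against the support matrix
#'
#' The canonical score of a tree is the sum, over its induced
#' clade-quartet topologies, of their median supports omega; the
#' matrix-sum variant counts each induced topology's three relation-cell
#' contributions and therefore equals three times the canonical score.
#' Ranking uses the canonical score (the two are proportional).
#'
#' @param tree a \linkS4class{RootedCladeTree}.
#' @param sm support matrix from [buildSupportMatrix()].
#' @param outgroup outgroup clade code.
#' @return list with \code{score} (canonical) and \code{matrix_sum}.
#' @export
scoreCladeTree <- function(tree, sm, outgroup) {
  iq <- inducedCladeQuartets(tree, outgroup)
  s <- 0
  for (i in seq_len(nrow(iq))) {
    om <- sm$omega[[iq$clade_quartet[i]]]
    if (!is.null(om)) s <- s + om[iq$topology[i]]
  }
  list(score = s, matrix_sum = 3 * s)
}

#' Rank all rooted clade trees by quartet-compatibility support
#'
#' Enumerates every rooted binary tree of the ingroup clades, scores each
#' against the support matrix and returns them sorted by descending
#' canonical score (ties broken by canonical Newick string).  Score
#' differences of the best tree to the second and third best are reported.
#'
#' @param supports data.frame from [medianSupport()].
#' @param cmap the \linkS4class{CladeMap}.
#' @param top_k keep at most this many trees (default 100).
#' @param limit enumeration limit, see [enumerateRootedCladeTrees()].
#' @return data.frame: \code{rank}, \code{tree} (canonical Newick),
#'   \code{score}, \code{matrix_sum}, \code{delta_next} (gap to the next
#'   ranked tree), plus attributes \code{delta_best_2nd},
#'   \code{delta_best_3rd}.
#' @export
rankCladeTrees <- function(supports, cmap, top_k = 100L, limit = 9L) {
  sm <- buildSupportMatrix(supports, cmap)
  trees <- enumerateRootedCladeTrees(ingroupCodes(cmap), limit)
  out <- outgroupCode(cmap)
  sc <- vapply(trees, function(tr) scoreCladeTree(tr, sm, out)$score,
               numeric(1))
  nwk <- vapply(trees, writeNewick, character(1))
  ord <- order(-sc, nwk)
  sc <- sc[ord]; nwk <- nwk[ord]
  keep <- seq_len(min(top_k, length(sc)))
  df <- data.frame(rank = keep, tree = nwk[keep], score = sc[keep],
                   matrix_sum = 3 * sc[keep],
                   delta_next = c(-diff(sc[keep]), NA_real_),
                   stringsAsFactors = FALSE)
  attr(df, "delta_best_2nd") <- if (length(sc) >= 2) sc[1] - sc[2] else NA
  attr(df, "delta_best_3rd") <- if (length(sc) >= 3) sc[1] - sc[3] else NA
  df
}
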