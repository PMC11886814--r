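#' Enumerate clade-quartets
#'
#' A clade-quartet combines the outgroup with each 3-subset of the ingroup
#' clades.  Its name concatenates the four clade codes in sorted order
#' (e.g. \code{CDOP}), and its three rooted topologies are indexed
#' \code{k = 1, 2, 3}, where topology \code{k} places the k-th (sorted)
#' ingroup clade as the earliest-diverging ingroup lineage:
#' \code{(O,(Xk,(Xi,Xj)))}.
#'
#' @param cmap a \linkS4class{CladeMap} with at least three ingroup clades.
#' @return data.frame with columns \code{name}, \code{outgroup},
#'   \code{x1}, \code{x2}, \code{x3} (ingroup codes, sorted), in
#'   lexicographic order of \code{name}.
#' @export
enumerateCladeQuartets <- function(cmap) {
  stopifnot(is(cmap, "CladeMap"))
  ing <- ingroupCodes(cmap)
  if (length(ing) < 3L)
    stop("at least 3 ingroup clades are required (found ", length(ing), ")")
  trips <- combn(ing, 3L)
  out <- outgroupCode(cmap)
  df <- data.frame(
    name = apply(trips, 2, function(x) paste(sort(c(out, x)), collapse = "")),
    outgroup = out,
    x1 = trips[1, ], x2 = trips[2, ], x3 = trips[3, ],
    stringsAsFactors = FALSE)
  df[order(df$name), , drop = FALSE]
}

#' Enumerate species-quartets of a clade-quartet
#'
#' The species-quartets of a clade-quartet are the Cartesian product of the
#' four clades' taxon sets (one species per clade); their count is the
#' product of the four clade sizes.
#'
#' @param cq one row of [enumerateCladeQuartets()] output (or a list with
#'   \code{outgroup}, \code{x1}, \code{x2}, \code{x3}).
#' @param cmap the \linkS4class{CladeMap}.
#' @return data.frame with columns \code{o}, \code{t1}, \code{t2},
#'   \code{t3} (taxon labels in role order), in lexicographic order.
#' @export
enumerateSpeciesQuartets <- function(cq, cmap) {
  stopifnot(is(cmap, "CladeMap"))
  pools <- lapply(c(cq$outgroup, cq$x1, cq$x2, cq$x3),
                  function(code) sort(cladeTaxa(cmap, code)))
  g <- expand.grid(t3 = pools[[4]], t2 = pools[[3]], t1 = pools[[2]],
                   o = pools[[1]], stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("o", "t1", "t2", "t3")]
}

#' Extract the usable alignment columns of a species-quartet
#'
#' Keeps only columns in which none of the four sequences has a missing or
#' ambiguous state, and encodes them as 4-state patterns in role order
#' (outgroup, x1, x2, x3).  Sites are additionally collapsed into counts of
#' the 256 possible nucleotide patterns (index \code{64*o + 16*s1 + 4*s2 +
#' s3}, states 0..3 = A,C,G,T, 1-based vector position).
#'
#' @param aln alignment matrix.
#' @param taxa character vector of 4 taxon labels in role order.
#' @return list with \code{counts} (integer vector of length 256),
#'   \code{n_sites} (retained column count) and \code{usable}
#'   (\code{FALSE} when no column survives; such quartets are skipped
#'   downstream).
#' @export
extractQuartetColumns <- function(aln, taxa) {
  stopifnot(length(taxa) == 4L)
  if (!all(taxa %in% rownames(aln)))
    stop("taxa absent from alignment: ",
         paste(setdiff(taxa, rownames(aln)), collapse = ", "))
  sub <- aln[taxa, , drop = FALSE]
  enc <- matrix(match(sub, NUC_STATES), nrow = 4L)
  keep <- colSums(is.na(enc)) == 0L
  enc <- enc[, keep, drop = FALSE] - 1L
  n <- ncol(enc)
  if (n == 0L)
    return(list(counts = integer(256), n_sites = 0L, usable = FALSE))
  idx <- 64L * enc[1, ] + 16L * enc[2, ] + 4L * enc[3, ] + enc[4, ] + 1L
  list(counts = tabulate(idx, nbins = 256L), n_sites = n, usable = TRUE)
}

#' Manifest of all species-quartets
#'
#' Convenience enumeration across all clade-quartets, with usable-site
#' counts; corresponds to the optional \code{quartets.tsv} report.
#'
#' @param aln alignment matrix.
#' @param cmap a \linkS4class{CladeMap}.
#' @return data.frame with quartet id, clade-quartet name, the four taxa
#'   and \code{n_sites}.
#' @export
quartetManifest <- function(aln, cmap) {
  cqs <- enumerateCladeQuartets(cmap)
  out <- lapply(seq_len(nrow(cqs)), function(i) {
    cq <- cqs[i, ]
    sq <- enumerateSpeciesQuartets(cq, cmap)
    ns <- vapply(seq_len(nrow(sq)), function(j) {
      extractQuartetColumns(aln, unlist(sq[j, ], use.names = FALSE))$n_sites
    }, integer(1))
    cbind(data.frame(clade_quartet = cq$name, stringsAsFactors = FALSE),
          sq, n_sites = ns)
  })
  res <- do.call(rbind, out)
  res$quartet_id <- seq_len(nrow(res))
  res[, c("quartet_id", "clade_quartet", "o", "t1", "t2", "t3", "n_sites")]
}
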