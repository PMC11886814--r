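#' Clade map: named clades of taxa with one designated outgroup
#'
#' Assigns every analysed taxon to exactly one named clade; exactly one clade
#' is the outgroup used to polarize quartets.  Clade names double as the
#' short codes used in clade-quartet naming (e.g. \code{C}, \code{D},
#' \code{P}, \code{S}, \code{O}).
#'
#' @slot clades named list of character vectors; names are clade codes,
#'   elements are taxon labels.
#' @slot outgroup single clade code designating the outgroup.
#' @export
setClass("CladeMap",
         representation(clades = "list", outgroup = "character"))

setValidity("CladeMap", function(object) {
  msg <- character()
  cl <- object@clades
  if (is.null(names(cl)) || any(!nzchar(names(cl))))
    msg <- c(msg, "all clades must be named")
  if (anyDuplicated(names(cl)))
    msg <- c(msg, "duplicate clade codes")
  if (any(lengths(cl) == 0L))
    msg <- c(msg, "clades must be non-empty")
  taxa <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(taxa)) {
    dup <- unique(taxa[duplicated(taxa)])
    msg <- c(msg, paste0("taxon assigned to more than one clade: ",
                         paste(dup, collapse = ", ")))
  }
  if (length(object@outgroup) != 1L || !object@outgroup %in% names(cl))
    msg <- c(msg, "exactly one existing clade must be designated outgroup")
  if (length(msg)) msg else TRUE
})

#' Construct a CladeMap
#'
#' @param clades named list of character vectors (clade code -> taxon labels).
#' @param outgroup clade code of the outgroup.
#' @return a validated \linkS4class{CladeMap}.
#' @examples
#' cladeMap(list(C = "c1", D = "d1", P = "p1", O = c("o1", "o2")), "O")
#' @export
cladeMap <- function(clades, outgroup) {
  new("CladeMap", clades = lapply(clades, as.character),
      outgroup = as.character(outgroup))
}

#' @describeIn cladeMap codes of the ingroup clades (sorted).
#' @param x a \code{CladeMap}.
#' @export
ingroupCodes <- function(x) {
  stopifnot(is(x, "CladeMap"))
  sort(setdiff(names(x@clades), x@outgroup))
}

#' @describeIn cladeMap code of the outgroup clade.
#' @export
outgroupCode <- function(x) {
  stopifnot(is(x, "CladeMap"))
  x@outgroup
}

#' @describeIn cladeMap taxon labels of one clade.
#' @param code a clade code.
#' @export
cladeTaxa <- function(x, code) {
  stopifnot(is(x, "CladeMap"))
  if (!code %in% names(x@clades)) stop("unknown clade code: ", code)
  x@clades[[code]]
}

setMethod("show", "CladeMap", function(object) {
  n <- lengths(object@clades)
  cat("CladeMap with", length(n) - 1L, "ingroup clades + outgroup\n")
  for (code in c(ingroupCodes(object), object@outgroup)) {
    role <- if (code == object@outgroup) "outgroup" else "ingroup"
    cat(sprintf("  %-4s %-8s %3d taxa\n", code, role, n[[code]]))
  }
})

#' Rooted clade tree
#'
#' A rooted binary tree whose leaves are ingroup clade codes; the outgroup is
#' implicit as the root attachment.  Stored in canonical form: the children
#' of every node are ordered by their smallest leaf label, so equal trees
#' have identical Newick strings.
#'
#' @slot node nested list representation (a leaf is a character scalar, an
#'   internal node a list of two children), already canonicalized.
#' @slot tips sorted leaf labels.
#' @export
setClass("RootedCladeTree",
         representation(node = "ANY", tips = "character"))

setValidity("RootedCladeTree", function(object) {
  tips <- .treeTips(object@node)
  if (anyDuplicated(tips)) return("duplicate leaf labels")
  if (!identical(sort(tips), object@tips)) return("tips slot out of sync")
  ok <- .checkBinary(object@node)
  if (!isTRUE(ok)) return(ok)
  TRUE
})

.treeTips <- function(node) {
  if (is.character(node)) return(node)
  unlist(lapply(node, .treeTips), use.names = FALSE)
}

.checkBinary <- function(node) {
  if (is.character(node)) {
    if (length(node) != 1L) return("leaf must be a single label")
    return(TRUE)
  }
  if (!is.list(node) || length(node) != 2L)
    return("internal nodes must be binary")
  for (ch in node) {
    ok <- .checkBinary(ch)
    if (!isTRUE(ok)) return(ok)
  }
  TRUE
}

setMethod("show", "RootedCladeTree", function(object) {
  cat("RootedCladeTree:", writeNewick(object), "\n")
})

#' Result container for a full pipeline run
#'
#' @slot cladeMap the \linkS4class{CladeMap} used.
#' @slot scores per species-quartet scoring table.
#' @slot verdicts per species-quartet filter verdicts.
#' @slot thresholds per clade-quartet filter thresholds.
#' @slot supports per clade-quartet median supports (omega).
#' @slot ranking ranked rooted clade trees.
#' @slot supportMatrix pairwise-compatibility support matrix (long format).
#' @slot summary named list of per-stage counts and settings.
#' @export
setClass("QuartetAnalysis",
         representation(cladeMap = "CladeMap", scores = "data.frame",
                        verdicts = "data.frame", thresholds = "data.frame",
                        supports = "data.frame", ranking = "data.frame",
                        supportMatrix = "data.frame", summary = "list"))

setMethod("show", "QuartetAnalysis", function(object) {
  s <- object@summary
  cat("QuartetAnalysis\n")
  cat("  clade-quartets:     ", s$n_clade_quartets, "\n")
  cat("  species-quartets:   ", s$n_species_quartets_scored, "scored,",
      s$n_species_quartets_retained, "retained\n")
  cat("  ranked clade trees: ", s$n_trees_ranked, "\n")
  if (nrow(object@ranking)) {
    cat("  best tree:          ", object@ranking$tree[1L],
        sprintf("(score %.4f)\n", object@ranking$score[1L]))
  }
})

#' @describeIn QuartetAnalysis-class ranked tree table.
#' @param x a \code{QuartetAnalysis}.
#' @export
treeRanking <- function(x) { stopifnot(is(x, "QuartetAnalysis")); x@ranking }

#' @describeIn QuartetAnalysis-class per clade-quartet median supports.
#' @export
cladeSupports <- function(x) { stopifnot(is(x, "QuartetAnalysis")); x@supports }

#' @describeIn QuartetAnalysis-class per species-quartet scoring table.
#' @export
quartetScores <- function(x) { stopifnot(is(x, "QuartetAnalysis")); x@scores }
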