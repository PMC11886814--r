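# End-to-end orchestration: scoring -> filtering -> aggregation -> tree
# ranking, with all tabular report artifacts.

#' Run the full quartet-support pipeline
#'
#' Executes quartet enumeration, species-quartet scoring, optional
#' filtering, median aggregation and rooted clade-tree ranking, and
#' (optionally) writes every report table to an output directory.  Results
#' are deterministic for identical inputs: species-quartets are independent
#' work units merged in quartet-id order.
#'
#' @param alignment alignment matrix or path to a FASTA/PHYLIP file.
#' @param clades a \linkS4class{CladeMap} or path to a clade-definition
#'   TSV (see [readCladeMap()]).
#' @param model substitution model for the ML stage (default
#'   \code{"GTR+G"}).
#' @param filters \code{"none"}, \code{"risk"}, \code{"dist"} or
#'   \code{"risk+dist"} (default).
#' @param l_risk RISK threshold or \code{"auto"} (default: optimized per
#'   clade-quartet).
#' @param l_dist DIST threshold (default 0.1) or \code{"auto"}.
#' @param rule pattern rule, \code{"relaxed"} (default) or
#'   \code{"strict"}.
#' @param score score rule, \code{"excess"} (default) or \code{"ratio"}.
#' @param top_k number of ranked trees to keep (default 100).
#' @param out_dir optional directory for report files.
#' @param alignment_format format when \code{alignment} is a path.
#' @param control optimizer control, see [fitQuartetML()].
#' @param verbose print stage progress.
#' @return a \linkS4class{QuartetAnalysis}.
#' @export
runPipeline <- function(alignment, clades, model = "GTR+G",
                        filters = "risk+dist", l_risk = "auto",
                        l_dist = 0.1, rule = "relaxed", score = "excess",
                        top_k = 100L, out_dir = NULL,
                        alignment_format = "fasta", control = list(),
                        verbose = FALSE) {
  if (is.character(alignment) && length(alignment) == 1L)
    alignment <- readAlignment(alignment, alignment_format)
  if (is.character(clades) && length(clades) == 1L)
    clades <- readCladeMap(clades, alignment)
  stopifnot(is(clades, "CladeMap"))

  scores <- scoreSpeciesQuartets(alignment, clades, model = model,
                                 rule = rule, score = score,
                                 control = control, verbose = verbose)
  flt <- applyFilters(scores, filters = filters, l_risk = l_risk,
                      l_dist = l_dist)
  retained <- flt$verdicts$retained[match(scores$quartet_id,
                                          flt$verdicts$quartet_id)]
  supports <- medianSupport(scores, retained)
  ranking <- rankCladeTrees(supports, clades, top_k = top_k)
  sm <- buildSupportMatrix(supports, clades)
  contrib <- speciesContribution(scores, clades, retained)

  summary <- list(
    n_taxa = nrow(alignment), n_sites = ncol(alignment),
    n_ingroup_clades = length(ingroupCodes(clades)),
    n_clade_quartets = length(unique(scores$clade_quartet)),
    n_species_quartets_scored = nrow(scores),
    n_species_quartets_usable = sum(scores$usable),
    n_species_quartets_retained = sum(retained),
    n_trees_ranked = nrow(ranking),
    model = model, filters = filters, rule = rule, score = score,
    best_tree = if (nrow(ranking)) ranking$tree[1] else NA_character_,
    best_score = if (nrow(ranking)) ranking$score[1] else NA_real_,
    delta_best_2nd = attr(ranking, "delta_best_2nd"),
    delta_best_3rd = attr(ranking, "delta_best_3rd"))

  res <- new("QuartetAnalysis", cladeMap = clades, scores = scores,
             verdicts = flt$verdicts, thresholds = flt$thresholds,
             supports = supports, ranking = ranking,
             supportMatrix = sm$cells, summary = summary)
  if (!is.null(out_dir)) writeReports(res, out_dir)
  res
}

#' Write all pipeline report artifacts
#'
#' Emits the tabular reports (\code{quartet_scores.tsv},
#' \code{filter_report.tsv}, \code{thresholds.tsv},
#' \code{clade_quartet_support.tsv}, \code{ternary_points.tsv},
#' \code{species_contribution.tsv}, \code{tree_ranking.tsv},
#' \code{support_matrix.tsv}), the ranked trees as Newick
#' (\code{best_trees.nwk}) and a machine-readable \code{summary.json}.
#' Site and column indices in reports are 1-based.
#'
#' @param x a \linkS4class{QuartetAnalysis}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
writeReports <- function(x, out_dir) {
  stopifnot(is(x, "QuartetAnalysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  tsv(x@scores, "quartet_scores.tsv")
  tsv(merge(x@verdicts,
            x@scores[, c("quartet_id", "sd12", "ratio_best")],
            by = "quartet_id"), "filter_report.tsv")
  tsv(x@thresholds, "thresholds.tsv")
  tsv(x@supports, "clade_quartet_support.tsv")
  ok <- x@scores$usable & !is.na(x@scores$R1)
  xy <- ternaryCoordinates(as.matrix(x@scores[ok, c("R1", "R2", "R3")]))
  if (is.null(dim(xy))) xy <- matrix(xy, nrow = 1,
                                     dimnames = list(NULL, c("x", "y")))
  tp <- cbind(x@scores[ok, c("quartet_id", "clade_quartet")],
              xy, row.names = NULL)
  tsv(tp, "ternary_points.tsv")
  contrib <- speciesContribution(
    x@scores, x@cladeMap,
    x@verdicts$retained[match(x@scores$quartet_id,
                              x@verdicts$quartet_id)])
  tsv(contrib$perQuartet, "species_contribution.tsv")
  tsv(contrib$perTaxon, "species_consistency.tsv")
  tsv(x@ranking, "tree_ranking.tsv")
  tsv(x@supportMatrix, "support_matrix.tsv")
  writeLines(x@ranking$tree, file.path(out_dir, "best_trees.nwk"))
  jsonlite::write_json(x@summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
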