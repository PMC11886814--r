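# Simulation-based validation: simulate alignments on known clade trees,
# run the full pipeline, and check that the generating tree ranks first.

#' Build a species tree from a rooted clade tree
#'
#' Expands every clade code of a rooted clade tree (plus the outgroup
#' attached at the root) into a small subtree of \code{taxaPerClade} taxa
#' labelled \code{<code>_1 ...}, with the given stem/within-clade/terminal
#' branch lengths, returning a Newick string suitable for
#' [simulateAlignment()].
#'
#' @param cladeNewick rooted Newick on the ingroup clade codes, with branch
#'   lengths on every branch (internal branches of this tree separate the
#'   clades).
#' @param outgroup outgroup clade code.
#' @param taxaPerClade taxa per clade (default 3).
#' @param withinClade depth of the within-clade subtree (default 0.05).
#' @param terminal terminal branch length added to every taxon
#'   (default 0.15).
#' @param outgroupStem branch length from the root to the outgroup clade
#'   (default 0.3).
#' @return Newick string of the species tree.
#' @export
speciesTreeFromCladeTree <- function(cladeNewick, outgroup,
                                     taxaPerClade = 3L, withinClade = 0.05,
                                     terminal = 0.15, outgroupStem = 0.3) {
  # subtree WITHOUT a top-level branch length: the clade's stem length in
  # `cladeNewick` (or `outgroupStem`) becomes the subtree's stem
  expand <- function(code) {
    labs <- paste0(code, "_", seq_len(taxaPerClade))
    if (taxaPerClade == 1L) return(labs)
    tips <- paste0(labs, ":", terminal)
    sub <- tips[1]
    for (i in 2:taxaPerClade) {
      inner <- paste0("(", sub, ",", tips[i], ")")
      sub <- if (i < taxaPerClade) paste0(inner, ":", withinClade) else inner
    }
    sub
  }
  body <- sub(";\\s*$", "", cladeNewick)
  # replace each clade-code leaf by its subtree (leaf = code followed by
  # ':' or a closing token)
  codes <- sort(unique(c(outgroup, strsplit(gsub("[();:0-9.,]+", " ",
                                                 body), "\\s+")[[1]])))
  codes <- codes[nzchar(codes)]
  for (code in setdiff(codes, outgroup)) {
    body <- gsub(paste0("(?<![A-Za-z0-9_])", code, "(?=[:,)])"),
                 expand(code), body, perl = TRUE)
  }
  paste0("(", expand(outgroup), ":", outgroupStem, ",", body, ":0.02);")
}

#' Simulation recovery study
#'
#' For each generating rooted clade tree, simulates replicate alignments
#' (optionally half of them with Lavalette indels), runs the full pipeline
#' unfiltered and filtered, and records whether the generating tree ranks
#' first and how its support compares between the two analyses.
#'
#' @param cladeTrees named list of rooted clade-tree Newick strings with
#'   branch lengths (leaves = ingroup codes).
#' @param outgroup outgroup clade code.
#' @param nRep replicates per generating tree (default 20).
#' @param nSites sites per alignment (default 20000).
#' @param taxaPerClade taxa per clade (default 3).
#' @param model substitution model used for both simulation and fitting.
#' @param indelHalf simulate indels in every second replicate (default
#'   TRUE, giving an even split with/without indels).
#' @param filters filter setting for the filtered analysis.
#' @param seed base seed; replicate r of tree t uses
#'   \code{seed + 1000*t + r}.
#' @param verbose print per-replicate progress.
#' @return data.frame with one row per (tree, replicate): recovery flags
#'   and best-tree supports for the unfiltered and filtered analyses.
#' @export
recoveryStudy <- function(cladeTrees, outgroup = "O", nRep = 20L,
                          nSites = 20000L, taxaPerClade = 3L,
                          model = "JC", indelHalf = TRUE,
                          filters = "risk+dist", seed = 1L,
                          verbose = FALSE) {
  rows <- list()
  for (t in seq_along(cladeTrees)) {
    gen_name <- names(cladeTrees)[t] %||% paste0("tree", t)
    gen_canon <- writeNewick(parseNewick(cladeTrees[[t]]))
    sp_tree <- speciesTreeFromCladeTree(cladeTrees[[t]], outgroup,
                                        taxaPerClade)
    phy <- ape::read.tree(text = sp_tree)
    codes <- setdiff(sort(unique(sub("_\\d+$", "", phy$tip.label))),
                     outgroup)
    cmap <- cladeMap(
      c(setNames(lapply(c(codes, outgroup), function(cd)
        grep(paste0("^", cd, "_"), phy$tip.label, value = TRUE)),
        c(codes, outgroup))), outgroup)
    for (r in seq_len(nRep)) {
      rep_seed <- seed + 1000L * t + r
      with_indels <- indelHalf && (r %% 2L == 0L)
      aln <- simulateAlignment(phy, nSites, model = model,
                               indels = with_indels, seed = rep_seed)
      # the scoring stage is shared; only the filtering differs between
      # the unfiltered and filtered analyses
      scores <- scoreSpeciesQuartets(aln, cmap, model = model)
      one <- function(flt) {
        v <- applyFilters(scores, filters = flt)
        ret <- v$verdicts$retained[match(scores$quartet_id,
                                         v$verdicts$quartet_id)]
        supports <- medianSupport(scores, ret)
        rk <- rankCladeTrees(supports, cmap, top_k = 3L)
        hit <- match(gen_canon, rk$tree)
        sc <- if (!is.na(hit)) rk$score[hit] else
          scoreCladeTree(parseNewick(gen_canon),
                         buildSupportMatrix(supports, cmap),
                         outgroup)$score
        list(recovered = rk$tree[1] == gen_canon, support = sc)
      }
      unf <- one("none"); fil <- one(filters)
      rows[[length(rows) + 1L]] <- data.frame(
        tree = gen_name, replicate = r, indels = with_indels,
        recovered_unfiltered = unf$recovered,
        recovered_filtered = fil$recovered,
        support_unfiltered = unf$support,
        support_filtered = fil$support,
        stringsAsFactors = FALSE)
      if (verbose)
        message(gen_name, " rep ", r, ": unfiltered ",
                rows[[length(rows)]]$recovered_unfiltered, ", filtered ",
                rows[[length(rows)]]$recovered_filtered)
    }
  }
  do.call(rbind, rows)
}

#' Generating clade trees of the standard validation study
#'
#' Two rooted trees of four ingroup clades used by the package's
#' simulation-based validation: a caterpillar tree with C as the earliest
#' ingroup lineage and a balanced tree pairing (C,D) and (P,S).  Internal
#' branches are 0.08 expected substitutions/site, clade stems 0.2--0.3.
#'
#' @return named list of Newick strings with branch lengths.
#' @export
validationCladeTrees <- function() {
  list(
    caterpillar = "(C:0.3,(D:0.25,(P:0.2,S:0.2):0.08):0.08);",
    balanced = "((C:0.25,D:0.25):0.08,(P:0.2,S:0.2):0.08);")
}

#' Summarize a recovery study
#'
#' @param study data.frame from [recoveryStudy()].
#' @return list with per-tree and overall recovery rates (percent of
#'   replicates whose generating tree ranked first) and the fraction of
#'   replicates whose filtered best-tree support was at least the
#'   unfiltered one.
#' @export
summarizeRecovery <- function(study) {
  rate <- function(v) 100 * mean(v)
  list(
    recovery_unfiltered_pct = rate(study$recovered_unfiltered),
    recovery_filtered_pct = rate(study$recovered_filtered),
    filtered_support_ge_unfiltered_frac =
      mean(study$support_filtered >= study$support_unfiltered - 1e-12),
    per_tree = vapply(split(study, study$tree), function(d)
      c(unfiltered = rate(d$recovered_unfiltered),
        filtered = rate(d$recovered_filtered)), numeric(2)))
}
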