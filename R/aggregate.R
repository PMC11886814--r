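# Aggregation of retained species-quartet supports: clade-quartet medians
# (omega), ternary coordinates, and per-species contribution summaries.

#' Median clade-quartet support (omega)
#'
#' Aggregates the retained species-quartets of every clade-quartet into
#' per-topology medians \code{omega_k = median(R_k)}.  Medians are computed
#' independently per topology (even counts average the two middle values)
#' and are not renormalized, so they need not sum to 1.  A clade-quartet
#' with no retained quartet is flagged empty; downstream tree scoring
#' treats its omegas as 0 with a warning.
#'
#' @param scores scoring table from [scoreSpeciesQuartets()].
#' @param retained logical vector of retention verdicts (e.g. from
#'   [applyFilters()]); by default every usable, signal-bearing quartet.
#' @return data.frame per clade-quartet: \code{omega1..3},
#'   \code{n_retained}, \code{n_total}, \code{retained_fraction},
#'   \code{empty}.
#' @export
medianSupport <- function(scores, retained = NULL) {
  if (is.null(retained)) retained <- scores$usable & !scores$no_signal
  stopifnot(length(retained) == nrow(scores))
  cqs <- unique(scores$clade_quartet)
  rows <- lapply(cqs, function(cq) {
    sel <- scores$clade_quartet == cq
    kept <- sel & retained
    n_ret <- sum(kept)
    if (n_ret == 0L) {
      om <- c(NA_real_, NA_real_, NA_real_)
    } else {
      om <- c(median(scores$R1[kept]), median(scores$R2[kept]),
              median(scores$R3[kept]))
    }
    data.frame(clade_quartet = cq, omega1 = om[1], omega2 = om[2],
               omega3 = om[3], n_retained = n_ret, n_total = sum(sel),
               retained_fraction = n_ret / sum(sel), empty = n_ret == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Barycentric (ternary) coordinates of topology supports
#'
#' Maps a normalized support triple onto the 2-D ternary plot with corners
#' topology 1 at (0,0), topology 2 at (1,0) and topology 3 at
#' (0.5, sqrt(3)/2): \code{x = R2 + R3/2}, \code{y = R3 * sqrt(3)/2}.
#'
#' @param R numeric vector of 3 supports summing to 1, or a 3-column
#'   matrix of such rows.
#' @return numeric vector \code{c(x, y)} or a 2-column matrix.
#' @export
ternaryCoordinates <- function(R) {
  if (is.null(dim(R))) R <- matrix(R, nrow = 1L)
  stopifnot(ncol(R) == 3L)
  xy <- cbind(x = R[, 2] + R[, 3] / 2, y = R[, 3] * sqrt(3) / 2)
  if (nrow(xy) == 1L) xy[1, ] else xy
}

#' Ternary plot of species-quartet supports
#'
#' Draws the support triples of one clade-quartet in barycentric
#' coordinates, with labeled corners and the median support marked.
#'
#' @param R 3-column matrix of support triples.
#' @param labels corner labels (topology 1, 2, 3).
#' @param main plot title.
#' @param col point colour.
#' @return invisibly, the plotted xy coordinates.
#' @export
plotTernary <- function(R, labels = c("T1", "T2", "T3"), main = "",
                        col = "#3366AAAA") {
  xy <- ternaryCoordinates(R)
  if (is.null(dim(xy))) xy <- matrix(xy, nrow = 1L)
  plot(NA, xlim = c(-0.08, 1.08), ylim = c(-0.08, sqrt(3) / 2 + 0.08),
       axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2), border = "grey30")
  text(c(0, 1, 0.5), c(-0.04, -0.04, sqrt(3) / 2 + 0.05), labels)
  points(xy[, 1], xy[, 2], pch = 16, cex = 0.6, col = col)
  med <- c(median(R[, 1]), median(R[, 2]), median(R[, 3]))
  mxy <- ternaryCoordinates(med / sum(med))
  points(mxy[1], mxy[2], pch = 17, cex = 1.2, col = "red")
  invisible(xy)
}

#' Per-species contribution and consistency summary
#'
#' For every taxon and every clade-quartet it participates in, reports the
#' percentage of its quartet participations that survived filtering, the
#' per-topology medians of its retained participations and the resulting
#' best topology.  A taxon is classed consistent when a single rooted tree
#' of all ingroup clades induces exactly its best topologies in every
#' clade-quartet where it has retained participations (the witnessing tree
#' is reported); taxa with no retained participations anywhere are marked
#' fully rejected.  Supports below 0.6 are flagged as moderate.
#'
#' @param scores scoring table from [scoreSpeciesQuartets()].
#' @param cmap the \linkS4class{CladeMap}.
#' @param retained logical retention verdicts (default: all usable,
#'   signal-bearing quartets).
#' @return list with \code{perQuartet} (taxon x clade-quartet table) and
#'   \code{perTaxon} (consistency class, witness tree, fully-rejected
#'   flag).
#' @export
speciesContribution <- function(scores, cmap, retained = NULL) {
  if (is.null(retained)) retained <- scores$usable & !scores$no_signal
  taxa_cols <- c("o", "t1", "t2", "t3")
  all_taxa <- sort(unique(unlist(scores[taxa_cols])))
  cqs <- sort(unique(scores$clade_quartet))
  trees <- enumerateRootedCladeTrees(ingroupCodes(cmap))
  induced <- lapply(trees, function(tr) {
    iq <- inducedCladeQuartets(tr, outgroupCode(cmap))
    setNames(iq$topology, iq$clade_quartet)
  })

  per_q <- list(); per_t <- list()
  for (tx in all_taxa) {
    part <- scores$o == tx | scores$t1 == tx | scores$t2 == tx |
      scores$t3 == tx
    best_by_cq <- c()
    for (cq in cqs) {
      sel <- part & scores$clade_quartet == cq
      if (!any(sel)) next
      kept <- sel & retained
      n_tot <- sum(sel); n_ret <- sum(kept)
      if (n_ret > 0L) {
        med <- c(median(scores$R1[kept]), median(scores$R2[kept]),
                 median(scores$R3[kept]))
        best <- which.max(med)
        best_by_cq[cq] <- best
      } else {
        med <- rep(NA_real_, 3); best <- NA_integer_
      }
      per_q[[length(per_q) + 1L]] <- data.frame(
        taxon = tx, clade_quartet = cq, n_participations = n_tot,
        n_retained = n_ret, percent_retained = 100 * n_ret / n_tot,
        med1 = med[1], med2 = med[2], med3 = med[3], best = best,
        moderate = !is.na(best) && med[best] < 0.6,
        stringsAsFactors = FALSE)
    }
    fully_rejected <- length(best_by_cq) == 0L
    if (fully_rejected) {
      cls <- "fully-rejected"; witness <- NA_character_
    } else {
      hit <- vapply(induced, function(top) {
        all(top[names(best_by_cq)] == best_by_cq)
      }, logical(1))
      if (any(hit)) {
        cls <- "consistent"
        witness <- writeNewick(trees[[which(hit)[1]]])
      } else {
        cls <- "inconsistent"; witness <- NA_character_
      }
    }
    clade <- names(which(vapply(cmap@clades, function(v) tx %in% v,
                                logical(1))))[1]
    per_t[[length(per_t) + 1L]] <- data.frame(
      taxon = tx, clade = clade, consistency = cls, witness = witness,
      stringsAsFactors = FALSE)
  }
  list(perQuartet = do.call(rbind, per_q),
       perTaxon = do.call(rbind, per_t))
}
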