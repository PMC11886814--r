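# RISK and DIST species-quartet filters and threshold optimization.

#' Support-distance statistic
#'
#' \code{SD_{1,2}}: difference between the normalized supports of the best
#' and second-best topology of a species-quartet.  Values near 0 indicate
#' strong conflict, values near 1 a dominant signal.
#'
#' @param R numeric vector of 3 normalized supports (sums to 1).
#' @return \code{SD_{1,2}} in [0, 1].
#' @export
distStatistic <- function(R) {
  stopifnot(length(R) == 3L)
  sr <- sort(R, decreasing = TRUE)
  sr[1] - sr[2]
}

#' Apply the DIST filter
#'
#' Retains species-quartets whose best-vs-second support distance
#' \code{SD_{1,2}} is at least \code{l_dist} (boundary kept).  Quartets
#' flagged \code{no_signal} or unusable are never retained.
#'
#' @param scores scoring table from [scoreSpeciesQuartets()].
#' @param l_dist threshold in [0, 1] (default 0.1).
#' @return logical vector of retention verdicts.
#' @export
applyDistFilter <- function(scores, l_dist = 0.1) {
  stopifnot(l_dist >= 0, l_dist <= 1)
  ok <- scores$usable & !scores$no_signal
  ok & !is.na(scores$sd12) & scores$sd12 >= l_dist
}

#' Apply the RISK filter
#'
#' Retains species-quartets whose best topology's convergence-to-signal
#' ratio \code{Nc/Na} is strictly below \code{l_risk}; a quartet with
#' \code{Na = 0} for its best topology (ratio infinite) is always excluded,
#' as are \code{no_signal} quartets.
#'
#' @param scores scoring table from [scoreSpeciesQuartets()].
#' @param l_risk threshold in (0, 1].
#' @return logical vector of retention verdicts.
#' @export
applyRiskFilter <- function(scores, l_risk) {
  stopifnot(l_risk > 0, l_risk <= 1)
  ok <- scores$usable & !scores$no_signal
  ok & is.finite(scores$ratio_best) & scores$ratio_best < l_risk
}

#' Default threshold objective: retention times purity
#'
#' \code{f(L) = (fraction of quartets retained at L)^exponent * (1 - mean
#' best-tree Nc/Na ratio among retained)}: a balance between keeping many
#' quartets and keeping only quartets whose best tree has a low
#' convergence ratio.  With \code{exponent = 1} the plain
#' retention-times-purity product reduces to the mean of \code{1 - ratio}
#' over the retained set, which is monotone non-decreasing in \code{L} for
#' ratios below 1 and therefore always optimized by full retention; the
#' default concave retention term (\code{exponent = 0.5}) makes admitting
#' high-ratio quartets cost more purity than it gains retention, producing
#' the intended interior threshold between well-separated ratio clusters.
#' Any function with the signature \code{f(L, ratios, n_total)} can be
#' substituted in [optimizeRiskThreshold()] and [applyFilters()].
#'
#' @param L candidate threshold.
#' @param ratios finite best-tree Nc/Na ratios of the candidate quartets.
#' @param n_total total number of quartets (denominator of the retained
#'   fraction).
#' @param exponent exponent of the retention term (default 0.5).
#' @return objective value (0 when nothing is retained).
#' @export
riskObjective <- function(L, ratios, n_total = length(ratios),
                          exponent = 0.5) {
  kept <- ratios[ratios < L]
  if (length(kept) == 0L) return(0)
  (length(kept) / n_total)^exponent * (1 - mean(kept))
}

#' Optimize the RISK threshold by deterministic uphill climbing
#'
#' Starting from \code{L = 1} with step 0.05, the climber moves to whichever
#' neighbour \code{L + delta} or \code{L - delta} (within (0, 1]) improves
#' the objective most, resolving ties toward the larger threshold; a failed
#' move halves the step, and the search stops when the step falls below
#' 1e-3.
#'
#' @param scores scoring table from [scoreSpeciesQuartets()] restricted to
#'   one clade-quartet, or a numeric vector of best-tree Nc/Na ratios.
#' @param objective objective function, by default [riskObjective()].
#' @return list with \code{l_risk}, \code{objective} (value at the
#'   optimum) and \code{trace} (data.frame of visited thresholds).
#' @export
optimizeRiskThreshold <- function(scores, objective = riskObjective) {
  ratios <- if (is.numeric(scores)) scores else scores$ratio_best
  n_total <- length(ratios)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L) {
    warning("no finite best-tree ratios; returning L_RISK = 1")
    return(list(l_risk = 1, objective = 0,
                trace = data.frame(L = 1, f = 0)))
  }
  L <- 1; delta <- 0.05
  f <- objective(L, ratios, n_total)
  trace <- list(c(L, f))
  while (delta >= 1e-3) {
    cand <- c(min(L + delta, 1), max(L - delta, 1e-3))
    fc <- vapply(cand, objective, numeric(1), ratios = ratios,
                 n_total = n_total)
    # ties toward the larger threshold: candidates ordered high-to-low
    pick <- which(fc > f + 1e-15)
    if (length(pick)) {
      best <- pick[which.max(fc[pick])]
      if (length(pick) == 2L && abs(fc[1] - fc[2]) <= 1e-15) best <- 1L
      L <- cand[best]; f <- fc[best]
      trace[[length(trace) + 1L]] <- c(L, f)
    } else {
      delta <- delta / 2
    }
  }
  tr <- do.call(rbind, trace)
  list(l_risk = L, objective = f,
       trace = data.frame(L = tr[, 1], f = tr[, 2]))
}

#' @describeIn optimizeRiskThreshold analogous climber for the DIST
#'   threshold, with objective \code{f(L) = retained fraction * mean
#'   SD_{1,2} among retained} (retention keeps \code{SD >= L}); provided
#'   because the DIST threshold may also be optimized, though it defaults
#'   to the fixed value 0.1.
#' @export
optimizeDistThreshold <- function(scores) {
  sd12 <- if (is.numeric(scores)) scores else scores$sd12
  sd12 <- sd12[!is.na(sd12)]
  n_total <- length(sd12)
  if (n_total == 0L) {
    warning("no support distances; returning L_DIST = 0.1")
    return(list(l_dist = 0.1, objective = 0))
  }
  obj <- function(L) {
    kept <- sd12[sd12 >= L]
    if (!length(kept)) return(0)
    (length(kept) / n_total) * mean(kept)
  }
  L <- 0; delta <- 0.05
  f <- obj(L)
  while (delta >= 1e-3) {
    cand <- c(min(L + delta, 1), max(L - delta, 0))
    fc <- vapply(cand, obj, numeric(1))
    pick <- which(fc > f + 1e-15)
    if (length(pick)) {
      best <- pick[which.max(fc[pick])]
      if (length(pick) == 2L && abs(fc[1] - fc[2]) <= 1e-15) best <- 1L
      L <- cand[best]; f <- fc[best]
    } else delta <- delta / 2
  }
  list(l_dist = L, objective = f)
}

#' Apply the configured filters per clade-quartet
#'
#' Runs the enabled filters (RISK first, then DIST) on every clade-quartet,
#' optimizing \code{L_RISK} per clade-quartet when requested.  The final
#' verdict is the conjunction of the enabled filters' verdicts.
#'
#' @param scores scoring table from [scoreSpeciesQuartets()].
#' @param filters \code{"none"}, \code{"risk"}, \code{"dist"} or
#'   \code{"risk+dist"}.
#' @param l_risk numeric threshold or \code{"auto"} (per-clade-quartet
#'   uphill-climbing optimization, the default).
#' @param l_dist numeric threshold (default 0.1) or \code{"auto"}.
#' @param objective RISK objective, see [optimizeRiskThreshold()].
#' @return list with \code{verdicts} (data.frame: quartet id,
#'   \code{retained_risk}, \code{retained_dist}, \code{retained}) and
#'   \code{thresholds} (per clade-quartet: thresholds, objective value,
#'   retained counts).
#' @export
applyFilters <- function(scores, filters = "risk+dist", l_risk = "auto",
                         l_dist = 0.1, objective = riskObjective) {
  filters <- match.arg(filters, c("none", "risk", "dist", "risk+dist"))
  use_risk <- filters %in% c("risk", "risk+dist")
  use_dist <- filters %in% c("dist", "risk+dist")
  cqs <- unique(scores$clade_quartet)
  verdicts <- vector("list", length(cqs))
  thr <- vector("list", length(cqs))
  for (i in seq_along(cqs)) {
    sc <- scores[scores$clade_quartet == cqs[i], , drop = FALSE]
    lr <- NA_real_; obj_val <- NA_real_
    if (use_risk) {
      if (identical(l_risk, "auto")) {
        opt <- optimizeRiskThreshold(sc, objective)
        lr <- opt$l_risk; obj_val <- opt$objective
      } else lr <- as.numeric(l_risk)
    }
    ld <- NA_real_
    if (use_dist)
      ld <- if (identical(l_dist, "auto"))
        optimizeDistThreshold(sc)$l_dist else as.numeric(l_dist)
    rr <- if (use_risk) applyRiskFilter(sc, lr) else
      (sc$usable & !sc$no_signal)
    rd <- if (use_dist) applyDistFilter(sc, ld) else
      (sc$usable & !sc$no_signal)
    keep <- if (filters == "none") (sc$usable & !sc$no_signal) else rr & rd
    verdicts[[i]] <- data.frame(
      quartet_id = sc$quartet_id, clade_quartet = cqs[i],
      retained_risk = rr, retained_dist = rd, retained = keep,
      stringsAsFactors = FALSE)
    thr[[i]] <- data.frame(
      clade_quartet = cqs[i], l_risk = lr, l_dist = ld,
      objective = obj_val, n_total = nrow(sc), n_retained = sum(keep),
      stringsAsFactors = FALSE)
  }
  list(verdicts = do.call(rbind, verdicts),
       thresholds = do.call(rbind, thr))
}
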