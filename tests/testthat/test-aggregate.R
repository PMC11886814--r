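test_that("clade-quartet medians follow the per-topology median rules", {
  R <- rbind(c(0.2, 0.5, 0.3), c(0.5, 0.3, 0.2), c(0.9, 0.05, 0.05))
  sc <- make_scores_stub(R, ratio_best = rep(0.1, 3))
  ms <- medianSupport(sc)
  expect_equal(ms$omega1, 0.5)  # odd count
  expect_identical(ms$n_retained, 3L)

  sc2 <- make_scores_stub(rbind(c(0.2, 0.4, 0.4), c(0.4, 0.3, 0.3)),
                          ratio_best = c(0.1, 0.1))
  expect_equal(medianSupport(sc2)$omega1, 0.3)  # even count averages

  sc1 <- make_scores_stub(rbind(c(0.7, 0.2, 0.1)), ratio_best = 0.1)
  ms1 <- medianSupport(sc1)
  expect_equal(c(ms1$omega1, ms1$omega2, ms1$omega3), c(0.7, 0.2, 0.1))

  # nothing retained -> flagged empty
  mse <- medianSupport(sc, retained = rep(FALSE, 3))
  expect_true(mse$empty)
  expect_identical(mse$n_retained, 0L)
})

test_that("medians are permutation invariant and bounded by the inputs", {
  set.seed(12)
  vals <- runif(7)
  R <- cbind(vals, (1 - vals) / 2, (1 - vals) / 2)
  sc <- make_scores_stub(R, ratio_best = rep(0.1, 7))
  m1 <- medianSupport(sc)$omega1
  perm <- sample(7)
  scp <- make_scores_stub(R[perm, ], ratio_best = rep(0.1, 7))
  expect_equal(medianSupport(scp)$omega1, m1)
  expect_gte(m1, min(vals))
  expect_lte(m1, max(vals))
})

test_that("ternary coordinates map corners, centroid, and stay affine", {
  expect_equal(ternaryCoordinates(c(1, 0, 0)), c(x = 0, y = 0))
  expect_equal(ternaryCoordinates(c(0, 1, 0)), c(x = 1, y = 0))
  expect_equal(ternaryCoordinates(c(0, 0, 1)), c(x = 0.5, y = sqrt(3) / 2))
  expect_equal(ternaryCoordinates(rep(1 / 3, 3)),
               c(x = 0.5, y = sqrt(3) / 6))
  # affine: coordinates of a convex combination are the combination of
  # coordinates; injective on the simplex
  set.seed(4)
  for (i in 1:10) {
    a <- rgamma(3, 1); a <- a / sum(a)
    b <- rgamma(3, 1); b <- b / sum(b)
    w <- runif(1)
    lhs <- ternaryCoordinates(w * a + (1 - w) * b)
    rhs <- w * ternaryCoordinates(a) + (1 - w) * ternaryCoordinates(b)
    expect_equal(lhs, rhs, tolerance = 1e-12)
    if (max(abs(a - b)) > 1e-9)
      expect_gt(max(abs(ternaryCoordinates(a) - ternaryCoordinates(b))), 0)
  }
})

test_that("species contributions classify tree-consistent taxa with a witness", {
  cmap <- make_clade_map(c(C = 1, D = 1, P = 1, S = 1, O = 2))
  ref <- parseNewick("(C,(D,(P,S)));")
  induced <- inducedCladeQuartets(ref, "O")
  # craft scores where O_1's best topologies follow `ref` in all four
  # clade-quartets, and O_2 contradicts it in exactly one
  rows <- list()
  qid <- 0L
  for (i in seq_len(nrow(induced))) {
    cq <- induced$clade_quartet[i]
    for (o in c("O_1", "O_2")) {
      qid <- qid + 1L
      best <- induced$topology[i]
      if (o == "O_2" && cq == "CDOP") best <- (best %% 3L) + 1L
      R <- rep(0.05, 3); R[best] <- 0.9
      rows[[qid]] <- data.frame(
        quartet_id = qid, clade_quartet = cq, o = o,
        t1 = "x1", t2 = "x2", t3 = "x3", n_sites = 100L, usable = TRUE,
        Na1 = 1, Na2 = 1, Na3 = 1, Nc1 = 0, Nc2 = 0, Nc3 = 0,
        S1 = R[1], S2 = R[2], S3 = R[3],
        R1 = R[1], R2 = R[2], R3 = R[3], best = best, ratio_best = 0.1,
        sd12 = 0.85, no_signal = FALSE, converged = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  sc <- do.call(rbind, rows)
  contrib <- speciesContribution(sc, cmap)
  pt <- contrib$perTaxon
  expect_identical(pt$consistency[pt$taxon == "O_1"], "consistent")
  expect_identical(pt$witness[pt$taxon == "O_1"], writeNewick(ref))
  expect_identical(pt$consistency[pt$taxon == "O_2"], "inconsistent")
  # exhaustive-witness oracle: O_1's best topologies match some tree
  trees <- enumerateRootedCladeTrees(c("C", "D", "P", "S"))
  best_o1 <- setNames(induced$topology, induced$clade_quartet)
  hits <- vapply(trees, function(tr) {
    it <- inducedCladeQuartets(tr, "O")
    all(setNames(it$topology, it$clade_quartet)[names(best_o1)] == best_o1)
  }, logical(1))
  expect_identical(sum(hits), 1L)
  expect_identical(writeNewick(trees[[which(hits)]]), writeNewick(ref))

  # fully-rejected taxon
  contrib2 <- speciesContribution(sc, cmap,
                                  retained = sc$o != "O_2")
  pt2 <- contrib2$perTaxon
  expect_identical(pt2$consistency[pt2$taxon == "O_2"], "fully-rejected")
  pq2 <- contrib2$perQuartet
  expect_true(all(pq2$percent_retained[pq2$taxon == "O_2"] == 0))
})
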