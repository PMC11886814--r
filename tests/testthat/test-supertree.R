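dfact <- function(n) prod(seq(2 * n - 3, 1, by = -2))  # (2n-3)!!

test_that("rooted tree enumeration yields (2n-3)!! distinct canonical trees", {
  expect_identical(length(enumerateRootedCladeTrees(c("A", "B"))), 1L)
  expect_identical(length(enumerateRootedCladeTrees(c("A", "B", "C"))), 3L)
  expect_identical(length(enumerateRootedCladeTrees(c("A", "B", "C", "D"))),
                   15L)
  for (n in 2:6) {
    trees <- enumerateRootedCladeTrees(paste0("c", 1:n))
    nwk <- vapply(trees, writeNewick, character(1))
    expect_identical(length(trees), as.integer(dfact(n)))
    expect_identical(anyDuplicated(nwk), 0L)  # canonical deduplication
    expect_identical(nwk, sort(nwk))
  }
  expect_error(enumerateRootedCladeTrees(paste0("c", 1:10)),
               "enumeration limit")
})

test_that("a balanced 4-clade tree induces the four expected quartet trees", {
  tree <- parseNewick("((C,D),(P,S));")
  iq <- inducedCladeQuartets(tree, "O")
  got <- setNames(iq$basal, iq$clade_quartet)
  # (O,(P,(C,D))), (O,(S,(C,D))), (O,(C,(P,S))), (O,(D,(P,S)))
  expect_identical(got[["CDOP"]], "P")
  expect_identical(got[["CDOS"]], "S")
  expect_identical(got[["COPS"]], "C")
  expect_identical(got[["DOPS"]], "D")
})

test_that("induced topologies restrict the tree correctly", {
  cat <- parseNewick("(C,(D,(P,S)));")
  iq <- inducedCladeQuartets(cat, "O")
  got <- setNames(iq$basal, iq$clade_quartet)
  # restriction of (O,(C,(D,(P,S)))) to {C,D,P} is (O,(C,(D,P)))
  expect_identical(got[["CDOP"]], "C")
  expect_identical(got[["CDOS"]], "C")
  expect_identical(got[["COPS"]], "C")
  expect_identical(got[["DOPS"]], "D")
  # a 3-leaf tree induces exactly itself
  t3 <- parseNewick("(C,(D,P));")
  iq3 <- inducedCladeQuartets(t3, "O")
  expect_identical(nrow(iq3), 1L)
  expect_identical(iq3$basal, "C")
})

test_that("support matrix accumulates omega into the three relation cells", {
  cmap <- make_clade_map(c(C = 1, D = 1, P = 1, O = 1))
  sup <- data.frame(clade_quartet = "CDOP", omega1 = 1, omega2 = 0,
                    omega3 = 0, empty = FALSE)
  sm <- buildSupportMatrix(sup, cmap)
  # topology 1 of CDOP: (O,(C,(D,P)))
  expect_equal(sm$precedes["C", "D"], 1)
  expect_equal(sm$precedes["C", "P"], 1)
  expect_equal(sm$derivedPair["D", "P"], 1)
  expect_equal(sum(sm$precedes) + sum(sm$derivedPair) / 2, 3)

  # accumulation across clade-quartets sharing a derived pair
  cmap5 <- make_clade_map(c(C = 1, D = 1, P = 1, S = 1, O = 1))
  sup5 <- data.frame(
    clade_quartet = c("CDOP", "CDOS", "COPS", "DOPS"),
    omega1 = c(0.57, 0.34, 0, 0), omega2 = c(0, 0, 0, 0),
    omega3 = c(0, 0, 0, 0), empty = FALSE)
  sm5 <- buildSupportMatrix(sup5, cmap5)
  # CDOP topology 1 basal C pairs (D,P); CDOS topology 1 basal C pairs (D,S)
  expect_equal(sm5$precedes["C", "D"], 0.57 + 0.34)
  expect_equal(sm5$derivedPair["D", "P"], 0.57)
  expect_equal(sm5$derivedPair["D", "S"], 0.34)
  # total weight = 3 * sum of omegas
  expect_equal(sum(sm5$precedes) + sum(sm5$derivedPair) / 2,
               3 * sum(sup5$omega1))
})

test_that("tree scores sum induced omegas; matrix-sum is three times that", {
  cmap <- make_clade_map(c(C = 1, D = 1, P = 1, S = 1, O = 1))
  sup <- data.frame(
    clade_quartet = c("CDOP", "CDOS", "COPS", "DOPS"),
    omega1 = c(0, 0, 0.62, 0.45), omega2 = c(0.57, 0.34, 0, 0),
    omega3 = c(0, 0, 0, 0), empty = FALSE)
  # balanced tree ((C,D),(P,S)) induces: CDOP basal P (topology 3 of
  # sorted triple C,D,P), CDOS basal S, COPS basal C, DOPS basal D
  sup$omega3 <- c(0.57, 0.34, 0, 0)  # basal P in CDOP, basal S in CDOS
  sup$omega2 <- c(0, 0, 0, 0)
  sup$omega1 <- c(0, 0, 0.62, 0.45) # basal C in COPS, basal D in DOPS
  sm <- buildSupportMatrix(sup, cmap)
  bal <- parseNewick("((C,D),(P,S));")
  sc <- scoreCladeTree(bal, sm, "O")
  expect_equal(sc$score, 0.57 + 0.34 + 0.62 + 0.45)
  expect_equal(sc$matrix_sum, 3 * sc$score)

  # perfect supports bound: all induced omegas 1 -> score = choose(4,3)
  sup1 <- sup
  sup1$omega1 <- c(0, 0, 1, 1); sup1$omega2 <- 0; sup1$omega3 <- c(1, 1, 0, 0)
  sm1 <- buildSupportMatrix(sup1, cmap)
  expect_equal(scoreCladeTree(bal, sm1, "O")$score, choose(4, 3))
})

test_that("ranking is descending, deterministic, and self-consistent", {
  cmap <- make_clade_map(c(C = 1, D = 1, P = 1, S = 1, O = 1))
  ref <- parseNewick("(C,(D,(P,S)));")
  iq <- inducedCladeQuartets(ref, "O")
  sup <- data.frame(clade_quartet = iq$clade_quartet,
                    omega1 = 0, omega2 = 0, omega3 = 0, empty = FALSE)
  for (i in seq_len(nrow(iq)))
    sup[i, paste0("omega", iq$topology[i])] <- 1
  rk <- rankCladeTrees(sup, cmap)
  expect_identical(nrow(rk), 15L)
  expect_identical(rk$tree[1], writeNewick(ref))
  expect_equal(rk$score[1], choose(4, 3))
  expect_true(all(diff(rk$score) <= 1e-12))
  expect_equal(rk$matrix_sum, 3 * rk$score)
  expect_equal(attr(rk, "delta_best_2nd"), rk$score[1] - rk$score[2])

  # random omega tables: canonical and matrix-sum ranks agree
  set.seed(8)
  sup$omega1 <- runif(4); sup$omega2 <- runif(4); sup$omega3 <- runif(4)
  rk2 <- rankCladeTrees(sup, cmap)
  expect_identical(order(-rk2$score), order(-rk2$matrix_sum))
  # upper bound: score <= choose(n,3) * max omega
  mx <- max(as.matrix(sup[, c("omega1", "omega2", "omega3")]))
  expect_true(all(rk2$score <= choose(4, 3) * mx + 1e-12))

  # 3-ingroup case ranks exactly 3 trees
  cmap3 <- make_clade_map(c(C = 1, D = 1, X = 1, O = 1))
  sup3 <- data.frame(clade_quartet = "CDOX", omega1 = 0.2, omega2 = 0.5,
                     omega3 = 0.3, empty = FALSE)
  rk3 <- rankCladeTrees(sup3, cmap3)
  expect_identical(nrow(rk3), 3L)
  expect_identical(rk3$tree[1], "((C,X),D);")  # topology 2: basal D
})
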