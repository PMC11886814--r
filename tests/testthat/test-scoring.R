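test_that("site patterns classify by the polarized apomorphy rule", {
  # role order (O, x1, x2, x3)
  expect_identical(classifySitePattern(c("A", "A", "G", "G")), 1L)
  expect_identical(classifySitePattern(c("A", "C", "G", "G")), 1L)
  expect_identical(classifySitePattern(c("A", "G", "A", "G")), 2L)
  expect_identical(classifySitePattern(c("A", "G", "G", "A")), 3L)
  expect_identical(classifySitePattern(c("A", "G", "G", "G")), 0L)
  expect_identical(classifySitePattern(c("A", "A", "A", "G")), 0L)
  expect_identical(classifySitePattern(c("A", "A", "A", "A")), 0L)
  # pair shares the outgroup state: plesiomorphy risk, never support
  expect_identical(classifySitePattern(c("G", "A", "G", "G")), 0L)

  # strict rule additionally requires the outgroup to match the basal taxon
  expect_identical(classifySitePattern(c("A", "A", "G", "G"), "strict"), 1L)
  expect_identical(classifySitePattern(c("A", "C", "G", "G"), "strict"), 0L)
})

test_that("every pattern supports at most one topology, symmetrically in the pair", {
  for (rule in c("relaxed", "strict")) {
    for (idx in 1:256) {
      st <- oracle_decode(idx)
      k <- classifySitePattern(st, rule)
      if (k > 0L) {
        ij <- setdiff(1:3, k)
        swapped <- st
        swapped[1 + ij] <- st[1 + rev(ij)]
        expect_identical(classifySitePattern(swapped, rule), k)
      }
    }
  }
})

test_that("Na counts supporting columns per topology", {
  aln <- make_aln(o = "AAAAAAAAAA",
                  a = "AAAAGGAAAA",
                  b = "GGGGAGAAAA",
                  c = "GGGGAGAAAA")
  # cols 1-4: (A,A,G,G) -> T1; col 5: (A,G,A,A) -> pair shares outgroup
  # state; col 6: (A,G,G,G) -> ingroup-wide state; rest constant
  qc <- extractQuartetColumns(aln, c("o", "a", "b", "c"))
  expect_equal(countNa(qc$counts), c(4, 0, 0))

  counts <- integer(256)
  counts[64 * 0 + 16 * 0 + 4 * 2 + 2 + 1] <- 4L  # (A,A,G,G) x4 -> T1
  counts[64 * 0 + 16 * 2 + 4 * 0 + 2 + 1] <- 2L  # (A,G,A,G) x2 -> T2
  counts[1] <- 4L                                # constant
  expect_equal(countNa(counts), c(4, 2, 0))
  expect_equal(countNa(integer(256)), c(0, 0, 0))
})

test_that("pruning likelihood matches the explicit 256-term enumeration", {
  set.seed(101)
  for (rep in 1:12) {
    p <- random_model_params()
    probs <- quartetPatternProbs(p$bl, p$pi, p$exch, p$alpha, p$ncat)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    oracle <- oracle_probs(p$bl, p$pi, p$exch, p$alpha, p$ncat)
    expect_lt(max(abs(probs - oracle)), 1e-10)
    counts <- as.numeric(rmultinom(1, 200, oracle))
    ll <- quartetLoglik(counts, p$bl, p$pi, p$exch, p$alpha, p$ncat)
    expect_equal(ll, sum(counts[counts > 0] * log(oracle[counts > 0])),
                 tolerance = 1e-10)
  }
})

test_that("pruning likelihood agrees with phangorn on the same model", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  aln <- simulateAlignment("((A:0.15,B:0.2):0.07,(C:0.1,D:0.3):0.07);",
                           800, model = "JC", seed = 5)
  qc <- extractQuartetColumns(aln, c("A", "B", "C", "D"))
  bl <- c(0.15, 0.2, 0.1, 0.3, 0.14)
  ll <- quartetLoglik(qc$counts, bl)
  tr <- ape::read.tree(text = "((A:0.15,B:0.2):0.14,C:0.1,D:0.3);")
  dat <- phangorn::phyDat(aln[c("A", "B", "C", "D"), ])
  pm <- phangorn::pml(tr, dat, bf = rep(0.25, 4), k = 1)
  expect_equal(ll, pm$logLik, tolerance = 1e-6)
})

test_that("quartet ML recovers simulated branch lengths", {
  aln <- simulateAlignment("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);",
                           10000, model = "JC", seed = 42)
  qc <- extractQuartetColumns(aln, c("A", "B", "C", "D"))
  fit <- fitQuartetML(qc$counts, 1, model = "JC")
  expect_true(fit$converged)
  # terminals 0.1 each; internal path through the root is 0.2
  expect_equal(fit$bl[1:4], rep(0.1, 4), tolerance = 0.2)
  expect_lt(max(abs(fit$bl[1:4] - 0.1)), 0.02)
  expect_lt(abs(fit$bl[5] - 0.2), 0.03)
  # identical sequences drive branch lengths to the lower bound
  alnc <- make_aln(o = "ACGTACGT", a = "ACGTACGT", b = "ACGTACGT",
                   c = "ACGTACGT")
  qcc <- extractQuartetColumns(alnc, c("o", "a", "b", "c"))
  fitc <- fitQuartetML(qcc$counts, 1, model = "JC")
  expect_true(all(fitc$bl <= 1e-6))
})

test_that("fitted log-likelihood equals the brute-force value at the optimum", {
  set.seed(13)
  aln <- simulateAlignment("((A:0.2,B:0.1):0.05,(C:0.15,D:0.25):0.05);",
                           500, model = "GTR+G", seed = 9)
  qc <- extractQuartetColumns(aln, c("A", "B", "C", "D"))
  fit <- fitQuartetML(qc$counts, 1, model = "GTR+G")
  tcounts <- numeric(256)
  tcounts[polarquart:::.topologyIndexMap(1)] <- qc$counts
  oracle <- oracle_probs(fit$bl, fit$pi, fit$exch, fit$alpha, 4L)
  ll_oracle <- sum(tcounts[tcounts > 0] * log(oracle[tcounts > 0]))
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-8)
})

test_that("Nc matches exact pattern-class expectations and symmetry limits", {
  set.seed(3)
  aln <- simulateAlignment("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);",
                           2000, model = "JC", seed = 31)
  qc <- extractQuartetColumns(aln, c("A", "B", "C", "D"))
  fits <- lapply(1:3, function(k) fitQuartetML(qc$counts, k, model = "JC"))
  nc <- estimateNc(fits, qc$n_sites)
  # oracle: per fit, brute-force probabilities restricted to the class
  cls <- vapply(1:256, function(i) classifySitePattern(oracle_decode(i)),
                integer(1))
  for (i in 1:3) {
    e <- vapply(setdiff(1:3, i), function(j) {
      m <- polarquart:::.topologyIndexMap(j)
      probs_role <- oracle_probs(fits[[j]]$bl, fits[[j]]$pi,
                                 fits[[j]]$exch, 1, 1L)[m]
      qc$n_sites * sum(probs_role[cls == i])
    }, numeric(1))
    expect_equal(nc[i], mean(e), tolerance = 1e-8)
  }
  expect_true(all(nc >= 0))

  # star-like model: all three classes equally probable by symmetry
  star <- quartetPatternProbs(c(1, 1, 1, 1, 1e-8))
  pcls <- vapply(1:3, function(k) sum(star[cls == k]), numeric(1))
  # internal branch is at the 1e-8 lower bound, not exactly 0, so the
  # three classes agree only to that order
  expect_equal(pcls[1], pcls[2], tolerance = 1e-6)
  expect_equal(pcls[2], pcls[3], tolerance = 1e-6)
  expect_gt(pcls[1], 0)

  # zero branch lengths: only constant patterns have mass
  frozen <- quartetPatternProbs(rep(1e-8, 5))
  expect_lt(sum(frozen[cls > 0]), 1e-6)
})

test_that("support normalization follows the excess-count rule", {
  ns <- normalizeSupport(c(4, 2, 1), c(2, 1, 1))
  expect_equal(ns$S, c(2, 1, 0))
  expect_equal(ns$R, c(2, 1, 0) / 3)
  expect_identical(ns$best, 1L)
  expect_false(ns$no_signal)
  expect_equal(sum(ns$R), 1, tolerance = 1e-12)

  # S = (2,1,1) -> R = (0.5, 0.25, 0.25)
  ns2 <- normalizeSupport(c(4, 3, 3), c(2, 2, 2))
  expect_equal(ns2$R, c(0.5, 0.25, 0.25))

  # degenerate: all excess zero -> uniform R and no_signal
  ns3 <- normalizeSupport(c(5, 5, 0), c(5, 5, 0))
  expect_true(ns3$no_signal)
  expect_equal(ns3$R, rep(1 / 3, 3))
  expect_identical(ns3$best, 1L)

  # ratio variant
  nsr <- normalizeSupport(c(10, 5, 0), c(5, 5, 3), score = "ratio")
  expect_equal(nsr$S, c(0.5, 0, 0))
  expect_equal(nsr$ratio, c(0.5, 1, Inf))
})

test_that("adding topology-1 supporting columns never decreases R1", {
  counts <- integer(256)
  counts[64 * 0 + 16 * 0 + 4 * 2 + 2 + 1] <- 5L   # T1 support
  counts[64 * 0 + 16 * 2 + 4 * 0 + 2 + 1] <- 5L   # T2 support
  nc <- c(1, 1, 1)
  prev <- -Inf
  for (extra in 0:10) {
    na <- countNa(counts) + c(extra, 0, 0)
    r1 <- normalizeSupport(na, nc)$R[1]
    expect_gte(r1, prev)
    prev <- r1
  }
})

test_that("permuting ingroup roles permutes Na, Nc and R identically", {
  aln <- simulateAlignment("((O:0.2,A:0.15):0.06,(B:0.1,C:0.25):0.06);",
                           3000, model = "JC", seed = 77)
  score_one <- function(order) {
    qc <- extractQuartetColumns(aln, c("O", order))
    na <- countNa(qc$counts)
    fits <- lapply(1:3, function(k) fitQuartetML(qc$counts, k, model = "JC"))
    nc <- estimateNc(fits, qc$n_sites)
    list(na = na, nc = nc, R = normalizeSupport(na, nc)$R)
  }
  base <- score_one(c("A", "B", "C"))
  perm <- score_one(c("B", "C", "A"))  # role r now holds old role r+1
  reorder <- c(2L, 3L, 1L)
  expect_equal(perm$na, base$na[reorder])
  # the coordinate-descent sweep order differs between the two role
  # orders, so the optima agree only to optimizer precision
  expect_equal(perm$nc, base$nc[reorder], tolerance = 1e-4)
  expect_equal(perm$R, base$R[reorder], tolerance = 1e-3)
})
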