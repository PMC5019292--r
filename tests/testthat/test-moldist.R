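test_that("site pattern counts match hand counts, with pairwise deletion", {
  c0 <- site_pattern_counts("ACGT", "ACGT")
  expect_equal(c0[c("P", "Q", "L")], list(P = 0, Q = 0, L = 4L))
  c1 <- site_pattern_counts("ACGT", "GCGT")  # A>G is a transition
  expect_equal(c1$P, 0.25); expect_equal(c1$Q, 0); expect_equal(c1$L, 4L)
  c2 <- site_pattern_counts("AC-T", "ACGT")  # gapped site dropped
  expect_equal(c2$L, 3L); expect_equal(c2$P + c2$Q, 0)
  c3 <- site_pattern_counts("ANGT", "ACGT")  # N excluded like a gap
  expect_equal(c3$L, 3L)
  expect_error(site_pattern_counts("AC", "ACGT"), "equal length")
  expect_error(site_pattern_counts("--NN", "ACGT"), "no overlapping")
})

test_that("K2P distance matches its closed form and flags saturation", {
  expect_equal(k2p_distance(list(P = 0, Q = 0)), 0)
  expect_equal(k2p_distance(list(P = 0.1, Q = 0.05)),
               k2p_closed_form(0.1, 0.05), tolerance = 1e-12)
  expect_equal(k2p_closed_form(0.1, 0.05), 0.1701812, tolerance = 1e-6)
  expect_true(is.na(k2p_distance(list(P = 0.5, Q = 0))))   # domain boundary
  expect_true(is.na(k2p_distance(list(P = 0.1, Q = 0.5))))
})

test_that("K2P dominates the p-distance except at zero differences", {
  set.seed(31)
  for (i in 1:200) {
    Q <- runif(1, 0, 0.35); P <- runif(1, 0, (1 - Q) / 2 - 0.01)
    d <- k2p_distance(list(P = P, Q = Q))
    if (P + Q == 0) expect_equal(d, 0) else expect_gt(d, P + Q)
  }
})

test_that("TN93 reduces to K2P under uniform frequencies and equal rates", {
  set.seed(5)
  for (i in 1:50) {
    Q <- runif(1, 0, 0.3); P <- runif(1, 0, (1 - Q) / 2 - 0.05)
    cnt <- list(P1 = P / 2, P2 = P / 2, Q = Q,
                freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
    expect_equal(tn93_distance(cnt), k2p_distance(list(P = P, Q = Q)),
                 tolerance = 1e-9)
  }
})

test_that("K2P and TN93 on real pairs agree with ape's dist.dna", {
  set.seed(17)
  tr <- ape::read.tree(text = "(a:0.08,b:0.08);")
  aln <- simulate_alignment(tr, 600, list(freq = c(A = .3, C = .2, G = .2, T = .3),
                                          kappa1 = 4, kappa2 = 6), seed = 99)
  bin <- ape::as.DNAbin(t(sapply(rownames(aln), function(i) tolower(aln[i, ]))))
  cnt <- site_pattern_counts(aln["a", ], aln["b", ])
  expect_equal(k2p_distance(cnt),
               as.numeric(ape::dist.dna(bin, model = "K80")), tolerance = 1e-9)
  expect_equal(tn93_distance(cnt),
               as.numeric(ape::dist.dna(bin, model = "TN93")), tolerance = 1e-9)
  expect_equal(k2p_distance(cnt, gamma_shape = 0.4292),
               as.numeric(ape::dist.dna(bin, model = "K80", gamma = 0.4292)),
               tolerance = 1e-9)
})

test_that("gamma correction increases distances and vanishes as shape grows", {
  d0 <- k2p_distance(list(P = 0.1, Q = 0.05))
  expect_equal(k2p_distance(list(P = 0, Q = 0), gamma_shape = 0.4292), 0)
  expect_gt(k2p_distance(list(P = 0.1, Q = 0.05), gamma_shape = 0.4292), d0)
  expect_gt(k2p_distance(list(P = 0.1, Q = 0.05), gamma_shape = 1),
            k2p_distance(list(P = 0.1, Q = 0.05), gamma_shape = 2))
  expect_equal(k2p_distance(list(P = 0.1, Q = 0.05), gamma_shape = 1e6), d0,
               tolerance = 1e-4)
  cnt <- list(P1 = 0.04, P2 = 0.05, Q = 0.06,
              freq = c(A = .3, C = .2, G = .2, T = .3))
  expect_equal(tn93_distance(cnt, gamma_shape = 1e6), tn93_distance(cnt),
               tolerance = 1e-4)
})

test_that("pairwise matrix is symmetric with hand-computed toy values", {
  aln <- toy_alignment()
  d <- pairwise_distances(aln, model = "k2p")
  expect_equal(unclass(d), t(unclass(d)))
  expect_equal(diag(unclass(d)), setNames(rep(0, 4), rownames(aln)))
  expect_equal(d["s1", "s2"], k2p_closed_form(2 / 20, 0), tolerance = 1e-12)
  expect_equal(d["s1", "s3"], k2p_closed_form(0, 1 / 20), tolerance = 1e-12)
  expect_equal(d["s2", "s3"], k2p_closed_form(1 / 20, 1 / 20), tolerance = 1e-12)
  expect_equal(d["s1", "s4"], 0)                      # gap site dropped, L = 19
  expect_equal(d["s2", "s4"], k2p_closed_form(2 / 19, 0), tolerance = 1e-12)
  # identical sequences give a zero 2x2 matrix
  aln_id <- rbind(t1 = aln["s1", ], t2 = aln["s1", ])
  expect_true(all(unclass(pairwise_distances(aln_id)) == 0))
})

test_that("saturated and non-overlapping pairs are flagged, not fatal", {
  a <- rep(c("A", "G"), 10)
  cc <- a; cc[1] <- "C"  # one transversion from a
  aln <- rbind(a = a, b = rep(c("G", "A"), 10), c = cc)
  d <- pairwise_distances(aln, model = "k2p")
  expect_true(is.na(d["a", "b"]))  # P = 1: past saturation
  expect_false(is.na(d["a", "c"]))
  expect_true("a" %in% attr(d, "undefined"))
  aln2 <- rbind(a = c("A", "-", "-"), b = c("-", "A", "A"), c = c("A", "A", "A"))
  d2 <- pairwise_distances(aln2, model = "p")
  expect_true(is.na(d2["a", "b"]))
})

test_that("deletion policies drop the right columns", {
  aln <- rbind(a = c("A", "C", "G", "T"), b = c("A", "-", "G", "T"),
               c = c("A", "C", "N", "T"))
  dc <- pairwise_distances(aln, model = "p", deletion = "complete")
  expect_true(all(dc == 0))                             # 2 clean columns left
  dcov <- pairwise_distances(aln, model = "p", deletion = "coverage",
                             coverage = 0.6)
  expect_true(all(dcov == 0))
})

test_that("group means average the cross-species pairs", {
  d <- matrix(c(0, .05, .1, .05, 0, .3, .1, .3, 0), 3,
              dimnames = rep(list(c("a1", "a2", "b1")), 2))
  gm <- group_mean_distance(d, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(gm["A", "B"], 0.2)          # mean of 0.1 and 0.3
  expect_equal(gm["A", "A"], 0.05)         # within-group mean on the diagonal
  expect_true(is.na(gm["B", "B"]))         # single member: no within pairs
  expect_equal(group_mean_distance(d, c(a1 = "A", a2 = "A", b1 = "B"),
                                   percent = TRUE)["A", "B"], 20)
  # constant cross distances return that constant
  dc <- matrix(0.07, 4, 4, dimnames = rep(list(c("x1", "x2", "y1", "y2")), 2))
  diag(dc) <- 0
  expect_equal(group_mean_distance(dc, c(x1 = "X", x2 = "X", y1 = "Y",
                                         y2 = "Y"))["X", "Y"], 0.07)
  # undefined cross cell is an error listing the pair
  d[1, 3] <- d[3, 1] <- NA
  expect_error(group_mean_distance(d, c(a1 = "A", a2 = "A", b1 = "B")),
               "a1~b1")
})

test_that("group means are invariant to within-group taxon order", {
  sc <- kor_scenario()
  aln <- simulate_alignment(sc$tree, 300, sc$model, seed = 3)
  d <- pairwise_distances(aln)
  gm1 <- group_mean_distance(d, sc$species_map)
  perm <- sample(rownames(aln))
  gm2 <- group_mean_distance(unclass(d)[perm, perm], sc$species_map)
  expect_equal(gm2[rownames(gm1), colnames(gm1)], gm1)
})
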