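test_that("karyotype generator honours composition, seed and validation", {
  tab <- simulate_karyotype(c(m = 2, sm = 20, st = 3), seed = 1)
  expect_identical(nrow(tab), 25L)
  expect_identical(as.vector(table(tab$true_class)[c("m", "sm", "st", "t")]),
                   c(2L, 20L, 3L, 0L))
  expect_true(all(tab$long_arm >= tab$short_arm))
  expect_true(all(diff(tab$long_arm + tab$short_arm) <= 0))  # size-ordered
  expect_identical(simulate_karyotype(c(m = 4, st = 2), seed = 9),
                   simulate_karyotype(c(m = 4, st = 2), seed = 9))
  expect_error(simulate_karyotype(c(zz = 3)), "composition")
  expect_error(simulate_karyotype(c(m = 2), noise_sd = -1), "noise_sd")
  expect_error(simulate_karyotype(c(m = 2), ar_ranges = list(m = c(1, 2.5))),
               "class interval")
})

test_that("zero-noise labels classify exactly; 2% noise recovers >= 95%", {
  tab0 <- simulate_karyotype(c(m = 5, sm = 5, st = 5, t = 5), noise_sd = 0,
                             seed = 2)
  k0 <- karyotype(tab0, "sim")
  expect_identical(
    as.character(k0$metrics$morph_class[order(k0$metrics$pair_id)]),
    as.character(tab0$true_class))
  # 500 pairs = 1000 chromosomes, ratios kept 0.15 from boundaries
  tab <- simulate_karyotype(c(m = 125, sm = 125, st = 125, t = 125),
                            boundary_margin = 0.15, noise_sd = 0.02, seed = 3)
  k <- karyotype(tab, "sim")
  acc <- mean(as.character(k$metrics$morph_class[order(k$metrics$pair_id)]) ==
                as.character(tab$true_class))
  expect_gte(acc, 0.95)
})

test_that("discrete gamma categories have mean rate one", {
  for (shape in c(0.4292, 1, 5)) {
    r <- discrete_gamma_rates(shape, 5)
    expect_length(r, 5)
    expect_true(all(diff(r) > 0))
    expect_equal(mean(r), 1, tolerance = 1e-9)
  }
  expect_error(discrete_gamma_rates(0), "shape")
})

test_that("alignment simulator is seed-deterministic and degenerate-safe", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  aln <- simulate_alignment(tr, 100, seed = 4)
  expect_identical(aln["a", ], aln["b", ])   # zero branch lengths: clones
  expect_identical(aln["a", ], aln["c", ])
  sc <- kor_scenario()
  a1 <- simulate_alignment(sc$tree, 150, sc$model, seed = 10)
  a2 <- simulate_alignment(sc$tree, 150, sc$model, seed = 10)
  expect_identical(a1, a2)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(a1, f1); write_fasta(a2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
})

test_that("simulated base composition converges to the stationary frequencies", {
  freq <- c(A = 0.25, C = 0.27, G = 0.18, T = 0.30)
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  aln <- simulate_alignment(tr, 50000, list(freq = freq, kappa1 = 8, kappa2 = 8),
                            seed = 13)
  obs <- table(factor(aln, c("A", "C", "G", "T")))
  p <- stats::chisq.test(obs, p = freq)$p.value
  expect_gt(p, 0.01)
})

test_that("estimated K2P is unbiased for the generating divergence", {
  # matched generator/estimator: K2P process, 600 sites, 200 replicates
  set.seed(77)
  for (t_true in c(0.05, 0.103)) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t_true / 2, t_true / 2))
    est <- replicate(200, {
      aln <- simulate_alignment(tr, 600, list(kappa1 = 4, kappa2 = 4))
      k2p_distance(site_pattern_counts(aln["a", ], aln["b", ]))
    })
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - t_true), 2 * se + 1e-12)
  }
})

test_that("scenario group means recover the generating divergences", {
  # estimate with the model that generated the data (TN93 + gamma at the
  # scenario shape); 20 replicate alignments, mean within 2 Monte-Carlo SE
  sc <- kor_scenario()
  gms <- sapply(1:20, function(s) {
    aln <- simulate_alignment(sc$tree, sc$length, sc$model, seed = 300 + s)
    d <- pairwise_distances(aln, model = "tn93",
                            gamma_shape = sc$model$gamma_shape)
    gm <- group_mean_distance(d, sc$species_map)
    c(gm["Oxynoemacheilus persa", "Oxynoemacheilus tongiorgii"],
      gm["Cobitis linea", "Oxynoemacheilus persa"],
      gm["Cobitis linea", "Oxynoemacheilus tongiorgii"])
  })
  truth <- c(0.103, 0.400, 0.400)
  se <- apply(gms, 1, stats::sd) / sqrt(ncol(gms))
  for (i in 1:3) expect_lt(abs(mean(gms[i, ]) - truth[i]), 2 * se[i])
})

test_that("the three-species scenario has the declared structure", {
  sc <- kor_scenario(seed = 1)
  true_d <- ape::cophenetic.phylo(sc$tree)
  gm <- group_mean_distance(true_d, sc$species_map)
  expect_equal(gm["Oxynoemacheilus persa", "Oxynoemacheilus tongiorgii"], 0.103)
  expect_equal(gm["Cobitis linea", "Oxynoemacheilus persa"], 0.400)
  expect_equal(gm["Cobitis linea", "Oxynoemacheilus tongiorgii"], 0.400)
  expect_equal(gm["Cobitis linea", "Cobitis linea"], 0.005)
  expect_identical(sort(as.vector(table(sc$species_map))), c(1L, 2L, 4L, 6L))
  # end-to-end: simulate, K2P distances, NJ, monophyly of all three species
  aln <- simulate_alignment(sc$tree, sc$length, sc$model, seed = 20)
  d <- pairwise_distances(aln)
  mono <- is_monophyletic(nj_tree(d), sc$species_map, outgroup = sc$outgroup)
  expect_true(all(mono))
  # barcode gap: within-species means below the smallest between-species mean
  gm_est <- group_mean_distance(d, sc$species_map)
  ingroup <- setdiff(rownames(gm_est), "Misgurnus")
  within <- diag(gm_est[ingroup, ingroup])
  between <- gm_est[ingroup, ingroup][upper.tri(diag(3))]
  expect_lt(max(within, na.rm = TRUE), min(between))
})
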