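#' Simulate per-chromosome arm measurements with known classes
#'
#' Generates a measurement table shaped like a published karyotype table:
#' for each chromosome pair a total length is drawn uniformly from
#' `length_range` and an arm ratio uniformly from the class's arm-ratio
#' interval (optionally shrunk away from the class boundaries by
#' `boundary_margin`); arms are derived and then perturbed by independent
#' multiplicative Gaussian measurement noise. Pairs are numbered by
#' decreasing total length, as in size-ordered karyotype tables.
#'
#' @param composition named integer vector of pair counts per class,
#'   e.g. `c(m = 2, sm = 20, st = 3)`.
#' @param length_range range (µm) of total chromosome lengths; the
#'   default spans the scale of small loach chromosomes.
#' @param ar_ranges named list of per-class arm-ratio sampling intervals;
#'   defaults to the class intervals themselves (`t` capped at 12).
#' @param boundary_margin shrink each sampling interval this far from
#'   the class boundaries (default 0.15, keeping noisy ratios
#'   classifiable).
#' @param noise_sd relative standard deviation of the multiplicative
#'   measurement noise per arm (default 0.02).
#' @param seed optional integer seed.
#' @return A data frame with columns `pair_id`, `long_arm`, `short_arm`,
#'   `true_class` (factor), ready for [karyotype()].
#' @export
simulate_karyotype <- function(composition,
                               length_range = c(1.5, 9.5),
                               ar_ranges = NULL,
                               boundary_margin = 0.15,
                               noise_sd = 0.02,
                               seed = NULL) {
  counts <- composition[composition > 0]
  if (length(counts) == 0L || is.null(names(counts)) ||
      !all(names(counts) %in% morph_classes()))
    stop("composition must be named pair counts over classes m, sm, st, t")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  base_ranges <- list(m = c(1, 1.7), sm = c(1.7, 3), st = c(3, 7), t = c(7, 12))
  if (is.null(ar_ranges)) ar_ranges <- base_ranges
  rows <- list()
  for (cl in names(counts)) {
    rng <- ar_ranges[[cl]]
    lo <- rng[1] + boundary_margin
    hi <- rng[2] - boundary_margin
    if (cl == "m") lo <- max(1, rng[1])  # the r >= 1 edge needs no margin
    if (cl == "t") hi <- rng[2]          # open-ended class above
    if (lo >= hi) stop("empty arm-ratio sampling interval for class ", cl)
    bounds <- base_ranges[[cl]]
    if (lo < bounds[1] - 1e-9 || hi > bounds[2] + 1e-9)
      stop("ar_ranges for class ", cl, " exceed the class interval")
    for (p in seq_len(counts[[cl]])) {
      for (try in seq_len(100L)) {
        tl <- stats::runif(1, length_range[1], length_range[2])
        r <- stats::runif(1, lo, hi)
        short <- tl / (1 + r)
        long <- tl - short
        long_n <- long * (1 + stats::rnorm(1, 0, noise_sd))
        short_n <- short * (1 + stats::rnorm(1, 0, noise_sd))
        if (short_n > 0 && long_n >= short_n) break
        if (try == 100L)
          stop("measurement noise too large: could not keep long >= short")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        long_arm = long_n, short_arm = short_n, true_class = cl)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-(out$long_arm + out$short_arm)), , drop = FALSE]
  out <- data.frame(pair_id = seq_len(nrow(out)),
                    long_arm = out$long_arm, short_arm = out$short_arm,
                    true_class = factor(out$true_class, morph_classes()))
  rownames(out) <- NULL
  out
}

#' Mean rates of equal-probability discrete gamma categories
#'
#' Discretizes a mean-1 gamma distribution with shape `shape` into `k`
#' equal-probability rate categories, each represented by its conditional
#' mean, the usual "+G" discretization of among-site rate heterogeneity.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories (default 5).
#' @return Numeric vector of `k` rates averaging 1.
#' @export
discrete_gamma_rates <- function(shape, k = 5) {
  if (shape <= 0) stop("shape must be > 0")
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  p <- stats::pgamma(q, shape = shape + 1, rate = shape)
  k * diff(p)
}

# Scaled TN93 rate matrix (rows/cols in order A, C, G, T), mean rate 1.
tn93_rate_matrix <- function(freq, kappa1 = 1, kappa2 = 1) {
  if (abs(sum(freq) - 1) > 1e-9) stop("base frequencies must sum to 1")
  Q <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  Q["A", "G"] <- Q["G", "A"] <- kappa1
  Q["C", "T"] <- Q["T", "C"] <- kappa2
  Q <- sweep(Q, 2, freq, `*`)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q / mu
}

# Transition probability matrix exp(Q t) via the symmetrized
# eigendecomposition of the reversible generator.
transition_probabilities <- function(Q, freq, t) {
  s <- sqrt(freq)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / s) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(s)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an alignment along a tree
#'
#' Evolves gap-free sequences down a tree under a Tamura-Nei
#' substitution process with optional discrete-gamma rate heterogeneity:
#' the root sequence is drawn from the stationary base frequencies, each
#' site is assigned one of `categories` equal-probability gamma rate
#' categories, and each branch multiplies the site rate into its length
#' (in expected substitutions/site).
#'
#' @param tree a `phylo` tree with branch lengths; tip labels become
#'   taxon ids.
#' @param length number of sites.
#' @param model list with elements `freq` (stationary frequencies named
#'   A, C, G, T), `kappa1`/`kappa2` (purine/pyrimidine transition rate
#'   multipliers relative to transversions), optional `gamma_shape` and
#'   `categories` (default 5). Defaults: uniform frequencies, no
#'   transition bias, no rate heterogeneity.
#' @param seed optional integer seed; the same seed and inputs give an
#'   identical alignment.
#' @return Character matrix (taxa x sites) of bases, with the seed
#'   recorded in attribute `seed`.
#' @export
simulate_alignment <- function(tree, length = 600, model = list(), seed = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (length < 1) stop("length must be >= 1")
  mod <- utils::modifyList(list(freq = setNames(rep(0.25, 4), DNA_BASES),
                                kappa1 = 1, kappa2 = 1,
                                gamma_shape = NULL, categories = 5),
                           model)
  freq <- mod$freq[DNA_BASES]
  Q <- tn93_rate_matrix(freq, mod$kappa1, mod$kappa2)
  rates <- if (is.null(mod$gamma_shape)) 1 else
    discrete_gamma_rates(mod$gamma_shape, mod$categories)
  if (!is.null(seed)) set.seed(seed)
  site_cat <- sample.int(length(rates), length, replace = TRUE)
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(4L, length, replace = TRUE, prob = freq)
  tree_cw <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(tree_cw$edge))) {
    parent <- tree_cw$edge[k, 1]; child <- tree_cw$edge[k, 2]
    t_edge <- tree_cw$edge.length[k]
    parent_seq <- seqs[[parent]]
    child_seq <- integer(length)
    for (c_idx in seq_along(rates)) {
      P <- transition_probabilities(Q, freq, t_edge * rates[c_idx])
      for (s in 1:4) {
        idx <- which(parent_seq == s & site_cat == c_idx)
        if (length(idx))
          child_seq[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                       prob = P[s, ])
      }
    }
    seqs[[child]] <- child_seq
  }
  out <- do.call(rbind, lapply(seqs[seq_len(n_tip)],
                               function(s) DNA_BASES[s]))
  rownames(out) <- tree$tip.label
  attr(out, "seed") <- seed
  out
}

#' Ready-made three-species barcoding scenario
#'
#' Builds the simulation scenario used throughout the package's
#' molecular tests: three ingroup species — two close congeners at a
#' between-species divergence of about 0.103 substitutions/site and a
#' third species of a different genus at about 0.40 from both — plus a
#' single outgroup taxon, with small within-species divergence (0.005)
#' and a COI-like substitution model (transition-biased TN93, discrete
#' gamma shape 0.4292 with 5 categories, AT-rich base composition).
#' Species sample sizes are 2, 4 and 6 taxa.
#'
#' @param seed optional seed forwarded to [simulate_alignment()] by the
#'   caller; stored in the returned config.
#' @return List with elements `tree` (true `phylo`), `species_map`,
#'   `outgroup`, `model`, `length` (600) and `seed`.
#' @export
kor_scenario <- function(seed = NULL) {
  tips <- list(linea = paste0("linea_", 1:2),
               persa = paste0("persa_", 1:4),
               tongiorgii = paste0("tongiorgii_", 1:6))
  crown <- function(ids) paste0("(", paste0(ids, ":0.0025", collapse = ","), ")")
  nwk <- sprintf("((%s:0.25,(%s:0.049,%s:0.049):0.096):0.05,outgroup_1:0.25);",
                 crown(tips$linea), crown(tips$persa), crown(tips$tongiorgii))
  map <- c(setNames(rep("Cobitis linea", 2), tips$linea),
           setNames(rep("Oxynoemacheilus persa", 4), tips$persa),
           setNames(rep("Oxynoemacheilus tongiorgii", 6), tips$tongiorgii),
           outgroup_1 = "Misgurnus")
  list(tree = ape::read.tree(text = nwk),
       species_map = map,
       outgroup = "outgroup_1",
       model = list(freq = c(A = 0.25, C = 0.27, G = 0.18, T = 0.30),
                    kappa1 = 8, kappa2 = 8,
                    gamma_shape = 0.4292, categories = 5),
       length = 600,
       seed = seed)
}
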