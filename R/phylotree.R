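#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (with the Studier-Keppler Q criterion) on a
#' symmetric distance matrix. On an additive matrix the tree is exact:
#' leaf-to-leaf path lengths reproduce the input distances. Negative
#' branch-length estimates are clamped to zero with the deficit moved to
#' the sister branch, so the joined pair's path length is preserved; ties
#' in the Q criterion are broken by the lowest (i, j) index pair, making
#' the result deterministic on degenerate inputs.
#'
#' @param d symmetric numeric matrix with taxon ids as dimnames (e.g. a
#'   `pairwise_dist`); no `NA` cells allowed.
#' @return An unrooted `phylo` tree (trifurcating root record; for 2
#'   taxa, the single split).
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = rep(list(c("A", "B", "C")), 2))
#' nj_tree(d)  # terminal branches 0.05, 0.15, 0.25
#' @export
nj_tree <- function(d) {
  d <- unclass(as.matrix(d))
  ids <- rownames(d)
  n <- nrow(d)
  if (is.null(ids) || is.null(colnames(d))) stop("d must have taxon dimnames")
  if (n < 2L) stop("need at least 2 taxa")
  if (anyNA(d)) {
    und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("distance matrix has undefined cells: ",
         paste(ids[und[, 1]], ids[und[, 2]], sep = "~", collapse = ", "))
  }
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  lab <- vapply(ids, quote_nwk_label, "")
  if (n == 2L) {
    half <- d[1, 2] / 2
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);", lab[1], fmt_bl(half),
                                         lab[2], fmt_bl(half))))
  }
  while (n > 3L) {
    r <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      q <- (n - 2) * d[i, j] - r[i] - r[j]
      if (q < best_q) { best_q <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    new_lab <- sprintf("(%s:%s,%s:%s)", lab[i], fmt_bl(vi), lab[j], fmt_bl(vj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    lab <- c(lab[keep], new_lab)
    dimnames(d_new) <- list(seq_len(n - 1L), seq_len(n - 1L))
    d <- d_new
    n <- n - 1L
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 lab[1], fmt_bl(max(v1, 0)), lab[2], fmt_bl(max(v2, 0)),
                 lab[3], fmt_bl(max(v3, 0)))
  ape::read.tree(text = nwk)
}

fmt_bl <- function(x) sprintf("%.12g", x)

quote_nwk_label <- function(x) {
  if (grepl("[,:;()\\[\\]' \t]", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Nonparametric bootstrap over alignment columns: each replicate
#' resamples sites with replacement, recomputes the distance matrix and
#' its NJ tree, and every bipartition of the point-estimate tree is
#' scored with the percentage of replicate trees containing it. Supports
#' are attached to the point-estimate tree (not a consensus) as integer
#' internal-node labels. A replicate whose resampled matrix contains a
#' saturated (undefined) distance is redrawn, up to `max_retries` times.
#'
#' @param aln alignment matrix as in [pairwise_distances()].
#' @param model,deletion,gamma_shape forwarded to [pairwise_distances()].
#' @param replicates number of bootstrap replicates (>= 1); the source
#'   study style is 500.
#' @param seed integer seed making the resampling reproducible.
#' @param max_retries redraw budget per replicate for saturated matrices.
#' @return The point-estimate `phylo` tree with `node.label` set to
#'   bootstrap percentages in [0, 100].
#' @export
bootstrap_support <- function(aln, model = "k2p", replicates = 500, seed = 1,
                              deletion = "pairwise", gamma_shape = NULL,
                              max_retries = 100) {
  if (replicates < 1) stop("replicates must be >= 1")
  aln <- as_alignment_matrix(aln)
  point <- nj_tree(pairwise_distances(aln, model = model, deletion = deletion,
                                      gamma_shape = gamma_shape))
  set.seed(seed)
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    for (try in seq_len(max_retries + 1L)) {
      cols <- sample.int(ncol(aln), replace = TRUE)
      db <- pairwise_distances(aln[, cols, drop = FALSE], model = model,
                               deletion = deletion, gamma_shape = gamma_shape)
      if (!anyNA(db)) break
      if (try > max_retries)
        stop("could not draw a bootstrap replicate without saturated distances")
    }
    reps[[b]] <- nj_tree(db)
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- as.integer(round(100 * counts / replicates))
  point
}

#' Test species monophyly on an outgroup-rooted tree
#'
#' Roots the tree on the given outgroup taxa and asks, for each species,
#' whether the smallest clade containing all its members contains no
#' other leaves. Single-member species are monophyletic by definition.
#'
#' @param tree a `phylo` tree whose tip labels are taxon ids.
#' @param species_map named character vector, taxon id -> species.
#' @param species species labels to test; defaults to every non-outgroup
#'   species present in the tree.
#' @param outgroup character vector of outgroup taxon ids (all must be
#'   tips of `tree`; rooting fails if they are not monophyletic).
#' @return Named logical vector, one element per species tested.
#' @export
is_monophyletic <- function(tree, species_map, species = NULL, outgroup) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  missing_og <- setdiff(outgroup, tree$tip.label)
  if (length(missing_og))
    stop("outgroup taxa not found in tree: ", paste(missing_og, collapse = ", "))
  if (length(outgroup) < length(tree$tip.label) - 1L &&
      length(outgroup) > 1L &&
      !ape::is.monophyletic(tree, outgroup))
    stop("outgroup is not monophyletic; cannot place the root")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  in_tree <- names(species_map)[names(species_map) %in% tree$tip.label]
  if (is.null(species))
    species <- setdiff(unique(unname(species_map[in_tree])),
                       unique(unname(species_map[outgroup[outgroup %in% names(species_map)]])))
  out <- logical(length(species)); names(out) <- species
  for (s in species) {
    tips <- in_tree[species_map[in_tree] == s]
    if (length(tips) == 0L) stop("species has no leaves in the tree: ", s)
    out[s] <- if (length(tips) == 1L) TRUE else ape::is.monophyletic(rooted, tips)
  }
  out
}
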