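# Shared fixtures and small independent oracles used across test files.

fixture_path <- function(name) {
  system.file("extdata", name, package = "karyobarcode")
}

linea_table <- function() read_measurements(fixture_path("cobitis_linea.tsv"))

# Four 20-mers with hand-countable differences:
#   s1~s2: two transitions (A>G, C>T); s1~s3: one transversion (A>C);
#   s2~s3: one transition + one transversion; s4 = s1 with a gap at site 2.
toy_alignment <- function() {
  rbind(
    s1 = strsplit("AAAAAAAAAACCCCCCCCCC", "")[[1]],
    s2 = strsplit("GAAAAAAAAACCCCCCCCCT", "")[[1]],
    s3 = strsplit("CAAAAAAAAACCCCCCCCCC", "")[[1]],
    s4 = strsplit("A-AAAAAAAACCCCCCCCCC", "")[[1]]
  )
}

# Closed-form K2P evaluated directly from P and Q, independent of the
# package's neg_log plumbing.
k2p_closed_form <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# Random additive matrix from a random topology on n taxa.
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Brute-force enumeration of all labelled unrooted binary topologies on
# 4 or 5 taxa, from their closed-form shapes: every 4-taxon tree is one
# split pair|pair (3 trees), every 5-taxon tree is two cherries plus a
# middle taxon (15 trees).
all_unrooted_topologies <- function(taxa) {
  n <- length(taxa)
  trees <- list()
  if (n == 4) {
    for (j in 2:4) {
      pair <- c(taxa[1], taxa[j]); rest <- setdiff(taxa, pair)
      trees <- c(trees, list(ape::read.tree(text = sprintf(
        "((%s,%s),%s,%s);", pair[1], pair[2], rest[1], rest[2]))))
    }
  } else if (n == 5) {
    seen <- character(0)
    for (p1 in utils::combn(taxa, 2, simplify = FALSE)) {
      rest <- setdiff(taxa, p1)
      for (p2 in utils::combn(rest, 2, simplify = FALSE)) {
        mid <- setdiff(rest, p2)
        key <- paste(sort(c(paste(sort(p1), collapse = ","),
                            paste(sort(p2), collapse = ","))), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        trees <- c(trees, list(ape::read.tree(text = sprintf(
          "((%s,%s),%s,(%s,%s));", p1[1], p1[2], mid, p2[1], p2[2]))))
      }
    }
  } else stop("only 4 or 5 taxa supported")
  trees
}

# Small rooted test trees for monophyly checks.
tree_good <- function() ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1,O:2);")
tree_mixed <- function() ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1,O:2);")
ab_map <- function() c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", O = "out")
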