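#' Site-pattern counts for a pair of aligned sequences
#'
#' Tallies transition and transversion differences between two equal
#' length nucleotide sequences. Transitions are A<->G (purine, counted in
#' `P1`) and C<->T (pyrimidine, `P2`); all other mismatches are
#' transversions. Sites carrying a gap (`-`) or ambiguity (`N`; any
#' non-ACGT symbol is treated as `N`) in either sequence are excluded
#' under pairwise deletion; under complete deletion the caller is
#' expected to have masked such sites alignment-wide first (see
#' [pairwise_distances()]).
#'
#' @param a,b character vectors of single upper-case bases (or length-1
#'   strings, which are split), equal length.
#' @return A list of class `site_counts`: `L` compared sites, `P1`, `P2`
#'   purine/pyrimidine transition proportions, `P = P1 + P2`, `Q`
#'   transversion proportion, and `freq`, the base frequencies pooled
#'   over both sequences at compared sites.
#' @examples
#' site_pattern_counts("ACGT", "GCGT")  # P = 0.25, Q = 0, L = 4
#' @export
site_pattern_counts <- function(a, b) {
  a <- as_base_vector(a)
  b <- as_base_vector(b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L == 0L) stop("no overlapping ungapped sites between the sequences")
  ts_pur <- sum((a == "A" & b == "G") | (a == "G" & b == "A"))
  ts_pyr <- sum((a == "C" & b == "T") | (a == "T" & b == "C"))
  diff <- sum(a != b)
  tv <- diff - ts_pur - ts_pyr
  freq <- (tabulate(factor(a, DNA_BASES), 4) +
           tabulate(factor(b, DNA_BASES), 4)) / (2 * L)
  names(freq) <- DNA_BASES
  structure(list(L = L, P1 = ts_pur / L, P2 = ts_pyr / L,
                 P = (ts_pur + ts_pyr) / L, Q = tv / L, freq = freq),
            class = "site_counts")
}

DNA_BASES <- c("A", "C", "G", "T")

as_base_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  x <- toupper(as.character(x))
  x[!(x %in% c(DNA_BASES, "-"))] <- "N"   # any ambiguity code counts as N
  x
}

#' Kimura two-parameter distance
#'
#' Evaluates \deqn{d = -\tfrac12 \ln\{(1-2P-Q)\sqrt{1-2Q}\}} from the
#' transition proportion P and transversion proportion Q, optionally with
#' a gamma rate-heterogeneity correction in which each logarithm
#' \eqn{-\ln x} is replaced by \eqn{\alpha(x^{-1/\alpha}-1)}. Pairs
#' outside the logarithm domain (saturation) yield `NA` rather than an
#' error so that whole matrices degrade gracefully.
#'
#' @param counts a `site_counts` object, or a list with elements `P` and
#'   `Q`.
#' @param gamma_shape optional gamma shape \eqn{\alpha > 0}; `NULL`
#'   (default) applies no rate-heterogeneity correction.
#' @return Distance in substitutions/site, or `NA_real_` if saturated.
#' @examples
#' k2p_distance(list(P = 0.1, Q = 0.05))  # ~0.1702
#' @export
k2p_distance <- function(counts, gamma_shape = NULL) {
  P <- counts$P; Q <- counts$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  0.5 * neg_log(w1, gamma_shape) + 0.25 * neg_log(w2, gamma_shape)
}

# -log(x), or its discrete-gamma analogue alpha*(x^(-1/alpha) - 1)
neg_log <- function(x, gamma_shape = NULL) {
  if (is.null(gamma_shape)) return(-log(x))
  if (!is.numeric(gamma_shape) || gamma_shape <= 0)
    stop("gamma_shape must be > 0")
  gamma_shape * (x^(-1 / gamma_shape) - 1)
}

#' Tamura-Nei (TN93) distance
#'
#' Closed-form TN93 distance distinguishing purine (`P1`) and pyrimidine
#' (`P2`) transitions with unequal base frequencies. With uniform
#' frequencies and `P1 = P2` it reduces to the Kimura two-parameter
#' distance. The optional gamma correction replaces each logarithm as in
#' [k2p_distance()].
#'
#' @param counts a `site_counts` object (carries `P1`, `P2`, `Q` and the
#'   empirical base frequencies of the pair).
#' @param freq optional base frequencies (names A, C, G, T, summing to
#'   1); defaults to the frequencies stored in `counts`.
#' @param gamma_shape optional gamma shape.
#' @return Distance in substitutions/site, or `NA_real_` if saturated or
#'   if a frequency class is empty.
#' @export
tn93_distance <- function(counts, freq = NULL, gamma_shape = NULL) {
  if (is.null(freq)) freq <- counts$freq
  if (abs(sum(freq) - 1) > 1e-9) stop("base frequencies must sum to 1")
  piA <- freq[["A"]]; piC <- freq[["C"]]; piG <- freq[["G"]]; piT <- freq[["T"]]
  piR <- piA + piG; piY <- piC + piT
  if (piA * piG == 0 || piC * piT == 0 || piR * piY == 0) return(NA_real_)
  k1 <- 2 * piA * piG / piR
  k2 <- 2 * piC * piT / piY
  k3 <- 2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY)
  w1 <- 1 - counts$P1 / k1 - counts$Q / (2 * piR)
  w2 <- 1 - counts$P2 / k2 - counts$Q / (2 * piY)
  w3 <- 1 - counts$Q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  k1 * neg_log(w1, gamma_shape) + k2 * neg_log(w2, gamma_shape) +
    k3 * neg_log(w3, gamma_shape)
}

#' Pairwise distance matrix of an alignment
#'
#' Computes all pairwise distances of an aligned set of sequences under
#' the chosen model. Saturated pairs are flagged, not errors: their
#' cells are `NA` and listed in the `undefined` attribute.
#'
#' @param aln an alignment: character matrix (taxa x sites, rownames =
#'   taxon ids) as returned by [read_fasta_alignment()] or
#'   [simulate_alignment()].
#' @param model `"k2p"` (default), `"tn93"`, or `"p"` (raw proportion of
#'   differing sites).
#' @param deletion `"pairwise"` (default) drops gap/ambiguity sites per
#'   pair; `"complete"` drops every column containing a gap or ambiguity
#'   in any sequence before comparison; `"coverage"` drops columns whose
#'   fraction of unambiguous bases falls below `coverage`.
#' @param coverage minimum site coverage for `deletion = "coverage"`
#'   (default 0.95).
#' @param gamma_shape optional gamma shape forwarded to the distance.
#' @return A symmetric numeric matrix of class `pairwise_dist` with zero
#'   diagonal, taxon ids as dimnames, and attributes `model` and
#'   `undefined` (two-column matrix of flagged taxon pairs).
#' @export
pairwise_distances <- function(aln, model = c("k2p", "tn93", "p"),
                               deletion = c("pairwise", "complete", "coverage"),
                               coverage = 0.95, gamma_shape = NULL) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  aln <- as_alignment_matrix(aln)
  n <- nrow(aln)
  if (n < 2L) stop("alignment must contain at least 2 taxa")
  good <- matrix(aln %in% DNA_BASES, nrow = n)
  if (deletion == "complete") {
    aln <- aln[, colSums(good) == n, drop = FALSE]
  } else if (deletion == "coverage") {
    aln <- aln[, colMeans(good) >= coverage, drop = FALSE]
  }
  if (ncol(aln) == 0L) stop("no columns left after site filtering")
  ids <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  undef <- NULL
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    # a pair with no overlapping ungapped sites is flagged, not fatal
    cnt <- tryCatch(site_pattern_counts(aln[i, ], aln[j, ]),
                    error = function(e) NULL)
    val <- if (is.null(cnt)) NA_real_ else switch(model,
      p = cnt$P + cnt$Q,
      k2p = k2p_distance(cnt, gamma_shape),
      tn93 = tn93_distance(cnt, gamma_shape = gamma_shape))
    if (is.na(val)) undef <- rbind(undef, c(ids[i], ids[j]))
    d[i, j] <- d[j, i] <- val
  }
  structure(d, class = c("pairwise_dist", "matrix"), model = model,
            undefined = undef)
}

as_alignment_matrix <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- toupper(as.character(aln))
  if (is.list(aln) && !is.data.frame(aln)) {
    lens <- lengths(lapply(aln, as_base_vector))
    if (length(unique(lens)) != 1L) stop("sequences are not all the same length")
    aln <- do.call(rbind, lapply(aln, as_base_vector))
  }
  if (!is.matrix(aln)) stop("aln must be a character matrix or DNAbin")
  if (is.null(rownames(aln))) stop("alignment rows must be named by taxon id")
  if (anyDuplicated(rownames(aln))) stop("duplicate taxon ids in alignment")
  toupper(aln)
}

#' Between-species mean distances
#'
#' Summarizes a pairwise taxon distance matrix at the species level: each
#' off-diagonal cell is the arithmetic mean distance over every pair of
#' taxa crossing the two species, the conventional between-group summary
#' of barcoding studies; the diagonal holds the within-species mean (NA
#' for single-member species).
#'
#' @param d a `pairwise_dist` (or plain symmetric) matrix.
#' @param species_map named character vector mapping taxon id -> species.
#' @param percent report distances multiplied by 100.
#' @return Symmetric species x species matrix.
#' @examples
#' d <- matrix(c(0, .1, .3, .1, 0, .3, .3, .3, 0), 3,
#'             dimnames = rep(list(c("a1", "a2", "b1")), 2))
#' group_mean_distance(d, c(a1 = "A", a2 = "A", b1 = "B"))
#' @export
group_mean_distance <- function(d, species_map, percent = FALSE) {
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must carry taxon ids as dimnames")
  missing_ids <- setdiff(ids, names(species_map))
  if (length(missing_ids))
    stop("taxa absent from species map: ", paste(missing_ids, collapse = ", "))
  sp <- species_map[ids]
  species <- unique(unname(sp))
  k <- length(species)
  out <- matrix(NA_real_, k, k, dimnames = list(species, species))
  for (i in seq_len(k)) for (j in i:k) {
    rows <- which(sp == species[i]); cols <- which(sp == species[j])
    if (i == j) {
      if (length(rows) > 1L) {
        prs <- utils::combn(rows, 2)
        out[i, i] <- mean(d[cbind(prs[1, ], prs[2, ])])
      }
    } else {
      cells <- d[rows, cols, drop = FALSE]
      if (anyNA(cells)) {
        bad <- which(is.na(cells), arr.ind = TRUE)
        stop("undefined distance between taxa: ",
             paste(ids[rows][bad[, 1]], ids[cols][bad[, 2]],
                   sep = "~", collapse = ", "))
      }
      out[i, j] <- out[j, i] <- mean(cells)
    }
  }
  if (percent) out <- out * 100
  out
}
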