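#' Per-chromosome metrics from arm measurements
#'
#' Computes total length, arm ratio and centromeric index for each
#' chromosome pair from its long- and short-arm lengths.
#'
#' The arm ratio is \eqn{r = LA/SA} and the centromeric index
#' \eqn{CI = SA/(LA+SA)}, so the two are tied by the identity
#' \eqn{CI = 1/(1+r)}. Values are kept at full precision; rounding (2
#' decimals, half-up) happens only in reporting functions.
#'
#' @param long_arm numeric vector of long-arm lengths (µm).
#' @param short_arm numeric vector of short-arm lengths (µm), same length.
#' @param pair_id optional integer identifiers used in error messages and
#'   carried into the result; defaults to `1:n`.
#' @return A data frame with columns `pair_id`, `long_arm`, `short_arm`,
#'   `total_len`, `arm_ratio`, `centromeric_index`.
#' @examples
#' chromosome_metrics(6.53, 2.69)  # arm ratio 2.43, CI 0.29 at 2 dp
#' @export
chromosome_metrics <- function(long_arm, short_arm, pair_id = NULL) {
  long_arm <- as.numeric(long_arm)
  short_arm <- as.numeric(short_arm)
  if (length(long_arm) != length(short_arm))
    stop("long_arm and short_arm must have the same length")
  if (length(long_arm) == 0L) stop("no measurements supplied")
  if (is.null(pair_id)) pair_id <- seq_along(long_arm)
  bad <- !is.finite(short_arm) | short_arm <= 0
  if (any(bad))
    stop("short_arm must be > 0; offending pair_id: ",
         paste(pair_id[bad], collapse = ", "))
  bad <- !is.finite(long_arm) | long_arm < short_arm
  if (any(bad))
    stop("long_arm must be >= short_arm; offending pair_id: ",
         paste(pair_id[bad], collapse = ", "))
  total <- long_arm + short_arm
  data.frame(
    pair_id = pair_id,
    long_arm = long_arm,
    short_arm = short_arm,
    total_len = total,
    arm_ratio = long_arm / short_arm,
    centromeric_index = short_arm / total
  )
}

#' Chromosome morphology from the arm ratio
#'
#' Assigns each arm ratio to a morphology class using fixed intervals in
#' the Levan tradition: metacentric (`m`) for \eqn{1 \le r \le 1.7},
#' submetacentric (`sm`) for \eqn{1.7 < r \le 3}, subtelocentric (`st`)
#' for \eqn{3 < r \le 7} and telocentric/acrocentric (`t`) for
#' \eqn{r > 7}. Boundary values fall in the lower (more metacentric)
#' class.
#'
#' @param arm_ratio numeric vector of arm ratios, each >= 1.
#' @return Factor with levels `m`, `sm`, `st`, `t`.
#' @examples
#' classify_morphology(c(1, 1.69, 2.43, 3.41, 8))
#' @export
classify_morphology <- function(arm_ratio) {
  arm_ratio <- as.numeric(arm_ratio)
  if (any(!is.finite(arm_ratio) | arm_ratio < 1))
    stop("arm_ratio must be finite and >= 1")
  cls <- cut(arm_ratio, breaks = c(1, 1.7, 3, 7, Inf),
             labels = c("m", "sm", "st", "t"),
             include.lowest = TRUE, right = TRUE)
  factor(as.character(cls), levels = morph_classes())
}

morph_classes <- function() c("m", "sm", "st", "t")

#' Fundamental number (NF) of a karyotype
#'
#' The fundamental number counts chromosome arms over the diploid
#' complement: bi-armed chromosomes (metacentric and submetacentric)
#' contribute two arms each, subtelocentric and telocentric chromosomes
#' one arm each, i.e. \eqn{NF = 2(m + sm) + (st + t)} on chromosome
#' counts.
#'
#' @param class_counts named numeric vector or list with (a subset of)
#'   names `m`, `sm`, `st`, `t`, giving chromosome counts (not pair
#'   counts). Counts must be even and nonnegative.
#' @return Integer fundamental number.
#' @examples
#' fundamental_number(c(m = 4, sm = 40, st = 6))  # 94
#' fundamental_number(c(m = 18, sm = 24, st = 8)) # 92
#' @export
fundamental_number <- function(class_counts) {
  counts <- normalize_class_counts(class_counts)
  as.integer(2L * (counts[["m"]] + counts[["sm"]]) +
             counts[["st"]] + counts[["t"]])
}

normalize_class_counts <- function(class_counts) {
  counts <- unlist(class_counts)
  if (is.null(names(counts)) || !all(names(counts) %in% morph_classes()))
    stop("class_counts must be named with classes among: ",
         paste(morph_classes(), collapse = ", "))
  full <- setNames(rep(0, 4), morph_classes())
  full[names(counts)] <- counts
  if (any(full < 0) || any(full != round(full)))
    stop("class counts must be nonnegative integers")
  if (any(full %% 2 != 0))
    stop("chromosome counts must be even (chromosomes come in pairs): ",
         paste(names(full)[full %% 2 != 0], collapse = ", "))
  full
}

#' Canonical karyotype formula string
#'
#' @param class_counts named chromosome counts as in
#'   [fundamental_number()].
#' @return A string such as `"4m+40sm+6st"`; zero-count classes are
#'   omitted and classes appear in the fixed order m, sm, st, t.
#' @export
karyotype_formula <- function(class_counts) {
  counts <- normalize_class_counts(class_counts)
  keep <- counts > 0
  if (!any(keep)) return("")
  paste0(counts[keep], names(counts)[keep], collapse = "+")
}

#' Summarize a karyotype from arm measurements
#'
#' The central constructor of the cytogenetic track: takes one
#' measurement per chromosome pair, derives metrics and morphology
#' classes, and returns the species karyotype summary (2n, class counts,
#' formula, fundamental number).
#'
#' @param x a data frame with columns `pair_id`, `long_arm`, `short_arm`
#'   (as returned by [read_measurements()]; may also carry `printed_ar`,
#'   `printed_ci`, `printed_ct` columns).
#' @param species_label character label for the species or population.
#' @param use_printed_ar if `TRUE` and `x` has a `printed_ar` column,
#'   classification uses the published arm-ratio values instead of ratios
#'   recomputed from the arm lengths. Published tables round to 2
#'   decimals and occasionally contain internally inconsistent rows, so
#'   reproducing a published karyotype formula exactly may require the
#'   printed column.
#' @return An object of class `karyotype`: a list with elements
#'   `species_label`, `metrics` (per-pair data frame including
#'   `morph_class`), `n_pairs`, `diploid_number`, `class_counts`
#'   (chromosome counts), `formula` and `fundamental_number`.
#' @examples
#' tab <- read_measurements(system.file("extdata", "cobitis_linea.tsv",
#'                                      package = "karyobarcode"))
#' karyotype(tab, "Cobitis linea", use_printed_ar = TRUE)
#' @export
karyotype <- function(x, species_label = "unknown", use_printed_ar = FALSE) {
  if (!is.data.frame(x) || nrow(x) == 0L)
    stop("x must be a nonempty data frame of arm measurements")
  req <- c("pair_id", "long_arm", "short_arm")
  if (!all(req %in% names(x)))
    stop("x must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(x$pair_id))
    stop("pair_id values must be unique")
  metrics <- chromosome_metrics(x$long_arm, x$short_arm, x$pair_id)
  ar_for_class <- if (use_printed_ar) {
    if (is.null(x$printed_ar))
      stop("use_printed_ar = TRUE but x has no printed_ar column")
    as.numeric(x$printed_ar)
  } else {
    metrics$arm_ratio
  }
  metrics$morph_class <- classify_morphology(ar_for_class)
  pair_counts <- table(metrics$morph_class)
  counts <- setNames(2L * as.integer(pair_counts), names(pair_counts))
  structure(list(
    species_label = species_label,
    metrics = metrics,
    n_pairs = nrow(metrics),
    diploid_number = 2L * nrow(metrics),
    class_counts = normalize_class_counts(counts),
    formula = karyotype_formula(counts),
    fundamental_number = fundamental_number(counts),
    classified_from = if (use_printed_ar) "printed_ar" else "arm_lengths"
  ), class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat("Karyotype of", x$species_label, "\n")
  cat("  chromosome pairs:", x$n_pairs, "  2n =", x$diploid_number, "\n")
  cat("  formula:", x$formula, "   NF =", x$fundamental_number, "\n")
  cat("  classified from:", x$classified_from, "\n")
  invisible(x)
}

#' @export
summary.karyotype <- function(object, digits = 2, ...) {
  m <- object$metrics
  out <- data.frame(
    pair_id = m$pair_id,
    long_arm = round_half_up(m$long_arm, digits),
    short_arm = round_half_up(m$short_arm, digits),
    total_len = round_half_up(m$total_len, digits),
    arm_ratio = round_half_up(m$arm_ratio, digits),
    centromeric_index = round_half_up(m$centromeric_index, digits),
    morph_class = m$morph_class
  )
  structure(list(species_label = object$species_label, table = out,
                 diploid_number = object$diploid_number,
                 formula = object$formula,
                 fundamental_number = object$fundamental_number),
            class = "summary.karyotype")
}

#' @export
print.summary.karyotype <- function(x, ...) {
  cat("Karyotype of", x$species_label, ":",
      paste0("2n=", x$diploid_number), x$formula,
      paste0("NF=", x$fundamental_number), "\n\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Half-up decimal rounding, matching the presentation convention of
# cytogenetic tables (2.425 -> 2.43). A tiny relative nudge guards
# against binary representations falling just under the .5 boundary.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
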