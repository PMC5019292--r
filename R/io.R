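#' Read a per-chromosome arm-measurement table
#'
#' Reads a TSV/CSV table with one row per chromosome pair. Required
#' columns: `pair_id`, `long_arm`, `short_arm`; optional columns
#' `printed_ar`, `printed_ci`, `printed_ct` (and `printed_ta`) carry the
#' values of a published table alongside the raw measurements. A header
#' row is required and the decimal mark is ".". No cleaning is applied:
#' the bundled fixtures were cleaned at transcription time and every
#' edit is listed in the fixtures' PROVENANCE file.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param sep optional field separator.
#' @return Data frame of validated measurements.
#' @export
read_measurements <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("malformed measurement table (", path, "): ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty measurement table: ", path)
  req <- c("pair_id", "long_arm", "short_arm")
  if (!all(req %in% names(tab)))
    stop("header must contain columns: ", paste(req, collapse = ", "))
  for (col in req) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop("non-numeric ", col, " at data line(s): ",
           paste(bad + 1L, collapse = ", "))
    tab[[col]] <- vals
  }
  # chromosome_metrics re-validates; errors here carry the pair_id
  invisible(chromosome_metrics(tab$long_arm, tab$short_arm, tab$pair_id))
  if ("printed_ct" %in% names(tab))
    tab$printed_ct <- factor(tolower(tab$printed_ct), morph_classes())
  tab
}

#' Read / write an aligned FASTA file
#'
#' `read_fasta_alignment` returns the alignment as an upper-case
#' character matrix (taxa x sites); all sequences must have equal
#' length and unique ids. `write_fasta` writes sequences wrapped at 70
#' columns; writing then reading reproduces ids and sequences exactly.
#'
#' @param path file path.
#' @return For the reader, a character matrix with taxon ids as
#'   rownames.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in FASTA file: ", path)
  if (anyDuplicated(names(dna)))
    stop("duplicate taxon ids in FASTA: ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "))
  if (length(unique(lengths(dna))) != 1L)
    stop("sequences are not aligned (unequal lengths) in: ", path)
  as_alignment_matrix(lapply(as.character(dna), toupper))
}

#' @rdname read_fasta_alignment
#' @param aln character matrix of bases (taxa x sites).
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(aln, path, width = 70) {
  aln <- as_alignment_matrix(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in rownames(aln)) {
    s <- paste(aln[id, ], collapse = "")
    writeLines(paste0(">", id), con)
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a taxon-to-species map
#'
#' Two-column TSV (`taxon_id`, `species`), with or without a header.
#'
#' @param path file path.
#' @param taxa optional character vector of taxon ids the map must
#'   cover exactly; unmatched taxa on either side raise an error.
#' @return Named character vector taxon id -> species.
#' @export
read_species_map <- function(path, taxa = NULL) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("species map must have two tab-separated columns")
  if (identical(tolower(raw[1, 1]), "taxon_id")) raw <- raw[-1, , drop = FALSE]
  map <- setNames(as.character(raw[[2]]), as.character(raw[[1]]))
  if (anyDuplicated(names(map)))
    stop("duplicate taxon ids in species map")
  if (!is.null(taxa)) {
    unmatched <- c(setdiff(taxa, names(map)), setdiff(names(map), taxa))
    if (length(unmatched))
      stop("species map and alignment do not match; unmatched taxa: ",
           paste(unique(unmatched), collapse = ", "))
  }
  map
}

#' @rdname read_species_map
#' @param map named character vector.
#' @export
write_species_map <- function(map, path) {
  utils::write.table(data.frame(taxon_id = names(map), species = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a PHYLIP square distance matrix
#'
#' Standard square PHYLIP format: a line with the number of taxa, then
#' one line per taxon with its id followed by the full row of distances.
#'
#' @param d symmetric matrix with taxon dimnames.
#' @param path file path.
#' @export
write_phylip_dist <- function(d, path) {
  d <- unclass(as.matrix(d))
  ids <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(formatC(ids[i], width = -10),
                       sprintf("%.8f", d[i, ])), collapse = "  "), con)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP matrix: ", path)
  ids <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    ids[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1][seq_len(n)])
  }
  dimnames(d) <- list(ids, ids)
  d
}

#' Thin newick wrappers
#'
#' Convenience wrappers around \pkg{ape}'s newick reader/writer so trees
#' with branch lengths and integer internal-node supports round-trip
#' losslessly.
#'
#' @param path file path.
#' @return `read_newick` returns a `phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write the karyotype report files
#'
#' Emits the per-chromosome metrics as TSV (2-decimal, half-up rounding,
#' matching the presentation of published tables) and the summary (2n,
#' class counts, formula, NF) as JSON.
#'
#' @param k a `karyotype` object.
#' @param dir output directory (created if needed).
#' @param name file stem; defaults to a slug of the species label.
#' @return Invisibly, the paths written.
#' @export
write_karyotype_report <- function(k, dir, name = NULL) {
  if (!inherits(k, "karyotype")) stop("k must be a karyotype object")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(name)) name <- gsub("[^A-Za-z0-9]+", "_", k$species_label)
  tsv <- file.path(dir, paste0(name, "_metrics.tsv"))
  json <- file.path(dir, paste0(name, "_summary.json"))
  utils::write.table(summary(k)$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    species_label = k$species_label,
    n_pairs = k$n_pairs,
    diploid_number = k$diploid_number,
    class_counts = as.list(k$class_counts),
    formula = k$formula,
    fundamental_number = k$fundamental_number,
    classified_from = k$classified_from
  ), json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(metrics = tsv, summary = json))
}

#' Read a YAML run configuration
#'
#' Shared configuration for the command-line entry point and reporting
#' functions (model choice, deletion policy, bootstrap replicates, seed,
#' idiogram style overrides). Flags given on the command line override
#' config values.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
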