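# Sequence-compositional feature encoding.
#
# Six blocks, concatenated in declared order:
#   aac            20    amino-acid frequencies
#   dpc           400    overlapping dipeptide frequencies
#   tpc          8000    overlapping tripeptide frequencies
#   multiplet      20    per-residue fraction lying in homopolymer runs >= 2
#   charge          2    fractions of positively / negatively charged residues
#   hydrophobicity  2    fractions of hydrophobic / non-hydrophobic residues
#
# Non-canonical residues (X and anything outside the 20-letter alphabet) fall
# into no bin but remain in every denominator, so vectors stay comparable
# across sequences with rare ambiguity.

BLOCK_WIDTHS <- c(aac = 20L, dpc = 400L, tpc = 8000L, multiplet = 20L,
                  charge = 2L, hydrophobicity = 2L)

#' Configure the feature encoding
#'
#' The residue sets below are the package's working definitions: charged sets
#' \{K,R,H\} / \{D,E\} and the Kyte-Doolittle-positive hydrophobic set
#' \{A,C,F,I,L,M,V\}. All are overridable so alternative definitions can be
#' tested.
#'
#' @param blocks ordered subset of
#'   `c("aac","dpc","tpc","multiplet","charge","hydrophobicity")`.
#' @param positive_set,negative_set charged residue sets (must be disjoint).
#' @param hydrophobic_set hydrophobic residue set.
#' @param min_length minimum protein length accepted by [encode_protein]
#'   (default 50; tripeptide statistics are meaningless on short fragments).
#' @return An object of class `encoding_config`.
#' @export
encoding_config <- function(blocks = names(BLOCK_WIDTHS),
                            positive_set = c("K", "R", "H"),
                            negative_set = c("D", "E"),
                            hydrophobic_set = c("A", "C", "F", "I", "L", "M", "V"),
                            min_length = 50L) {
  blocks <- match.arg(blocks, names(BLOCK_WIDTHS), several.ok = TRUE)
  if (!length(blocks)) stop("at least one feature block is required")
  if (length(intersect(positive_set, negative_set))) {
    stop("positive_set and negative_set must be disjoint")
  }
  stopifnot(all(positive_set %in% CANONICAL_AA),
            all(negative_set %in% CANONICAL_AA),
            all(hydrophobic_set %in% CANONICAL_AA),
            min_length >= 1L)
  cfg <- list(blocks = blocks,
              positive_set = sort(positive_set),
              negative_set = sort(negative_set),
              hydrophobic_set = sort(hydrophobic_set),
              min_length = as.integer(min_length))
  class(cfg) <- "encoding_config"
  cfg
}

#' Fingerprint of an encoding configuration
#'
#' A canonical JSON rendering of the configuration; two configs encode
#' identically iff their fingerprints are equal. Stored in trained models and
#' checked at prediction and load time.
#' @param config an [encoding_config].
#' @return character scalar.
#' @export
encoding_fingerprint <- function(config) {
  stopifnot(inherits(config, "encoding_config"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
}

#' @export
print.encoding_config <- function(x, ...) {
  cat("<encoding_config> blocks:", paste(x$blocks, collapse = "+"),
      sprintf("(width %d), min_length %d\n",
              sum(BLOCK_WIDTHS[x$blocks]), x$min_length))
  invisible(x)
}

# residue indices 1..20 over the canonical alphabet, NA for non-canonical
aa_indices <- function(protein) {
  match(strsplit(protein, "")[[1]], CANONICAL_AA)
}

#' Amino-acid composition
#'
#' Count of each canonical residue divided by sequence length. Non-canonical
#' residues contribute to no bin but stay in the denominator.
#' @param protein protein string (length >= 1).
#' @return named 20-vector.
#' @export
aa_composition <- function(protein) {
  idx <- aa_indices(protein)
  n <- length(idx)
  if (n == 0L) stop("empty sequence")
  setNames(tabulate(idx, 20L) / n, CANONICAL_AA)
}

kmer_labels <- function(k) {
  grids <- rev(rep(list(CANONICAL_AA), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' k-mer (dipeptide / tripeptide) composition
#'
#' Overlapping k-mer counts divided by the number of windows
#' (`length - k + 1`), bins in lexicographic order of the canonical alphabet.
#' Windows containing a non-canonical residue contribute to no bin but remain
#' in the denominator.
#' @param protein protein string of length >= k.
#' @param k window size, 2 or 3.
#' @return named `20^k`-vector.
#' @export
kmer_composition <- function(protein, k) {
  stopifnot(k %in% c(2L, 3L))
  idx <- aa_indices(protein)
  n <- length(idx)
  if (n < k) stop("sequence shorter than k = ", k)
  nwin <- n - k + 1L
  code <- idx[seq_len(nwin)] - 1L
  for (j in seq_len(k - 1L)) {
    code <- code * 20L + (idx[seq_len(nwin) + j] - 1L)
  }
  counts <- tabulate(code + 1L, 20L^k)  # NA codes (non-canonical) drop out
  setNames(counts / nwin, kmer_labels(k))
}

#' Multiplet composition
#'
#' For each residue type, the number of residues lying inside maximal
#' homopolymer runs of length >= 2 of that type, divided by sequence length.
#' @param protein protein string (length >= 1).
#' @return named 20-vector.
#' @export
multiplet_composition <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence")
  r <- rle(chars)
  keep <- r$lengths >= 2L & r$values %in% CANONICAL_AA
  counts <- setNames(numeric(20L), CANONICAL_AA)
  if (any(keep)) {
    agg <- tapply(r$lengths[keep], r$values[keep], sum)
    counts[names(agg)] <- agg
  }
  counts / n
}

#' Charge composition
#' @param protein protein string (length >= 1).
#' @param positive_set,negative_set charged residue sets.
#' @return 2-vector `(positive fraction, negative fraction)`.
#' @export
charge_composition <- function(protein, positive_set = c("K", "R", "H"),
                               negative_set = c("D", "E")) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence")
  c(positive = sum(chars %in% positive_set) / n,
    negative = sum(chars %in% negative_set) / n)
}

#' Hydrophobicity composition
#' @param protein protein string (length >= 1).
#' @param hydrophobic_set hydrophobic residue set.
#' @return 2-vector: fractions of hydrophobic and of canonical
#'   non-hydrophobic residues.
#' @export
hydrophobicity_composition <- function(protein,
                                       hydrophobic_set = c("A", "C", "F", "I",
                                                           "L", "M", "V")) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty sequence")
  hyd <- sum(chars %in% hydrophobic_set)
  other <- sum(chars %in% setdiff(CANONICAL_AA, hydrophobic_set))
  c(hydrophobic = hyd / n, polar = other / n)
}

#' Block layout for an encoding configuration
#' @param config an [encoding_config].
#' @return data.frame with columns `block`, `offset` (0-based), `width`.
#' @export
encoding_layout <- function(config) {
  w <- BLOCK_WIDTHS[config$blocks]
  data.frame(block = config$blocks,
             offset = cumsum(c(0L, unname(w)))[seq_along(w)],
             width = unname(w))
}

encode_residues <- function(protein, config) {
  parts <- lapply(config$blocks, function(b) {
    switch(b,
      aac = aa_composition(protein),
      dpc = kmer_composition(protein, 2L),
      tpc = kmer_composition(protein, 3L),
      multiplet = multiplet_composition(protein),
      charge = charge_composition(protein, config$positive_set,
                                  config$negative_set),
      hydrophobicity = hydrophobicity_composition(protein,
                                                  config$hydrophobic_set))
  })
  unlist(parts, use.names = FALSE)
}

#' Encode one protein record as a feature vector
#'
#' Concatenates the enabled blocks in declared order. Deterministic, and
#' invariant to the record's description. With the default configuration the
#' vector has width 8444 = 20 + 400 + 8000 + 20 + 2 + 2.
#'
#' @param record a one-row protein [seq_set], or a plain protein string.
#' @param config an [encoding_config].
#' @return numeric vector with attributes `layout` (see [encoding_layout])
#'   and `source_id`.
#' @export
encode_protein <- function(record, config = encoding_config()) {
  if (inherits(record, "seq_set")) {
    stopifnot(nrow(record) == 1L, seq_alphabet(record) == "protein")
    protein <- record$residues
    src <- record$id
  } else {
    protein <- toupper(as.character(record))
    src <- NA_character_
  }
  if (nchar(protein) < config$min_length) {
    stop("sequence ", if (!is.na(src)) src else "", " rejected: length ",
         nchar(protein), " < min_length ", config$min_length)
  }
  v <- encode_residues(protein, config)
  attr(v, "layout") <- encoding_layout(config)
  attr(v, "source_id") <- src
  v
}

#' Encode a protein set as a feature matrix
#'
#' Sequences shorter than `config$min_length` are not encoded; they are
#' reported in the `skipped` component with a reason, never silently dropped.
#'
#' @param x a protein [seq_set].
#' @param config an [encoding_config].
#' @return list with `features` (numeric matrix, rows named by id), `layout`,
#'   and `skipped` (data.frame id, reason).
#' @export
encode_matrix <- function(x, config = encoding_config()) {
  stopifnot(inherits(x, "seq_set"), seq_alphabet(x) == "protein")
  width <- sum(BLOCK_WIDTHS[config$blocks])
  ok <- nchar(x$residues) >= config$min_length
  skipped <- data.frame(id = x$id[!ok],
                        reason = sprintf("length %d < min_length %d",
                                         nchar(x$residues[!ok]),
                                         config$min_length))
  kept <- x[ok, , drop = FALSE]
  m <- matrix(0, nrow = nrow(kept), ncol = width,
              dimnames = list(kept$id, feature_labels(config)))
  for (i in seq_len(nrow(kept))) {
    m[i, ] <- encode_residues(kept$residues[i], config)
  }
  list(features = m, layout = encoding_layout(config), skipped = skipped)
}

feature_labels <- function(config) {
  unlist(lapply(config$blocks, function(b) {
    bins <- switch(b,
      aac = CANONICAL_AA,
      dpc = kmer_labels(2L),
      tpc = kmer_labels(3L),
      multiplet = CANONICAL_AA,
      charge = c("positive", "negative"),
      hydrophobicity = c("hydrophobic", "polar"))
    paste(b, bins, sep = ".")
  }), use.names = FALSE)
}

#' Export a feature matrix as TSV
#' @param features matrix from [encode_matrix]`$features`.
#' @param path output path.
#' @export
write_feature_tsv <- function(features, path) {
  df <- data.frame(seq_id = rownames(features), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
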