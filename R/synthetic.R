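# Synthetic labeled sequence generator.
#
# Each class couples a residue-composition bias (three class-specific
# residues at triple weight) with a planted 10-residue motif inserted three
# times, so both the single-residue and the k-mer feature blocks carry class
# signal — mimicking the way domain-bearing R-proteins combine global
# composition shifts with distinctive local sequence. The negative profile is
# uniform with no motif.

# fixed class profiles: enriched residue triples and motifs are constants
# chosen pairwise-distinct (motif Hamming distance >= 5)
PROFILE_SPEC <- list(
  TNL = list(enriched = c("W", "K", "D"), motif = "WKDLYDWHKD"),
  CNL = list(enriched = c("E", "L", "Q"), motif = "ELQAELQMEL"),
  RLK = list(enriched = c("S", "T", "G"), motif = "STGRSTGYST"),
  RLP = list(enriched = c("N", "I", "P"), motif = "NIPFNIPCNI")
)

#' Default synthetic class profiles
#'
#' Four R-gene class profiles plus a negative profile. Enriched residues get
#' weight 3 (others 1); each class has a distinct 10-residue motif implanted
#' `motif_copies = 3` times. The negative profile is uniform (weight 1/20)
#' with no motif. Profiles are fixed constants; `seed` is accepted for
#' interface symmetry with the samplers and does not alter them.
#'
#' @param seed integer (unused by the profiles themselves).
#' @return named list of profiles; each has `class`, `weights` (named
#'   20-vector summing to 1), `motif`, `motif_copies`, `length_range`.
#' @export
default_profiles <- function(seed = 42L) {
  mk <- function(cl, enriched, motif) {
    w <- setNames(rep(1, 20L), CANONICAL_AA)
    w[enriched] <- 3
    list(class = cl, weights = w / sum(w), motif = motif,
         motif_copies = 3L, length_range = c(150L, 400L))
  }
  profs <- lapply(names(PROFILE_SPEC), function(cl) {
    mk(cl, PROFILE_SPEC[[cl]]$enriched, PROFILE_SPEC[[cl]]$motif)
  })
  names(profs) <- names(PROFILE_SPEC)
  profs$negative <- list(class = "negative",
                         weights = setNames(rep(1 / 20, 20L), CANONICAL_AA),
                         motif = NULL, motif_copies = 0L,
                         length_range = c(150L, 400L))
  profs
}

#' Sample one protein from a class profile
#'
#' Residues are drawn i.i.d. from the profile weights; motif copies are then
#' written over random non-overlapping positions (sequence length is
#' unchanged). Uses the current RNG state; seed externally for
#' reproducibility.
#'
#' @param profile one element of [default_profiles].
#' @param length protein length; must accommodate the motif copies.
#' @param id record id.
#' @return a one-row protein [seq_set]; the description carries the class.
#' @export
sample_protein <- function(profile, length, id = "synthetic") {
  mlen <- if (is.null(profile$motif)) 0L else nchar(profile$motif)
  ncopy <- profile$motif_copies
  if (length < ncopy * mlen) {
    stop("length ", length, " too short for ", ncopy, " motif copies")
  }
  chars <- sample(CANONICAL_AA, length, replace = TRUE,
                  prob = profile$weights)
  if (ncopy > 0L) {
    taken <- integer()
    placed <- 0L
    while (placed < ncopy) {
      pos <- sample.int(length - mlen + 1L, 1L)
      span <- pos:(pos + mlen - 1L)
      if (!any(span %in% taken)) {
        chars[span] <- strsplit(profile$motif, "")[[1]]
        taken <- c(taken, span)
        placed <- placed + 1L
      }
    }
  }
  seq_set(id, paste(chars, collapse = ""),
          description = paste("class", profile$class), alphabet = "protein")
}

#' Generate a labeled synthetic training set
#'
#' @param n_per_class positives per R-gene class (default 100).
#' @param n_negative negatives (default 400).
#' @param length_range protein length range, sampled uniformly
#'   (default 150-400).
#' @param seed integer seed; output is deterministic given it.
#' @return list: `records` (protein [seq_set], positives then negatives),
#'   `truth` (data.frame seq_id, true_class), `profiles`.
#' @export
generate_training_set <- function(n_per_class = 100L, n_negative = 400L,
                                  length_range = c(150L, 400L), seed = 42L) {
  stopifnot(n_per_class >= 1L, n_negative >= 1L)
  profiles <- default_profiles(seed)
  with_local_seed(seed, {
    recs <- list()
    truth <- list()
    for (cl in names(PROFILE_SPEC)) {
      prof <- profiles[[cl]]
      prof$length_range <- length_range
      lens <- sample(length_range[1]:length_range[2], n_per_class,
                     replace = TRUE)
      for (i in seq_len(n_per_class)) {
        id <- sprintf("%s_%03d", cl, i)
        recs[[length(recs) + 1L]] <- sample_protein(prof, lens[i], id)
        truth[[length(truth) + 1L]] <- data.frame(seq_id = id, true_class = cl)
      }
    }
    lens <- sample(length_range[1]:length_range[2], n_negative, replace = TRUE)
    for (i in seq_len(n_negative)) {
      id <- sprintf("NEG_%03d", i)
      recs[[length(recs) + 1L]] <- sample_protein(profiles$negative, lens[i], id)
      truth[[length(truth) + 1L]] <- data.frame(seq_id = id,
                                                true_class = "negative")
    }
    list(records = do.call(bind_seq_sets, recs),
         truth = do.call(rbind, truth),
         profiles = profiles)
  })
}

#' Convert a synthetic set into a training_dataset
#'
#' Splits the labeled records of [generate_training_set] into per-class
#' positives and negatives without re-running curation (the labels are ground
#' truth by construction).
#' @param synth output of [generate_training_set].
#' @return a `training_dataset`-shaped list accepted by [rgene_svm].
#' @export
as_training_dataset <- function(synth) {
  pos <- lapply(names(PROFILE_SPEC), function(cl) {
    subset_seq_set(synth$records,
                   synth$truth$true_class == cl)
  })
  names(pos) <- names(PROFILE_SPEC)
  out <- list(positives = pos,
              negatives = subset_seq_set(synth$records,
                                         synth$truth$true_class == "negative"),
              log = data.frame(seq_id = character(), action = character(),
                               reason = character()),
              counts = c(vapply(pos, nrow, integer(1)),
                         negative = sum(synth$truth$true_class == "negative")))
  class(out) <- "training_dataset"
  out
}

# codon table keyed by amino acid, stops excluded
synonymous_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
})

#' Reverse-translate a protein into a coding sequence
#'
#' Each residue maps to a uniformly chosen synonymous codon (standard code);
#' `ATG` is prefixed when the protein does not start with M, and a `TAA` stop
#' is appended. `translate_cds` of the result (stop stripped) recovers the
#' protein (with a leading M added when one was prefixed). Uses the current
#' RNG state.
#'
#' @param record a one-row protein [seq_set] (no `X` residues), or a protein
#'   string.
#' @return a one-row nucleotide [seq_set] with the same id.
#' @export
reverse_translate <- function(record) {
  if (inherits(record, "seq_set")) {
    stopifnot(nrow(record) == 1L, seq_alphabet(record) == "protein")
    protein <- record$residues
    id <- record$id
    desc <- record$description
  } else {
    protein <- toupper(as.character(record))
    id <- "cds"
    desc <- ""
  }
  chars <- strsplit(protein, "")[[1]]
  if (any(chars == "X")) stop("cannot reverse-translate ambiguous residue X")
  codons <- vapply(chars, function(aa) {
    opts <- synonymous_codons[[aa]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  cds <- paste(codons, collapse = "")
  if (chars[1] != "M") cds <- paste0("ATG", cds)
  cds <- paste0(cds, "TAA")
  seq_set(id, cds, description = desc, alphabet = "nucleotide")
}

#' Generate synthetic transcripts for labeled proteins
#'
#' Reverse-translates every record and pads both ends with random
#' stop-free UTR sequence so the coding region must be found by ORF
#' extraction.
#' @param records a protein [seq_set].
#' @param utr_max maximum UTR length per side (default 30 nt; UTR lengths are
#'   sampled uniformly in 0..utr_max).
#' @param seed integer seed.
#' @return a nucleotide [seq_set] with the same ids.
#' @export
generate_transcripts <- function(records, utr_max = 30L, seed = 42L) {
  stopifnot(inherits(records, "seq_set"))
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(records)), function(i) {
      cds <- reverse_translate(subset_seq_set(records, i))
      utr5 <- paste(sample(c("C", "T"), sample.int(utr_max + 1L, 1L) - 1L,
                           replace = TRUE), collapse = "")
      utr3 <- paste(sample(c("C", "T"), sample.int(utr_max + 1L, 1L) - 1L,
                           replace = TRUE), collapse = "")
      seq_set(cds$id, paste0(utr5, cds$residues, utr3),
              description = cds$description, alphabet = "nucleotide")
    })
    do.call(bind_seq_sets, rows)
  })
}

#' Write a truth-label TSV for a synthetic set
#' @param synth output of [generate_training_set].
#' @param path output path.
#' @export
write_truth_tsv <- function(synth, path) {
  utils::write.table(synth$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
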