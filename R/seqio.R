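#' @importFrom methods as is
#' @importFrom stats setNames
NULL

CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PROTEIN_ALPHABET <- c(CANONICAL_AA, "X")
NUCLEOTIDE_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a set of sequence records
#'
#' A `seq_set` is the package's universal sequence carrier: a data.frame with
#' columns `id`, `description` and `residues`, plus an `alphabet` attribute
#' (`"protein"` or `"nucleotide"`). Residues are uppercased on construction and
#' validated against the alphabet: proteins may use the 20 canonical residues
#' plus `X`, nucleotides `A/C/G/T/N`.
#'
#' @param id character vector of unique record ids.
#' @param residues character vector of sequences (non-empty).
#' @param description optional character vector of header descriptions.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A data.frame of class `seq_set`.
#' @export
seq_set <- function(id, residues, description = "", alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  description <- rep_len(as.character(description), length(id))
  if (length(residues) != length(id)) {
    stop("'id' and 'residues' must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop("empty record(s): ", paste(id[!nzchar(residues)], collapse = ", "))
  }
  allowed <- if (alphabet == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  bad <- !vapply(strsplit(residues, ""), function(ch) all(ch %in% allowed), logical(1))
  if (any(bad)) {
    stop("alphabet violation (", alphabet, ") in record(s): ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, description = description, residues = residues,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", "data.frame")
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s record(s)\n", nrow(x), attr(x, "alphabet")))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %s (%d residues)\n", show$id[i], nchar(show$residues[i])))
    }
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

seq_alphabet <- function(x) attr(x, "alphabet")

subset_seq_set <- function(x, idx) {
  out <- x[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alphabet") <- attr(x, "alphabet")
  class(out) <- c("seq_set", "data.frame")
  out
}

bind_seq_sets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, nrow, integer(1)) > 0L]
  alphabets <- unique(vapply(sets, seq_alphabet, character(1)))
  if (length(alphabets) != 1L) stop("cannot bind seq_sets with mixed alphabets")
  df <- do.call(rbind, lapply(sets, as.data.frame))
  seq_set(df$id, df$residues, df$description, alphabets)
}

#' Read a FASTA file
#'
#' Records are returned in file order with residues uppercased. Duplicate ids,
#' empty records and alphabet violations are rejected with distinct errors.
#' The id is the header token up to the first whitespace; the remainder is the
#' description.
#'
#' @param path path to a FASTA file.
#' @param alphabet expected alphabet, `"protein"` or `"nucleotide"`.
#' @return A [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && !startsWith(first, ">")) {
    stop("malformed FASTA header: file does not start with '>' (", path, ")")
  }
  bs <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(bs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("malformed FASTA header: empty id in ", path)
  seq_set(ids, as.character(bs), desc, alphabet)
}

#' Write a FASTA file
#'
#' Round-trips exactly through [read_fasta]: ids, descriptions and residues
#' are preserved.
#'
#' @param x a [seq_set].
#' @param path output path.
#' @param line_width sequence line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, line_width = 60L) {
  stopifnot(inherits(x, "seq_set"), line_width >= 1L)
  if (nrow(x) == 0L) {
    # zero records: an empty file is the valid empty FASTA
    file.create(path)
    return(invisible(path))
  }
  bs <- Biostrings::BStringSet(x$residues)
  names(bs) <- ifelse(nzchar(x$description),
                      paste(x$id, x$description), x$id)
  Biostrings::writeXStringSet(bs, path, format = "fasta", width = line_width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string over A/C/G/T/N.
#' @return reverse complement string.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Translate a coding sequence
#'
#' Uses the standard genetic code (table 1). A codon containing `N` translates
#' to `X`; the trailing stop codon, if present, is stripped; an internal stop
#' codon is an error.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return protein string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("coding sequence length (", n, ") is not a positive multiple of 3")
  }
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa) & grepl("N", codons)] <- "X"
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(codons[is.na(aa)], collapse = ", "))
  }
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

# Maximal ORFs on one reading strand. seq is the strand being read; returns
# 0-based half-open [start, end) on that strand, with the stop codon included.
orfs_one_strand <- function(seq, min_len_codons) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  for (frame in 0:2) {
    if (frame + 1L > n - 2L) next
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    open_at <- NA_integer_  # codon index of earliest ATG since last stop
    for (i in seq_along(codons)) {
      if (is_stop[i]) {
        if (!is.na(open_at)) {
          len_codons <- i - open_at  # codons excluding the stop
          if (len_codons >= min_len_codons - 1L) {
            hits[[length(hits) + 1L]] <- c(start = starts[open_at] - 1L,
                                           end = starts[i] + 2L,
                                           frame = frame)
          }
          open_at <- NA_integer_
        }
      } else if (is_atg[i] && is.na(open_at)) {
        open_at <- i
      }
    }
  }
  hits
}

#' Find open reading frames in a nucleotide record
#'
#' Enumerates every maximal ORF (earliest in-frame ATG to the next in-frame
#' stop) whose codon count, including the stop, is at least `min_len_codons`.
#' ORFs running off the end of the sequence are excluded. Coordinates are
#' 0-based half-open on the forward strand regardless of ORF strand; `frame`
#' is the ORF start modulo 3 on its own reading strand. Candidate ORFs whose
#' span contains `N` are skipped with a warning.
#'
#' @param record a single-row nucleotide [seq_set] (or a row index into one).
#' @param min_len_codons minimum ORF length in codons, stop included
#'   (default 100, the conventional minimum for transcript ORF calling).
#' @param both_strands search the reverse strand too (default TRUE).
#' @return data.frame with columns `source_id`, `start`, `end`, `strand`,
#'   `frame`, `protein`, sorted by protein length descending, ties by
#'   (strand `+` first, then start ascending).
#' @export
find_orfs <- function(record, min_len_codons = 100L, both_strands = TRUE) {
  stopifnot(min_len_codons >= 1L)
  if (inherits(record, "seq_set")) {
    stopifnot(nrow(record) == 1L, seq_alphabet(record) == "nucleotide")
    src_id <- record$id
    seq <- record$residues
  } else {
    stop("'record' must be a single-row nucleotide seq_set")
  }
  n <- nchar(seq)
  empty <- data.frame(source_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      stringsAsFactors = FALSE)
  if (n < 6L) return(empty)
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (h in orfs_one_strand(s, min_len_codons)) {
      sub <- substr(s, h["start"] + 1L, h["end"])
      if (grepl("N", sub, fixed = TRUE)) {
        warning("ORF in ", src_id, " (", strand, " strand) skipped: contains N")
        next
      }
      if (strand == "+") {
        start_f <- unname(h["start"]); end_f <- unname(h["end"])
      } else {
        start_f <- n - unname(h["end"]); end_f <- n - unname(h["start"])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = src_id, start = start_f, end = end_f, strand = strand,
        frame = unname(h["frame"]), protein = translate_cds(sub),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ord <- order(-nchar(out$protein), out$strand, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the single best (longest) ORF protein from a transcript
#'
#' Ties in protein length are broken by strand (`+` before `-`) then start.
#'
#' @inheritParams find_orfs
#' @return A one-row protein [seq_set] with the source id (NULL when no ORF
#'   qualifies). The ORF coordinates are attached as attribute `"orf"`.
#' @export
longest_orf_protein <- function(record, min_len_codons = 100L,
                                both_strands = TRUE) {
  orfs <- find_orfs(record, min_len_codons, both_strands)
  if (nrow(orfs) == 0L) return(NULL)
  best <- orfs[1L, ]
  out <- seq_set(best$source_id, best$protein,
                 description = sprintf("ORF %d-%d strand %s",
                                       best$start, best$end, best$strand),
                 alphabet = "protein")
  attr(out, "orf") <- best
  out
}

#' Write an ORF report as TSV
#' @param orfs data.frame from [find_orfs] (rows from several records may be
#'   bound together).
#' @param path output TSV path.
#' @export
write_orf_report <- function(orfs, path) {
  rep <- data.frame(source_id = orfs$source_id, start = orfs$start,
                    end = orfs$end, strand = orfs$strand, frame = orfs$frame,
                    protein_length = nchar(orfs$protein))
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
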