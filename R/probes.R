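# Hybridization-capture probe design: tile, filter, deduplicate, emit.
#
# Defaults follow RenSeq convention for NimbleGen/Roche-style capture:
# 120-nt probes at 2x tiling (step 60), GC within 25-65%, homopolymer runs
# capped at 10, ambiguous bases rejected. All are configuration, not fixed
# requirements.

#' Configure probe design
#'
#' @param length probe length in nt (default 120).
#' @param step tiling step in nt (default 60; `0 < step <= length`).
#' @param gc_min,gc_max allowed GC fraction window (default 0.25-0.65).
#' @param max_homopolymer longest allowed single-base run (default 10).
#' @param allow_ambiguous keep probes containing non-ACGT bases
#'   (default FALSE).
#' @param terminal_flush add a final probe flush with the source 3' end when
#'   the tiling does not already reach it (default TRUE).
#' @param strand_aware_dedupe also collapse probes equal to the reverse
#'   complement of a kept probe (default TRUE).
#' @return object of class `probe_config`.
#' @export
probe_config <- function(length = 120L, step = 60L, gc_min = 0.25,
                         gc_max = 0.65, max_homopolymer = 10L,
                         allow_ambiguous = FALSE, terminal_flush = TRUE,
                         strand_aware_dedupe = TRUE) {
  stopifnot(step > 0L, step <= length,
            gc_min >= 0, gc_min < gc_max, gc_max <= 1)
  cfg <- list(length = as.integer(length), step = as.integer(step),
              gc_min = gc_min, gc_max = gc_max,
              max_homopolymer = as.integer(max_homopolymer),
              allow_ambiguous = isTRUE(allow_ambiguous),
              terminal_flush = isTRUE(terminal_flush),
              strand_aware_dedupe = isTRUE(strand_aware_dedupe))
  class(cfg) <- "probe_config"
  cfg
}

gc_fraction <- function(seqs) {
  total <- nchar(seqs)
  gc <- nchar(gsub("[^GC]", "", seqs))
  gc / total
}

max_run <- function(seqs) {
  vapply(strsplit(seqs, ""), function(ch) max(rle(ch)$lengths), integer(1))
}

#' Tile probes across nucleotide sources
#'
#' Probes start at 0, step, 2*step, ... while `start + length <= source
#' length`; with `terminal_flush` a final probe ending exactly at the source
#' 3' end is appended when the last regular probe falls short of it. Sources
#' shorter than the probe length are skipped and reported in the `skipped`
#' attribute.
#'
#' @param x a nucleotide [seq_set].
#' @param config a [probe_config].
#' @return data.frame: `source_id`, `start`, `end` (0-based half-open),
#'   `sequence`, `gc_fraction`; attribute `skipped` lists skipped sources.
#' @export
tile_probes <- function(x, config = probe_config()) {
  stopifnot(inherits(x, "seq_set"), seq_alphabet(x) == "nucleotide",
            inherits(config, "probe_config"))
  L <- config$length
  S <- config$step
  skipped <- data.frame(source_id = character(), reason = character())
  rows <- list()
  for (i in seq_len(nrow(x))) {
    n <- nchar(x$residues[i])
    if (n < L) {
      skipped[nrow(skipped) + 1L, ] <- list(
        x$id[i], sprintf("source length %d < probe length %d", n, L))
      next
    }
    starts <- seq(0L, n - L, by = S)
    if (config$terminal_flush && starts[length(starts)] + L < n) {
      starts <- c(starts, n - L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source_id = x$id[i], start = starts, end = starts + L,
      sequence = substring(x$residues[i], starts + 1L, starts + L),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(), start = integer(), end = integer(),
               sequence = character(), stringsAsFactors = FALSE)
  out$gc_fraction <- if (nrow(out)) gc_fraction(out$sequence) else numeric(0)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Filter tiled probes
#'
#' A probe fails when its GC fraction falls outside the configured window,
#' when it contains a homopolymer run longer than `max_homopolymer`, or when
#' it contains a non-ACGT base and `allow_ambiguous` is off. Every failed
#' probe is labeled with all violated rules.
#'
#' @param probes data.frame from [tile_probes].
#' @param config a [probe_config].
#' @return list: `passed` (probes), `failed` (probes plus a `reasons`
#'   column, comma-joined among `gc_low`, `gc_high`, `homopolymer`,
#'   `ambiguous`).
#' @export
filter_probes <- function(probes, config = probe_config()) {
  if (!nrow(probes)) {
    return(list(passed = probes, failed = cbind(probes, reasons = character(0))))
  }
  reasons <- vector("list", nrow(probes))
  gc <- probes$gc_fraction
  lows <- gc < config$gc_min
  highs <- gc > config$gc_max
  runs <- max_run(probes$sequence) > config$max_homopolymer
  ambig <- grepl("[^ACGT]", probes$sequence) & !config$allow_ambiguous
  for (i in seq_len(nrow(probes))) {
    r <- c(if (lows[i]) "gc_low", if (highs[i]) "gc_high",
           if (runs[i]) "homopolymer", if (ambig[i]) "ambiguous")
    reasons[[i]] <- r
  }
  fail <- lengths(reasons) > 0L
  failed <- probes[fail, , drop = FALSE]
  failed$reasons <- vapply(reasons[fail], paste, character(1), collapse = ",")
  rownames(failed) <- NULL
  passed <- probes[!fail, , drop = FALSE]
  rownames(passed) <- NULL
  list(passed = passed, failed = failed)
}

#' Deduplicate probes
#'
#' Exact sequence duplicates collapse onto the first occurrence in
#' (source_id, start) order; with `strand_aware`, a probe equal to the
#' reverse complement of an already-kept probe collapses too. If a collapse
#' removes the only probe covering part of a source, a coverage-loss warning
#' is raised.
#'
#' @param probes data.frame of passed probes from [filter_probes].
#' @param strand_aware collapse reverse-complement duplicates (default TRUE).
#' @return object of class `probe_set`: list with `probes` (kept, with
#'   `probe_id`), `collapse_map` (data.frame kept_id, source_id, start, end).
#' @export
dedupe_probes <- function(probes, strand_aware = TRUE) {
  probes <- probes[order(probes$source_id, probes$start), , drop = FALSE]
  kept <- logical(nrow(probes))
  key_of <- character(0)  # canonical key -> kept probe id
  ids <- sprintf("%s_%d_%d", probes$source_id, probes$start, probes$end)
  collapse <- data.frame(kept_id = character(), source_id = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(probes))) {
    s <- probes$sequence[i]
    keys <- if (strand_aware) c(s, reverse_complement(s)) else s
    hit <- keys[keys %in% names(key_of)]
    if (length(hit)) {
      collapse[nrow(collapse) + 1L, ] <- list(unname(key_of[hit[1]]),
                                              probes$source_id[i],
                                              probes$start[i], probes$end[i])
    } else {
      kept[i] <- TRUE
      key_of[s] <- ids[i]
    }
  }
  out_probes <- probes[kept, , drop = FALSE]
  out_probes$probe_id <- ids[kept]
  rownames(out_probes) <- NULL
  if (nrow(collapse)) {
    lost <- !collapse$source_id %in% out_probes$source_id
    if (any(lost)) {
      warning("dedupe removed all probes of source(s): ",
              paste(unique(collapse$source_id[lost]), collapse = ", "),
              " (coverage loss)")
    }
  }
  structure(list(probes = out_probes, collapse_map = collapse),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d probe(s) from %d source(s); %d collapsed duplicate(s)\n",
              nrow(x$probes), length(unique(x$probes$source_id)),
              nrow(x$collapse_map)))
  invisible(x)
}

#' Emit a probe set as FASTA and BED
#'
#' FASTA ids are `sourceid_start_end`; BED rows are
#' `source_id, start, end, probe_id, 0, +`. Extracting each BED interval from
#' the source FASTA reproduces the probe sequence exactly.
#' @param probe_set a `probe_set` from [dedupe_probes].
#' @param fasta_path,bed_path output paths.
#' @export
write_probe_set <- function(probe_set, fasta_path, bed_path) {
  p <- probe_set$probes
  if (nrow(p)) {
    write_fasta(seq_set(p$probe_id, p$sequence, alphabet = "nucleotide"),
                fasta_path)
  } else {
    file.create(fasta_path)
  }
  if (nrow(p)) {
    bed <- data.frame(p$source_id, p$start, p$end, p$probe_id, 0L, "+")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  invisible(list(fasta = fasta_path, bed = bed_path))
}

coverage_fraction <- function(probes, source_lengths) {
  vapply(names(source_lengths), function(sid) {
    n <- source_lengths[[sid]]
    sub <- probes[probes$source_id == sid, , drop = FALSE]
    if (!nrow(sub)) return(0)
    cov <- logical(n)
    for (j in seq_len(nrow(sub))) {
      cov[(sub$start[j] + 1L):sub$end[j]] <- TRUE
    }
    mean(cov)
  }, numeric(1))
}

#' Design probes end to end
#'
#' tile -> filter -> dedupe, with a design report: per-source probe counts,
#' filter-failure breakdown, and the fraction of each source covered by the
#' kept probes.
#' @param x a nucleotide [seq_set].
#' @param config a [probe_config].
#' @return a `probe_set` with an additional `report` component.
#' @export
design_probes <- function(x, config = probe_config()) {
  tiled <- tile_probes(x, config)
  flt <- filter_probes(tiled, config)
  ps <- dedupe_probes(flt$passed, config$strand_aware_dedupe)
  src_len <- setNames(nchar(x$residues), x$id)
  reason_tokens <- unlist(strsplit(flt$failed$reasons, ","))
  ps$report <- list(
    per_source = data.frame(
      source_id = x$id,
      length = unname(src_len),
      tiled = as.integer(table(factor(tiled$source_id, levels = x$id))),
      kept = as.integer(table(factor(ps$probes$source_id, levels = x$id))),
      coverage = unname(coverage_fraction(ps$probes, as.list(src_len)))),
    filter_failures = if (length(reason_tokens)) table(reason_tokens) else table(character(0)),
    skipped = attr(tiled, "skipped"))
  ps
}

#' Write a probe design report as TSV
#' @param probe_set output of [design_probes].
#' @param path output path.
#' @export
write_probe_report <- function(probe_set, path) {
  utils::write.table(probe_set$report$per_source, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
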