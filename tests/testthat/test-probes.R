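balanced_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("tiling arithmetic matches the closed form, with and without flush", {
  src <- seq_set("g300", balanced_dna(300, 1), alphabet = "nucleotide")
  p <- tile_probes(src, probe_config(length = 120, step = 60))
  expect_equal(p$start, c(0, 60, 120, 180))
  expect_equal(p$end[4], 300)  # ends flush, no extra probe

  src2 <- seq_set("g200", balanced_dna(200, 2), alphabet = "nucleotide")
  p2 <- tile_probes(src2, probe_config(length = 120, step = 60))
  expect_equal(p2$start, c(0, 60, 80))
  expect_equal(nrow(p2), 3)

  src3 <- seq_set("g120", balanced_dna(120, 3), alphabet = "nucleotide")
  expect_equal(nrow(tile_probes(src3, probe_config(length = 120))), 1)

  short <- seq_set("tiny", "ACGTACGT", alphabet = "nucleotide")
  p4 <- tile_probes(short, probe_config())
  expect_equal(nrow(p4), 0)
  expect_equal(attr(p4, "skipped")$source_id, "tiny")
})

test_that("tiling counts match floor((N-L)/S)+1 (+flush) on randomized cases", {
  set.seed(50)
  for (i in 1:60) {
    L <- sample(40:150, 1)
    S <- sample(seq_len(L), 1)
    N <- sample(L:1000, 1)
    cfg <- probe_config(length = L, step = S, terminal_flush = TRUE)
    src <- seq_set("s", random_dna(N), alphabet = "nucleotide")
    p <- tile_probes(src, cfg)
    base_count <- floor((N - L) / S) + 1
    flush <- as.integer((base_count - 1) * S + L < N)
    expect_equal(nrow(p), base_count + flush, info = sprintf("N=%d L=%d S=%d", N, L, S))
    expect_true(all(p$end - p$start == L))
    expect_true(all(p$sequence == substring(src$residues, p$start + 1, p$end)))
    # every base covered when flush is on
    cov <- logical(N)
    for (j in seq_len(nrow(p))) cov[(p$start[j] + 1):p$end[j]] <- TRUE
    expect_true(all(cov))
    # 2x interior coverage when step <= length/2
    if (S <= L / 2) {
      depth <- integer(N)
      for (j in seq_len(nrow(p))) {
        idx <- (p$start[j] + 1):p$end[j]
        depth[idx] <- depth[idx] + 1L
      }
      interior <- (S + 1):(N - S)
      expect_true(all(depth[interior] >= 2))
    }
  }
})

test_that("filters label every violated rule", {
  cfg <- probe_config(length = 120, step = 60)
  at_probe <- data.frame(source_id = "s", start = 0L, end = 120L,
                         sequence = strrep("AT", 60), stringsAsFactors = FALSE)
  at_probe$gc_fraction <- 0
  res <- filter_probes(at_probe, cfg)
  expect_equal(nrow(res$passed), 0)
  expect_match(res$failed$reasons, "gc_low")

  run_seq <- paste0(strrep("A", 11), balanced_dna(109, 4))
  runp <- data.frame(source_id = "s", start = 0L, end = 120L,
                     sequence = run_seq, stringsAsFactors = FALSE)
  runp$gc_fraction <- rgenecap:::gc_fraction(run_seq)
  res2 <- filter_probes(runp, cfg)
  expect_match(res2$failed$reasons, "homopolymer")

  amb <- paste0("N", balanced_dna(119, 5))
  ambp <- data.frame(source_id = "s", start = 0L, end = 120L, sequence = amb,
                     gc_fraction = rgenecap:::gc_fraction(amb),
                     stringsAsFactors = FALSE)
  res3 <- filter_probes(ambp, cfg)
  expect_match(res3$failed$reasons, "ambiguous")
  res3b <- filter_probes(ambp, probe_config(allow_ambiguous = TRUE))
  expect_false(any(grepl("ambiguous", res3b$failed$reasons)))

  # a probe violating several rules carries every reason
  multi <- paste0(strrep("A", 120))
  mp <- data.frame(source_id = "s", start = 0L, end = 120L, sequence = multi,
                   gc_fraction = 0, stringsAsFactors = FALSE)
  res4 <- filter_probes(mp, cfg)
  expect_match(res4$failed$reasons, "gc_low")
  expect_match(res4$failed$reasons, "homopolymer")
})

test_that("dedupe collapses exact and reverse-complement duplicates", {
  s <- balanced_dna(120, 6)
  probes <- data.frame(source_id = c("a", "b"), start = c(0L, 0L),
                       end = c(120L, 120L), sequence = c(s, s),
                       gc_fraction = 0.5, stringsAsFactors = FALSE)
  expect_warning(ps <- dedupe_probes(probes, strand_aware = FALSE),
                 "coverage loss")
  expect_equal(nrow(ps$probes), 1)
  expect_equal(ps$probes$source_id, "a")
  expect_equal(nrow(ps$collapse_map), 1)
  expect_equal(ps$collapse_map$source_id, "b")

  rc <- reverse_complement(s)
  probes2 <- data.frame(source_id = c("a", "b"), start = 0L, end = 120L,
                        sequence = c(s, rc), gc_fraction = 0.5,
                        stringsAsFactors = FALSE)
  expect_warning(rc_dedup <- dedupe_probes(probes2, strand_aware = TRUE),
                 "coverage loss")
  expect_equal(nrow(rc_dedup$probes), 1)
  expect_equal(nrow(dedupe_probes(probes2, strand_aware = FALSE)$probes), 2)

  uniq <- data.frame(source_id = "a", start = c(0L, 60L), end = c(120L, 180L),
                     sequence = c(balanced_dna(120, 7), balanced_dna(120, 8)),
                     gc_fraction = 0.5, stringsAsFactors = FALSE)
  expect_equal(nrow(dedupe_probes(uniq, TRUE)$probes), 2)
})

test_that("dedupe warns when a collapse removes all coverage of a source", {
  s <- balanced_dna(120, 9)
  probes <- data.frame(source_id = c("a", "b"), start = 0L, end = 120L,
                       sequence = c(s, s), gc_fraction = 0.5,
                       stringsAsFactors = FALSE)
  expect_warning(dedupe_probes(probes, TRUE), "coverage loss")
})

test_that("emitted FASTA/BED round-trip to the exact probe sequences", {
  set.seed(60)
  src <- seq_set(c("geneA", "geneB"),
                 c(random_dna(450), random_dna(333)),
                 alphabet = "nucleotide")
  ps <- design_probes(src, probe_config())
  fa <- withr::local_tempfile(fileext = ".fasta")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_probe_set(ps, fa, bed)

  bed_tab <- read.delim(bed, header = FALSE,
                        col.names = c("chrom", "start", "end", "name",
                                      "score", "strand"))
  expect_equal(bed_tab$strand, rep("+", nrow(bed_tab)))
  expect_equal(bed_tab$name,
               sprintf("%s_%d_%d", bed_tab$chrom, bed_tab$start, bed_tab$end))
  back <- read_fasta(fa, "nucleotide")
  # extract every BED interval from the source and compare
  for (i in seq_len(nrow(bed_tab))) {
    src_seq <- src$residues[src$id == bed_tab$chrom[i]]
    extracted <- substr(src_seq, bed_tab$start[i] + 1, bed_tab$end[i])
    expect_equal(back$residues[back$id == bed_tab$name[i]], extracted)
  }
  # every emitted probe passes all filters
  refiltered <- filter_probes(ps$probes, probe_config())
  expect_equal(nrow(refiltered$failed), 0)

  empty <- dedupe_probes(tile_probes(
    seq_set("t", "ACGT", alphabet = "nucleotide"), probe_config()))
  out <- write_probe_set(empty, fa, bed)
  expect_equal(file.size(out$fasta), 0)
})

test_that("one-probe BED row matches the documented format", {
  src <- seq_set("geneA", balanced_dna(120, 10), alphabet = "nucleotide")
  ps <- dedupe_probes(tile_probes(src, probe_config()))
  bed <- withr::local_tempfile(fileext = ".bed")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_probe_set(ps, fa, bed)
  expect_equal(readLines(bed), "geneA\t0\t120\tgeneA_0_120\t0\t+")
})

test_that("probe_config validates its invariants", {
  expect_error(probe_config(step = 0), "step")
  expect_error(probe_config(step = 200, length = 120))
  expect_error(probe_config(gc_min = 0.7, gc_max = 0.3))
})

test_that("design_probes reports per-source accounting and coverage", {
  set.seed(61)
  src <- seq_set(c("long", "short"), c(random_dna(600), random_dna(50)),
                 alphabet = "nucleotide")
  ps <- design_probes(src, probe_config())
  rep <- ps$report$per_source
  expect_equal(rep$tiled[rep$source_id == "long"], 9)
  expect_equal(rep$tiled[rep$source_id == "short"], 0)
  expect_equal(ps$report$skipped$source_id, "short")
  expect_true(rep$coverage[rep$source_id == "long"] <= 1)
})
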