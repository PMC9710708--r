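# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, with_x_prob = 0) {
  pool <- c(AA20, if (with_x_prob > 0) "X")
  prob <- c(rep((1 - with_x_prob) / 20, 20), if (with_x_prob > 0) with_x_prob)
  paste(sample(pool, len, replace = TRUE, prob = prob), collapse = "")
}

random_dna <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# naive k-mer tally by explicit substring loop
oracle_kmer <- function(protein, k) {
  labels <- apply(expand.grid(rev(rep(list(AA20), k)))[, k:1, drop = FALSE],
                  1, paste, collapse = "")
  counts <- setNames(numeric(20^k), sort(labels))
  n <- nchar(protein)
  for (i in 1:(n - k + 1)) {
    w <- substr(protein, i, i + k - 1)
    if (w %in% names(counts)) counts[w] <- counts[w] + 1
  }
  counts / (n - k + 1)
}

oracle_aac <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  setNames(vapply(AA20, function(a) sum(chars == a), numeric(1)),
           AA20) / length(chars)
}

# all-pairs greedy clustering: same ordering rule, quadratic membership scan
oracle_greedy_cluster <- function(ids, seqs, threshold, k) {
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(vapply(1:(n - k + 1), function(i) substr(s, i, i + k - 1),
                  character(1)))
  })
  reps <- integer()
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      km <- kmers[[i]]
      if (length(km) &&
          sum(km %in% kmers[[reps[r]]]) / length(km) >= threshold) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  list(representative_ids = ids[reps], assignment = setNames(assign, ids))
}

# exhaustive 6-frame ORF enumeration: every ATG, scan codon-wise to the first
# in-frame stop, keep maximal ORFs (earliest start per stop), drop N-spanning
oracle_orfs <- function(seq, min_len_codons, both_strands = TRUE) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  n <- nchar(seq)
  out <- list()
  for (strand in (if (both_strands) c("+", "-") else "+")) {
    s <- if (strand == "+") seq else rc(seq)
    hits <- list()
    for (i in 1:(n - 2)) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i
      stop_at <- NA
      while (j + 2 <= n) {
        if (substr(s, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
          stop_at <- j
          break
        }
        j <- j + 3
      }
      if (is.na(stop_at)) next
      prot_len <- (stop_at - i) / 3
      if (prot_len < min_len_codons - 1) next
      hits[[length(hits) + 1]] <- c(start = i - 1, end = stop_at + 2)
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    # maximal: smallest start for each stop
    h <- h[order(h[, "end"], h[, "start"]), , drop = FALSE]
    h <- h[!duplicated(h[, "end"]), , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      span <- substr(s, h[r, "start"] + 1, h[r, "end"])
      if (grepl("N", span, fixed = TRUE)) next
      if (strand == "+") {
        st <- h[r, "start"]; en <- h[r, "end"]
      } else {
        st <- n - h[r, "end"]; en <- n - h[r, "start"]
      }
      out[[length(out) + 1]] <- data.frame(
        start = unname(st), end = unname(en), strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

subset_seq_set_for_test <- function(x, idx) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  seq_set(out$id, out$residues, out$description, attr(x, "alphabet"))
}

# tiny toy dataset for fast classifier tests: well-separated compositions
toy_dataset <- function(n_per_class = 12, n_negative = 30, seed = 7) {
  synth <- generate_training_set(n_per_class = n_per_class,
                                 n_negative = n_negative, seed = seed)
  as_training_dataset(synth)
}

tiny_grid <- function(folds = 3, seed = 1) {
  grid_config(poly_d = 1L, poly_C_exponents = 2L,
              rbf_g_exponents = integer(), rbf_C_exponents = integer(),
              folds = folds, seed = seed)
}
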