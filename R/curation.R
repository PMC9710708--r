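# Training-set curation: domain-rule class assignment, greedy redundancy
# clustering, and positive/negative dataset assembly with a provenance log.

R_GENE_CLASSES <- c("TNL", "CNL", "RLK", "RLP")
KNOWN_DOMAINS <- c("NB-ARC", "TIR", "CC", "KINASE", "LRR",
                   "STK-LRR", "KINASE-LRR", "TM")

#' Assign an R-gene class from a domain annotation
#'
#' Rules, applied in order:
#' \itemize{
#'   \item TNL if \{TIR, NB-ARC, LRR\} are all present;
#'   \item CNL if \{CC, NB-ARC, LRR\} are present and TIR absent;
#'   \item RLK if \{KINASE, LRR\} are present and NB-ARC absent;
#'   \item RLP if LRR present and none of \{KINASE, NB-ARC, TIR\};
#'   \item otherwise UNCLASSIFIED.
#' }
#' The composite tokens `STK-LRR` and `KINASE-LRR` expand to
#' \{KINASE, LRR\} before matching. Unknown tokens are ignored with a warning.
#'
#' @param domains character vector of domain tokens (case-insensitive).
#' @return one of `"TNL"`, `"CNL"`, `"RLK"`, `"RLP"`, `"UNCLASSIFIED"`.
#' @export
assign_class <- function(domains) {
  d <- toupper(trimws(domains))
  d <- d[nzchar(d)]
  unknown <- setdiff(d, KNOWN_DOMAINS)
  if (length(unknown)) {
    warning("ignoring unknown domain token(s): ",
            paste(unknown, collapse = ", "))
    d <- intersect(d, KNOWN_DOMAINS)
  }
  if (any(d %in% c("STK-LRR", "KINASE-LRR"))) d <- c(d, "KINASE", "LRR")
  has <- function(...) all(c(...) %in% d)
  if (has("TIR", "NB-ARC", "LRR")) return("TNL")
  if (has("CC", "NB-ARC", "LRR") && !has("TIR")) return("CNL")
  if (has("KINASE", "LRR") && !has("NB-ARC")) return("RLK")
  if (has("LRR") && !any(c("KINASE", "NB-ARC", "TIR") %in% d)) return("RLP")
  "UNCLASSIFIED"
}

#' Read a domain-annotation TSV
#'
#' Format: `seq_id <tab> comma-separated domain tokens`, no header.
#' @param path TSV path.
#' @return named list: seq_id -> character vector of tokens.
#' @export
read_domain_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seq_id", "domains"),
                          colClasses = "character", quote = "")
  setNames(strsplit(df$domains, ","), df$seq_id)
}

distinct_kmers <- function(residues, k) {
  n <- nchar(residues)
  if (n < k) return(character())
  unique(substring(residues, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Greedy redundancy clustering by shared k-mer fraction
#'
#' CD-HIT-like greedy incremental clustering without alignment: records are
#' sorted by length descending (ties by id ascending); each record joins the
#' first existing cluster whose representative shares at least
#' `identity_threshold` of the shorter sequence's distinct k-mers, otherwise
#' it founds a new cluster.
#'
#' @param x a [seq_set].
#' @param identity_threshold fraction of shared distinct k-mers required
#'   (default 0.9).
#' @param k k-mer size (default 5). A sequence shorter than `k` always founds
#'   its own cluster (with a warning).
#' @return list with `representatives` (a [seq_set] in founding order) and
#'   `clusters` (data.frame: id, cluster_id, representative_id).
#' @export
cluster_redundant <- function(x, identity_threshold = 0.9, k = 5L) {
  stopifnot(inherits(x, "seq_set"), nrow(x) >= 1L,
            identity_threshold > 0, identity_threshold <= 1)
  ord <- order(-nchar(x$residues), x$id)
  x <- subset_seq_set(x, ord)
  if (any(nchar(x$residues) < k)) {
    warning("sequence(s) shorter than k = ", k,
            " found; each founds its own cluster")
  }
  rep_idx <- integer()       # indices (into sorted x) of representatives
  rep_kmers <- list()
  cluster_of <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    km <- distinct_kmers(x$residues[i], k)
    joined <- FALSE
    if (length(km)) {
      for (ci in seq_along(rep_idx)) {
        # candidate is <= representative in length, so candidate is 'shorter'
        shared <- sum(km %in% rep_kmers[[ci]]) / length(km)
        if (shared >= identity_threshold) {
          cluster_of[i] <- ci
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      rep_idx <- c(rep_idx, i)
      rep_kmers[[length(rep_kmers) + 1L]] <- km
      cluster_of[i] <- length(rep_idx)
    }
  }
  list(representatives = subset_seq_set(x, rep_idx),
       clusters = data.frame(id = x$id,
                             cluster_id = cluster_of,
                             representative_id = x$id[rep_idx][cluster_of],
                             stringsAsFactors = FALSE))
}

#' Build a labeled training dataset
#'
#' Positives are the annotated records whose domain rules yield a class;
#' negatives are caller-asserted R-gene-free sequences. Both sides are
#' redundancy-reduced with [cluster_redundant]. A negative whose annotation
#' matches an R-gene rule is expelled to the provenance log; a sequence whose
#' exact residues appear in two classes is kept only in the first class by
#' rule order (TNL, CNL, RLK, RLP). Records shorter than
#' `encoding_config$min_length` are dropped and logged.
#'
#' @param records protein [seq_set] of positive candidates.
#' @param annotations named list (seq_id -> domain tokens) covering `records`.
#' @param negatives protein [seq_set] of negative sequences.
#' @param config an [encoding_config] (supplies `min_length`).
#' @param identity_threshold,k passed to [cluster_redundant].
#' @return object of class `training_dataset`: list with `positives`
#'   (named list of per-class [seq_set]s), `negatives`, `log`
#'   (data.frame seq_id, action, reason), `counts`.
#' @export
build_dataset <- function(records, annotations, negatives,
                          config = encoding_config(),
                          identity_threshold = 0.9, k = 5L) {
  stopifnot(inherits(records, "seq_set"), inherits(negatives, "seq_set"))
  missing_ann <- setdiff(records$id, names(annotations))
  if (length(missing_ann)) {
    stop("no domain annotation for: ", paste(missing_ann, collapse = ", "))
  }
  log <- data.frame(seq_id = character(), action = character(),
                    reason = character(), stringsAsFactors = FALSE)
  note <- function(id, action, reason) {
    log[nrow(log) + 1L, ] <<- list(id, action, reason)
  }

  cls <- vapply(records$id, function(id) assign_class(annotations[[id]]),
                character(1))
  for (id in records$id[cls == "UNCLASSIFIED"]) {
    note(id, "dropped", "domain rules yield UNCLASSIFIED")
  }

  # length filter
  too_short <- nchar(records$residues) < config$min_length
  for (id in records$id[too_short & cls != "UNCLASSIFIED"]) {
    note(id, "dropped", sprintf("shorter than min_length %d", config$min_length))
  }
  keep <- !too_short & cls != "UNCLASSIFIED"

  # cross-class exact-duplicate exclusivity, first class by rule order wins
  seen <- character()
  positives <- list()
  for (cl in R_GENE_CLASSES) {
    idx <- which(keep & cls == cl)
    if (!length(idx)) {
      stop("class ", cl, " is empty after filtering")
    }
    sub <- subset_seq_set(records, idx)
    dup <- sub$residues %in% seen
    for (id in sub$id[dup]) {
      note(id, "dropped", paste0("duplicate of a sequence in an earlier class; kept in first class by rule order"))
    }
    sub <- subset_seq_set(sub, !dup)
    if (nrow(sub) == 0L) stop("class ", cl, " is empty after filtering")
    seen <- c(seen, sub$residues)
    cl_res <- cluster_redundant(sub, identity_threshold, k)
    for (id in setdiff(sub$id, cl_res$representatives$id)) {
      note(id, "clustered",
           paste0("redundant with ",
                  cl_res$clusters$representative_id[cl_res$clusters$id == id]))
    }
    positives[[cl]] <- cl_res$representatives
  }

  # negatives: expel any record whose annotation satisfies an R-gene rule
  neg <- negatives
  neg_cls <- vapply(neg$id, function(id) {
    if (id %in% names(annotations)) assign_class(annotations[[id]])
    else "UNCLASSIFIED"
  }, character(1))
  for (i in which(neg_cls != "UNCLASSIFIED")) {
    note(neg$id[i], "expelled",
         paste0("negative matches R-gene rule ", neg_cls[i]))
  }
  neg <- subset_seq_set(neg, neg_cls == "UNCLASSIFIED")
  short_neg <- nchar(neg$residues) < config$min_length
  for (id in neg$id[short_neg]) {
    note(id, "dropped", sprintf("shorter than min_length %d", config$min_length))
  }
  neg <- subset_seq_set(neg, !short_neg)
  if (nrow(neg) == 0L) stop("class negative is empty after filtering")
  neg_res <- cluster_redundant(neg, identity_threshold, k)
  for (id in setdiff(neg$id, neg_res$representatives$id)) {
    note(id, "clustered",
         paste0("redundant with ",
                neg_res$clusters$representative_id[neg_res$clusters$id == id]))
  }

  counts <- c(vapply(positives, nrow, integer(1)),
              negative = nrow(neg_res$representatives))
  out <- list(positives = positives, negatives = neg_res$representatives,
              log = log, counts = counts)
  class(out) <- "training_dataset"
  out
}

#' @export
print.training_dataset <- function(x, ...) {
  cat("<training_dataset>\n")
  for (cl in names(x$positives)) {
    cat(sprintf("  %s: %d\n", cl, nrow(x$positives[[cl]])))
  }
  cat(sprintf("  negatives: %d\n", nrow(x$negatives)))
  cat(sprintf("  provenance log: %d record(s)\n", nrow(x$log)))
  invisible(x)
}

#' Write a dataset manifest TSV
#'
#' One row per input record: seq_id, class, kept/dropped status and reason.
#' @param dataset a `training_dataset`.
#' @param path output path.
#' @export
write_dataset_manifest <- function(dataset, path) {
  rows <- list()
  for (cl in names(dataset$positives)) {
    s <- dataset$positives[[cl]]
    if (nrow(s)) {
      rows[[length(rows) + 1L]] <- data.frame(seq_id = s$id, class = cl,
                                              status = "kept", reason = "")
    }
  }
  if (nrow(dataset$negatives)) {
    rows[[length(rows) + 1L]] <- data.frame(seq_id = dataset$negatives$id,
                                            class = "negative",
                                            status = "kept", reason = "")
  }
  if (nrow(dataset$log)) {
    rows[[length(rows) + 1L]] <- data.frame(seq_id = dataset$log$seq_id,
                                            class = "",
                                            status = dataset$log$action,
                                            reason = dataset$log$reason)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
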