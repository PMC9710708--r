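# End-to-end workflow orchestration: train, predict, probes, run.
# Every run writes a machine-readable manifest (config snapshot, seed,
# package version, md5 checksums of every artifact); identical config + seed
# reproduce identical checksums. No sequence is ever silently dropped:
# skipped records always land in a skip report with a reason.

manifest_entry <- function(paths) {
  sums <- tools::md5sum(unlist(paths))
  lapply(seq_along(sums), function(i) {
    list(path = basename(names(sums)[i]), md5 = unname(sums[i]))
  })
}

write_manifest <- function(out_dir, stage, config_snapshot, seed, files) {
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("rgenecap")),
                   seed = seed,
                   config = config_snapshot,
                   files = manifest_entry(files))
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Train a classifier from files or from synthetic data
#'
#' Runs curation (or the synthetic generator), feature encoding and the
#' per-class grid search, then saves the model bundle, the grid report and a
#' run manifest into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param train_fasta protein FASTA of positive candidates (ignored when
#'   `synthetic = TRUE`).
#' @param annotations_tsv domain annotation TSV (see
#'   [read_domain_annotations]).
#' @param negatives_fasta protein FASTA of negative sequences.
#' @param synthetic use [generate_training_set] instead of input files.
#' @param n_per_class,n_negative synthetic set sizes.
#' @param seed integer seed (synthetic sampling and fold assignment).
#' @param encoding an [encoding_config].
#' @param grid a [grid_config]; its `seed` is overridden by `seed`.
#' @param verbose print progress.
#' @return invisibly, a list with the fitted `rgene_svm` and artifact paths.
#' @export
run_train <- function(out_dir, train_fasta = NULL, annotations_tsv = NULL,
                      negatives_fasta = NULL, synthetic = FALSE,
                      n_per_class = 100L, n_negative = 400L, seed = 42L,
                      encoding = encoding_config(), grid = reduced_grid(),
                      verbose = FALSE) {
  ensure_dir(out_dir)
  grid$seed <- as.integer(seed)
  if (synthetic) {
    synth <- generate_training_set(n_per_class = n_per_class,
                                   n_negative = n_negative, seed = seed)
    dataset <- as_training_dataset(synth)
    truth_path <- file.path(out_dir, "truth_labels.tsv")
    write_truth_tsv(synth, truth_path)
  } else {
    if (is.null(train_fasta) || is.null(annotations_tsv) ||
        is.null(negatives_fasta)) {
      stop("training requires train_fasta, annotations_tsv and ",
           "negatives_fasta (or synthetic = TRUE)")
    }
    for (p in c(train_fasta, annotations_tsv, negatives_fasta)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    records <- read_fasta(train_fasta, "protein")
    ann <- read_domain_annotations(annotations_tsv)
    negatives <- read_fasta(negatives_fasta, "protein")
    dataset <- build_dataset(records, ann, negatives, encoding)
  }
  model <- rgene_svm(dataset, encoding, grid, verbose = verbose)
  bundle_path <- file.path(out_dir, "model_bundle.rds")
  write_rgene_svm(model, bundle_path)
  report_path <- file.path(out_dir, "grid_report.tsv")
  write_grid_report(model, report_path)
  manifest_path <- write_manifest(
    out_dir, "train",
    list(synthetic = synthetic, n_per_class = n_per_class,
         n_negative = n_negative, encoding = unclass(encoding),
         grid = unclass(grid)),
    seed, c(bundle_path, report_path))
  invisible(list(model = model, bundle = bundle_path, grid_report = report_path,
                 manifest = manifest_path))
}

#' Predict R-gene classes for a FASTA input
#'
#' Protein input is classified directly; transcript input is routed through
#' [longest_orf_protein] first (the ORF coordinate map is retained so
#' per-class output stays in nucleotide space). Writes the prediction TSV,
#' one FASTA per predicted class, and a skipped-records TSV.
#'
#' @param model an `rgene_svm`, or a path to a bundle from [write_rgene_svm].
#' @param input_fasta input FASTA path.
#' @param out_dir output directory.
#' @param input_kind `"protein"` or `"transcript"`.
#' @param min_len_codons ORF length floor for transcript input.
#' @return invisibly: list with the predictions data.frame and artifact paths.
#' @export
run_predict <- function(model, input_fasta, out_dir,
                        input_kind = c("protein", "transcript"),
                        min_len_codons = 100L) {
  input_kind <- match.arg(input_kind)
  ensure_dir(out_dir)
  if (is.character(model)) model <- read_rgene_svm(model)
  stopifnot(inherits(model, "rgene_svm"))
  skipped <- data.frame(seq_id = character(), reason = character())
  if (input_kind == "protein") {
    prot <- read_fasta(input_fasta, "protein")
    nuc <- NULL
  } else {
    tx <- read_fasta(input_fasta, "nucleotide")
    prots <- list()
    nucs <- list()
    for (i in seq_len(nrow(tx))) {
      rec <- subset_seq_set(tx, i)
      best <- longest_orf_protein(rec, min_len_codons)
      if (is.null(best)) {
        skipped[nrow(skipped) + 1L, ] <- list(rec$id, "no qualifying ORF")
        next
      }
      orf <- attr(best, "orf")
      cds <- substr(rec$residues, orf$start + 1L, orf$end)
      if (orf$strand == "-") cds <- reverse_complement(cds)
      prots[[length(prots) + 1L]] <- best
      nucs[[length(nucs) + 1L]] <- seq_set(rec$id, cds,
                                           description = best$description,
                                           alphabet = "nucleotide")
    }
    if (!length(prots)) stop("no transcript yielded a qualifying ORF")
    prot <- do.call(bind_seq_sets, prots)
    nuc <- do.call(bind_seq_sets, nucs)
  }
  pred <- predict(model, prot)
  enc_skipped <- attr(pred, "skipped")
  if (nrow(enc_skipped)) {
    skipped <- rbind(skipped, data.frame(seq_id = enc_skipped$id,
                                         reason = enc_skipped$reason))
  }
  pred_path <- file.path(out_dir, "predictions.tsv")
  utils::write.table(pred, pred_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  skip_path <- file.path(out_dir, "skipped.tsv")
  utils::write.table(skipped, skip_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  class_files <- character()
  emit_src <- if (input_kind == "transcript") nuc else prot
  emit_alpha <- if (input_kind == "transcript") "nucleotide" else "protein"
  for (cl in model$classes) {
    ids <- pred$seq_id[pred$primary == cl]
    path <- file.path(out_dir, paste0("predicted_", cl, ".fasta"))
    write_fasta(subset_seq_set(emit_src, emit_src$id %in% ids), path)
    class_files[cl] <- path
  }
  manifest_path <- write_manifest(
    out_dir, "predict",
    list(input_kind = input_kind, min_len_codons = min_len_codons,
         fingerprint = as.character(model$fingerprint)),
    NA, c(pred_path, skip_path, unname(class_files)))
  invisible(list(predictions = pred, skipped = skipped,
                 predictions_tsv = pred_path, class_fastas = class_files,
                 skipped_tsv = skip_path, manifest = manifest_path,
                 proteins = prot, nucleotides = nuc))
}

#' Design probes for a nucleotide FASTA
#'
#' @param input either a nucleotide FASTA path or a nucleotide [seq_set]
#'   (typically the per-class output of [run_predict]).
#' @param out_dir output directory.
#' @param config a [probe_config].
#' @return invisibly: the `probe_set` plus artifact paths.
#' @export
run_probes <- function(input, out_dir, config = probe_config()) {
  ensure_dir(out_dir)
  x <- if (inherits(input, "seq_set")) input else read_fasta(input, "nucleotide")
  ps <- design_probes(x, config)
  fasta_path <- file.path(out_dir, "probes.fasta")
  bed_path <- file.path(out_dir, "probes.bed")
  write_probe_set(ps, fasta_path, bed_path)
  report_path <- file.path(out_dir, "probe_report.tsv")
  write_probe_report(ps, report_path)
  if (nrow(ps$report$skipped)) {
    warning("source(s) shorter than probe length skipped: ",
            paste(ps$report$skipped$source_id, collapse = ", "))
  }
  manifest_path <- write_manifest(out_dir, "probes", unclass(config), NA,
                                  c(fasta_path, bed_path, report_path))
  invisible(list(probe_set = ps, fasta = fasta_path, bed = bed_path,
                 report = report_path, manifest = manifest_path))
}

#' Run the full workflow: train (or load), predict, design probes
#'
#' Chains training (skipped when an existing bundle is supplied — reruns with
#' the same `out_dir` reuse it), prediction, and probe design on the
#' sequences predicted into any R-gene class. All intermediates are
#' persisted; a top-level manifest lists every artifact with checksums.
#'
#' @param input_fasta transcript (or protein) FASTA to classify. With protein
#'   input no probes can be designed unless `cds_fasta` supplies matching
#'   nucleotide sequences.
#' @param out_dir output directory.
#' @param input_kind `"transcript"` or `"protein"`.
#' @param bundle optional path to a pre-trained bundle; when the file exists,
#'   training is skipped.
#' @param cds_fasta nucleotide FASTA matching protein input ids (optional).
#' @param seed integer seed.
#' @param encoding,grid,probe_cfg module configurations.
#' @param synthetic_training train on synthetic data (default TRUE; file-based
#'   training needs `train_fasta`, `annotations_tsv`, `negatives_fasta`).
#' @param ... passed to [run_train].
#' @return invisibly: list of stage outputs and the manifest path.
#' @export
run_end_to_end <- function(input_fasta, out_dir,
                           input_kind = c("transcript", "protein"),
                           bundle = NULL, cds_fasta = NULL, seed = 42L,
                           encoding = encoding_config(), grid = reduced_grid(),
                           probe_cfg = probe_config(),
                           synthetic_training = TRUE, ...) {
  input_kind <- match.arg(input_kind)
  ensure_dir(out_dir)
  if (is.null(bundle)) bundle <- file.path(out_dir, "model_bundle.rds")
  if (file.exists(bundle)) {
    model <- read_rgene_svm(bundle)
    train_out <- list(bundle = bundle, reused = TRUE)
  } else {
    train_out <- run_train(out_dir, synthetic = synthetic_training,
                           seed = seed, encoding = encoding, grid = grid, ...)
    model <- train_out$model
    bundle <- train_out$bundle
  }
  pred_out <- run_predict(model, input_fasta, out_dir, input_kind)
  pred <- pred_out$predictions
  hit_ids <- pred$seq_id[pred$primary != "NON-R"]
  probe_out <- NULL
  if (length(hit_ids)) {
    nuc <- if (input_kind == "transcript") {
      subset_seq_set(pred_out$nucleotides, pred_out$nucleotides$id %in% hit_ids)
    } else if (!is.null(cds_fasta)) {
      cds <- read_fasta(cds_fasta, "nucleotide")
      subset_seq_set(cds, cds$id %in% hit_ids)
    } else {
      NULL
    }
    if (!is.null(nuc) && nrow(nuc)) {
      probe_out <- run_probes(nuc, out_dir, probe_cfg)
    }
  }
  files <- c(bundle, pred_out$predictions_tsv, pred_out$skipped_tsv,
             unname(pred_out$class_fastas))
  if (!is.null(probe_out)) files <- c(files, probe_out$fasta, probe_out$bed)
  manifest_path <- write_manifest(
    out_dir, "run",
    list(input_kind = input_kind, seed = seed,
         encoding = unclass(encoding), grid = unclass(grid),
         probes = unclass(probe_cfg)),
    seed, files)
  invisible(list(train = train_out, predict = pred_out, probes = probe_out,
                 manifest = manifest_path))
}
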