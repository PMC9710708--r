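# The top-level classifier: four one-vs-rest binary SVMs (TNL, CNL, RLK,
# RLP), each selected by grid search, bundled with the encoding
# configuration fingerprint and the selection cross-validation results.

BUNDLE_FORMAT_VERSION <- 1L

#' Fit the four-class R-gene classifier
#'
#' Encodes the training dataset with the compositional feature blocks and
#' trains one binary one-vs-rest SVM per R-gene class; for each class the
#' kernel and its parameters are selected by grid search with stratified
#' k-fold cross-validation, maximizing mean Matthews correlation coefficient.
#'
#' @param dataset a `training_dataset` from [build_dataset], or a list with
#'   components `positives` (named list of per-class protein [seq_set]s) and
#'   `negatives` (protein [seq_set]).
#' @param encoding an [encoding_config].
#' @param grid a [grid_config].
#' @param verbose print per-class progress (default FALSE).
#' @return object of class `rgene_svm`: per-class `binary_svm` models, their
#'   selection `cv_result`s, full grid result tables, the encoding config and
#'   its fingerprint, and the format version.
#' @export
rgene_svm <- function(dataset, encoding = encoding_config(),
                      grid = reduced_grid(), verbose = FALSE) {
  stopifnot(is.list(dataset$positives), inherits(dataset$negatives, "seq_set"))
  classes <- names(dataset$positives)
  all_seqs <- do.call(bind_seq_sets, c(unname(dataset$positives),
                                       list(dataset$negatives)))
  enc <- encode_matrix(all_seqs, encoding)
  if (nrow(enc$skipped)) {
    stop("training sequences below min_length: ",
         paste(enc$skipped$id, collapse = ", "))
  }
  x <- enc$features
  models <- cv <- reports <- setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    is_pos <- rownames(x) %in% dataset$positives[[cl]]$id
    if (verbose) {
      message("grid search for ", cl, " (", sum(is_pos), " positives vs ",
              sum(!is_pos), " rest)")
    }
    gs <- grid_search(x, is_pos, grid)
    models[[cl]] <- gs$model
    cv[[cl]] <- gs$best
    reports[[cl]] <- gs$results
    if (verbose) {
      message(sprintf("  best: %s d=%s C=%g g=%s mean MCC %.3f acc %.3f",
                      gs$best$params$kernel,
                      format(gs$best$params$d), gs$best$params$C,
                      format(gs$best$params$g),
                      gs$best$mean_mcc, gs$best$mean_accuracy))
    }
  }
  structure(list(models = models, cv = cv, grid_reports = reports,
                 classes = classes, encoding = encoding,
                 fingerprint = encoding_fingerprint(encoding),
                 grid = grid,
                 format_version = BUNDLE_FORMAT_VERSION),
            class = "rgene_svm")
}

#' @export
print.rgene_svm <- function(x, ...) {
  cat("<rgene_svm> one-vs-rest SVM classifier,",
      length(x$classes), "classes\n")
  for (cl in x$classes) {
    p <- x$cv[[cl]]$params
    cat(sprintf("  %s: %s%s C=%g%s | CV MCC %.3f, accuracy %.3f\n",
                cl, p$kernel,
                if (p$kernel == "polynomial") sprintf(" d=%d", p$d) else "",
                p$C,
                if (p$kernel == "rbf") sprintf(" g=%g", p$g) else "",
                x$cv[[cl]]$mean_mcc, x$cv[[cl]]$mean_accuracy))
  }
  invisible(x)
}

#' @export
summary.rgene_svm <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$classes, function(cl) {
    p <- object$cv[[cl]]$params
    data.frame(class = cl, kernel = p$kernel,
               d = if (is.null(p$d)) NA_integer_ else p$d,
               C = p$C,
               g = if (is.null(p$g)) NA_real_ else p$g,
               mean_mcc = object$cv[[cl]]$mean_mcc,
               mean_accuracy = object$cv[[cl]]$mean_accuracy,
               n_support_vectors = object$models[[cl]]$fit$tot.nSV)
  }))
  structure(list(selection = tab,
                 encoding_width = sum(BLOCK_WIDTHS[object$encoding$blocks])),
            class = "summary.rgene_svm")
}

#' @export
print.summary.rgene_svm <- function(x, ...) {
  cat("Selected models (encoding width", x$encoding_width, "):\n")
  print(x$selection, row.names = FALSE)
  invisible(x)
}

low_information <- function(x, encoding) {
  # all compositional signal absent: no canonical residue found
  layout <- encoding_layout(encoding)
  first <- layout[1, ]
  rowSums(x[, first$offset + seq_len(first$width), drop = FALSE]) == 0
}

#' Predict R-gene classes for new proteins
#'
#' Scores every sequence against the four binary models. A class is predicted
#' when its decision value is positive; the primary label is the class with
#' the largest decision value, or `NON-R` when none is positive. Sequences
#' below the encoding minimum length are reported in the `skipped` attribute,
#' never silently dropped. Output order follows input order, and predictions
#' are invariant to it.
#'
#' @param object an `rgene_svm`.
#' @param newdata a protein [seq_set], or a pre-encoded feature matrix whose
#'   layout matches the model's encoding.
#' @param ... unused.
#' @return data.frame: `seq_id`, one `decision_<class>` column per class,
#'   `predicted_classes` (comma-joined, possibly empty), `primary`,
#'   `low_information`. Attribute `skipped`: data.frame(id, reason).
#' @export
predict.rgene_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "seq_set")) {
    stopifnot(seq_alphabet(newdata) == "protein")
    enc <- encode_matrix(newdata, object$encoding)
    x <- enc$features
    skipped <- enc$skipped
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) != sum(BLOCK_WIDTHS[object$encoding$blocks])) {
      stop("feature matrix width ", ncol(newdata),
           " does not match the model encoding (fingerprint mismatch)")
    }
    x <- newdata
    skipped <- data.frame(id = character(), reason = character())
  } else {
    stop("'newdata' must be a protein seq_set or a feature matrix")
  }
  dv <- vapply(object$classes,
               function(cl) if (nrow(x)) decision_values(object$models[[cl]], x) else numeric(0),
               numeric(nrow(x)))
  dv <- matrix(dv, nrow = nrow(x), ncol = length(object$classes),
               dimnames = list(NULL, object$classes))
  pred_classes <- apply(dv, 1L, function(row) {
    paste(object$classes[row > 0], collapse = ",")
  })
  primary <- apply(dv, 1L, function(row) {
    if (any(row > 0)) object$classes[which.max(row)] else "NON-R"
  })
  out <- data.frame(seq_id = rownames(x),
                    setNames(as.data.frame(dv),
                             paste0("decision_", object$classes)),
                    predicted_classes = as.character(pred_classes),
                    primary = as.character(primary),
                    low_information = if (nrow(x)) low_information(x, object$encoding) else logical(0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Save a fitted classifier bundle
#'
#' The bundle carries a format version and the encoding fingerprint; both are
#' checked on load and at prediction time. Loading a saved bundle reproduces
#' decision values to 1e-10.
#' @param object an `rgene_svm`.
#' @param path output file path.
#' @export
write_rgene_svm <- function(object, path) {
  stopifnot(inherits(object, "rgene_svm"))
  saveRDS(object, path)
  invisible(path)
}

#' Load a fitted classifier bundle
#' @param path file written by [write_rgene_svm].
#' @param expected_encoding optional [encoding_config]; a fingerprint mismatch
#'   is an error.
#' @return an `rgene_svm`.
#' @export
read_rgene_svm <- function(path, expected_encoding = NULL) {
  if (!file.exists(path)) stop("bundle not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot parse model bundle ", path, ": ", conditionMessage(e))
  })
  if (!inherits(obj, "rgene_svm") || is.null(obj$format_version)) {
    stop("file is not an rgene_svm bundle: ", path)
  }
  if (obj$format_version != BUNDLE_FORMAT_VERSION) {
    stop("bundle format version ", obj$format_version,
         " does not match supported version ", BUNDLE_FORMAT_VERSION)
  }
  if (!is.null(expected_encoding) &&
      !identical(as.character(encoding_fingerprint(expected_encoding)),
                 as.character(obj$fingerprint))) {
    stop("encoding fingerprint mismatch: bundle was trained with a ",
         "different feature configuration")
  }
  obj
}

#' Write the per-class grid search report as TSV
#' @param object an `rgene_svm`.
#' @param path output path.
#' @export
write_grid_report <- function(object, path) {
  rows <- do.call(rbind, lapply(object$classes, function(cl) {
    r <- object$grid_reports[[cl]]
    cbind(class = cl, r)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
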