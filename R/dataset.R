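#' Construct a labelled sample-by-feature dataset
#'
#' The canonical container used throughout the package: a matrix of `m`
#' samples by `p` features (numeric or categorical), one discrete class label
#' per sample, and an optional ground-truth relevance table for synthetic
#' benchmarks.
#'
#' @param x data.frame of feature columns (numeric or factor), one row per
#'   sample. Column names are the feature names and must be unique.
#' @param labels vector of discrete class labels, one per sample; coerced to
#'   factor. At least two classes with at least two samples each are required.
#' @param truth optional data.frame with columns `feature`, `flag`
#'   (`"relevant"`, `"redundant"` or `"irrelevant"`) and `group` (character or
#'   `NA`), covering every feature. Records the ground truth of synthetic
#'   generators.
#' @return An object of class `rgife_dataset` with elements `x`, `labels` and
#'   `truth`.
#' @export
rgife_dataset <- function(x, labels, truth = NULL) {
  if (!is.data.frame(x)) x <- as.data.frame(x)
  x <- as.data.frame(lapply(x, function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  }), optional = TRUE, check.names = FALSE)
  rownames(x) <- NULL
  labels <- factor(labels)
  d <- structure(list(x = x, labels = labels, truth = truth),
                 class = "rgife_dataset")
  validate_dataset(d)
  d
}

validate_dataset <- function(d) {
  x <- d$x
  p <- ncol(x)
  if (p < 1) stop("dataset must have at least one feature")
  nm <- colnames(x)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))) {
    stop("feature names must be present and unique")
  }
  if (length(d$labels) != nrow(x)) {
    stop("number of labels (", length(d$labels),
         ") does not match number of samples (", nrow(x), ")")
  }
  if (anyNA(d$labels)) stop("missing class labels are not allowed")
  tab <- table(d$labels)
  if (length(tab) < 2) {
    stop("label column is constant: at least 2 distinct classes are required")
  }
  if (any(tab < 2)) {
    stop("every class needs at least 2 samples; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  na_cells <- which(is.na(as.matrix(x)), arr.ind = TRUE)
  if (nrow(na_cells) > 0) {
    shown <- utils::head(na_cells, 5)
    stop("missing feature values at (row, feature): ",
         paste(sprintf("(%d, %s)", shown[, 1], nm[shown[, 2]]),
               collapse = ", "))
  }
  if (!is.null(d$truth)) {
    if (!all(c("feature", "flag") %in% names(d$truth))) {
      stop("truth table needs 'feature' and 'flag' columns")
    }
    if (!setequal(d$truth$feature, nm)) {
      stop("truth table must cover exactly the dataset's features")
    }
  }
  invisible(d)
}

#' @export
print.rgife_dataset <- function(x, ...) {
  cat(sprintf("<rgife_dataset> %d samples x %d features\n",
              nrow(x$x), ncol(x$x)))
  cat("classes:",
      paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
            collapse = ", "), "\n")
  if (!is.null(x$truth)) {
    cat("ground truth:",
        paste(sprintf("%s (%d)", names(table(x$truth$flag)),
                      table(x$truth$flag)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples / features of a dataset
#' @param d an `rgife_dataset`.
#' @return integer count.
#' @export
n_samples <- function(d) nrow(d$x)

#' @rdname n_samples
#' @export
n_features <- function(d) ncol(d$x)

#' Feature names of a dataset
#' @param d an `rgife_dataset`.
#' @return character vector of feature names in column order.
#' @export
feature_names <- function(d) colnames(d$x)

#' Read a labelled dataset from CSV or ARFF
#'
#' CSV files must be comma-separated with a header row; ARFF files follow the
#' WEKA dialect (numeric and nominal attributes, class attribute in any
#' position). The file's column order is preserved as the feature order.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"arff"`; defaults to the file extension.
#' @param label_column name of the label column, or its 1-based column index.
#'   Defaults to `"class"`.
#' @return An [rgife_dataset()].
#' @export
load_dataset <- function(path, format = c("csv", "arff"),
                         label_column = "class") {
  if (length(format) > 1) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% format) ext else format[[1]]
  }
  format <- match.arg(format, c("csv", "arff"))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    out <- tryCatch(
      as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                      na.strings = c("NA", ""),
                                      stringsAsFactors = TRUE,
                                      check.names = FALSE)),
      error = function(e) stop("malformed CSV '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    out
  } else {
    tryCatch(foreign::read.arff(path),
             error = function(e) stop("malformed ARFF '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (is.numeric(label_column)) {
    idx <- as.integer(label_column)
    if (idx < 1 || idx > ncol(df)) {
      stop("label column index ", idx, " out of range 1..", ncol(df))
    }
  } else {
    idx <- match(label_column, names(df))
    if (is.na(idx)) stop("label column '", label_column, "' not found in ",
                         path)
  }
  labels <- df[[idx]]
  x <- df[, -idx, drop = FALSE]
  d <- rgife_dataset(x, labels)
  attr(d, "label_name") <- names(df)[idx]
  d
}

#' Write a dataset to CSV or ARFF
#'
#' Loading the written file with [load_dataset()] reproduces the matrix,
#' feature names and labels exactly. The label column is written last under
#' the name `"class"` (or the name remembered from [load_dataset()]).
#'
#' @param dataset an `rgife_dataset`.
#' @param path output path.
#' @param format `"csv"` or `"arff"`.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, format = c("csv", "arff")) {
  format <- match.arg(format)
  validate_dataset(dataset)
  label_name <- attr(dataset, "label_name")
  if (is.null(label_name) || label_name %in% feature_names(dataset)) {
    label_name <- "class"
  }
  df <- dataset$x
  df[[label_name]] <- dataset$labels
  if (format == "csv") {
    # doubles are written with 17 significant digits so the round trip is exact
    df <- as.data.frame(lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    }), optional = TRUE, check.names = FALSE)
    ok <- tryCatch({
      data.table::fwrite(df, path, sep = ",", quote = "auto")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write '", path, "'")
  } else {
    if (!dir.exists(dirname(path))) stop("cannot write '", path, "'")
    foreign::write.arff(df, path, relation = "rgife_dataset")
  }
  invisible(path)
}

#' Write / read a ground-truth relevance sidecar
#'
#' @param dataset an `rgife_dataset` carrying a `truth` table.
#' @param path CSV output path.
#' @return `path` invisibly (`save_truth`); a truth data.frame (`load_truth`).
#' @export
save_truth <- function(dataset, path) {
  if (is.null(dataset$truth)) stop("dataset carries no ground-truth table")
  data.table::fwrite(dataset$truth, path, sep = ",")
  invisible(path)
}

#' @rdname save_truth
#' @export
load_truth <- function(path) {
  as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                  check.names = FALSE))
}

#' Restrict a dataset to a subset of features
#'
#' Keeps the original relative column order regardless of the order of
#' `keep`; labels and ground truth rows are carried along untouched.
#'
#' @param dataset an `rgife_dataset`.
#' @param keep character vector of feature names to retain (non-empty).
#' @return An `rgife_dataset` with `length(keep)` features.
#' @export
subset_features <- function(dataset, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) == 0) stop("'keep' must name at least one feature")
  nm <- feature_names(dataset)
  unknown <- setdiff(keep, nm)
  if (length(unknown) > 0) {
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  sel <- nm[nm %in% keep]
  truth <- dataset$truth
  if (!is.null(truth)) {
    truth <- truth[truth$feature %in% sel, , drop = FALSE]
    rownames(truth) <- NULL
  }
  out <- structure(list(x = dataset$x[, sel, drop = FALSE],
                        labels = dataset$labels, truth = truth),
                   class = "rgife_dataset")
  attr(out, "label_name") <- attr(dataset, "label_name")
  out
}
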