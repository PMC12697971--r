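#' Construct an expression dataset
#'
#' Bundles a samples-by-features numeric matrix with per-sample class labels.
#' This is the container every stage of the pipeline scores, subsets and
#' classifies.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param labels vector of class labels, one per sample (coerced to factor).
#' @param feature_ids optional character vector of unique feature identifiers;
#'   defaults to the column names of `x` or `"f1"..."fp"`.
#' @param sample_ids optional character vector of sample identifiers.
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `matrix`, `labels` (factor), `feature_ids`, `sample_ids`.
#' @export
expression_dataset <- function(x, labels, feature_ids = NULL, sample_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric", call. = FALSE)
  if (anyNA(x)) stop("expression matrix contains missing values", call. = FALSE)
  if (nrow(x) != length(labels))
    stop("length of labels (", length(labels), ") does not match number of samples (",
         nrow(x), ")", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("at least 2 distinct label classes are required", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- colnames(x)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(x)))
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) {
    dup <- feature_ids[duplicated(feature_ids)][1L]
    stop("duplicate feature id: '", dup, "'", call. = FALSE)
  }
  if (length(feature_ids) != ncol(x))
    stop("feature_ids length does not match number of features", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  dimnames(x) <- list(sample_ids, feature_ids)
  structure(list(matrix = x, labels = labels,
                 feature_ids = feature_ids, sample_ids = as.character(sample_ids)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$matrix), "samples x", ncol(x$matrix), "features;",
      nlevels(x$labels), "classes (", paste(levels(x$labels), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Read an expression table from CSV/TSV
#'
#' Reads a delimited text file with a header row, extracts the designated label
#' column, and returns a validated [expression_dataset()]. Microarray exports
#' frequently store features in rows; `orientation = "features_in_rows"`
#' transposes such tables (the label row is then identified by its first-column
#' name).
#'
#' @param path file path; delimiter is inferred from the extension (`.tsv`/
#'   `.txt` tab, otherwise comma) unless `sep` is given.
#' @param label_column name of the column (or row, for features-in-rows input)
#'   holding the class label.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param sep optional field separator overriding the extension heuristic.
#' @param impute if `TRUE`, missing numeric cells are replaced by the
#'   per-feature median; the default rejects files with missing values.
#' @return An [expression_dataset()].
#' @export
load_expression_table <- function(path, label_column = "class",
                                  orientation = c("samples_in_rows", "features_in_rows"),
                                  sep = NULL, impute = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", row.names = NULL)
  if (orientation == "features_in_rows") {
    ids <- as.character(raw[[1L]])
    body <- raw[, -1L, drop = FALSE]
    li <- match(label_column, ids)
    if (is.na(li))
      stop("label column '", label_column, "' not found (feature rows: ",
           paste(utils::head(ids, 3), collapse = ", "), ", ...)", call. = FALSE)
    labels <- unlist(body[li, ], use.names = FALSE)
    vals <- t(as.matrix(body[-li, , drop = FALSE]))
    colnames(vals) <- ids[-li]
    raw <- data.frame(vals, check.names = FALSE, stringsAsFactors = FALSE)
    raw[[label_column]] <- labels
  }
  if (!label_column %in% names(raw))
    stop("label column '", label_column, "' not found in header", call. = FALSE)
  ids <- names(raw)[names(raw) != label_column]  # before subsetting: [.data.frame deduplicates
  if (anyDuplicated(ids))
    stop("duplicate feature id in header: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  labels <- raw[[label_column]]
  feats <- raw[names(raw) != label_column]
  m <- matrix(NA_real_, nrow(feats), ncol(feats), dimnames = list(NULL, ids))
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & !(trimws(as.character(v)) %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric cell at row ", bad[1L], ", column '", ids[j], "': '",
           v[bad[1L]], "'", call. = FALSE)
    m[, j] <- num
  }
  if (anyNA(m)) {
    if (!impute) {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing value at row ", idx[1L], ", column '", ids[idx[2L]],
           "' (set impute = TRUE for per-feature median imputation)", call. = FALSE)
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- stats::median(m[!nas, j])
    }
  }
  expression_dataset(m, labels, feature_ids = ids)
}

#' Write an expression dataset to CSV/TSV
#'
#' Inverse of [load_expression_table()] for the samples-in-rows orientation;
#' the label column is appended last.
#'
#' @param ds an [expression_dataset()].
#' @param path output file; extension selects the delimiter as in the loader.
#' @param label_column name for the label column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, label_column = "class") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(ds$matrix, check.names = FALSE)
  df[[label_column]] <- as.character(ds$labels)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalize an expression dataset
#'
#' Maps every non-constant feature affinely onto \[0, 1\]; constant features map
#' to 0. Labels are untouched. Idempotent on already-normalized data.
#'
#' @param ds an [expression_dataset()].
#' @return A normalized [expression_dataset()] with attribute `"ranges"` (a
#'   2-row matrix of the per-feature min and max used), needed to transform new
#'   samples consistently.
#' @export
minmax_normalize <- function(ds) {
  m <- ds$matrix
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  span <- hi - lo
  const <- span == 0
  span[const] <- 1
  out <- sweep(sweep(m, 2L, lo, "-"), 2L, span, "/")
  out[, const] <- 0
  res <- expression_dataset(out, ds$labels, ds$feature_ids, ds$sample_ids)
  attr(res, "ranges") <- rbind(min = lo, max = hi)
  res
}

# Apply stored min-max ranges to a new matrix (columns already subset/ordered).
apply_minmax <- function(x, ranges) {
  lo <- ranges["min", ]
  span <- ranges["max", ] - lo
  const <- span == 0
  span[const] <- 1
  out <- sweep(sweep(x, 2L, lo, "-"), 2L, span, "/")
  out[, const] <- 0
  out
}

#' Specification for a synthetic omics dataset
#'
#' Describes the generating model of [generate_synthetic_omics()]: a small set
#' of class-informative features, correlated redundant copies of each, and
#' Gaussian noise features, emulating the microarray/proteome regime of tens of
#' samples and thousands of features.
#'
#' @param n_samples,n_features dataset dimensions.
#' @param n_informative number of planted class-informative features.
#' @param n_redundant_per_informative correlated copies per informative feature.
#' @param n_classes number of (near-balanced) classes.
#' @param class_separation between-class mean shift, in units of `noise_sd`.
#' @param redundancy_rho target correlation between a redundant feature and its
#'   parent, in (0, 1).
#' @param noise_sd within-class standard deviation (> 0).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_samples = 60, n_features = 2000, n_informative = 10,
                           n_redundant_per_informative = 2, n_classes = 2,
                           class_separation = 2, redundancy_rho = 0.8,
                           noise_sd = 1, seed = 1) {
  spec <- list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               n_redundant_per_informative = as.integer(n_redundant_per_informative),
               n_classes = as.integer(n_classes),
               class_separation = as.numeric(class_separation),
               redundancy_rho = as.numeric(redundancy_rho),
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (spec$n_informative * (1L + spec$n_redundant_per_informative) > spec$n_features)
    stop("infeasible spec: n_informative * (1 + n_redundant_per_informative) exceeds n_features",
         call. = FALSE)
  if (spec$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (spec$redundancy_rho <= 0 || spec$redundancy_rho >= 1)
    stop("redundancy_rho must lie in (0, 1)", call. = FALSE)
  if (spec$n_classes < 2) stop("at least 2 classes required", call. = FALSE)
  if (spec$n_samples < 2L * spec$n_classes)
    stop("infeasible spec: fewer than 2 samples per class", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic omics dataset
#'
#' Informative features get class-dependent means separated by
#' `class_separation * noise_sd`; each redundant feature is
#' `rho * standardized(parent) + sqrt(1 - rho^2) * independent noise`, rescaled
#' to the noise scale; remaining features are pure Gaussian noise. Column order
#' is a seeded permutation so planted features carry no positional signal; the
#' planted indices (after permutation) are recorded in the `"planted"`
#' attribute and via feature ids (`inf*`, `red*`, `noise*`).
#'
#' @param spec a [synthetic_spec()].
#' @return An [expression_dataset()] with attribute `"planted"`, a list with
#'   `informative`, `redundant` (1-based column indices) and the generating
#'   `spec`.
#' @export
generate_synthetic_omics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples; p <- spec$n_features
  ni <- spec$n_informative; nr <- spec$n_redundant_per_informative
  rho <- spec$redundancy_rho; sdn <- spec$noise_sd
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  cls <- factor(rep_len(seq_len(spec$n_classes), n))
  m <- matrix(stats::rnorm(n * p, sd = sdn), n, p)
  ids <- paste0("noise", seq_len(p))
  shift <- spec$class_separation * sdn
  k <- 0L
  inf_cols <- integer(0); red_cols <- integer(0)
  for (i in seq_len(ni)) {
    k <- k + 1L
    m[, k] <- m[, k] + shift * (as.integer(cls) - 1L)
    ids[k] <- paste0("inf", i)
    inf_cols <- c(inf_cols, k)
    parent <- m[, k]
    zp <- (parent - mean(parent)) / stats::sd(parent)
    for (r in seq_len(nr)) {
      k <- k + 1L
      m[, k] <- (rho * zp + sqrt(1 - rho^2) * stats::rnorm(n)) * sdn
      ids[k] <- paste0("red", i, "_", r)
      red_cols <- c(red_cols, k)
    }
  }
  perm <- sample.int(p)
  m <- m[, perm, drop = FALSE]
  ids <- ids[perm]
  pos <- order(perm)  # pos[j] = new column of old column j
  ds <- expression_dataset(m, cls, feature_ids = ids)
  attr(ds, "planted") <- list(informative = sort(pos[inf_cols]),
                              redundant = sort(pos[red_cols]),
                              spec = unclass(spec))
  ds
}

#' Stratified cross-validation folds
#'
#' Partitions samples into `k` disjoint test sets covering every sample exactly
#' once, with per-fold class proportions within one sample of the global
#' proportions. Deterministic under `seed`.
#'
#' @param ds an [expression_dataset()], or a factor of labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return A list of `k` elements, each `list(train = <int>, test = <int>)`.
#' @export
stratified_folds <- function(ds, k = 10, seed = 1) {
  labels <- if (inherits(ds, "expression_dataset")) ds$labels else factor(ds)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k))
    stop("class '", names(tab)[which(tab < k)[1L]], "' has fewer than k = ", k,
         " samples", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}
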