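#' Features-by-donors omics matrix with missingness mask and processing log
#'
#' Lightweight container used by the preprocessing and association stages.
#' `values` holds the data (proteins: positive abundances before log; RNA:
#' non-negative integer counts before transformation), `mask` marks entries
#' that are missing (and, after imputation, entries that were imputed), and
#' `log` records every transform applied with its parameters, so a pipeline
#' can be replayed from the log.
#'
#' @param values numeric matrix, features in rows, donors in columns.
#' @param type `"protein"` or `"rna"`.
#' @param features optional data.frame of feature annotation (first column
#'   feature id; RNA may carry `length` for TPM-style use).
#' @param batch optional character/factor of per-donor batch labels (RNA).
#' @param mask optional logical matrix of missing entries (defaults to
#'   `is.na(values)`).
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, type = c("protein", "rna"),
                         features = NULL, batch = NULL, mask = NULL) {
  type <- match.arg(type)
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature rownames and donor colnames", call. = FALSE)
  if (is.null(mask)) mask <- is.na(values)
  if (!identical(dim(mask), dim(values)))
    stop("mask dimensions must match values", call. = FALSE)
  if (!is.null(batch) && length(batch) != ncol(values))
    stop("batch labels must match donor count", call. = FALSE)
  if (is.null(features))
    features <- data.frame(feature_id = rownames(values),
                           stringsAsFactors = FALSE)
  structure(list(values = values, mask = mask, type = type,
                 features = features, batch = batch, log = list()),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d features x %d donors, %.1f%% missing, %d transforms\n",
              x$type, nrow(x$values), ncol(x$values),
              100 * mean(x$mask), length(x$log)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

log_transform_step <- function(om, step, ...) {
  om$log[[length(om$log) + 1L]] <- c(list(step = step), list(...))
  om
}

#' Ordered processing log of an omics matrix
#'
#' @param om an [omics_matrix].
#' @return List of transform records (step name plus parameters).
#' @export
processing_log <- function(om) om$log
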