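#' Construct an ASV count table
#'
#' The central community object: a non-negative integer count matrix with
#' samples as rows and amplicon sequence variants (ASVs) as columns, plus a
#' sample-to-group map. Everything downstream (diversity profiling,
#' differential screening, networks, the neutral model) consumes this class.
#'
#' @param counts numeric matrix, samples x ASVs, non-negative integers.
#'   Row names are sample ids, column names ASV ids; both must be unique.
#' @param groups group label per sample: either a named vector/factor (names
#'   matching `rownames(counts)`) or an unnamed vector in row order.
#' @return An object of class `asv_table`: a list with elements `counts`
#'   (integer matrix) and `groups` (factor named by sample).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("ASV1", "ASV2")))
#' asv_table(m, c("A", "B"))
#' @export
asv_table <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("ASV", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("sample and ASV ids must be unique", call. = FALSE)
  }
  if (any(counts < 0) || any(is.na(counts))) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(names(groups))) {
    if (length(groups) != nrow(counts)) {
      stop("'groups' must have one label per sample", call. = FALSE)
    }
    names(groups) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(groups))) {
    stop("every sample needs a group label", call. = FALSE)
  }
  groups <- factor(unname(unlist(groups[rownames(counts)])),
                   levels = unique(unname(unlist(groups[rownames(counts)]))))
  names(groups) <- rownames(counts)
  structure(list(counts = counts, groups = groups), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$groups)
  cat("groups: ",
      paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("total reads: %d (mean %.0f per sample)\n",
              sum(x$counts), mean(rowSums(x$counts))))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

sample_ids <- function(table) rownames(table$counts)
asv_ids <- function(table) colnames(table$counts)

# Coerce asv_table-or-matrix input to a plain counts matrix.
as_counts <- function(x) {
  if (inherits(x, "asv_table")) x$counts else as.matrix(x)
}

#' Subset an ASV table
#'
#' @param x an [asv_table()].
#' @param samples,asvs character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @param drop_empty_asvs drop ASVs with zero counts after subsetting.
#' @return An `asv_table`.
#' @export
subset_asv_table <- function(x, samples = NULL, asvs = NULL,
                             drop_empty_asvs = FALSE) {
  stopifnot(inherits(x, "asv_table"))
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  if (drop_empty_asvs) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  asv_table(counts, droplevels(x$groups[rownames(counts)]))
}
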