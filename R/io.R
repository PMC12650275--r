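# Plain-text readers/writers for the pipeline's tabular formats.
# ASV tables travel as TSV with ASVs as rows and samples as columns (the
# common deposition layout); taxonomy as TSV of 7 ranks; phenotypes and
# Ct tables as CSV with a header row.

#' Write / read an ASV table as TSV
#'
#' @param table an [asv_table()].
#' @param file path; the table is written ASVs x samples with an `asv_id`
#'   first column, plus a companion `<file>.groups.tsv` sample-to-group
#'   map.
#' @export
write_asv_table <- function(table, file) {
  stopifnot(inherits(table, "asv_table"))
  df <- data.frame(asv_id = asv_ids(table), t(table$counts),
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = sample_ids(table),
                     group = as.character(table$groups))
  write.table(meta, paste0(file, ".groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_asv_table
#' @param groups_file optional explicit path of the group map.
#' @export
read_asv_table <- function(file, groups_file = paste0(file, ".groups.tsv")) {
  df <- read.delim(file, check.names = FALSE)
  counts <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(counts) <- df[[1]]
  meta <- read.delim(groups_file)
  asv_table(counts, setNames(meta$group, meta$sample))
}

#' Write / read a taxonomy table as TSV
#'
#' Lineages are stored as `asv_id` plus a single semicolon-separated
#' 7-rank string.
#'
#' @param taxonomy data.frame of ranks, rownames = ASV ids.
#' @param file path.
#' @export
write_taxonomy <- function(taxonomy, file) {
  lineage <- apply(taxonomy, 1, paste, collapse = ";")
  write.table(data.frame(asv_id = rownames(taxonomy), lineage = lineage),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  parts <- strsplit(df$lineage, ";", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
    length(p) <- length(ranks)
    p
  })), stringsAsFactors = FALSE)
  colnames(out) <- ranks
  rownames(out) <- df$asv_id
  out
}

#' Write a labelled square distance matrix as TSV
#'
#' @param d symmetric matrix.
#' @param file path.
#' @export
write_distance <- function(d, file) {
  d <- as.matrix(d)
  write.table(data.frame(label = rownames(d), d, check.names = FALSE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a signed network as an edge-list TSV
#'
#' Columns: `node_a`, `node_b`, `weight`, `sign`.
#'
#' @param net a `signed_network`.
#' @param file path.
#' @export
write_edgelist <- function(net, file) {
  stopifnot(inherits(net, "signed_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency != 0,
               arr.ind = TRUE)
  w <- net$adjacency[idx]
  df <- data.frame(node_a = rownames(net$adjacency)[idx[, 1]],
                   node_b = colnames(net$adjacency)[idx[, 2]],
                   weight = w,
                   sign = ifelse(w > 0, "positive", "negative"))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
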