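#' Per-ASV differential abundance screen between two groups
#'
#' For each ASV, an ordinary linear model of
#' `log2(relative abundance + pseudocount)` on the group indicator; the
#' slope is the log2 fold change and its t-test gives the p-value. With
#' two groups this linear model is algebraically the pooled-variance
#' two-sample t-test, which is how it is computed (vectorized across
#' ASVs). Direction calls follow the screen's thresholds: `up` iff
#' `p < p_threshold` and `log2fc > fc_threshold`, `down` for the mirrored
#' condition, otherwise `ns`.
#'
#' @param table an [asv_table()].
#' @param contrast character of length 2, `c(groupA, groupB)`; `log2fc` is
#'   groupA minus groupB.
#' @param pseudocount added to relative abundances before log2; default is
#'   half the smallest nonzero relative abundance in the table.
#' @param p_threshold raw p-value cutoff (no multiple-testing correction
#'   by default, mirroring a raw-threshold screen).
#' @param fc_threshold fold-change cutoff; with `fc_scale = "log2"`
#'   (default) it is a |log2 FC| bound, with `"ratio"` a bound on the
#'   natural-scale ratio.
#' @param fc_scale see `fc_threshold`.
#' @param adjust optional p adjustment method (e.g. "BH"); `"none"` keeps
#'   raw p-values.
#' @return data.frame of class `differential_result` with columns
#'   `asv_id`, `log2fc`, `p`, `direction` and attributes `contrast`,
#'   `pseudocount`. ASVs with zero counts across both groups are excluded.
#' @export
fit_differential <- function(table, contrast, pseudocount = NULL,
                             p_threshold = 0.05, fc_threshold = 1,
                             fc_scale = c("log2", "ratio"),
                             adjust = "none") {
  stopifnot(inherits(table, "asv_table"), length(contrast) == 2)
  fc_scale <- match.arg(fc_scale)
  groups <- table$groups
  if (!all(contrast %in% levels(groups))) {
    stop("contrast groups not in table: ",
         paste(setdiff(contrast, levels(groups)), collapse = ", "),
         call. = FALSE)
  }
  in_a <- groups == contrast[1]
  in_b <- groups == contrast[2]
  if (sum(in_a) < 2 || sum(in_b) < 2) {
    stop("both contrast groups need >= 2 samples", call. = FALSE)
  }
  rel <- relative_abundance(table)
  if (is.null(pseudocount)) pseudocount <- min(rel[rel > 0]) / 2
  sub <- rel[in_a | in_b, , drop = FALSE]
  keep <- colSums(sub) > 0
  y <- log2(sub[, keep, drop = FALSE] + pseudocount)
  a <- y[in_a[in_a | in_b], , drop = FALSE]
  b <- y[in_b[in_a | in_b], , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  diff <- m1 - m2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- diff / se
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  # degenerate variance: all values equal -> no evidence, p = 1
  p[se == 0 & abs(diff) < 1e-12] <- 1
  p[se == 0 & abs(diff) >= 1e-12] <- 0
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  fc_ok <- if (fc_scale == "log2") abs(diff) > fc_threshold
           else 2^abs(diff) > fc_threshold
  direction <- ifelse(p < p_threshold & fc_ok & diff > 0, "up",
                ifelse(p < p_threshold & fc_ok & diff < 0, "down", "ns"))
  out <- data.frame(asv_id = colnames(y), log2fc = unname(diff),
                    p = unname(p), direction = unname(direction),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Count up- and down-regulated ASVs
#'
#' @param result a [fit_differential()] result.
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
classify_counts <- function(result) {
  c(n_up = sum(result$direction == "up"),
    n_down = sum(result$direction == "down"))
}

#' Union and intersection of differential ASV sets across contrasts
#'
#' @param results list of [fit_differential()] results.
#' @return List with `union` (ASVs significant in any contrast) and
#'   `intersection` (significant in every contrast).
#' @export
shared_differentials <- function(results) {
  if (length(results) < 2) stop("need >= 2 contrasts", call. = FALSE)
  sets <- lapply(results, function(r) r$asv_id[r$direction != "ns"])
  list(union = sort(unique(unlist(sets))),
       intersection = sort(Reduce(intersect, sets)))
}
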