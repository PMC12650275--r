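#' Construct a qPCR Ct table
#'
#' @param ct numeric matrix of Ct values, samples x genes.
#' @param efficiencies named vector of primer amplification efficiencies in
#'   percent, one per gene.
#' @param reference_gene internal-control gene used for normalization.
#' @param calibrator_group group whose mean delta-Ct defines expression 1.
#' @param groups group label per sample (named by sample or in row order).
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, efficiencies, reference_gene, calibrator_group,
                     groups) {
  ct <- as.matrix(ct)
  if (any(!is.finite(ct))) stop("Ct values must be finite", call. = FALSE)
  if (!all(colnames(ct) %in% names(efficiencies))) {
    stop("every gene needs an efficiency value", call. = FALSE)
  }
  if (any(efficiencies <= 0)) stop("efficiencies must be positive",
                                   call. = FALSE)
  if (!reference_gene %in% colnames(ct)) {
    stop("reference gene not in table: ", reference_gene, call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- rownames(ct)
  groups <- setNames(as.character(groups[rownames(ct)]), rownames(ct))
  if (!calibrator_group %in% groups) {
    stop("calibrator group not present: ", calibrator_group, call. = FALSE)
  }
  structure(list(ct = ct, efficiencies = efficiencies[colnames(ct)],
                 reference_gene = reference_gene,
                 calibrator_group = calibrator_group, groups = groups),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d samples x %d genes (reference %s, calibrator %s)\n",
              nrow(x$ct), ncol(x$ct), x$reference_gene, x$calibrator_group))
  invisible(x)
}

# Dunn's test of pairwise rank comparisons after Kruskal-Wallis, with the
# tie-corrected z statistic; returns a symmetric matrix of adjusted p.
dunn_pairwise <- function(values, groups, adjust = "bonferroni") {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  k <- length(lev)
  p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  pr <- c()
  pairs <- utils::combn(k, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ng[a] + 1 / ng[b]))
    z <- if (se == 0) 0 else (rbar[a] - rbar[b]) / se
    pr[j] <- 2 * pnorm(-abs(z))
  }
  pr <- pmin(1, stats::p.adjust(pr, method = adjust))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    p[a, b] <- p[b, a] <- pr[j]
  }
  diag(p) <- 1
  p
}

# Compact letter display by insert-and-absorb: start from one column
# holding all groups; every significant pair splits each column containing
# both; absorb columns that became subsets. Letters run alphabetically
# from the highest group mean.
compact_letters <- function(pairwise_p, means, alpha = 0.05) {
  groups <- rownames(pairwise_p)
  cols <- list(groups)
  pairs <- utils::combn(length(groups), 2)
  for (j in seq_len(ncol(pairs))) {
    a <- groups[pairs[1, j]]; b <- groups[pairs[2, j]]
    if (is.na(pairwise_p[a, b]) || pairwise_p[a, b] >= alpha) next
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (k in seq_along(new_cols)) {
        if (i != k && keep[k] &&
            all(new_cols[[i]] %in% new_cols[[k]]) &&
            (length(new_cols[[i]]) < length(new_cols[[k]]) || i > k)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- unique(new_cols[keep])
  }
  # order columns so the letter 'a' goes with the highest mean
  best <- vapply(cols, function(col) max(means[col]), numeric(1))
  cols <- cols[order(-best)]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    lab <- letters[i]
    for (g in cols[[i]]) {
      letters_out[g] <- paste0(letters_out[g], lab)
    }
  }
  letters_out[order(match(groups, groups))]
}

#' Normality-gated group comparison with compact-letter display
#'
#' Applies the trial's univariate procedure: Shapiro-Wilk normality per
#' group and Levene homogeneity across groups (both at `alpha_gate`) gate
#' into one-way ANOVA with Tukey HSD post hoc tests; otherwise
#' Kruskal-Wallis with Dunn's pairwise tests (Bonferroni-adjusted by
#' default). Pairwise significance at `alpha` is summarized as superscript
#' letters (insert-and-absorb), alphabetical from the highest group mean.
#'
#' Groups with fewer than 3 observations (Shapiro-Wilk undefined) or
#' constant values route to the nonparametric branch; fully degenerate
#' input (zero overall variance) short-circuits to omnibus p = 1 with all
#' letters "a".
#'
#' @param values numeric vector of per-sample measurements.
#' @param groups group label per value.
#' @param alpha pairwise significance level for the letter display.
#' @param alpha_gate level of the normality/homogeneity gate.
#' @param dunn_adjust p adjustment for Dunn's pairwise tests
#'   ("bonferroni", "holm", or "none").
#' @param trait optional trait name carried into the result.
#' @return List of class `group_comparison`: per-group `mean` and `sem`,
#'   `omnibus_p`, `pairwise_p` matrix, `letters`, `test_used`.
#' @export
gate_and_compare <- function(values, groups, alpha = 0.05,
                             alpha_gate = 0.05,
                             dunn_adjust = c("bonferroni", "holm", "none"),
                             trait = NULL) {
  dunn_adjust <- match.arg(dunn_adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  ng <- table(groups)
  if (any(ng < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(ng)[ng < 2], collapse = ", "), call. = FALSE)
  }
  means <- tapply(values, groups, mean)
  sems <- tapply(values, groups, function(v) sd(v) / sqrt(length(v)))
  lev <- levels(groups)

  if (var(values) == 0) {
    pw <- matrix(1, nlevels(groups), nlevels(groups),
                 dimnames = list(lev, lev))
    return(structure(list(trait = trait, mean = means, sem = sems,
                          omnibus_p = 1, pairwise_p = pw,
                          letters = setNames(rep("a", length(lev)), lev),
                          test_used = "nonparametric"),
                     class = "group_comparison"))
  }

  normal_ok <- all(vapply(lev, function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value > alpha_gate
  }, logical(1)))
  homo_ok <- tryCatch(
    car::leveneTest(values ~ groups, center = mean)[1, "Pr(>F)"] > alpha_gate,
    error = function(e) FALSE)

  if (normal_ok && homo_ok) {
    fit <- aov(values ~ groups)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$groups
    pw <- matrix(NA_real_, length(lev), length(lev),
                 dimnames = list(lev, lev))
    diag(pw) <- 1
    for (row in rownames(tk)) {
      ab <- strsplit(row, "-", fixed = TRUE)[[1]]
      pw[ab[1], ab[2]] <- pw[ab[2], ab[1]] <- tk[row, "p adj"]
    }
    test_used <- "parametric"
  } else {
    omnibus_p <- kruskal.test(values, groups)$p.value
    if (is.na(omnibus_p)) omnibus_p <- 1
    pw <- dunn_pairwise(values, groups, adjust = dunn_adjust)
    test_used <- "nonparametric"
  }
  structure(list(trait = trait, mean = means, sem = sems,
                 omnibus_p = omnibus_p, pairwise_p = pw,
                 letters = compact_letters(pw, means, alpha = alpha),
                 test_used = test_used),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!is.null(x$trait)) cat("trait:", x$trait, "\n")
  df <- data.frame(mean = as.numeric(x$mean), sem = as.numeric(x$sem),
                   letter = x$letters[names(x$mean)],
                   row.names = names(x$mean))
  print(df)
  cat(sprintf("omnibus p = %.4g (%s)\n", x$omnibus_p, x$test_used))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Livak quantification: per sample, `dCt = Ct_target - Ct_reference`;
#' `ddCt = dCt - mean(dCt over calibrator samples)` (arithmetic mean);
#' expression `= 2^-ddCt`. The calibrator group's geometric-mean
#' expression is 1 by construction.
#'
#' @param ct a [ct_table()].
#' @param target_gene gene to quantify.
#' @return Named numeric vector of per-sample relative expression.
#' @export
ddct_expression <- function(ct, target_gene) {
  stopifnot(inherits(ct, "ct_table"))
  if (!target_gene %in% colnames(ct$ct)) {
    stop("gene not in table: ", target_gene, call. = FALSE)
  }
  dct <- ct$ct[, target_gene] - ct$ct[, ct$reference_gene]
  cal <- ct$groups == ct$calibrator_group
  ddct <- dct - mean(dct[cal])
  2^(-ddct)
}

#' Primer efficiency gate
#'
#' Flags genes whose amplification efficiency falls outside the inclusive
#' 90-110% acceptance window. Advisory: failing genes raise a warning, not
#' an error.
#'
#' @param ct a [ct_table()].
#' @return Named logical vector, `TRUE` = pass.
#' @export
efficiency_gate <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  pass <- ct$efficiencies >= 90 & ct$efficiencies <= 110
  if (any(!pass)) {
    warning("efficiency outside 90-110%: ",
            paste(sprintf("%s (%.2f%%)", names(pass)[!pass],
                          ct$efficiencies[!pass]), collapse = ", "),
            call. = FALSE)
  }
  pass
}
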