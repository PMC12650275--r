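#' Fit the Sloan neutral community model
#'
#' Sloan's neutral prediction: a taxon with mean relative abundance `p`
#' occurs in a sample (above the detection limit `d = 1/N`, `N` = mean
#' sample depth) with probability `1 - pbeta(d, Nm * p, Nm * (1 - p))`,
#' where `Nm` is the product of metacommunity size and migration rate.
#' `Nm` is fitted by least squares between observed and predicted
#' occurrence frequencies (bounded search over `[1, 1e6]`), the fit
#' quality is `R^2 = 1 - SSE/SST` (negative for fits worse than the mean
#' frequency), and the 95% band is the Wilson binomial interval of the
#' predicted frequency at the sample count.
#'
#' @param table an [asv_table()] or counts matrix (samples x taxa).
#' @param nm_range search interval for `Nm`.
#' @return Object of class `ncm_fit`: `Nm`, `m` (`Nm / N`), `r_squared`,
#'   `N`, `detection_limit`, `degenerate` flag, and `table` (per-taxon
#'   `p`, `obs_freq`, `pred_freq`, `lower`, `upper`).
#' @seealso [simulate_ncm()] for the matching simulator.
#' @export
fit_ncm <- function(table, nm_range = c(1, 1e6)) {
  counts <- as_counts(table)
  if (nrow(counts) < 3) stop("need >= 3 samples", call. = FALSE)
  rel <- relative_abundance(counts)
  p <- colMeans(rel)
  keep <- p > 0
  p <- p[keep]
  if (length(p) < 5) stop("need >= 5 taxa with nonzero mean abundance",
                          call. = FALSE)
  obs <- colMeans(counts[, keep, drop = FALSE] > 0)
  N <- mean(rowSums(counts))
  d <- 1 / N
  pred_at <- function(nm) 1 - pbeta(d, nm * p, nm * (1 - p))
  sse <- function(log_nm) sum((obs - pred_at(exp(log_nm)))^2)
  opt <- optimize(sse, interval = log(nm_range))
  nm <- exp(opt$minimum)
  pred <- pred_at(nm)
  sst <- sum((obs - mean(obs))^2)
  degenerate <- all(obs == 1) || sst == 0
  r2 <- if (sst == 0) NA_real_ else 1 - opt$objective / sst
  if (degenerate) {
    warning("saturated occurrence frequencies; fit is degenerate",
            call. = FALSE)
  }
  band <- wilson_interval(pred, nrow(counts))
  structure(list(
    Nm = nm, m = nm / N, r_squared = r2, N = N, detection_limit = d,
    degenerate = degenerate,
    table = data.frame(taxon = names(p), p = unname(p),
                       obs_freq = unname(obs), pred_freq = unname(pred),
                       lower = unname(band[, "lower"]),
                       upper = unname(band[, "upper"]),
                       row.names = NULL, stringsAsFactors = FALSE)),
    class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.1f  (m = %.4g, N = %.0f)\n", x$Nm, x$m, x$N))
  cat(sprintf("  R^2 = %.3f over %d taxa%s\n", x$r_squared,
              nrow(x$table), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
summary.ncm_fit <- function(object, ...) {
  within_band <- with(object$table, mean(obs_freq >= lower &
                                           obs_freq <= upper))
  out <- c(Nm = object$Nm, m = object$m, r_squared = object$r_squared,
           N = object$N, n_taxa = nrow(object$table),
           frac_within_band = within_band)
  print.ncm_fit(object)
  cat(sprintf("  %.1f%% of taxa within the 95%% prediction band\n",
              100 * within_band))
  invisible(out)
}

#' @export
coef.ncm_fit <- function(object, ...) {
  c(Nm = object$Nm, m = object$m)
}

#' Predicted occurrence frequency at new mean abundances
#'
#' @param object an `ncm_fit`.
#' @param newdata numeric vector of mean relative abundances; defaults to
#'   the fitted taxa.
#' @param ... unused.
#' @export
predict.ncm_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$table$p else newdata
  1 - pbeta(object$detection_limit, object$Nm * p,
            object$Nm * (1 - p))
}

#' Occurrence-frequency plot of a neutral model fit
#'
#' Observed occurrence frequency against log10 mean relative abundance,
#' with the fitted neutral curve and its 95% band.
#'
#' @param x an `ncm_fit`.
#' @param ... passed to `plot`.
#' @export
plot.ncm_fit <- function(x, ...) {
  tab <- x$table[order(x$table$p), ]
  plot(log10(tab$p), tab$obs_freq, pch = 16, cex = 0.6,
       col = "grey35", xlab = "log10 mean relative abundance",
       ylab = "occurrence frequency",
       main = sprintf("NCM fit: Nm = %.0f, R2 = %.2f", x$Nm, x$r_squared),
       ...)
  lines(log10(tab$p), tab$pred_freq, col = "blue", lwd = 2)
  lines(log10(tab$p), tab$lower, col = "blue", lty = 2)
  lines(log10(tab$p), tab$upper, col = "blue", lty = 2)
  invisible(x)
}

#' Simulate a community from the Sloan neutral model
#'
#' Metacommunity relative abundances are drawn lognormal (normalized);
#' per sample, each taxon's local relative abundance is Beta-distributed
#' around its metacommunity abundance per the Sloan stationary
#' distribution (`Beta(Nm p, Nm (1 - p))`), renormalized, and counts are
#' multinomial at the sample depth. Serves as the self-consistency oracle
#' for [fit_ncm()].
#'
#' @param n_taxa,n_samples community dimensions.
#' @param Nm neutral migration parameter.
#' @param depth reads per sample.
#' @param seed RNG seed.
#' @param meta_sdlog lognormal spread of metacommunity abundances.
#' @return An [asv_table()] (all samples in one group "sim").
#' @export
simulate_ncm <- function(n_taxa, Nm, depth, n_samples, seed = 1L,
                         meta_sdlog = 2) {
  stopifnot(n_taxa > 0, Nm > 0, depth > 0, n_samples > 0)
  with_seed(seed, {
    meta <- rlnorm(n_taxa, 0, meta_sdlog)
    meta <- meta / sum(meta)
    counts <- matrix(0L, n_samples, n_taxa,
                     dimnames = list(paste0("sim_", seq_len(n_samples)),
                                     sprintf("taxon%04d", seq_len(n_taxa))))
    for (s in seq_len(n_samples)) {
      x <- rbeta(n_taxa, Nm * meta, Nm * (1 - meta))
      x[!is.finite(x)] <- 0
      if (sum(x) == 0) x[which.max(meta)] <- 1
      counts[s, ] <- rmultinom(1L, depth, x)[, 1L]
    }
    asv_table(counts, setNames(rep("sim", n_samples), rownames(counts)))
  })
}
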