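#' Configuration for the synthetic feeding-trial generator
#'
#' Bundles every knob of the synthetic-data module. Defaults emulate a
#' 4-diet x 3-replicate trial profiled at ~33,000 reads per sample over
#' ~1,500 ASVs dominated by Proteobacteria, Actinobacteria, Chloroflexi,
#' Firmicutes and Fusobacteria, with planted group-differential ASVs and
#' correlated ASV modules tied to phenotype blocks.
#'
#' @param n_groups number of diet groups (first group is the reference).
#' @param n_reps replicates (cages/fish) per group.
#' @param n_asvs number of ASVs in the emitted table.
#' @param depth_mean expected sequencing depth per sample; realized depths
#'   are Poisson around this value.
#' @param n_diff_asvs planted differential ASVs per contrast (each
#'   non-reference group vs the reference); planted sets are disjoint
#'   across contrasts.
#' @param planted_log2fc planted effect size, log2 units; signs alternate
#'   up/down within each contrast.
#' @param n_modules number of planted correlated ASV modules.
#' @param module_size ASVs per module.
#' @param n_linked_blocks how many modules are tied to a phenotype trait
#'   block (modules `1..n_linked_blocks`); defaults to one linked module,
#'   or none when no modules are planted.
#' @param module_phenotype_r target correlation between a linked module's
#'   latent factor and its phenotype block traits.
#' @param noise_sd lognormal dispersion of per-cell latent abundance.
#' @param phylum_weights named numeric vector of expected phylum shares;
#'   must sum to 1.
#' @param occupancy_shape1,occupancy_shape2 Beta parameters of the per-ASV
#'   occupancy probability (most ASVs absent from most samples).
#' @param seed RNG seed; all generator randomness derives from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_groups = 4L,
                         n_reps = 3L,
                         n_asvs = 1500L,
                         depth_mean = 33000,
                         n_diff_asvs = 30L,
                         planted_log2fc = 3,
                         n_modules = 3L,
                         module_size = 12L,
                         n_linked_blocks = NULL,
                         module_phenotype_r = 0.8,
                         noise_sd = 0.6,
                         phylum_weights = c(
                           Proteobacteria = 0.35, Actinobacteria = 0.20,
                           Chloroflexi = 0.15, Firmicutes = 0.15,
                           Fusobacteria = 0.10, Bacteroidetes = 0.05),
                         occupancy_shape1 = 0.4,
                         occupancy_shape2 = 1.2,
                         seed = 1L) {
  for (nm in c("n_groups", "n_reps", "n_asvs")) {
    stop_if_not_scalar_count(get(nm), nm)
  }
  if (n_groups < 2) stop("need at least 2 groups", call. = FALSE)
  if (depth_mean <= 0 || noise_sd < 0) {
    stop("depth_mean must be positive and noise_sd non-negative",
         call. = FALSE)
  }
  if (is.null(n_linked_blocks)) n_linked_blocks <- min(1L, n_modules)
  if (n_diff_asvs < 0 || n_modules < 0 || module_size < 0 ||
      n_linked_blocks < 0 || n_linked_blocks > n_modules) {
    stop("planted-structure counts must be non-negative and ",
         "n_linked_blocks <= n_modules", call. = FALSE)
  }
  if (n_modules > 0 && module_size < 2) {
    stop("module_size must be >= 2 when modules are planted", call. = FALSE)
  }
  if (module_phenotype_r < 0 || module_phenotype_r > 1) {
    stop("module_phenotype_r must lie in [0, 1]", call. = FALSE)
  }
  n_planted <- n_diff_asvs * (n_groups - 1L) + n_modules * module_size
  if (n_planted > n_asvs) {
    stop(sprintf(paste0(
      "infeasible config: %d planted ASVs (%d differential per contrast x ",
      "%d contrasts + %d modules x %d) exceed n_asvs = %d"),
      n_planted, n_diff_asvs, n_groups - 1L, n_modules, module_size, n_asvs),
      call. = FALSE)
  }
  if (abs(sum(phylum_weights) - 1) > 1e-9) {
    stop("phylum_weights must sum to 1", call. = FALSE)
  }
  if (any(phylum_weights < 0) || is.null(names(phylum_weights))) {
    stop("phylum_weights must be a named non-negative vector", call. = FALSE)
  }
  structure(list(
    n_groups = as.integer(n_groups), n_reps = as.integer(n_reps),
    n_asvs = as.integer(n_asvs), depth_mean = depth_mean,
    n_diff_asvs = as.integer(n_diff_asvs), planted_log2fc = planted_log2fc,
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    n_linked_blocks = as.integer(n_linked_blocks),
    module_phenotype_r = module_phenotype_r, noise_sd = noise_sd,
    phylum_weights = phylum_weights,
    occupancy_shape1 = occupancy_shape1,
    occupancy_shape2 = occupancy_shape2,
    seed = as.integer(seed)), class = "synth_config")
}

group_labels <- function(n_groups) {
  if (n_groups == 4L) c("CK", "HFD", "LSF", "HSF")
  else c("CK", paste0("G", seq_len(n_groups - 1L)))
}

# Derived sub-seeds keep the three generators independent but reproducible.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7L + offset) %% (.Machine$integer.max - 1))
}

#' Generate a synthetic ASV table with planted ground truth
#'
#' Counts follow a lognormal-latent / multinomial-sampling model: each ASV
#' has a lognormal baseline abundance and a Beta-distributed occupancy
#' probability (so most ASVs are absent from most samples); planted
#' differential ASVs get a `planted_log2fc` shift in their contrast group;
#' planted module ASVs share a per-sample latent factor; per-sample read
#' totals are Poisson around `depth_mean` and cells are multinomial draws.
#'
#' @param config a [synth_config()].
#' @return A list with elements `table` (an [asv_table()]), `taxonomy`
#'   (data.frame of 7 ranks, rownames = ASV ids), and `truth` (class
#'   `synth_truth`: planted differential sets per contrast, module
#'   membership, module-trait link labels, latent module factors, and the
#'   group assignment).
#' @export
generate_asv_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  groups <- rep(group_labels(cfg$n_groups), each = cfg$n_reps)
  n_samples <- length(groups)
  sample_ids <- paste0(groups, "_", rep(seq_len(cfg$n_reps), cfg$n_groups))
  asv_ids <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
  contrasts <- group_labels(cfg$n_groups)[-1L]

  out <- with_seed(cfg$seed, {
    # planted feature assignment (disjoint)
    idx <- seq_len(cfg$n_asvs)
    diff_sets <- list()
    cursor <- 0L
    for (g in contrasts) {
      take <- if (cfg$n_diff_asvs > 0) idx[cursor + seq_len(cfg$n_diff_asvs)]
              else integer(0)
      cursor <- cursor + cfg$n_diff_asvs
      sgn <- rep_len(c(1, -1), length(take))
      diff_sets[[g]] <- data.frame(
        asv_id = asv_ids[take],
        log2fc = sgn * cfg$planted_log2fc,
        stringsAsFactors = FALSE)
    }
    module_membership <- character(0)
    module_idx <- integer(0)
    if (cfg$n_modules > 0) {
      module_idx <- idx[cursor + seq_len(cfg$n_modules * cfg$module_size)]
      module_membership <- setNames(
        rep(paste0("M", seq_len(cfg$n_modules)), each = cfg$module_size),
        asv_ids[module_idx])
    }
    planted_idx <- c(unlist(lapply(diff_sets, function(d)
      match(d$asv_id, asv_ids))), module_idx)

    # latent abundance model; planted differential ASVs sit on
    # moderately abundant baselines so their planted effect is observable
    # at the trial's sequencing depth; planted features are always present
    mu <- rnorm(cfg$n_asvs, 0, 2)
    diff_idx <- setdiff(planted_idx, module_idx)
    mu[diff_idx] <- rnorm(length(diff_idx), 1, 1)
    occ <- rbeta(cfg$n_asvs, cfg$occupancy_shape1, cfg$occupancy_shape2)
    occ[planted_idx] <- 1
    factors <- matrix(rnorm(n_samples * max(cfg$n_modules, 1L)),
                      n_samples, max(cfg$n_modules, 1L))
    if (ncol(factors) > 1) {
      # planted modules are distinct by design: orthogonalize the latent
      # factors so no chance in-sample correlation ties one module's
      # signal to another's phenotype block
      factors <- qr.Q(qr(factors)) * sqrt(n_samples)
    }
    rownames(factors) <- sample_ids
    colnames(factors) <- paste0("M", seq_len(ncol(factors)))

    log_lambda <- matrix(rep(mu, each = n_samples), n_samples, cfg$n_asvs)
    for (g in contrasts) {
      d <- diff_sets[[g]]
      if (nrow(d) == 0) next
      rows <- groups == g
      cols <- match(d$asv_id, asv_ids)
      log_lambda[rows, cols] <- log_lambda[rows, cols] +
        rep(d$log2fc * log(2), each = sum(rows))
    }
    if (cfg$n_modules > 0) {
      for (m in seq_len(cfg$n_modules)) {
        cols <- module_idx[(m - 1L) * cfg$module_size + seq_len(cfg$module_size)]
        log_lambda[, cols] <- log_lambda[, cols] + factors[, m]
      }
    }
    log_lambda <- log_lambda +
      matrix(rnorm(n_samples * cfg$n_asvs, 0, cfg$noise_sd),
             n_samples, cfg$n_asvs)
    present <- matrix(rbinom(n_samples * cfg$n_asvs, 1L,
                             rep(occ, each = n_samples)),
                      n_samples, cfg$n_asvs)
    lambda <- present * exp(log_lambda)

    depths <- rpois(n_samples, cfg$depth_mean)
    counts <- matrix(0L, n_samples, cfg$n_asvs,
                     dimnames = list(sample_ids, asv_ids))
    for (s in seq_len(n_samples)) {
      if (sum(lambda[s, ]) == 0) lambda[s, 1L] <- 1  # guard: never all-absent
      counts[s, ] <- rmultinom(1L, depths[s], lambda[s, ])[, 1L]
    }

    # taxonomy: phylum from weights, lower ranks synthesized within phylum
    phyla <- sample(names(cfg$phylum_weights), cfg$n_asvs, replace = TRUE,
                    prob = cfg$phylum_weights)
    genus_pool <- paste0("genus", seq_len(max(25L, cfg$n_asvs %/% 20L)))
    genus <- paste0(substr(phyla, 1, 4), "_", sample(genus_pool, cfg$n_asvs,
                                                     replace = TRUE))
    species <- ifelse(runif(cfg$n_asvs) < 0.3, "Unassigned",
                      paste0(genus, "_sp", sample(1:5, cfg$n_asvs, TRUE)))
    taxonomy <- data.frame(
      kingdom = "Bacteria",
      phylum = phyla,
      class = paste0(phyla, "_c", sample(1:3, cfg$n_asvs, TRUE)),
      order = paste0(phyla, "_o", sample(1:5, cfg$n_asvs, TRUE)),
      family = paste0(phyla, "_f", sample(1:8, cfg$n_asvs, TRUE)),
      genus = genus,
      species = species,
      row.names = asv_ids, stringsAsFactors = FALSE)

    links <- setNames(rep(NA_character_, cfg$n_modules),
                      paste0("M", seq_len(cfg$n_modules), recycle0 = TRUE))
    if (cfg$n_linked_blocks > 0) {
      links[seq_len(cfg$n_linked_blocks)] <-
        paste0("block", seq_len(cfg$n_linked_blocks))
    }
    truth <- structure(list(
      diff_asvs = diff_sets,
      module_membership = module_membership,
      module_trait_links = links,
      module_factors = factors[, seq_len(max(cfg$n_modules, 1L)),
                               drop = FALSE],
      group_assignment = setNames(groups, sample_ids),
      config = cfg), class = "synth_truth")

    list(table = asv_table(counts, setNames(groups, sample_ids)),
         taxonomy = taxonomy, truth = truth)
  })
  out
}

# The study-style trait panel: 6 biochemical markers, 3 histomorphometry
# metrics, 17 relative gene-expression traits.
trait_panel <- function() {
  data.frame(
    trait = c("MDA", "H2O2", "GSH", "SOD", "CAT", "T_AOC",
              "VH", "MT", "GC",
              "nrf2", "sod", "gpx1", "gpx8", "cat", "zo1", "zo2", "occludin",
              "claudin12", "nfkb", "tgfb1", "tlr5", "tlr8", "tnfa", "il15",
              "il8", "il1b"),
    category = c(rep("Gut health", 6), rep("Gut development", 3),
                 rep("Gut health", 17)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic phenotype matrix tied to planted modules
#'
#' Emits the study-style 26-trait panel (biochemistry, histomorphometry,
#' gene expression). Traits of a linked block equal
#' `r * factor + sqrt(1 - r^2) * noise` against their module's latent
#' factor (`r = module_phenotype_r`); all other traits carry independent
#' random group effects plus unit noise.
#'
#' @param truth `synth_truth` from [generate_asv_table()].
#' @param config the same [synth_config()].
#' @param block_size traits per linked block.
#' @return Numeric matrix samples x traits with attributes `categories`
#'   (trait -> "Gut health"/"Gut development") and `trait_blocks`
#'   (trait -> planted block label, NA for free traits).
#' @export
generate_phenotypes <- function(truth, config, block_size = 3L) {
  if (!inherits(truth, "synth_truth")) {
    stop("'truth' must come from generate_asv_table()", call. = FALSE)
  }
  stopifnot(inherits(config, "synth_config"))
  panel <- trait_panel()
  n_traits <- nrow(panel)
  samples <- names(truth$group_assignment)
  n_samples <- length(samples)
  groups <- truth$group_assignment
  r <- config$module_phenotype_r

  with_seed(sub_seed(config$seed, 1L), {
    phen <- matrix(rnorm(n_samples * n_traits), n_samples, n_traits,
                   dimnames = list(samples, panel$trait))
    blocks <- setNames(rep(NA_character_, n_traits), panel$trait)
    linked <- which(!is.na(truth$module_trait_links))
    needed <- length(linked) * block_size
    if (needed > n_traits) stop("too many linked blocks for the trait panel",
                                call. = FALSE)
    for (k in seq_along(linked)) {
      m <- linked[k]
      cols <- (k - 1L) * block_size + seq_len(block_size)
      f <- scale(truth$module_factors[samples, m])[, 1L]
      phen[, cols] <- r * f + sqrt(1 - r^2) * phen[, cols]
      blocks[cols] <- truth$module_trait_links[m]
    }
    # free traits: planted group effects
    free <- setdiff(seq_len(n_traits), seq_len(needed))
    for (j in free) {
      eff <- rnorm(nlevels(factor(groups)))
      phen[, j] <- phen[, j] + eff[as.integer(factor(groups))]
    }
    attr(phen, "categories") <- setNames(panel$category, panel$trait)
    attr(phen, "trait_blocks") <- blocks
    phen
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference gene `rpl17` has a group-invariant expected Ct; target genes
#' get per-gene baselines in the 22-28 cycle range, optional planted log2
#' fold changes (one cycle of Ct per doubling), and per-gene amplification
#' efficiencies drawn uniformly in 85-115%.
#'
#' @param config a [synth_config()].
#' @param effects optional data.frame with columns `gene`, `group`,
#'   `log2fc`: planted expression changes relative to the calibrator group.
#' @param ct_sd within-group Ct noise (cycles).
#' @return A [ct_table()] object.
#' @export
generate_ct_table <- function(config, effects = NULL, ct_sd = 0.1) {
  stopifnot(inherits(config, "synth_config"))
  genes <- c("rpl17", trait_panel()$trait[10:26])
  groups <- rep(group_labels(config$n_groups), each = config$n_reps)
  sample_ids <- paste0(groups, "_",
                       rep(seq_len(config$n_reps), config$n_groups))
  with_seed(sub_seed(config$seed, 2L), {
    base <- c(rpl17 = 18, setNames(runif(length(genes) - 1L, 22, 28),
                                   genes[-1L]))
    ct <- matrix(rnorm(length(sample_ids) * length(genes), 0, ct_sd),
                 length(sample_ids), length(genes),
                 dimnames = list(sample_ids, genes))
    ct <- sweep(ct, 2L, base, "+")
    if (!is.null(effects)) {
      for (i in seq_len(nrow(effects))) {
        g <- effects$gene[i]
        if (!g %in% genes) stop("unknown gene in effects: ", g, call. = FALSE)
        rows <- groups == effects$group[i]
        ct[rows, g] <- ct[rows, g] - effects$log2fc[i]
      }
    }
    ct <- pmin(pmax(ct, 15), 35)
    eff <- setNames(runif(length(genes), 85, 115), genes)
    ct_table(ct, efficiencies = eff, reference_gene = "rpl17",
             calibrator_group = group_labels(config$n_groups)[1L],
             groups = setNames(groups, sample_ids))
  })
}
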