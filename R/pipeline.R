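#' Run the full analysis pipeline on a synthetic trial
#'
#' Executes the stages in order -- community profiles (rarefaction, alpha
#' diversity, Bray-Curtis + PCoA, group partition), group statistics
#' (phenotype comparisons, qPCR quantification), differential ASV
#' screening per contrast, module-phenotype linking with threshold
#' sensitivity, ecological network topology with a random-network null
#' and module-pair similarity, the neutral community model, and the
#' functional projection (when a mapping is supplied) -- and writes one
#' CSV/TSV/JSON artifact per stage plus an md5 manifest. Reruns with the
#' same config reproduce identical checksums.
#'
#' @param config a [synth_config()] describing the trial to simulate.
#' @param outdir output directory (created if missing).
#' @param thresholds named list overriding any of: `rho` (0.7), `rho_alt`
#'   (0.8), `st` (0.995), `p` (0.05), `fc` (1), `mantel_r` (0.3),
#'   `mantel_perms` (199), `n_rand` (50), `n_phen_blocks` (10).
#' @param ko_map optional [ko_mapping()] for the functional stage.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config = synth_config(), outdir,
                         thresholds = list(), ko_map = NULL) {
  stopifnot(inherits(config, "synth_config"))
  th <- utils::modifyList(list(rho = 0.7, rho_alt = 0.8, st = 0.995,
                               p = 0.05, fc = 1, mantel_r = 0.3,
                               mantel_perms = 199L, n_rand = 50L,
                               n_phen_blocks = 10L), thresholds)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("gutlink pipeline, seed %d", config$seed),
                 sprintf("thresholds: %s",
                         paste(names(th), unlist(th), sep = "=",
                               collapse = ", ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # synthesis
  synth <- stage("synth", generate_asv_table(config))
  phen <- stage("synth", generate_phenotypes(synth$truth, config))
  ct <- stage("synth", generate_ct_table(config))
  write_asv_table(synth$table, file.path(outdir, "asv_table.tsv"))
  write_taxonomy(synth$taxonomy, file.path(outdir, "taxonomy.tsv"))
  write.csv(data.frame(sample = rownames(phen), phen, check.names = FALSE),
            file.path(outdir, "phenotypes.csv"), row.names = FALSE)

  # community profiles
  profiles <- stage("profiles", {
    rare <- rarefy(synth$table, seed = config$seed)
    alpha <- alpha_diversity(rare)
    bc <- bray_curtis(rare)
    ord <- pcoa(bc, n_axes = 2)
    part <- group_asv_partition(synth$table)
    write.csv(alpha, file.path(outdir, "alpha_diversity.csv"),
              row.names = FALSE)
    write_distance(bc, file.path(outdir, "bray_curtis.tsv"))
    write.csv(data.frame(sample = rownames(ord$coordinates),
                         ord$coordinates,
                         check.names = FALSE),
              file.path(outdir, "pcoa.csv"), row.names = FALSE)
    write.csv(data.frame(group = names(part$total), total = part$total,
                         unique = part$unique_to_group,
                         share_pct = part$share_pct),
              file.path(outdir, "partition.csv"), row.names = FALSE)
    list(rarefied = rare, alpha = alpha, bray_curtis = bc,
         ordination = ord, partition = part)
  })

  # group statistics on phenotypes + qPCR quantification
  stats_res <- stage("stats", {
    comps <- lapply(colnames(phen), function(tr)
      gate_and_compare(phen[, tr], synth$truth$group_assignment,
                       trait = tr))
    names(comps) <- colnames(phen)
    tidy <- do.call(rbind, lapply(comps, function(cmp) {
      data.frame(trait = cmp$trait, group = names(cmp$mean),
                 mean = as.numeric(cmp$mean), sem = as.numeric(cmp$sem),
                 letter = cmp$letters[names(cmp$mean)],
                 test_used = cmp$test_used, p = cmp$omnibus_p,
                 row.names = NULL)
    }))
    write.csv(tidy, file.path(outdir, "group_comparisons.csv"),
              row.names = FALSE)
    gate <- efficiency_gate(ct)
    targets <- setdiff(colnames(ct$ct), ct$reference_gene)
    expr <- sapply(targets, function(g) ddct_expression(ct, g))
    write.csv(data.frame(sample = rownames(expr), expr,
                         check.names = FALSE),
              file.path(outdir, "relative_expression.csv"),
              row.names = FALSE)
    list(comparisons = comps, tidy = tidy, efficiency_pass = gate,
         expression = expr)
  })

  # differential screen, each non-reference group vs the reference
  diff_res <- stage("differential", {
    ref <- levels(synth$table$groups)[1]
    res <- lapply(setdiff(levels(synth$table$groups), ref), function(g)
      fit_differential(synth$table, c(g, ref), p_threshold = th$p,
                       fc_threshold = th$fc))
    names(res) <- setdiff(levels(synth$table$groups), ref)
    all_rows <- do.call(rbind, lapply(names(res), function(g)
      cbind(contrast = paste0(g, "_vs_", ref), res[[g]])))
    write.csv(all_rows, file.path(outdir, "differential.csv"),
              row.names = FALSE)
    shared <- shared_differentials(res)
    res$shared <- shared
    res
  })

  # module mining and phenotype linking on the differential union set
  linking_res <- stage("linking", {
    union_set <- diff_res$shared$union
    if (length(union_set) < 4) {
      log_lines <<- c(log_lines,
                      "linking: < 4 differential ASVs; stage skipped")
      NULL
    } else {
      abund <- relative_abundance(synth$table)[, union_set, drop = FALSE]
      net <- suppressWarnings(spearman_adjacency(abund, th$rho))
      mods <- detect_modules(net)
      ids <- setdiff(unique(mods), "unassigned")
      mes <- lapply(ids, function(m)
        module_eigenvector(abund, names(mods)[mods == m], id = m))
      names(mes) <- ids
      pes <- phenotype_modules(phen,
                               min(th$n_phen_blocks, ncol(phen)))
      links <- if (length(mes)) {
        link_modules(mes, pes, abundances = abund,
                     r_threshold = th$mantel_r, p_threshold = th$p,
                     n_perm = th$mantel_perms, seed = config$seed)
      } else NULL
      sens <- sensitivity_check(abund, th$rho, th$rho_alt)
      if (!is.null(links)) {
        write.csv(as.data.frame(links),
                  file.path(outdir, "link_report.csv"), row.names = FALSE)
      }
      write.table(data.frame(asv_id = names(mods), module = mods),
                  file.path(outdir, "module_membership.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(network = net, modules = mods, mes = mes, phen_eigens = pes,
           links = links, sensitivity = sens)
    }
  })

  # whole-community ecological network at the St threshold
  network_res <- stage("network", {
    prevalent <- colMeans(synth$table$counts > 0) >= 0.5
    abund <- relative_abundance(synth$table)[, prevalent, drop = FALSE]
    net <- suppressWarnings(spearman_adjacency(abund, th$st))
    n_edges <- sum(net$adjacency[upper.tri(net$adjacency)] != 0)
    if (n_edges == 0) {
      log_lines <<- c(log_lines, sprintf(
        "network: no edges at St = %.3f over %d prevalent ASVs",
        th$st, sum(prevalent)))
      list(network = net, topology = NULL, null = NULL, similarity = NULL)
    } else {
      topo <- topology(net)
      null <- random_null(net, n_rand = th$n_rand, seed = config$seed)
      sim <- if (!is.null(linking_res)) {
        alt_mods <- detect_modules(
          suppressWarnings(spearman_adjacency(
            relative_abundance(synth$table)[, diff_res$shared$union,
                                            drop = FALSE], th$rho_alt)))
        module_similarity(list(base = linking_res$modules,
                               alt = alt_mods))
      } else NULL
      write_edgelist(net, file.path(outdir, "network_edges.tsv"))
      write.csv(data.frame(metric = c("n_nodes", "n_edges", "positive_pct",
                                      "negative_pct", "avg_degree",
                                      "avg_clustering", "modularity",
                                      "n_modules", "avg_path_distance"),
                           value = c(topo$n_nodes, topo$n_edges,
                                     topo$positive_pct, topo$negative_pct,
                                     topo$avg_degree, topo$avg_clustering,
                                     topo$modularity, topo$n_modules,
                                     topo$avg_path_distance)),
                file.path(outdir, "network_topology.csv"),
                row.names = FALSE)
      list(network = net, topology = topo, null = null, similarity = sim)
    }
  })

  # neutral community model
  ncm_res <- stage("ncm", {
    fit <- suppressWarnings(fit_ncm(synth$table))
    write.csv(fit$table, file.path(outdir, "ncm_fit.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(Nm = fit$Nm, m = fit$m,
                              r_squared = fit$r_squared),
                         file.path(outdir, "ncm_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  # optional functional projection
  func_res <- if (!is.null(ko_map)) {
    stage("function", {
      genus_tab <- aggregate_taxa(synth$table, synth$taxonomy, "genus")
      rel <- sweep(genus_tab, 1, rowSums(genus_tab), "/")
      proj <- suppressMessages(project_ko(rel, ko_map))
      metab <- suppressMessages(
        filter_metabolism(proj, ko_map$hierarchy))
      dp <- if (ncol(metab) > 0) {
        differential_pathways(metab, synth$truth$group_assignment)
      } else NULL
      if (!is.null(dp)) {
        write.csv(dp, file.path(outdir, "pathway_tests.csv"),
                  row.names = FALSE)
      }
      list(projected = proj, metabolism = metab, tests = dp)
    })
  } else NULL

  writeLines(log_lines, file.path(outdir, "run.log"))
  files <- setdiff(list.files(outdir, full.names = TRUE),
                   file.path(outdir, "manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA)
  invisible(list(synth = synth, phenotypes = phen, ct = ct,
                 profiles = profiles, stats = stats_res,
                 differential = diff_res, linking = linking_res,
                 network = network_res, ncm = ncm_res,
                 functional = func_res, manifest = manifest))
}
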