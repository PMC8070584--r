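#' Default pipeline configuration
#'
#' All stage parameters with their defaults: BH 0.05 for edge filtering,
#' differential expression and MRA; Bonferroni 0.01 for methylation;
#' regulon size filter 15; two cohorts of 120 samples; signature groups of
#' 20 case / 20 origin samples with an activity shift of 3; survival
#' effects -1 (cluster A, protective) and +1 (cluster B) with 20% uniform
#' censoring; methylation with 15 cases vs 9 controls and a planted beta
#' difference of 0.4. Each parameter can be overridden in a YAML file (see
#' [read_config()]) or directly on the returned list.
#'
#' @param seed master seed; every stage seed is derived from it.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    truth = list(n_tfs = 10, n_mr = 7, cluster_sizes = c(2, 5),
                 n_genes = 500, targets_per_regulon = 40,
                 cross_shared_fraction = 0.3, weight_magnitude = 1,
                 noise_sd = 1, activity_cor = 0.7, decoy_targets = 5),
    cohorts = list(n_samples = c(120, 120)),
    signature = list(n_case = 20, n_origin = 20, activity_shift = 3,
                     alpha = 0.05),
    network = list(n_bins = NULL, n_perm = 500, alpha = 0.05, dpi_eps = 0,
                   min_size = 15),
    mra = list(alpha = 0.05),
    activity = list(min_shared = 1, k = 2),
    survival = list(effect_A = -1, effect_B = 1, baseline_scale = 1,
                    censor_rate = 0.2, alpha = 0.05),
    methylation = list(n_case = 15, n_ctrl = 9, delta_beta = 0.4,
                       probes_per_gene = 2, noise_sd = 0.05,
                       threshold = 0.01),
    stages = list(activity = TRUE, survival = TRUE, methylation = TRUE)
  ), class = "pipeline_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @param seed optional master-seed override (e.g. from a CLI flag).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  override <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), override)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the analysis graph: plant a ground truth; simulate two tumour
#' cohorts; simulate a disease signature group and two cell-of-origin
#' groups; infer one regulatory network per cohort; derive two
#' case-vs-origin signatures; run the four MRAs (2 networks x 2
#' signatures) and intersect them into the consensus MR set; score
#' per-sample regulon activity, association maps and activity clustering
#' per cohort; simulate survival driven by cluster activity and screen
#' every regulon by median split + log-rank; simulate methylation with
#' planted differences in MR regulon targets and test regulon enrichment
#' per network. Fully deterministic for a fixed config and seed.
#'
#' @param config a [default_config()] / [read_config()] result.
#' @param outdir optional output directory; when given, stage outputs
#'   (TSV/GMT/CSV/JSON) and the run report (`report.json`) are written
#'   there.
#' @param quiet suppress per-stage progress messages.
#' @return An object of class `regmra_run`: all stage objects plus
#'   `report`, a serialisable summary sufficient to reproduce the run.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  tcfg <- do.call(truth_config, c(config$truth,
                                  list(seed = child_seed(seed, 1))))
  say("stage truth: planting %d MRs among %d TFs", tcfg$n_mr, tcfg$n_tfs)
  truth <- generate_truth(tcfg)
  mrs <- names(truth$cluster_of)

  say("stage cohorts: simulating %d tumour cohorts",
      length(config$cohorts$n_samples))
  cohorts <- lapply(seq_along(config$cohorts$n_samples), function(i)
    simulate_cohort(truth, config$cohorts$n_samples[i],
                    seed = child_seed(seed, 1 + i),
                    label = sprintf("cohort%d", i)))

  say("stage signature groups: case n=%d, origins n=%d",
      config$signature$n_case, config$signature$n_origin)
  case_grp <- simulate_cohort(truth, config$signature$n_case,
                              activity_shift = config$signature$activity_shift,
                              seed = child_seed(seed, 10), label = "case")
  origins <- lapply(1:2, function(i)
    simulate_origin_cohort(truth, config$signature$n_origin,
                           seed = child_seed(seed, 10 + i),
                           label = sprintf("origin%d", i)))

  say("stage networks: MI + permutation (n_perm=%d) + DPI",
      config$network$n_perm)
  networks <- lapply(seq_along(cohorts), function(i)
    infer_network(cohorts[[i]]$expression, truth$tfs,
                  n_bins = config$network$n_bins,
                  n_perm = config$network$n_perm,
                  alpha = config$network$alpha,
                  dpi_eps = config$network$dpi_eps,
                  min_size = config$network$min_size,
                  seed = child_seed(seed, 20 + i)))

  say("stage signatures: case vs each origin (Welch + BH %.2f)",
      config$signature$alpha)
  signatures <- lapply(origins, function(o)
    differential_expression(case_grp$expression, o$expression,
                            alpha = config$signature$alpha))

  say("stage MRA: %d networks x %d signatures", length(networks),
      length(signatures))
  mras <- list()
  for (i in seq_along(networks)) {
    for (j in seq_along(signatures)) {
      mras[[sprintf("net%d_sig%d", i, j)]] <-
        run_mra(networks[[i]], signatures[[j]], alpha = config$mra$alpha,
                network_id = sprintf("network%d", i),
                signature_id = sprintf("signature%d", j))
    }
  }
  consensus <- consensus_mrs(mras)
  say("stage consensus: %d MR(s)", length(consensus$consensus))

  activity <- association <- clusters <- NULL
  if (isTRUE(config$stages$activity)) {
    say("stage activity: two-tailed dES per cohort")
    activity <- lapply(seq_along(cohorts), function(i) {
      z <- zscore_transform(cohorts[[i]]$expression)
      regulon_activity_matrix(z, networks[[i]])
    })
    association <- lapply(networks, association_map,
                          min_shared = config$activity$min_shared)
    clusters <- lapply(activity, function(a) {
      a_mr <- unclass(a)[intersect(rownames(a), mrs), , drop = FALSE]
      if (nrow(a_mr) >= 2)
        cluster_activity(a_mr, k = min(config$activity$k, nrow(a_mr)))
      else NULL
    })
  }

  surv <- NULL
  if (isTRUE(config$stages$survival) && !is.null(activity)) {
    say("stage survival: median split + log-rank per regulon")
    surv <- lapply(seq_along(cohorts), function(i) {
      records <- simulate_survival(cohorts[[i]], truth,
                                   effect_A = config$survival$effect_A,
                                   effect_B = config$survival$effect_B,
                                   baseline_scale = config$survival$baseline_scale,
                                   censor_rate = config$survival$censor_rate,
                                   seed = child_seed(seed, 30 + i))
      list(records = records,
           screen = survival_screen(activity[[i]], records,
                                    alpha = config$survival$alpha))
    })
  }

  meth <- NULL
  if (isTRUE(config$stages$methylation)) {
    say("stage methylation: %d cases vs %d controls",
        config$methylation$n_case, config$methylation$n_ctrl)
    msim <- simulate_methylation(truth, dm_regulons = mrs,
                                 n_case = config$methylation$n_case,
                                 n_ctrl = config$methylation$n_ctrl,
                                 delta_beta = config$methylation$delta_beta,
                                 probes_per_gene = config$methylation$probes_per_gene,
                                 noise_sd = config$methylation$noise_sd,
                                 seed = child_seed(seed, 40))
    dm <- dm_probe_test(msim$beta[, msim$case_ids, drop = FALSE],
                        msim$beta[, msim$ctrl_ids, drop = FALSE],
                        threshold = config$methylation$threshold)
    dmg <- dm_genes(dm, msim$probe_map)
    enr <- lapply(networks, regulon_dm_enrichment, dm_gene_set = dmg,
                  probe_map = msim$probe_map,
                  threshold = config$methylation$threshold)
    meth <- list(sim = msim, dm_probes = dm, dm_genes = dmg,
                 enrichment = enr)
  }

  report <- build_report(config, truth, networks, signatures, mras,
                         consensus, activity, clusters, surv, meth)
  run <- structure(list(config = config, truth = truth, cohorts = cohorts,
                        case_group = case_grp, origins = origins,
                        networks = networks, signatures = signatures,
                        mras = mras, consensus = consensus,
                        activity = activity, association = association,
                        clusters = clusters, survival = surv,
                        methylation = meth, report = report),
                   class = "regmra_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

build_report <- function(config, truth, networks, signatures, mras,
                         consensus, activity, clusters, surv, meth) {
  reg_summary <- lapply(networks, function(net) {
    sizes <- vapply(net$regulons, `[[`, integer(1), "size")
    list(n_regulons = length(sizes),
         n_pass_size = sum(vapply(net$regulons, `[[`, logical(1),
                                  "pass_size")),
         sizes = as.list(sizes),
         dpi_removed = net$params$dpi_removed)
  })
  rep <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    truth = list(mrs = as.list(truth$cluster_of),
                 decoys = truth$non_mr_tfs),
    networks = reg_summary,
    signatures = lapply(signatures, function(s)
      list(n_genes = length(s$genes), n_tested = length(s$universe))),
    mra = lapply(mras, function(m) as.list(m$mrs)),
    consensus = consensus$consensus)
  if (!is.null(clusters)) {
    rep$activity_clusters <- lapply(clusters, function(cl)
      if (is.null(cl)) NULL else as.list(cl$regulon_clusters))
  }
  if (!is.null(surv)) {
    rep$survival <- lapply(surv, function(s)
      lapply(split(s$screen, s$screen$regulon), function(r)
        list(p = r$p, direction = r$direction,
             significant = r$significant)))
  }
  if (!is.null(meth)) {
    rep$methylation <- list(
      n_dm_probes = sum(meth$dm_probes$is_dm),
      n_dm_genes = length(meth$dm_genes),
      enriched = lapply(meth$enrichment, function(e)
        as.list(e$set_id[e$is_enriched])))
  }
  rep
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, sprintf(...))
  write_truth_json(run$truth, p("truth.json"))
  for (i in seq_along(run$cohorts))
    write_expression(run$cohorts[[i]]$expression, p("cohort%d_expr.tsv", i))
  for (i in seq_along(run$networks)) {
    write_edges_tsv(run$networks[[i]], p("network%d_edges.tsv", i))
    write_regulons_gmt(run$networks[[i]], p("network%d_regulons.gmt", i),
                       signed = TRUE)
  }
  for (i in seq_along(run$signatures))
    writeLines(run$signatures[[i]]$genes, p("signature%d_genes.txt", i))
  if (!is.null(run$activity)) {
    for (i in seq_along(run$activity))
      write_expression(unclass(run$activity[[i]]),
                       p("cohort%d_activity.tsv", i), id_col = "regulon")
    for (i in seq_along(run$association))
      write.table(run$association[[i]], p("network%d_association.tsv", i),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$survival)) {
    for (i in seq_along(run$survival)) {
      write_survival(run$survival[[i]]$records, p("cohort%d_survival.csv", i))
      write.table(run$survival[[i]]$screen, p("cohort%d_survival_screen.tsv", i),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(run$methylation)) {
    write.table(run$methylation$dm_probes, p("dm_probes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(run$methylation$dm_genes, p("dm_genes.txt"))
    for (i in seq_along(run$methylation$enrichment))
      write.table(run$methylation$enrichment[[i]],
                  p("network%d_methylation_enrichment.tsv", i), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(outdir)
}

#' @export
print.regmra_run <- function(x, ...) {
  cat("regmra pipeline run\n")
  cat(sprintf("  seed %d, config hash %s\n", x$report$seed,
              x$report$config_hash))
  for (i in seq_along(x$networks))
    cat(sprintf("  network %d: %d regulons (%d pass size filter)\n", i,
                x$report$networks[[i]]$n_regulons,
                x$report$networks[[i]]$n_pass_size))
  cat(sprintf("  consensus MRs (%d): %s\n", length(x$consensus$consensus),
              paste(x$consensus$consensus, collapse = ", ")))
  if (!is.null(x$survival)) {
    scr <- x$survival[[1]]$screen
    cat(sprintf("  survival (cohort 1): %d/%d regulons significant\n",
                sum(scr$significant, na.rm = TRUE), nrow(scr)))
  }
  if (!is.null(x$methylation)) {
    cat(sprintf("  methylation: %d DM genes; enriched regulons: %s\n",
                length(x$methylation$dm_genes),
                paste(x$methylation$enrichment[[1]]$set_id[
                  x$methylation$enrichment[[1]]$is_enriched],
                  collapse = ", ")))
  }
  invisible(x)
}
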