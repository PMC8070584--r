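#' Configuration for a planted regulatory ground truth
#'
#' Describes a synthetic regulome with two clusters of master regulators
#' (MRs) that are agonists within a cluster and antagonists between
#' clusters: a fraction of each MR regulon is a common pool of targets
#' regulated with one sign by cluster A and the opposite sign by cluster B.
#' Remaining transcription factors are decoys carrying sub-threshold
#' regulons, so the regulon size filter and MRA specificity are exercised.
#'
#' @param n_tfs number of transcription factors (regulators).
#' @param n_mr number of planted master regulators; must not exceed `n_tfs`.
#' @param cluster_sizes integer vector of length 2 partitioning the MRs into
#'   clusters A and B; must sum to `n_mr`.
#' @param n_genes number of non-TF genes in the universe.
#' @param targets_per_regulon targets planted per MR regulon (at least 15 so
#'   planted regulons survive the default regulon size filter).
#' @param cross_shared_fraction fraction in \[0, 1\] of each MR regulon drawn
#'   from the cross-cluster shared pool, regulated with opposite signs by the
#'   two clusters.
#' @param weight_magnitude absolute planted regulatory weight, in log2
#'   expression units per unit of TF activity.
#' @param noise_sd default residual standard deviation for simulated
#'   expression (log2 units).
#' @param activity_cor within-cluster correlation of MR activities; between
#'   clusters the correlation is its negative (one shared antagonism factor).
#' @param decoy_targets targets planted per decoy (non-MR) regulon; must stay
#'   below 15 so decoys fall under the size filter.
#' @param seed RNG seed making the truth reproducible.
#' @return An object of class `truth_config`.
#' @seealso [generate_truth()]
#' @export
truth_config <- function(n_tfs = 10, n_mr = 7, cluster_sizes = c(2, 5),
                         n_genes = 500, targets_per_regulon = 40,
                         cross_shared_fraction = 0.3, weight_magnitude = 1,
                         noise_sd = 1, activity_cor = 0.7, decoy_targets = 5,
                         seed = 1) {
  cfg <- list(n_tfs = as.integer(n_tfs), n_mr = as.integer(n_mr),
              cluster_sizes = as.integer(cluster_sizes),
              n_genes = as.integer(n_genes),
              targets_per_regulon = as.integer(targets_per_regulon),
              cross_shared_fraction = cross_shared_fraction,
              weight_magnitude = weight_magnitude, noise_sd = noise_sd,
              activity_cor = activity_cor,
              decoy_targets = as.integer(decoy_targets),
              seed = as.integer(seed))
  if (length(cfg$cluster_sizes) != 2)
    stop("'cluster_sizes' must have length 2")
  if (sum(cfg$cluster_sizes) != cfg$n_mr)
    stop("'cluster_sizes' must sum to 'n_mr'")
  if (cfg$n_mr > cfg$n_tfs)
    stop("'n_mr' must not exceed 'n_tfs'")
  if (cfg$targets_per_regulon < 15)
    stop("'targets_per_regulon' must be at least 15 so planted regulons ",
         "survive the size filter")
  if (cfg$targets_per_regulon > cfg$n_genes)
    stop("'targets_per_regulon' exceeds 'n_genes'")
  if (cfg$cross_shared_fraction < 0 || cfg$cross_shared_fraction > 1)
    stop("'cross_shared_fraction' must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (cfg$activity_cor < 0 || cfg$activity_cor >= 1)
    stop("'activity_cor' must lie in [0, 1)")
  if (cfg$decoy_targets >= 15)
    stop("'decoy_targets' must stay below the regulon size filter (15)")
  n_shared <- round(cfg$cross_shared_fraction * cfg$targets_per_regulon)
  need <- n_shared + cfg$n_mr * (cfg$targets_per_regulon - n_shared)
  if (need > cfg$n_genes)
    stop("not enough genes for disjoint private target pools; ",
         "reduce 'targets_per_regulon' or raise 'n_genes'")
  structure(cfg, class = "truth_config")
}

#' Generate a planted regulatory ground truth
#'
#' Builds the signed TF-to-target weight map described by a [truth_config()]:
#' the first `cluster_sizes[1]` MRs form cluster A, the next
#' `cluster_sizes[2]` cluster B. A shared pool of
#' `round(cross_shared_fraction * targets_per_regulon)` genes is regulated by
#' every MR, with a per-gene sign for cluster A and the flipped sign for
#' cluster B (agonism within, antagonism between clusters). The remaining
#' targets of each MR are private and mutually disjoint, with random signs.
#' Decoy TFs receive small disjoint regulons below the size-15 filter.
#'
#' @param config a [truth_config()].
#' @return An object of class `synthetic_truth` with elements `regulons`
#'   (named list of signed weight vectors), `cluster_of` (named "A"/"B"
#'   vector over MRs), `non_mr_tfs`, `tfs`, `genes`, `universe`, and
#'   `config`.
#' @export
generate_truth <- function(config = truth_config()) {
  stopifnot(inherits(config, "truth_config"))
  with_seed(config$seed, {
    tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    mrs <- tfs[seq_len(config$n_mr)]
    cluster_of <- setNames(rep(c("A", "B"), config$cluster_sizes), mrs)
    decoys <- setdiff(tfs, mrs)

    n_shared <- round(config$cross_shared_fraction *
                        config$targets_per_regulon)
    n_private <- config$targets_per_regulon - n_shared
    pool <- sample(genes)
    shared <- pool[seq_len(n_shared)]
    if (n_shared > 0) pool <- pool[-seq_len(n_shared)]
    shared_sign <- setNames(sample(c(-1, 1), n_shared, replace = TRUE),
                            shared)

    w <- config$weight_magnitude
    regulons <- list()
    for (mr in mrs) {
      priv <- pool[seq_len(n_private)]
      if (n_private > 0) pool <- pool[-seq_len(n_private)]
      s_shared <- if (cluster_of[[mr]] == "A") shared_sign else -shared_sign
      weights <- c(s_shared * w,
                   setNames(sample(c(-1, 1), n_private, replace = TRUE) * w,
                            priv))
      regulons[[mr]] <- weights
    }
    for (tf in decoys) {
      nd <- min(config$decoy_targets, length(pool))
      if (nd > 0) {
        tg <- pool[seq_len(nd)]
        pool <- pool[-seq_len(nd)]
        regulons[[tf]] <- setNames(sample(c(-1, 1), nd, replace = TRUE) * w,
                                   tg)
      }
    }
    structure(list(regulons = regulons, cluster_of = cluster_of,
                   non_mr_tfs = decoys, tfs = tfs, genes = genes,
                   universe = c(tfs, genes), config = config),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Planted regulatory truth\n")
  cat(sprintf("  %d TFs (%d MRs: cluster A = %d, cluster B = %d), %d genes\n",
              length(x$tfs), length(x$cluster_of),
              sum(x$cluster_of == "A"), sum(x$cluster_of == "B"),
              length(x$genes)))
  sizes <- vapply(x$regulons, length, integer(1))
  cat(sprintf("  regulon sizes: %s\n",
              paste(names(sizes), sizes, sep = "=", collapse = ", ")))
  invisible(x)
}

# Latent TF activities: MRs load on one shared antagonism factor with
# opposite signs per cluster; decoys are independent standard normals.
simulate_activities <- function(truth, n_samples, activity_shift) {
  cfg <- truth$config
  r <- cfg$activity_cor
  f <- rnorm(n_samples)
  act <- matrix(rnorm(length(truth$tfs) * n_samples),
                nrow = length(truth$tfs),
                dimnames = list(truth$tfs, sprintf("S%03d",
                                                   seq_len(n_samples))))
  for (mr in names(truth$cluster_of)) {
    s <- if (truth$cluster_of[[mr]] == "A") 1 else -1
    act[mr, ] <- s * sqrt(r) * f + sqrt(1 - r) * act[mr, ]
  }
  if (length(activity_shift) == 1) activity_shift <- rep(activity_shift, 2)
  act[names(truth$cluster_of)[truth$cluster_of == "A"], ] <-
    act[names(truth$cluster_of)[truth$cluster_of == "A"], , drop = FALSE] +
    activity_shift[1]
  act[names(truth$cluster_of)[truth$cluster_of == "B"], ] <-
    act[names(truth$cluster_of)[truth$cluster_of == "B"], , drop = FALSE] +
    activity_shift[2]
  act
}

#' Simulate an expression cohort from a planted truth
#'
#' Expression follows a linear-Gaussian model on the log2 scale:
#' `x(g, s) = sum_t w_tg * a(t, s) + e`, with `e ~ Normal(0, noise_sd)` and
#' a TF's own expression equal to its latent activity plus noise. Genes not
#' targeted by any TF are pure noise. Master regulator activities share one
#' antagonism factor (see [truth_config()] `activity_cor`), so cluster A and
#' cluster B activities are anti-correlated across samples.
#'
#' @param truth a [generate_truth()] result.
#' @param n_samples number of samples (at least 4).
#' @param noise_sd residual standard deviation; defaults to the truth
#'   config's value. Zero gives noise-free expression.
#' @param tf_noise_sd residual standard deviation of the TF rows; defaults
#'   to `noise_sd / 4`. A TF transcript is the proximal readout of its own
#'   activity, so it is simulated with less residual noise than downstream
#'   targets; this also keeps TF-TF statistical dependence stronger than
#'   indirect TF-target dependence, the regime in which DPI pruning of
#'   shared-factor artefacts is valid.
#' @param activity_shift mean shift added to MR activities; a scalar applies
#'   to both clusters, a length-2 vector shifts clusters A and B separately.
#'   Used to simulate disease-like groups for signature contrasts.
#' @param seed RNG seed.
#' @param label cohort label stored on the result.
#' @return An object of class `cohort_sim` with elements `expression`
#'   (genes x samples matrix), `activities` (TF x samples latent matrix),
#'   and `label`.
#' @export
simulate_cohort <- function(truth, n_samples, noise_sd = NULL,
                            activity_shift = 0, seed = 1,
                            label = "cohort", tf_noise_sd = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_samples < 4) stop("'n_samples' must be at least 4")
  if (is.null(noise_sd)) noise_sd <- truth$config$noise_sd
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (is.null(tf_noise_sd)) tf_noise_sd <- noise_sd / 4
  if (tf_noise_sd < 0) stop("'tf_noise_sd' must be non-negative")
  with_seed(seed, {
    act <- simulate_activities(truth, n_samples, activity_shift)
    n_feat <- length(truth$universe)
    W <- matrix(0, nrow = n_feat, ncol = length(truth$tfs),
                dimnames = list(truth$universe, truth$tfs))
    for (tf in names(truth$regulons)) {
      w <- truth$regulons[[tf]]
      W[names(w), tf] <- w
    }
    diag_idx <- cbind(match(truth$tfs, truth$universe),
                      seq_along(truth$tfs))
    W[diag_idx] <- 1  # a TF reads out its own activity
    expr <- W %*% act +
      matrix(rnorm(n_feat * n_samples, sd = noise_sd), nrow = n_feat)
    dimnames(expr) <- list(truth$universe, colnames(act))
    expr[truth$tfs, ] <- act +
      matrix(rnorm(length(truth$tfs) * n_samples, sd = tf_noise_sd),
             nrow = length(truth$tfs))
    structure(list(expression = expr, activities = act, label = label),
              class = "cohort_sim")
  })
}

#' Simulate a cell-of-origin cohort
#'
#' Origin samples have all master regulator programs at baseline
#' (`activity_shift = 0`), so contrasting a disease cohort simulated with a
#' positive shift against an origin cohort makes the planted MR targets
#' differentially expressed. Group sizes down to 2 are accepted.
#'
#' @inheritParams simulate_cohort
#' @return A `cohort_sim`.
#' @export
simulate_origin_cohort <- function(truth, n_samples, noise_sd = NULL,
                                   seed = 1, label = "origin") {
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  if (n_samples < 4) {
    # bypass the cohort minimum used for network inference; origin groups
    # only feed differential expression
    big <- simulate_cohort(truth, 4, noise_sd = noise_sd,
                           activity_shift = 0, seed = seed, label = label)
    big$expression <- big$expression[, seq_len(n_samples), drop = FALSE]
    big$activities <- big$activities[, seq_len(n_samples), drop = FALSE]
    return(big)
  }
  simulate_cohort(truth, n_samples, noise_sd = noise_sd, activity_shift = 0,
                  seed = seed, label = label)
}

#' Simulate survival under a proportional-hazards model on cluster activity
#'
#' Event times are exponential with per-sample hazard
#' `h_s = (1 / baseline_scale) * exp(effect_A * meanA_s + effect_B *
#' meanB_s)`, where `meanA_s` / `meanB_s` are the sample's mean latent
#' activities over cluster A and B master regulators. Censoring is
#' independent uniform on `(0, tau)`, with `tau` calibrated so the expected
#' censoring fraction at baseline hazard equals `censor_rate`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param truth the [generate_truth()] object the cohort came from.
#' @param effect_A,effect_B log-hazard per unit of mean cluster activity;
#'   negative values are protective.
#' @param baseline_scale mean survival time at zero activity; must be
#'   positive.
#' @param censor_rate target censoring fraction in \[0, 1).
#' @param seed RNG seed.
#' @return A data.frame with columns `sample`, `time` (> 0) and `event`
#'   (1 = death observed, 0 = censored).
#' @export
simulate_survival <- function(cohort, truth, effect_A = -1, effect_B = 1,
                              baseline_scale = 1, censor_rate = 0.2,
                              seed = 1) {
  stopifnot(inherits(cohort, "cohort_sim"),
            inherits(truth, "synthetic_truth"))
  if (baseline_scale <= 0) stop("'baseline_scale' must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("'censor_rate' must lie in [0, 1)")
  mrs_a <- names(truth$cluster_of)[truth$cluster_of == "A"]
  mrs_b <- names(truth$cluster_of)[truth$cluster_of == "B"]
  mean_a <- colMeans(cohort$activities[mrs_a, , drop = FALSE])
  mean_b <- colMeans(cohort$activities[mrs_b, , drop = FALSE])
  h0 <- 1 / baseline_scale
  rate <- h0 * exp(effect_A * mean_a + effect_B * mean_b)
  with_seed(seed, {
    t_event <- rexp(length(rate), rate = rate)
    if (censor_rate > 0) {
      # (1 - exp(-h0 * tau)) / (h0 * tau) = censor_rate, solved for tau
      f <- function(tau) (1 - exp(-h0 * tau)) / (h0 * tau) - censor_rate
      tau <- uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
      t_cens <- runif(length(rate), min = 0, max = tau)
    } else {
      t_cens <- rep(Inf, length(rate))
    }
    data.frame(sample = colnames(cohort$activities),
               time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' Simulate array methylation with planted regulon-level differences
#'
#' Every gene in the universe receives `probes_per_gene` probes with a
#' shared baseline beta distribution (uniform on 0.15-0.85). Probes of genes
#' targeted by the `dm_regulons` master regulators are shifted by
#' `+/- delta_beta` (one direction per gene) in the case group; Gaussian
#' probe noise is added and values are clipped to \[0, 1\].
#'
#' @param truth a [generate_truth()] result.
#' @param dm_regulons character vector of MRs whose target genes are planted
#'   as differentially methylated.
#' @param n_case,n_ctrl group sizes (each at least 2); defaults 15 and 9.
#' @param delta_beta planted case-control beta difference in (0, 1); 0 turns
#'   planting off (null simulation).
#' @param probes_per_gene probes simulated per gene.
#' @param noise_sd per-probe Gaussian noise standard deviation (beta scale).
#' @param seed RNG seed.
#' @return An object of class `methylation_sim` with elements `beta`
#'   (probes x samples), `case_ids`, `ctrl_ids`, `probe_map` (data.frame
#'   probe, gene), and `dm_truth` (planted gene set; empty when
#'   `delta_beta = 0`).
#' @export
simulate_methylation <- function(truth, dm_regulons, n_case = 15,
                                 n_ctrl = 9, delta_beta = 0.4,
                                 probes_per_gene = 2, noise_sd = 0.05,
                                 seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_case < 2 || n_ctrl < 2)
    stop("'n_case' and 'n_ctrl' must both be at least 2")
  if (delta_beta < 0 || delta_beta >= 1)
    stop("'delta_beta' must lie in [0, 1)")
  if (!all(dm_regulons %in% names(truth$regulons)))
    stop("unknown regulon in 'dm_regulons'")
  genes <- truth$universe
  probes <- sprintf("cg%05d", seq_len(length(genes) * probes_per_gene))
  probe_map <- data.frame(probe = probes,
                          gene = rep(genes, each = probes_per_gene),
                          stringsAsFactors = FALSE)
  dm_genes <- if (delta_beta > 0) {
    sort(unique(unlist(lapply(truth$regulons[dm_regulons], names))))
  } else {
    character(0)
  }
  with_seed(seed, {
    n_probe <- nrow(probe_map)
    base <- runif(n_probe, 0.15, 0.85)
    dirn <- setNames(sample(c(-1, 1), length(genes), replace = TRUE), genes)
    shift <- ifelse(probe_map$gene %in% dm_genes,
                    dirn[probe_map$gene] * delta_beta, 0)
    n_all <- n_case + n_ctrl
    beta <- matrix(base, nrow = n_probe, ncol = n_all) +
      matrix(rnorm(n_probe * n_all, sd = noise_sd), nrow = n_probe)
    beta[, seq_len(n_case)] <- beta[, seq_len(n_case)] + shift
    beta <- pmin(pmax(beta, 0), 1)
    case_ids <- sprintf("case%02d", seq_len(n_case))
    ctrl_ids <- sprintf("ctrl%02d", seq_len(n_ctrl))
    dimnames(beta) <- list(probes, c(case_ids, ctrl_ids))
    structure(list(beta = beta, case_ids = case_ids, ctrl_ids = ctrl_ids,
                   probe_map = probe_map, dm_truth = dm_genes),
              class = "methylation_sim")
  })
}

#' Convert a planted truth into a regulatory-network object
#'
#' Builds a `regnet` whose regulons are the planted target sets, with mode
#' equal to the planted weight sign and `|weight|` standing in for MI.
#' Useful for exercising activity scoring, association maps and enrichment
#' with noise-free modes, independently of network inference.
#'
#' @param truth a [generate_truth()] result.
#' @param min_size regulon size filter recorded on the network.
#' @return A `regnet`.
#' @export
truth_network <- function(truth, min_size = 15) {
  stopifnot(inherits(truth, "synthetic_truth"))
  regs <- lapply(names(truth$regulons), function(tf) {
    w <- truth$regulons[[tf]]
    list(tf = tf, targets = abs(w),
         mode = setNames(as.integer(sign(w)), names(w)),
         size = length(w), pass_size = length(w) >= min_size)
  })
  names(regs) <- names(truth$regulons)
  structure(list(regulons = regs, universe = truth$universe,
                 params = list(min_size = min_size, source = "planted")),
            class = "regnet")
}
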