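#' Probe-wise differential methylation
#'
#' Welch two-sample t-tests per probe on M-values
#' `M = log2(beta / (1 - beta))`, with beta clipped to
#' `[1e-3, 1 - 1e-3]` before the transform (variance stabilisation;
#' testing on M rather than raw beta is standard practice). P-values are
#' Bonferroni-adjusted across probes; a probe is differentially methylated
#' (DM) when the adjusted p is strictly below `threshold`.
#'
#' @param case,control probe x sample beta matrices in \[0, 1\] (each at
#'   least 2 samples); only shared probes are tested, others are skipped
#'   with a warning.
#' @param threshold Bonferroni threshold (default 0.01).
#' @param qc_mask optional character vector of probes failing quality
#'   control, dropped before testing.
#' @return A data.frame with columns `probe`, `delta_beta` (case minus
#'   control mean beta), `statistic`, `p`, `p_adj`, `is_dm`.
#' @export
dm_probe_test <- function(case, control, threshold = 0.01,
                          qc_mask = NULL) {
  stop_if_not_matrix(case); stop_if_not_matrix(control)
  if (any(case < 0 | case > 1) || any(control < 0 | control > 1))
    stop("beta values must lie in [0, 1]")
  if (ncol(case) < 2 || ncol(control) < 2)
    stop("each group needs at least 2 samples")
  probes <- intersect(rownames(case), rownames(control))
  skipped <- length(union(rownames(case), rownames(control))) -
    length(probes)
  if (skipped > 0)
    warning(sprintf("%d probe(s) absent from one matrix skipped", skipped))
  if (!is.null(qc_mask)) probes <- setdiff(probes, qc_mask)
  if (length(probes) == 0) stop("no probe left to test")
  eps <- 1e-3
  mval <- function(b) log2(pmin(pmax(b, eps), 1 - eps) /
                             (1 - pmin(pmax(b, eps), 1 - eps)))
  x <- mval(case[probes, , drop = FALSE])
  y <- mval(control[probes, , drop = FALSE])
  n1 <- ncol(x); n2 <- ncol(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (rowMeans(x) - rowMeans(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[is.na(p)] <- 1  # zero variance in both groups: no evidence
  p_adj <- adjust_pvalues(p, "bonferroni")
  data.frame(probe = probes,
             delta_beta = rowMeans(case[probes, , drop = FALSE]) -
               rowMeans(control[probes, , drop = FALSE]),
             statistic = tstat, p = p, p_adj = p_adj,
             is_dm = p_adj < threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse differentially methylated probes to genes
#'
#' A gene is differentially methylated if at least one of its probes is
#' (`rule = "any"`, the default) or if more than half are
#' (`rule = "majority"`). Probes without a mapping are reported and
#' excluded.
#'
#' @param dm a [dm_probe_test()] result.
#' @param probe_map data.frame with columns `probe`, `gene` (each probe
#'   maps to exactly one gene).
#' @param rule collapsing rule, `"any"` or `"majority"`.
#' @return Sorted character vector of DM genes.
#' @export
dm_genes <- function(dm, probe_map, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe))
    stop("'probe_map' maps some probe to more than one gene")
  unmapped <- setdiff(dm$probe, probe_map$probe)
  if (length(unmapped) > 0)
    warning(sprintf("%d unmapped probe(s) excluded", length(unmapped)))
  dm <- dm[dm$probe %in% probe_map$probe, , drop = FALSE]
  gene <- probe_map$gene[match(dm$probe, probe_map$probe)]
  if (rule == "any") {
    sort(unique(gene[dm$is_dm]))
  } else {
    frac <- tapply(dm$is_dm, gene, mean)
    sort(names(frac)[frac > 0.5])
  }
}

#' Regulon enrichment for differentially methylated genes
#'
#' One Fisher (hypergeometric enrichment tail) test per size-filtered
#' regulon, asking whether its targets are overrepresented among the
#' differentially methylated genes. The universe is the intersection of
#' the genes covered by the probe map and the network universe. P-values
#' are Bonferroni-adjusted across regulons; run the function once per
#' network when several networks are analysed.
#'
#' @param network a `regnet` or `synthetic_truth`.
#' @param dm_gene_set character vector of DM genes (see [dm_genes()]).
#' @param probe_map data.frame `probe`, `gene` defining methylation
#'   coverage.
#' @param threshold Bonferroni threshold (default 0.01).
#' @return A data.frame per regulon: `set_id`, `k`, `K`, `n`, `N`, `p`,
#'   `p_adj`, `is_enriched`.
#' @export
regulon_dm_enrichment <- function(network, dm_gene_set, probe_map,
                                  threshold = 0.01) {
  modes <- network_modes(network)
  if (length(modes) == 0) stop("no regulon to test")
  net_universe <- if (inherits(network, "regnet")) network$universe else
    network$universe
  universe <- intersect(unique(probe_map$gene), net_universe)
  if (length(universe) == 0) stop("empty methylation/network universe")
  dm_set <- intersect(dm_gene_set, universe)
  enr <- do.call(rbind, lapply(names(modes), function(tf) {
    overrepresentation_test(dm_set, names(modes[[tf]]), universe,
                            set_id = tf)
  }))
  enr$p_adj <- adjust_pvalues(enr$p, "bonferroni")
  enr$is_enriched <- enr$p_adj < threshold
  rownames(enr) <- NULL
  enr
}
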