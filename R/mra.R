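#' Differential expression between a case and an origin cohort
#'
#' Per-gene Welch two-sample t-test on log2 expression, adjusted with
#' Benjamini-Hochberg across genes. The signature is the set of genes with
#' adjusted p at or below `alpha`. Genes with zero variance in both groups
#' cannot be tested and are excluded with a warning.
#'
#' @param case,origin genes x samples log2 matrices; the contrast runs on
#'   their shared genes (each group needs at least 2 samples).
#' @param alpha signature threshold on the BH-adjusted p-value
#'   (default 0.05).
#' @return An object of class `gene_signature`: `genes` (the signature),
#'   `stats` (per-gene mean difference, t, p, p_adj), `universe` (tested
#'   genes) and `alpha`.
#' @export
differential_expression <- function(case, origin, alpha = 0.05) {
  stop_if_not_matrix(case); stop_if_not_matrix(origin)
  if (ncol(case) < 2 || ncol(origin) < 2)
    stop("each group needs at least 2 samples")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  genes <- intersect(rownames(case), rownames(origin))
  if (length(genes) == 0) stop("no shared genes between the two matrices")
  x <- case[genes, , drop = FALSE]
  y <- origin[genes, , drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  untestable <- v1 == 0 & v2 == 0
  if (any(untestable)) {
    warning(sprintf("%d gene(s) with zero variance in both groups excluded",
                    sum(untestable)))
  }
  keep <- !untestable
  se2 <- v1[keep] / n1 + v2[keep] / n2
  tstat <- (m1[keep] - m2[keep]) / sqrt(se2)
  df <- se2^2 / ((v1[keep] / n1)^2 / (n1 - 1) +
                   (v2[keep] / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[is.na(p)] <- 1  # identical groups: 0/0 statistic, no evidence
  p_adj <- p.adjust(p, "BH")
  stats <- data.frame(gene = genes[keep], diff = m1[keep] - m2[keep],
                      t = tstat, p = p, p_adj = p_adj,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(genes = stats$gene[stats$p_adj <= alpha], stats = stats,
                 universe = genes[keep], alpha = alpha),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature: %d of %d tested genes at BH p <= %g\n",
              length(x$genes), length(x$universe), x$alpha))
  invisible(x)
}

#' One-tailed hypergeometric overrepresentation test
#'
#' Tests whether `query` and `reference` overlap more than expected by
#' chance within `universe`: with overlap `k`, reference size `K`, query
#' size `n` and universe size `N`, the p-value is the upper hypergeometric
#' tail `sum_{j >= k} C(K, j) C(N - K, n - j) / C(N, n)`. This is the
#' shared kernel of the master regulator analysis and of regulon
#' methylation enrichment (Fisher's exact test, enrichment tail).
#'
#' @param query,reference gene sets (character vectors); elements outside
#'   `universe` are ignored.
#' @param universe the background gene set (non-empty).
#' @param set_id optional identifier stored in the result.
#' @return A one-row data.frame with columns `set_id`, `k`, `K`, `n`, `N`,
#'   `p`.
#' @export
overrepresentation_test <- function(query, reference, universe,
                                    set_id = NA_character_) {
  if (length(universe) == 0) stop("'universe' must be non-empty")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  reference <- intersect(unique(reference), universe)
  k <- length(intersect(query, reference))
  K <- length(reference)
  n <- length(query)
  N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(set_id = set_id, k = k, K = K, n = n, N = N, p = p,
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with monotone enforcement, capped at 1) or
#' Bonferroni (`min(1, m * p)`).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length as `p` (empty in, empty out).
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = method)
}

#' Master regulator analysis
#'
#' Runs one overrepresentation test per size-filtered regulon against a
#' gene signature, with the universe taken as the intersection of the
#' network universe and the signature's tested genes, then adjusts across
#' regulons with Benjamini-Hochberg. Master regulators (MRs) are the TFs
#' with adjusted p at or below `alpha`.
#'
#' @param network a `regnet`.
#' @param signature a [differential_expression()] result, or a character
#'   vector of signature genes (its universe then defaults to the network
#'   universe).
#' @param alpha MR threshold on the BH-adjusted p (default 0.05).
#' @param network_id,signature_id labels stored on the result.
#' @return An object of class `mra_result`: `enrichments` (per-regulon
#'   table with `is_mr`), `mrs` (character vector), plus the labels.
#' @export
run_mra <- function(network, signature, alpha = 0.05,
                    network_id = "network", signature_id = "signature") {
  stopifnot(inherits(network, "regnet"))
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (is.character(signature))
    signature <- list(genes = signature, universe = network$universe)
  universe <- intersect(network$universe, signature$universe)
  if (length(universe) == 0)
    stop("network universe and signature universe do not overlap")
  regs <- regulons(network, size_filtered = TRUE)
  if (length(regs) == 0) {
    warning("no regulon passes the size filter; empty MRA result")
    enr <- data.frame(set_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), is_mr = logical(0))
    return(structure(list(network_id = network_id,
                          signature_id = signature_id,
                          enrichments = enr, mrs = character(0),
                          alpha = alpha), class = "mra_result"))
  }
  sig <- intersect(signature$genes, universe)
  enr <- do.call(rbind, lapply(regs, function(r) {
    overrepresentation_test(sig, names(r$mode), universe, set_id = r$tf)
  }))
  enr$p_adj <- adjust_pvalues(enr$p, "BH")
  enr$is_mr <- enr$p_adj <= alpha
  rownames(enr) <- NULL
  structure(list(network_id = network_id, signature_id = signature_id,
                 enrichments = enr, mrs = enr$set_id[enr$is_mr],
                 alpha = alpha),
            class = "mra_result")
}

#' @export
print.mra_result <- function(x, ...) {
  cat(sprintf("MRA [%s x %s]: %d regulon(s) tested, %d master regulator(s): %s\n",
              x$network_id, x$signature_id, nrow(x$enrichments),
              length(x$mrs), paste(x$mrs, collapse = ", ")))
  invisible(x)
}

#' Consensus master regulators across analyses
#'
#' Strict intersection of the MR sets of several [run_mra()] results; the
#' per-analysis sets are retained for reporting.
#'
#' @param results list of `mra_result` objects (at least one).
#' @return An object of class `consensus_result`: `per_analysis` (named
#'   list of MR sets) and `consensus` (their intersection).
#' @export
consensus_mrs <- function(results) {
  if (length(results) == 0) stop("at least one MRA result is required")
  stopifnot(all(vapply(results, inherits, logical(1), "mra_result")))
  sets <- lapply(results, `[[`, "mrs")
  names(sets) <- vapply(results, function(r)
    paste(r$network_id, r$signature_id, sep = " x "), character(1))
  structure(list(per_analysis = sets,
                 consensus = sort(Reduce(intersect, sets))),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus of %d analyses: %d MR(s): %s\n",
              length(x$per_analysis), length(x$consensus),
              paste(x$consensus, collapse = ", ")))
  invisible(x)
}
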