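#' Z-score transform across a cohort
#'
#' Per gene: `z = (x - mean) / sd` across samples, with the sample standard
#' deviation (denominator n - 1). Constant genes cannot be standardised and
#' are dropped with a warning.
#'
#' @param expr genes x samples matrix (at least 2 samples).
#' @return The z-score matrix (same shape, minus dropped rows), with the
#'   dropped gene ids in attribute `dropped`.
#' @export
zscore_transform <- function(expr) {
  stop_if_not_matrix(expr)
  if (ncol(expr) < 2) stop("z-scores need at least 2 samples")
  sds <- apply(expr, 1, sd)
  drop <- sds == 0
  if (any(drop))
    warning(sprintf("%d constant gene(s) dropped in z-score transform",
                    sum(drop)))
  z <- (expr[!drop, , drop = FALSE] - rowMeans(expr[!drop, , drop = FALSE])) /
    sds[!drop]
  attr(z, "dropped") <- rownames(expr)[drop]
  z
}

# Weighted Kolmogorov-Smirnov running-sum enrichment of `hit` positions in
# an already-ordered list. `w` are the |z| weights in ranking order.
es_from_order <- function(hit, w) {
  n <- length(hit)
  n_hit <- sum(hit)
  if (n_hit == 0) return(0)
  if (n_hit == n) stop("hit set cannot contain every ranked gene")
  step <- ifelse(hit, w / sum(w[hit]), -1 / (n - n_hit))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Weighted enrichment score of a gene set in a z-ranked list
#'
#' Genes are ranked by z descending (ties broken lexicographically by gene
#' id); walking down the ranking, hits increment the running sum by
#' `|z| / sum_hits |z|` and misses decrement it by `1 / (N - n_hits)`. The
#' enrichment score (ES) is the maximum-magnitude (signed) deviation of the
#' running sum; ties go to the earliest extreme.
#'
#' @param z named numeric vector of per-gene z-scores for one sample.
#' @param hits non-empty subset of `names(z)`; must not contain every gene.
#' @return ES in \[-1, 1\].
#' @export
enrichment_score <- function(z, hits) {
  if (is.null(names(z))) stop("'z' must be a named vector")
  if (length(hits) == 0) stop("'hits' must be non-empty")
  if (!all(hits %in% names(z))) stop("'hits' must be a subset of names(z)")
  ord <- order(-z, names(z))
  es_from_order(names(z)[ord] %in% hits, abs(z)[ord])
}

#' Per-sample two-tailed regulon activity (dES)
#'
#' For each size-filtered regulon and each sample, computes the enrichment
#' score of the positively regulated targets and of the negatively
#' regulated targets in the sample's z-score ranking, and reports
#' `dES = ES(positive) - ES(negative)` in \[-2, 2\]. An empty positive or
#' negative target set contributes ES = 0, so one-sided regulons still
#' score. The network may come from a different cohort (projection):
#' targets are intersected with the available genes, regulons losing more
#' than half their targets are flagged, and regulons with no overlapping
#' target yield `NA` with a warning.
#'
#' @param z a [zscore_transform()] result.
#' @param network a `regnet` (or a `synthetic_truth`, whose planted signs
#'   then serve as modes).
#' @return A regulons x samples matrix of class `activity_matrix` with
#'   attributes `es_pos`, `es_neg` (component matrices) and `flagged`
#'   (regulons losing > 50% of targets).
#' @export
regulon_activity_matrix <- function(z, network) {
  stop_if_not_matrix(z)
  regs <- network_modes(network)
  if (length(regs) == 0) stop("no regulon to score")
  genes <- rownames(z)
  n_s <- ncol(z)
  des <- es_pos <- es_neg <- matrix(
    NA_real_, nrow = length(regs), ncol = n_s,
    dimnames = list(names(regs), colnames(z)))
  flagged <- character(0)
  ords <- apply(z, 2, function(v) order(-v, genes))
  absz <- abs(z)
  for (i in seq_along(regs)) {
    mode <- regs[[i]]
    present <- names(mode)[names(mode) %in% genes]
    if (length(present) == 0) {
      warning(sprintf("regulon %s has no target in the matrix; NA activity",
                      names(regs)[i]))
      next
    }
    if (length(present) < 0.5 * length(mode))
      flagged <- c(flagged, names(regs)[i])
    pos <- present[mode[present] > 0]
    neg <- present[mode[present] < 0]
    is_pos <- genes %in% pos
    is_neg <- genes %in% neg
    for (s in seq_len(n_s)) {
      ord <- ords[, s]
      w <- absz[ord, s]
      ep <- if (length(pos) > 0) es_from_order(is_pos[ord], w) else 0
      en <- if (length(neg) > 0) es_from_order(is_neg[ord], w) else 0
      es_pos[i, s] <- ep
      es_neg[i, s] <- en
      des[i, s] <- ep - en
    }
  }
  structure(des, class = c("activity_matrix", class(des)),
            es_pos = es_pos, es_neg = es_neg, flagged = flagged)
}

# Extract per-regulon mode vectors from a regnet or a planted truth.
network_modes <- function(network) {
  if (inherits(network, "regnet")) {
    lapply(regulons(network, size_filtered = TRUE), `[[`, "mode")
  } else if (inherits(network, "synthetic_truth")) {
    keep <- vapply(network$regulons, length, integer(1)) >= 15
    lapply(network$regulons[keep], function(w)
      setNames(as.integer(sign(w)), names(w)))
  } else {
    stop("'network' must be a 'regnet' or 'synthetic_truth'")
  }
}

#' Agonist/antagonist regulon association map
#'
#' For every pair of size-filtered regulons sharing at least `min_shared`
#' targets, reports the number of shared targets and the fraction regulated
#' in the same direction (mode product +1). Pairs with agreement above 0.5
#' are agonists, below 0.5 antagonists, exactly 0.5 ambiguous.
#'
#' @param network a `regnet` or `synthetic_truth` (at least 2 regulons).
#' @param min_shared minimum shared-target count for a pair to be reported
#'   (default 1).
#' @return A data.frame with columns `tf1`, `tf2`, `shared`, `agreement`,
#'   `label`.
#' @export
association_map <- function(network, min_shared = 1) {
  modes <- network_modes(network)
  if (length(modes) < 2) stop("at least 2 regulons are required")
  tfs <- names(modes)
  out <- list()
  for (i in seq_len(length(tfs) - 1)) {
    for (j in seq(i + 1, length(tfs))) {
      shared <- intersect(names(modes[[i]]), names(modes[[j]]))
      if (length(shared) < min_shared) next
      agree <- mean(modes[[i]][shared] * modes[[j]][shared] == 1)
      out[[length(out) + 1]] <- data.frame(
        tf1 = tfs[i], tf2 = tfs[j], shared = length(shared),
        agreement = agree,
        label = if (agree > 0.5) "agonist" else
          if (agree < 0.5) "antagonist" else "ambiguous",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(tf1 = character(0), tf2 = character(0),
                      shared = integer(0), agreement = numeric(0),
                      label = character(0)))
  do.call(rbind, out)
}

#' Hierarchical clustering of regulon activity
#'
#' Regulon profiles are clustered by average-linkage agglomeration on
#' `1 - Pearson correlation`; samples are clustered on Euclidean distance.
#' Ties in merge distance resolve by item order, which is deterministic for
#' a fixed input.
#'
#' @param activity a [regulon_activity_matrix()] result (at least 2
#'   regulons and 2 samples, no missing rows).
#' @param k number of flat regulon clusters to cut (at most the number of
#'   regulons).
#' @return An object of class `cluster_tree`: `regulon_hclust`,
#'   `sample_hclust`, `regulon_clusters` (cut at `k`) and `k`.
#' @export
cluster_activity <- function(activity, k = 2) {
  a <- unclass(activity)
  if (nrow(a) < 2 || ncol(a) < 2)
    stop("need at least 2 regulons and 2 samples")
  if (anyNA(a)) stop("activity matrix contains NA rows; drop them first")
  if (k > nrow(a)) stop("'k' exceeds the number of regulons")
  d_reg <- as.dist(1 - cor(t(a)))
  hc_reg <- hclust(d_reg, method = "average")
  hc_smp <- hclust(dist(t(a)), method = "average")
  structure(list(regulon_hclust = hc_reg, sample_hclust = hc_smp,
                 regulon_clusters = cutree(hc_reg, k = k), k = k),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("Activity clustering: %d regulons cut at k = %d\n",
              length(x$regulon_clusters), x$k))
  print(split(names(x$regulon_clusters), x$regulon_clusters))
  invisible(x)
}
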