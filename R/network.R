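#' Rank-transform a vector into equal-frequency bins
#'
#' Ties take average ranks; a constant vector collapses into a single bin
#' (its MI with anything is then 0).
#'
#' @param x numeric vector.
#' @param n_bins number of bins.
#' @return Integer vector of bin indices in `1..n_bins`.
#' @keywords internal
rank_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "average")
  b <- ceiling(r * n_bins / length(x))
  as.integer(pmin(pmax(b, 1L), n_bins))
}

discretize_expr <- function(expr, n_bins) {
  n <- ncol(expr)
  bins <- matrix(0L, nrow = n, ncol = nrow(expr),
                 dimnames = list(colnames(expr), rownames(expr)))
  for (i in seq_len(nrow(expr))) bins[, i] <- rank_bins(expr[i, ], n_bins)
  bins
}

#' Mutual information between regulators and all genes
#'
#' Estimates MI (in nats) with the plug-in entropy estimator on
#' rank-transformed values discretised into `n_bins` equal-frequency bins.
#' For a perfectly monotone pair with `n` divisible by `n_bins` the estimate
#' equals `log(n_bins)` exactly. The estimator is symmetric in its
#' arguments; self-pairs are set to `NA`.
#'
#' @param expr genes x samples log2 expression matrix with dimnames.
#' @param tfs character vector of regulator gene ids; ids absent from
#'   `expr` are reported and skipped.
#' @param n_bins number of bins; default `round(n_samples^(1/3))` (cube-root
#'   rule), which keeps the `n_bins^2` joint cells populated and the
#'   permutation null tight. Square-root binning leaves most joint cells
#'   with 0-1 samples at typical cohort sizes and costs detection power.
#' @return A TFs x genes matrix of MI values (nats) of class `mi_matrix`,
#'   with attributes `n_bins`, `bins` (the discretised data, reused by
#'   [filter_edges_by_permutation()]) and `constant_genes` (zero-variance
#'   genes, flagged but kept).
#' @export
compute_mi_matrix <- function(expr, tfs, n_bins = NULL) {
  stop_if_not_matrix(expr)
  if (length(tfs) == 0) stop("'tfs' must be non-empty")
  missing_tfs <- setdiff(tfs, rownames(expr))
  if (length(missing_tfs) > 0) {
    message(sprintf("%d regulator(s) absent from the expression matrix, skipped: %s",
                    length(missing_tfs),
                    paste(head(missing_tfs, 5), collapse = ", ")))
    tfs <- intersect(tfs, rownames(expr))
  }
  if (length(tfs) == 0) stop("no regulator is present in the matrix")
  n <- ncol(expr)
  if (is.null(n_bins)) n_bins <- max(2L, as.integer(round(n^(1 / 3))))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  if (n < 2 * n_bins)
    stop("need at least 2 * n_bins samples for MI estimation")
  constant <- rownames(expr)[apply(expr, 1, function(v) max(v) == min(v))]
  bins <- discretize_expr(expr, n_bins)
  mi <- cpp_mi_all(bins[, tfs, drop = FALSE], bins, n_bins)
  dimnames(mi) <- list(tfs, rownames(expr))
  for (tf in tfs) mi[tf, tf] <- NA_real_
  structure(mi, class = c("mi_matrix", class(mi)), n_bins = n_bins,
            bins = bins, constant_genes = constant)
}

#' Filter MI edges by a pooled permutation null
#'
#' Builds an empirical null by permuting the sample labels of targets and
#' recomputing MI for every (TF, target) pair; all draws are pooled into a
#' single null distribution (so `n_perm` permutations yield
#' `n_perm * n_pairs` null values). Empirical p-values use the add-one
#' estimator `p = (1 + #\{null >= mi\}) / (1 + total draws)` and are adjusted
#' with Benjamini-Hochberg across all tested pairs (globally by default).
#'
#' @param mi a [compute_mi_matrix()] result.
#' @param n_perm number of permutations (at least 100).
#' @param alpha BH-adjusted significance level for retaining edges.
#' @param per_tf adjust p-values within each TF instead of globally.
#' @param seed RNG seed for the permutations.
#' @return A data.frame of retained edges with columns `tf`, `target`,
#'   `mi`, `p`, `p_adj`, carrying the stage parameters as the `params`
#'   attribute.
#' @export
filter_edges_by_permutation <- function(mi, n_perm = 1000, alpha = 0.05,
                                        per_tf = FALSE, seed = 1) {
  if (!inherits(mi, "mi_matrix"))
    stop("'mi' must come from compute_mi_matrix()")
  if (n_perm < 100) stop("'n_perm' must be at least 100")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  bins <- attr(mi, "bins")
  n_bins <- attr(mi, "n_bins")
  tfs <- rownames(mi)
  n <- nrow(bins)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  null_mi <- cpp_mi_null(bins[, tfs, drop = FALSE], bins, n_bins, perms)
  # drop self-pair draws so the pool matches the tested pairs exactly
  dim(null_mi) <- c(length(tfs), ncol(mi), n_perm)
  self_idx <- cbind(seq_along(tfs), match(tfs, colnames(mi)))
  keep_mask <- matrix(TRUE, length(tfs), ncol(mi))
  keep_mask[self_idx] <- FALSE
  null_sorted <- sort(null_mi[rep_len(as.vector(keep_mask),
                                      length(null_mi))])
  total <- length(null_sorted)

  obs <- data.frame(tf = rep(tfs, times = ncol(mi)),
                    target = rep(colnames(mi), each = length(tfs)),
                    mi = as.vector(unclass(mi)), stringsAsFactors = FALSE)
  obs <- obs[!is.na(obs$mi), ]
  n_ge <- total - findInterval(obs$mi, null_sorted, left.open = TRUE)
  obs$p <- (1 + n_ge) / (1 + total)
  if (per_tf) {
    obs$p_adj <- stats::ave(obs$p, obs$tf,
                            FUN = function(p) p.adjust(p, "BH"))
  } else {
    obs$p_adj <- p.adjust(obs$p, "BH")
  }
  edges <- obs[obs$p_adj <= alpha, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "params") <- list(n_bins = n_bins, n_perm = n_perm,
                                alpha = alpha, per_tf = per_tf, seed = seed,
                                universe = colnames(mi))
  edges
}

# MI lookup for an unordered pair among retained edges
edge_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Prune indirect edges with the data-processing inequality (DPI)
#'
#' For every triplet (TF1, TF2, g) in which the TF1-TF2, TF1-g and TF2-g
#' edges are all present, the TF-g edge with the smallest MI is removed if
#' it is smaller than both other edges by more than `dpi_eps`. The TF-TF
#' edge anchoring a triplet is never removed by that triplet. All removals
#' are decided against the pre-pruning edge set, so the result does not
#' depend on processing order.
#'
#' @param edges a [filter_edges_by_permutation()] result (must include
#'   TF-TF pairs where significant).
#' @param dpi_eps non-negative tolerance; larger values prune less.
#' @return The edge data.frame with pruned rows removed; the number removed
#'   is recorded in `params$dpi_removed`.
#' @export
apply_dpi <- function(edges, dpi_eps = 0) {
  if (dpi_eps < 0) stop("'dpi_eps' must be non-negative")
  params <- attr(edges, "params")
  if (nrow(edges) == 0) {
    attr(edges, "params") <- c(params, list(dpi_eps = dpi_eps,
                                            dpi_removed = 0L))
    return(edges)
  }
  tfs <- unique(edges$tf)
  mi_of <- setNames(edges$mi, edge_key(edges$tf, edges$target))
  mi_of <- mi_of[!duplicated(names(mi_of))]
  targets_of <- split(edges$target, edges$tf)

  drop_keys <- character(0)
  tf_pairs <- if (length(tfs) >= 2) utils::combn(sort(tfs), 2) else
    matrix(character(0), nrow = 2)
  for (j in seq_len(ncol(tf_pairs))) {
    t1 <- tf_pairs[1, j]; t2 <- tf_pairs[2, j]
    k_tt <- edge_key(t1, t2)
    m_tt <- mi_of[k_tt]
    if (is.na(m_tt)) next
    shared <- setdiff(intersect(targets_of[[t1]], targets_of[[t2]]),
                      c(t1, t2))
    if (length(shared) == 0) next
    k1 <- edge_key(t1, shared); k2 <- edge_key(t2, shared)
    m1 <- mi_of[k1]; m2 <- mi_of[k2]
    rm1 <- m1 < m2 - dpi_eps & m1 < m_tt - dpi_eps
    rm2 <- m2 < m1 - dpi_eps & m2 < m_tt - dpi_eps
    drop_keys <- c(drop_keys, k1[rm1], k2[rm2])
  }
  drop_keys <- unique(drop_keys)
  keep <- !(edge_key(edges$tf, edges$target) %in% drop_keys)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- c(params, list(dpi_eps = dpi_eps,
                                        dpi_removed = sum(!keep)))
  out
}

#' Assemble signed regulons from filtered edges
#'
#' The mode of action of each retained (TF, target) edge is the sign of the
#' Spearman correlation between the TF and target expression profiles;
#' targets with exactly zero correlation are dropped with a warning.
#' Regulons below `min_size` targets are kept in the listing but flagged, so
#' association and MRA stages can exclude them.
#'
#' @param edges a filtered (and optionally DPI-pruned) edge data.frame.
#' @param expr the expression matrix the edges were inferred from.
#' @param min_size minimum regulon size for downstream analyses
#'   (default 15).
#' @return An object of class `regnet` with elements `regulons` (per TF:
#'   `targets` MI weights, `mode` +/-1, `size`, `pass_size`), `universe`
#'   and `params`.
#' @export
build_regulons <- function(edges, expr, min_size = 15) {
  stop_if_not_matrix(expr)
  if (min_size < 1) stop("'min_size' must be at least 1")
  params <- attr(edges, "params")
  if (is.null(params)) params <- list()
  params$min_size <- min_size
  universe <- if (!is.null(params$universe)) params$universe else
    rownames(expr)
  regulons <- list()
  n_zero <- 0L
  for (tf in unique(edges$tf)) {
    sub <- edges[edges$tf == tf & edges$target != tf, , drop = FALSE]
    if (nrow(sub) == 0) next
    rho <- suppressWarnings(
      cor(expr[tf, ], t(expr[sub$target, , drop = FALSE]),
          method = "spearman"))
    mode <- sign(as.vector(rho))
    zero <- mode == 0 | is.na(mode)
    n_zero <- n_zero + sum(zero)
    sub <- sub[!zero, , drop = FALSE]
    mode <- mode[!zero]
    if (nrow(sub) == 0) next
    regulons[[tf]] <- list(tf = tf,
                           targets = setNames(sub$mi, sub$target),
                           mode = setNames(as.integer(mode), sub$target),
                           size = nrow(sub),
                           pass_size = nrow(sub) >= min_size)
  }
  if (n_zero > 0)
    warning(sprintf("%d target(s) with zero TF-target correlation dropped",
                    n_zero))
  structure(list(regulons = regulons, universe = universe, params = params),
            class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  sizes <- vapply(x$regulons, `[[`, integer(1), "size")
  pass <- vapply(x$regulons, `[[`, logical(1), "pass_size")
  cat("Regulatory network\n")
  cat(sprintf("  %d regulons (%d of size >= %d), universe of %d genes\n",
              length(sizes), sum(pass), x$params$min_size,
              length(x$universe)))
  invisible(x)
}

#' Regulons passing the size filter
#'
#' @param network a `regnet`.
#' @param size_filtered keep only regulons meeting `min_size`.
#' @return Named list of regulon records.
#' @export
regulons <- function(network, size_filtered = TRUE) {
  stopifnot(inherits(network, "regnet"))
  regs <- network$regulons
  if (size_filtered)
    regs <- Filter(function(r) isTRUE(r$pass_size), regs)
  regs
}

#' One-call network inference
#'
#' Chains [compute_mi_matrix()], [filter_edges_by_permutation()],
#' [apply_dpi()] (unless `dpi_eps` is `NA`) and [build_regulons()].
#'
#' @inheritParams compute_mi_matrix
#' @inheritParams filter_edges_by_permutation
#' @inheritParams apply_dpi
#' @inheritParams build_regulons
#' @param dpi_eps DPI tolerance; `NA` disables DPI pruning.
#' @return A `regnet`.
#' @export
infer_network <- function(expr, tfs, n_bins = NULL, n_perm = 1000,
                          alpha = 0.05, dpi_eps = 0, min_size = 15,
                          seed = 1) {
  mi <- compute_mi_matrix(expr, tfs, n_bins = n_bins)
  edges <- filter_edges_by_permutation(mi, n_perm = n_perm, alpha = alpha,
                                       seed = seed)
  if (!is.na(dpi_eps)) edges <- apply_dpi(edges, dpi_eps = dpi_eps)
  build_regulons(edges, expr, min_size = min_size)
}
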