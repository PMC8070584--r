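test_that("MI of a monotone pair equals the bin entropy exactly", {
  n <- 120
  for (B in c(4, 5, 10)) {
    m <- rbind(x = seq_len(n), y = exp(seq_len(n) / 20))
    colnames(m) <- sprintf("s%03d", seq_len(n))
    mi <- compute_mi_matrix(m, "x", n_bins = B)
    expect_equal(mi["x", "y"], log(B))
  }
})

test_that("MI is symmetric and self-pairs are excluded", {
  m <- toy_matrix(n_genes = 12, n_samples = 40, seed = 8)
  mi_fwd <- compute_mi_matrix(m, rownames(m)[1:6], n_bins = 4)
  mi_rev <- compute_mi_matrix(m, rownames(m)[7:12], n_bins = 4)
  for (a in rownames(m)[1:6]) for (b in rownames(m)[7:12]) {
    expect_equal(mi_fwd[a, b], mi_rev[b, a])
  }
  expect_true(all(is.na(diag(mi_fwd[, 1:6]))))
})

test_that("constant genes are flagged and carry zero MI", {
  m <- toy_matrix(n_genes = 5, n_samples = 24, seed = 3)
  m["g03", ] <- 7
  mi <- compute_mi_matrix(m, "g01", n_bins = 4)
  expect_true("g03" %in% attr(mi, "constant_genes"))
  expect_equal(mi["g01", "g03"], 0)
})

test_that("independent pairs stay inside the pooled permutation null band", {
  set.seed(10)
  n <- 200
  m <- matrix(rnorm(2 * n), nrow = 2,
              dimnames = list(c("x", "y"), sprintf("s%03d", seq_len(n))))
  mi <- compute_mi_matrix(m, "x", n_bins = 14)
  bins <- attr(mi, "bins")
  null <- replicate(1000, {
    idx <- sample.int(n)
    tab <- table(bins[, "x"], bins[idx, "y"])
    p <- tab / n
    px <- rowSums(p); py <- colSums(p)
    sum(p[p > 0] * log(p[p > 0] / outer(px, py)[p > 0]))
  })
  expect_gt(mi["x", "y"], quantile(null, 0.001))
  expect_lt(mi["x", "y"], quantile(null, 0.999))
})

test_that("empirical permutation p-values respect the add-one floor", {
  truth <- small_truth(seed = 2)
  co <- simulate_cohort(truth, 40, seed = 3)
  expr <- rbind(co$expression, DUP1 = co$expression["TF01", ])
  mi <- compute_mi_matrix(expr, truth$tfs)
  edges <- filter_edges_by_permutation(mi, n_perm = 100, alpha = 0.05,
                                       seed = 4)
  n_pairs <- sum(!is.na(mi))
  p_min <- 1 / (1 + 100 * n_pairs)
  expect_true(all(edges$p >= p_min))
  # a perfectly monotone pair beats every pooled null draw: minimum p
  expect_equal(edges$p[edges$tf == "TF01" & edges$target == "DUP1"], p_min)
  expect_true(all(edges$p_adj >= edges$p))
  expect_true(all(edges$p_adj <= 0.05))
  expect_error(filter_edges_by_permutation(mi, n_perm = 50), "at least 100")
  expect_error(filter_edges_by_permutation(mi, n_perm = 100, alpha = 1.5),
               "0, 1")
})

test_that("DPI removes the weakest edge of a fully connected triplet", {
  edges <- data.frame(
    tf = c("TF1", "TF1", "TF2"),
    target = c("TF2", "g", "g"),
    mi = c(0.8, 0.3, 0.7),
    p = 0.001, p_adj = 0.001, stringsAsFactors = FALSE)
  out <- apply_dpi(edges, dpi_eps = 0)
  expect_false(any(out$tf == "TF1" & out$target == "g"))
  expect_equal(nrow(out), 2)
  # tolerance saturation: eps larger than every gap removes nothing
  out2 <- apply_dpi(edges, dpi_eps = 1)
  expect_equal(nrow(out2), 3)
  # TF-TF edge is never removed by the triplet it anchors
  edges$mi <- c(0.2, 0.8, 0.7)
  out3 <- apply_dpi(edges, dpi_eps = 0)
  expect_equal(nrow(out3), 3)
  # empty edge list passes through
  expect_equal(nrow(apply_dpi(edges[0, ])), 0)
})

test_that("DPI prunes a planted chain and spares every direct edge", {
  # TF1 -> TF2 -> targets with small observation noise: the indirect
  # TF1-target MI is strictly smallest by the data-processing inequality
  set.seed(7)
  n <- 200
  tf1 <- rnorm(n)
  tf2 <- tf1 + rnorm(n, sd = 0.3)
  targets <- vapply(1:20, function(i) tf2 + rnorm(n, sd = 0.3),
                    numeric(n))
  m <- rbind(TF1 = tf1, TF2 = tf2, t(targets))
  rownames(m) <- c("TF1", "TF2", sprintf("g%02d", 1:20))
  colnames(m) <- sprintf("s%03d", seq_len(n))
  mi <- compute_mi_matrix(m, c("TF1", "TF2"))
  edges <- filter_edges_by_permutation(mi, n_perm = 200, seed = 8)
  pruned <- apply_dpi(edges, dpi_eps = 0)
  indirect <- pruned$tf == "TF1" & pruned$target != "TF2"
  direct <- pruned$tf == "TF2" & pruned$target != "TF1"
  expect_equal(sum(indirect), 0)
  expect_equal(sum(direct), 20)
  expect_true(any(pruned$tf == "TF1" & pruned$target == "TF2"))
})

test_that("regulon assembly applies the size filter at the stated boundary", {
  set.seed(5)
  n <- 60
  act <- rnorm(n)
  m <- rbind(TF1 = act + rnorm(n, sd = 0.1),
             TF2 = rnorm(n),
             t(vapply(1:15, function(i) act + rnorm(n, sd = 0.3),
                      numeric(n))),
             t(vapply(1:14, function(i) rnorm(n), numeric(n))))
  rownames(m) <- c("TF1", "TF2", sprintf("a%02d", 1:15),
                   sprintf("b%02d", 1:14))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  edges <- data.frame(tf = c(rep("TF1", 15), rep("TF2", 14)),
                      target = c(sprintf("a%02d", 1:15),
                                 sprintf("b%02d", 1:14)),
                      mi = 1, p = 0.001, p_adj = 0.001,
                      stringsAsFactors = FALSE)
  net <- build_regulons(edges, m, min_size = 15)
  expect_true(net$regulons$TF1$pass_size)   # 15 targets: retained
  expect_false(net$regulons$TF2$pass_size)  # 14 targets: excluded
  expect_length(regulons(net), 1)
  expect_length(regulons(net, size_filtered = FALSE), 2)
  expect_error(build_regulons(edges, m, min_size = 0), "at least 1")
})

test_that("mode of action follows the sign of the TF-target correlation", {
  set.seed(6)
  n <- 80
  a <- rnorm(n)
  m <- rbind(TF1 = a, up = 2 * a + rnorm(n, sd = 0.2),
             down = -2 * a + rnorm(n, sd = 0.2))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  edges <- data.frame(tf = "TF1", target = c("up", "down"), mi = 1,
                      p = 0.001, p_adj = 0.001, stringsAsFactors = FALSE)
  net <- build_regulons(edges, m, min_size = 1)
  expect_equal(net$regulons$TF1$mode[["up"]], 1L)
  expect_equal(net$regulons$TF1$mode[["down"]], -1L)
})

test_that("planted regulons are recovered with high precision and recall", {
  truth <- small_truth(seed = 12)
  co <- simulate_cohort(truth, 100, seed = 13)
  net <- infer_network(co$expression, truth$tfs, n_perm = 300, seed = 14)
  regs <- regulons(net)
  tp <- fp <- fn <- 0
  for (mr in names(truth$cluster_of)) {
    planted <- names(truth$regulons[[mr]])
    got <- setdiff(if (mr %in% names(regs)) names(regs[[mr]]$mode)
                   else character(0), truth$tfs)
    tp <- tp + length(intersect(got, planted))
    fp <- fp + length(setdiff(got, planted))
    fn <- fn + length(setdiff(planted, got))
  }
  expect_gt(tp / (tp + fp), 0.75)
  expect_gt(tp / (tp + fn), 0.75)
})
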