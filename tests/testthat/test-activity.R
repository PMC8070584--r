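test_that("z-score transform standardises rows and drops constants", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(2, 8, 5))
  colnames(m) <- c("s1", "s2", "s3")
  expect_warning(z <- zscore_transform(m), "constant")
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(attr(z, "dropped"), "g2")
  for (g in rownames(z)) {
    expect_lt(abs(mean(z[g, ])), 1e-10)
    expect_lt(abs(sd(z[g, ]) - 1), 1e-10)
  }
  expect_error(zscore_transform(m[, 1, drop = FALSE]), "2 samples")
})

test_that("enrichment score reproduces the hand-walked running sums", {
  z <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  # hits at the top: +3/5, +2/5 -> peak 1.0
  expect_equal(enrichment_score(z, c("g1", "g2")), 1.0)
  # hits at the bottom: four misses of -1/4 -> trough -1.0
  expect_equal(enrichment_score(z, c("g5", "g6")), -1.0)
  # reversing the ranking negates the score for symmetric weights
  expect_equal(enrichment_score(-z, c("g1", "g2")), -1.0)
  expect_error(enrichment_score(z, character(0)), "non-empty")
  expect_error(enrichment_score(z, names(z)), "every ranked gene")
})

test_that("dES composes the two tails and is antisymmetric", {
  truth <- small_truth(seed = 1)
  net <- truth_network(truth)
  reg <- regulons(net)[[1]]
  pos <- names(reg$mode)[reg$mode > 0]
  neg <- names(reg$mode)[reg$mode < 0]
  genes <- truth$universe
  # build one sample whose top-|pos| genes are exactly the positive targets
  # and bottom-|neg| genes exactly the negative targets: dES = 2
  z_val <- seq(3, -3, length.out = length(genes))
  others <- setdiff(genes, c(pos, neg))
  ordering <- c(pos, others, neg)
  z <- matrix(z_val, ncol = 1, dimnames = list(ordering, "s1"))
  z <- cbind(z, -z[, 1])
  colnames(z) <- c("s1", "s2")
  act <- regulon_activity_matrix(z, net)
  expect_equal(act[reg$tf, "s1"], 2, tolerance = 1e-12)
  # negating every z-score negates the activity
  expect_equal(act[, "s2"], -act[, "s1"], tolerance = 1e-12)
  comp_pos <- attr(act, "es_pos"); comp_neg <- attr(act, "es_neg")
  expect_true(all(abs(comp_pos) <= 1 + 1e-12))
  expect_true(all(abs(comp_neg) <= 1 + 1e-12))
  expect_true(all(abs(unclass(act)) <= 2 + 1e-12))
})

test_that("activity tracks planted activities and separates the clusters", {
  truth <- small_truth(seed = 5)
  co <- simulate_cohort(truth, 80, seed = 6)
  z <- zscore_transform(co$expression)
  act <- regulon_activity_matrix(z, truth_network(truth))
  mrs <- names(truth$cluster_of)
  for (mr in mrs) {
    expect_gt(cor(co$activities[mr, ], unclass(act)[mr, ]), 0.7)
  }
  cl <- cluster_activity(unclass(act)[mrs, ], k = 2)
  grp <- cl$regulon_clusters
  expect_length(unique(grp[truth$cluster_of == "A"]), 1)
  expect_length(unique(grp[truth$cluster_of == "B"]), 1)
  expect_false(grp[[mrs[1]]] == grp[[mrs[3]]])
  # antagonistic mean activities across clusters
  mean_a <- colMeans(unclass(act)[mrs[truth$cluster_of == "A"], ])
  mean_b <- colMeans(unclass(act)[mrs[truth$cluster_of == "B"], ])
  expect_lt(cor(mean_a, mean_b), -0.5)
})

test_that("projection onto a reduced gene set flags depleted regulons", {
  truth <- small_truth(seed = 7)
  co <- simulate_cohort(truth, 30, seed = 8)
  z <- zscore_transform(co$expression)
  net <- truth_network(truth)
  reg1 <- regulons(net)[[1]]
  keep <- setdiff(rownames(z), names(reg1$mode)[-(1:3)])
  act <- regulon_activity_matrix(z[keep, ], net)
  expect_true(reg1$tf %in% attr(act, "flagged"))
  # a regulon with zero overlapping targets yields NA with a warning
  keep2 <- setdiff(rownames(z), names(reg1$mode))
  expect_warning(act2 <- regulon_activity_matrix(z[keep2, ], net),
                 "no target")
  expect_true(all(is.na(unclass(act2)[reg1$tf, ])))
})

test_that("association labels follow shared-target mode agreement", {
  mk_net <- function(defs) {
    regs <- lapply(names(defs), function(tf) {
      w <- defs[[tf]]
      list(tf = tf, targets = abs(w),
           mode = setNames(as.integer(sign(w)), names(w)),
           size = length(w), pass_size = TRUE)
    })
    names(regs) <- names(defs)
    structure(list(regulons = regs,
                   universe = unique(unlist(lapply(defs, names))),
                   params = list(min_size = 1)), class = "regnet")
  }
  net <- mk_net(list(R1 = c(g1 = 1, g2 = 1, g3 = -1),
                     R2 = c(g1 = 1, g2 = -1, g3 = -1)))
  am <- association_map(net)
  expect_equal(am$shared, 3)
  expect_equal(am$agreement, 2 / 3)
  expect_equal(am$label, "agonist")
  net2 <- mk_net(list(R1 = c(g1 = 1, g2 = 1), R2 = c(g1 = -1, g2 = -1)))
  am2 <- association_map(net2)
  expect_equal(am2$agreement, 0)
  expect_equal(am2$label, "antagonist")
})

test_that("planted clusters are agonistic within and antagonistic between", {
  truth <- generate_truth(truth_config(seed = 2))
  am <- association_map(truth_network(truth))
  cl <- truth$cluster_of
  for (i in seq_len(nrow(am))) {
    same <- cl[[am$tf1[i]]] == cl[[am$tf2[i]]]
    expect_equal(am$label[i], if (same) "agonist" else "antagonist")
  }
})

test_that("clustering distances behave at the extremes", {
  a <- rbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2, 3, 4) + 0.001,
             r3 = -c(1, 2, 3, 4))
  colnames(a) <- paste0("s", 1:4)
  cl <- cluster_activity(a, k = 2)
  grp <- cl$regulon_clusters
  expect_equal(grp[["r1"]], grp[["r2"]])  # near-duplicates merge first
  expect_false(grp[["r1"]] == grp[["r3"]])  # anti-correlated: distance 2
  expect_error(cluster_activity(a, k = 5), "exceeds")
})
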