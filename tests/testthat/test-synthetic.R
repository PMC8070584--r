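test_that("truth generation respects the configured cluster structure", {
  truth <- generate_truth(truth_config(seed = 7))
  expect_length(truth$cluster_of, 7)
  expect_equal(unname(table(truth$cluster_of)[c("A", "B")]),
               c(2L, 5L), ignore_attr = TRUE)
  sizes <- vapply(truth$regulons[names(truth$cluster_of)], length,
                  integer(1))
  expect_true(all(sizes == 40))
  decoy_sizes <- vapply(truth$regulons[truth$non_mr_tfs], length,
                        integer(1))
  expect_true(all(decoy_sizes < 15))
})

test_that("cross-cluster shared targets carry opposite signs", {
  truth <- small_truth(seed = 3)
  mrs_a <- names(truth$cluster_of)[truth$cluster_of == "A"]
  mrs_b <- names(truth$cluster_of)[truth$cluster_of == "B"]
  found_shared <- 0
  for (a in mrs_a) for (b in mrs_b) {
    shared <- intersect(names(truth$regulons[[a]]),
                        names(truth$regulons[[b]]))
    found_shared <- found_shared + length(shared)
    expect_true(all(truth$regulons[[a]][shared] *
                      truth$regulons[[b]][shared] < 0))
  }
  expect_gt(found_shared, 0)
  # within a cluster, shared targets have equal signs
  for (pair in list(mrs_a, mrs_b)) {
    shared <- intersect(names(truth$regulons[[pair[1]]]),
                        names(truth$regulons[[pair[2]]]))
    expect_true(all(truth$regulons[[pair[1]]][shared] ==
                      truth$regulons[[pair[2]]][shared]))
  }
})

test_that("cross_shared_fraction = 0 gives disjoint cluster target sets", {
  cfg <- truth_config(n_tfs = 8, n_mr = 4, cluster_sizes = c(2, 2),
                      n_genes = 200, targets_per_regulon = 20,
                      cross_shared_fraction = 0, seed = 2)
  truth <- generate_truth(cfg)
  a_targets <- unlist(lapply(
    truth$regulons[names(truth$cluster_of)[truth$cluster_of == "A"]],
    names))
  b_targets <- unlist(lapply(
    truth$regulons[names(truth$cluster_of)[truth$cluster_of == "B"]],
    names))
  expect_length(intersect(a_targets, b_targets), 0)
})

test_that("truth and cohorts are deterministic for a fixed seed", {
  t1 <- generate_truth(small_config(seed = 11))
  t2 <- generate_truth(small_config(seed = 11))
  expect_identical(t1, t2)
  c1 <- simulate_cohort(t1, 20, seed = 5)
  c2 <- simulate_cohort(t2, 20, seed = 5)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(t1, 20, seed = 6)
  expect_false(identical(c1$expression, c3$expression))
})

test_that("invalid configurations are rejected", {
  expect_error(truth_config(cluster_sizes = c(3, 5)), "sum to 'n_mr'")
  expect_error(truth_config(targets_per_regulon = 600), "exceeds 'n_genes'")
  expect_error(truth_config(cross_shared_fraction = 1.2), "\\[0, 1\\]")
  truth <- small_truth()
  expect_error(simulate_cohort(truth, 3), "at least 4")
  expect_error(simulate_cohort(truth, 10, noise_sd = -1), "non-negative")
})

test_that("cohort dimensions and noise-free identities hold", {
  truth <- generate_truth(truth_config(seed = 1))
  co <- simulate_cohort(truth, 120, seed = 2)
  expect_equal(dim(co$expression), c(510, 120))
  expect_equal(dim(co$activities), c(10, 120))

  # noise_sd = 0: a target regulated only by one MR with w = +1 reads the
  # activity exactly; untargeted genes are exactly zero
  co0 <- simulate_cohort(truth, 10, noise_sd = 0, seed = 3)
  mr <- names(truth$cluster_of)[3]
  n_regulators <- table(unlist(lapply(truth$regulons, names)))
  priv <- setdiff(names(truth$regulons[[mr]])[truth$regulons[[mr]] > 0],
                  names(n_regulators)[n_regulators > 1])
  expect_gt(length(priv), 0)
  expect_equal(co0$expression[priv[1], ], co0$activities[mr, ])
  untargeted <- setdiff(truth$genes, names(n_regulators))
  expect_true(all(co0$expression[untargeted, ] == 0))
})

test_that("target-activity correlation matches the attenuation closed form", {
  # target = a + e with e ~ N(0, 0.5^2): corr(a, target) = 1/sqrt(1.25)
  truth <- generate_truth(truth_config(noise_sd = 0.5, seed = 4))
  co <- simulate_cohort(truth, 120, seed = 9)
  n_regulators <- table(unlist(lapply(truth$regulons, names)))
  mr <- names(truth$cluster_of)[5]
  priv <- setdiff(names(truth$regulons[[mr]])[truth$regulons[[mr]] > 0],
                  names(n_regulators)[n_regulators > 1])
  obs <- mean(vapply(priv, function(g)
    cor(co$activities[mr, ], co$expression[g, ]), numeric(1)))
  expect_equal(obs, 1 / sqrt(1.25), tolerance = 0.03)
})

test_that("origin cohorts sit at baseline while shifted cohorts move", {
  truth <- small_truth(seed = 6)
  origin <- simulate_origin_cohort(truth, 20, seed = 21)
  case <- simulate_cohort(truth, 20, activity_shift = 3, seed = 22)
  targets <- unique(unlist(lapply(
    truth$regulons[names(truth$cluster_of)], names)))
  expect_lt(mean(abs(rowMeans(origin$expression[targets, ]))), 0.8)
  expect_gt(mean(abs(rowMeans(case$expression[targets, ]))), 1.5)
  # tiny origin groups (down to n = 2) are accepted
  tiny <- simulate_origin_cohort(truth, 2, seed = 23)
  expect_equal(ncol(tiny$expression), 2)
})

test_that("survival simulation produces valid records with monotone hazard", {
  truth <- generate_truth(truth_config(seed = 8))
  co <- simulate_cohort(truth, 120, seed = 31)
  recs <- simulate_survival(co, truth, effect_A = 0, effect_B = 1,
                            censor_rate = 0.2, seed = 32)
  expect_equal(nrow(recs), 120)
  expect_true(all(recs$time > 0))
  expect_true(all(recs$event %in% c(0, 1)))
  # higher cluster-B activity => shorter survival
  mrs_b <- names(truth$cluster_of)[truth$cluster_of == "B"]
  mean_b <- colMeans(co$activities[mrs_b, ])
  top <- recs$time[mean_b > median(mean_b)]
  bottom <- recs$time[mean_b <= median(mean_b)]
  expect_lt(median(top), median(bottom))
  expect_error(simulate_survival(co, truth, baseline_scale = 0),
               "positive")
})

test_that("methylation simulation plants beta shifts in regulon targets", {
  truth <- small_truth(seed = 9)
  mrs <- names(truth$cluster_of)
  sim <- simulate_methylation(truth, mrs, n_case = 15, n_ctrl = 9,
                              delta_beta = 0.4, noise_sd = 0.05, seed = 41)
  expect_equal(ncol(sim$beta), 24)
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  expect_setequal(sim$dm_truth,
                  unique(unlist(lapply(truth$regulons[mrs], names))))
  planted_probes <- sim$probe_map$probe[sim$probe_map$gene %in% sim$dm_truth]
  dbeta <- abs(rowMeans(sim$beta[planted_probes, sim$case_ids]) -
                 rowMeans(sim$beta[planted_probes, sim$ctrl_ids]))
  expect_gt(median(dbeta), 0.25)
  null_sim <- simulate_methylation(truth, mrs, delta_beta = 0, seed = 42)
  expect_length(null_sim$dm_truth, 0)
})
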