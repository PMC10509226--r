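test_that("pattern enumeration matches the brute-force orbit count", {
  expect_equal(nrow(enumerate_patterns(2, with_self_loops = TRUE)), 7)
  expect_equal(nrow(enumerate_patterns(3, with_self_loops = FALSE)), 13)
  expect_equal(nrow(enumerate_patterns(2, with_self_loops = FALSE)), 2)
  # independent exhaustive enumerator over all edge subsets modulo node swaps
  expect_equal(oracle_count_patterns(2, TRUE), 7)
  expect_equal(oracle_count_patterns(3, FALSE), 13)
  expect_equal(oracle_count_patterns(2, FALSE), 2)
  expect_equal(nrow(enumerate_patterns(3, with_self_loops = TRUE)),
               oracle_count_patterns(3, TRUE))
  expect_error(enumerate_patterns(5, TRUE), "k must be")
})

test_that("canonical keys are label-invariant and unique per class", {
  pats <- enumerate_patterns(3, with_self_loops = TRUE)
  expect_false(any(duplicated(pats$canonical_key)))
  set.seed(3)
  for (i in sample(nrow(pats), 10)) {
    adj <- pats$adj[[i]]
    p <- sample(3)
    expect_equal(cellcircuit:::pattern_canonical_key(adj[p, p]),
                 pats$canonical_key[i])
  }
})

test_that("induced instance matching agrees with the all-mappings oracle", {
  for (seed in 1:6) {
    W <- oracle_random_W(n = sample(4:6, 1), p_edge = 0.45, seed = seed)
    net <- net_from_W(W)
    for (spec in list(list(k = 2, loops = TRUE), list(k = 3, loops = FALSE))) {
      pats <- enumerate_patterns(spec$k, with_self_loops = spec$loops)
      inst <- find_motif_instances(net, pats)
      for (i in seq_len(nrow(pats))) {
        got <- inst[inst$pattern_id == pats$pattern_id[i], ]
        ora <- oracle_find_instances(W, pats$adj[[i]], spec$loops)
        expect_equal(nrow(got), nrow(ora))
        if (nrow(ora) > 0) {
          got_key <- sort(vapply(got$nodes, function(nd) {
            paste(sort(match(nd, rownames(W))), collapse = "-")
          }, character(1)))
          expect_equal(got_key, sort(ora$key))
          expect_equal(sort(round(got$mean_weight, 9)),
                       sort(round(ora$mean_w, 9)))
        }
      }
    }
  }
})

test_that("basic instance cases behave as forced", {
  # mutual pair, no loops: one instance, mean weight 3
  net <- as_cell_network(data.frame(sender = c("A", "B"),
                                    receiver = c("B", "A"),
                                    weight = c(2, 4)))
  pats <- enumerate_patterns(2, with_self_loops = TRUE)
  inst <- find_motif_instances(net, pats)
  expect_equal(nrow(inst), 1)
  expect_equal(inst$mean_weight, 3)
  mutual_key <- inst$canonical_key

  # single node with a self-loop engages no 2-node pattern
  loopnet <- as_cell_network(data.frame(sender = "A", receiver = "A",
                                        weight = 1))
  expect_equal(nrow(find_motif_instances(loopnet, pats)), 0)

  # directed 3-cycle: exactly one instance after automorphism dedup
  cyc <- as_cell_network(data.frame(sender = c("A", "B", "C"),
                                    receiver = c("B", "C", "A"),
                                    weight = c(1, 1, 1)))
  pats3 <- enumerate_patterns(3, with_self_loops = FALSE)
  inst3 <- find_motif_instances(cyc, pats3)
  expect_equal(nrow(inst3), 1)
  cm <- count_motifs(cyc, 3)
  hit <- cm[cm$n_instances > 0, ]
  expect_equal(hit$n_instances, 1)
  # the cycle has 3 automorphisms, so the raw mapping count is 3
  expect_equal(hit$n_mappings, 3)

  # adding a self-loop does not change 3-node class membership
  cyc_loop <- as_cell_network(data.frame(sender = c("A", "B", "C", "A"),
                                         receiver = c("B", "C", "A", "A"),
                                         weight = c(1, 1, 1, 9)))
  cm2 <- count_motifs(cyc_loop, 3)
  expect_equal(cm2$n_instances, cm$n_instances)
  # but the mutual 2-node class with a loop differs from mutual without
  expect_false(isTRUE(all.equal(
    count_motifs(cyc_loop, 2)$n_instances,
    count_motifs(cyc, 2)$n_instances)))
  expect_true(mutual_key %in% pats$canonical_key)
})

test_that("class scores sum instance mean weights", {
  expect_equal(score_pattern(data.frame(mean_weight = numeric(0))), 0)
  expect_equal(score_pattern(data.frame(mean_weight = c(3, 5))), 8)
  net <- as_cell_network(data.frame(sender = c("A", "B"),
                                    receiver = c("B", "A"),
                                    weight = c(2, 4)))
  inst <- find_motif_instances(net, enumerate_patterns(2, TRUE))
  expect_equal(score_pattern(inst), 3)
})

test_that("z-scores follow the stated arithmetic and boundary rules", {
  set.seed(1)
  null2 <- matrix(rnorm(4000, 10, 2), ncol = 2)
  z <- motif_zscores(c(a = 14, b = 13.3), null2)
  expect_equal(z$z, (c(14, 13.3) - colMeans(null2)) /
                 apply(null2, 2, sd))
  # exact threshold is NOT significant (strict inequality):
  # null mean 0, sd exactly 2, real score 3.3 -> z = 1.65 exactly
  z2 <- motif_zscores(c(x = 3.3), matrix(c(-2, 0, 2), ncol = 1))
  expect_identical(z2$z, 3.3 / 2)
  expect_false(z2$significant)
  # degenerate null
  z3 <- motif_zscores(c(x = 5, y = 7), cbind(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(z3$z, c(0, Inf))
  expect_equal(z3$significant, c(FALSE, TRUE))
  expect_error(motif_zscores(c(1, 2), matrix(1:3, ncol = 3)), "match")
  expect_error(motif_zscores(1, matrix(1, ncol = 1)), "2 null samples")
})
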