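test_that("association pairs are the support of the path product", {
  net <- toy_net()
  pairs <- association_pairs(net)
  expect_equal(nrow(pairs), 4)
  expect_setequal(paste(pairs$ncrna, pairs$disease),
                  c("1 1", "1 2", "2 1", "2 2"))

  # no target-disease edges: no association pairs
  net0 <- toy_net()
  net0$A_TD[] <- 0
  expect_equal(nrow(association_pairs(net0)), 0)

  withr::with_seed(31, {
    for (rep in 1:30) {
      net <- random_net(sample(2:6, 1), sample(2:6, 1), sample(2:6, 1))
      pairs <- association_pairs(net)
      expected <- character(0)
      for (i in seq_along(net$ncrna)) {
        for (j in oracle_known(net, i)) expected <- c(expected, paste(i, j))
      }
      expect_setequal(paste(pairs$ncrna, pairs$disease), expected)
    }
  })
})

test_that("folds partition the pairs, are seed-deterministic, and never leak", {
  net <- generate_network(generator_config(25, 20, 30, 70, 65, seed = 2))
  pairs <- association_pairs(net)
  folds <- make_folds(net, k = 5, repetitions = 2, seed = 9)
  expect_length(folds, 10)
  for (r in 1:2) {
    rep_folds <- Filter(function(f) f$repetition_id == r, folds)
    test_sets <- lapply(rep_folds, function(f) {
      paste(f$test_pairs$ncrna, f$test_pairs$disease)
    })
    all_pairs <- unlist(test_sets)
    expect_equal(sort(all_pairs), sort(paste(pairs$ncrna, pairs$disease)))
    expect_false(any(duplicated(all_pairs)))
  }
  for (f in folds) expect_true(net_is_connected(f$train_network))
  expect_equal(leakage_count(folds), 0L)

  folds2 <- make_folds(net, k = 5, repetitions = 2, seed = 9)
  expect_identical(lapply(folds, function(f) f$test_pairs),
                   lapply(folds2, function(f) f$test_pairs))

  expect_error(make_folds(toy_net(), k = 10, repetitions = 1, seed = 1),
               "association pairs")
})

test_that("held-out pairs have no length-2 path in their training network", {
  withr::with_seed(32, {
    for (s in 1:15) {
      net <- generate_network(generator_config(
        12, 10, 14, sample(25:35, 1), sample(20:30, 1), seed = s))
      folds <- make_folds(net, k = 4, repetitions = 2, seed = s + 50)
      expect_equal(leakage_count(folds), 0L)
      for (f in folds) {
        tn <- f$train_network
        i <- match(f$test_pairs$ncrna_name, tn$ncrna)
        j <- match(f$test_pairs$disease_name, tn$disease)
        for (r in which(!is.na(i) & !is.na(j))) {
          expect_false(j[r] %in% oracle_known(tn, i[r]))
        }
      }
    }
  })
})

make_rec <- function(net, R) {
  known <- (net$A_OT %*% net$A_TD) > 0
  ranked <- lapply(seq_along(net$ncrna), function(i) {
    cand <- which(!known[i, ])
    s <- R[i, cand]
    o <- order(-s, cand)
    data.frame(disease = cand[o], score = unname(s[o]))
  })
  structure(list(R = R, known = known, ranked = ranked,
                 lambda1 = NA, lambda2 = NA,
                 ncrna = net$ncrna, disease = net$disease),
            class = "recommendation")
}

test_that("a perfect ranker maximizes enhancement and zeroes recovery", {
  # 1 ncRNA, 1 target it uses, 10 candidate diseases, 2 of them held out
  A_OT <- matrix(c(1, 0, rep(0, 9)), 1, 11)
  A_TD <- rbind(c(1, rep(0, 10)), matrix(0, 10, 11))
  net <- make_net(A_OT, A_TD)
  R <- matrix(0, 1, 11)
  R[1, c(2, 3)] <- c(2, 1)    # held-out diseases scored on top
  rec <- make_rec(net, R)
  tp <- data.frame(i = c(1L, 1L), j = c(2L, 3L))
  enh <- precision_recall_enhancement(rec, tp, L = 5)
  expect_equal(unname(enh["recall"]), 1)
  # R_null = min(L, C)/C = 5/10, so e_R = 2; P_null = 2/10, P = 2/5, e_P = 2
  expect_equal(unname(enh["e_R"]), 2)
  expect_equal(unname(enh["e_P"]), 2)
  expect_equal(recovery(rec, tp), (0 + 1) / 2 / 9)
  expect_equal(roc_auc(rec, tp), 1)

  expect_error(precision_recall_enhancement(rec, tp, L = 0), "positive")
  expect_error(precision_recall_enhancement(rec, tp[0, ], L = 5), "no test")
})

test_that("a random scorer calibrates to the null model", {
  net <- generate_network(generator_config(30, 25, 60, 100, 150, seed = 12))
  folds <- make_folds(net, k = 4, repetitions = 1, seed = 13)
  res <- vapply(1:200, function(r) {
    f <- folds[[(r - 1) %% 4 + 1]]
    row <- evaluate_fold(f, scorer = "random", scorer_seed = r)
    c(row$e_P, row$e_R, row$auc, row$recovery)
  }, numeric(4))
  means <- rowMeans(res)
  expect_gt(means[1], 0.85); expect_lt(means[1], 1.15)   # e_P
  expect_gt(means[2], 0.85); expect_lt(means[2], 1.15)   # e_R
  expect_gt(means[3], 0.47); expect_lt(means[3], 0.53)   # AUC
  expect_gt(means[4], 0.45); expect_lt(means[4], 0.55)   # recovery
})

test_that("AUC matches the exhaustive pairwise oracle, with midrank ties", {
  withr::with_seed(33, {
    for (rep in 1:30) {
      net <- random_net(sample(2:5, 1), sample(2:5, 1), sample(4:8, 1), 0.3)
      R <- matrix(sample(0:3, length(net$ncrna) * length(net$disease),
                         replace = TRUE) / 3,
                  length(net$ncrna), length(net$disease))
      rec <- make_rec(net, R)
      cand <- which(!rec$known, arr.ind = TRUE)
      if (nrow(cand) < 4) next
      take <- sample(nrow(cand), max(1, nrow(cand) %/% 3))
      tp <- data.frame(i = cand[take, 1], j = cand[take, 2])
      if (nrow(cand) - length(take) == 0) next
      lab <- matrix(FALSE, nrow(R), ncol(R))
      lab[cbind(tp$i, tp$j)] <- TRUE
      sel <- !rec$known
      expect_equal(roc_auc(rec, tp), oracle_auc(R[sel], lab[sel]),
                   tolerance = 1e-12)
    }
  })
  # degenerate label sets are refused
  net <- toy_net()
  net$A_OT[2, ] <- 0
  rec <- make_rec(net, matrix(stats::runif(4), 2, 2))
  expect_error(roc_auc(rec, data.frame(i = integer(), j = integer())),
               "positive")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(34, {
    net <- random_net(5, 5, 10, 0.3)
    R <- matrix(stats::runif(50), 5, 10)
    rec <- make_rec(net, R)
    cand <- which(!rec$known, arr.ind = TRUE)
    take <- sample(nrow(cand), nrow(cand) %/% 4)
    tp <- data.frame(i = cand[take, 1], j = cand[take, 2])
    lab <- matrix(FALSE, 5, 10); lab[cbind(tp$i, tp$j)] <- TRUE
    sel <- !rec$known
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = lab[sel], predictor = R[sel], quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(roc_auc(rec, tp), ref, tolerance = 1e-12)
  })
})

test_that("ROC points rise from (0,0) to (1,1) and bracket the AUC", {
  net <- generate_network(generator_config(10, 8, 15, 25, 25, seed = 14))
  folds <- make_folds(net, k = 3, repetitions = 1, seed = 15)
  rec <- recommend(folds[[1]]$train_network, check_connected = FALSE)
  tp <- triplink:::map_test_pairs(folds[[1]])$pairs
  pts <- roc_points(rec, tp)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("recovery is 1 for a reversed ranker and skips degenerate lists", {
  A_OT <- matrix(c(1, rep(0, 5)), 1, 6)
  A_TD <- rbind(c(1, 0, 0, 0, 0, 0), matrix(0, 5, 6))
  net <- make_net(A_OT, A_TD)       # candidates: diseases 2..6
  R <- matrix(0, 1, 6)
  R[1, 2:6] <- 5:1                  # descending over candidate index
  rec <- make_rec(net, R)
  expect_equal(recovery(rec, data.frame(i = 1L, j = 6L)), 1)  # ranked last
  expect_equal(recovery(rec, data.frame(i = 1L, j = 2L)), 0)  # ranked first

  # candidate list of length 1: skipped with a warning
  A_TD1 <- rbind(c(1, 1, 1, 1, 1, 0), matrix(0, 5, 6))
  net1 <- make_net(A_OT, A_TD1)
  rec1 <- make_rec(net1, matrix(1, 1, 6))
  expect_warning(out <- recovery(rec1, data.frame(i = 1L, j = 6L)), "skipped")
  expect_true(is.nan(out))
})

test_that("personalization spans identical to disjoint lists and matches brute force", {
  net <- make_net(matrix(1, 3, 2), rbind(c(1, rep(0, 9)), c(1, rep(0, 9))))
  p <- length(net$disease)
  same <- matrix(rep(seq(p, 1), each = 3), 3, p, byrow = FALSE)
  expect_equal(personalization(make_rec(net, same), L = 3), 0)

  R <- matrix(0, 3, p)
  R[1, 2:4] <- 3:1; R[2, 5:7] <- 3:1; R[3, 8:10] <- 3:1
  expect_equal(personalization(make_rec(net, R), L = 3), 1)

  withr::with_seed(35, {
    for (rep in 1:10) {
      n <- sample(3:5, 1)
      net <- random_net(n, 3, 12, 0.2)
      R <- matrix(stats::runif(n * 12), n, 12)
      rec <- make_rec(net, R)
      L <- 4
      tops <- lapply(rec$ranked, function(rl) rl$disease[seq_len(min(L, nrow(rl)))])
      acc <- c()
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        acc <- c(acc, 1 - length(intersect(tops[[i]], tops[[j]])) / L)
      }
      expect_equal(personalization(rec, L), mean(acc), tolerance = 1e-12)
    }
  })
})

test_that("surprisal is log2(n) when only singleton diseases are recommended", {
  # 4 ncRNAs; diseases 1..2 known to one ncRNA each via distinct targets
  A_OT <- diag(4)
  A_TD <- matrix(0, 4, 6)
  A_TD[1, 1] <- 1; A_TD[2, 2] <- 1
  net <- make_net(A_OT, A_TD)
  R <- matrix(0, 4, 6)
  R[3, 1] <- 5; R[3, 2] <- 4      # o3 recommends the two singleton diseases
  rec <- make_rec(net, R)
  rec$ranked <- lapply(1:4, function(i) {
    if (i == 3) data.frame(disease = c(1L, 2L), score = c(5, 4))
    else data.frame(disease = integer(), score = numeric())
  })
  expect_equal(surprisal(rec, L = 2), log2(4))

  withr::with_seed(36, {
    net <- random_net(5, 4, 10, 0.3)
    R <- matrix(stats::runif(50), 5, 10)
    rec <- make_rec(net, R)
    L <- 3
    k_assoc <- pmax(colSums(rec$known), 1)
    slots <- unlist(lapply(rec$ranked, function(rl) rl$disease[seq_len(min(L, nrow(rl)))]))
    expect_equal(surprisal(rec, L), mean(log2(5 / k_assoc[slots])),
                 tolerance = 1e-12)
  })
})

test_that("Friedman comparison matches closed form and handles ties", {
  swept <- friedman_compare(seq(0.6, 0.69, by = 0.01),
                            seq(0.5, 0.59, by = 0.01))
  expect_equal(swept$friedman_chi2, 10, tolerance = 1e-12)
  expect_equal(swept$p_value, stats::pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  tied <- friedman_compare(rep(0.5, 6), rep(0.5, 6))
  expect_equal(tied$friedman_chi2, 0)     # identical series: indistinguishable
  expect_equal(tied$p_value, 1)
  same <- friedman_compare(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(same$friedman_chi2, 0)
  expect_equal(same$p_value, 1)

  # closed form for two untied treatments: chi2 = (wins - losses)^2 / blocks
  withr::with_seed(37, {
    for (rep in 1:20) {
      nb <- sample(4:12, 1)
      a <- stats::runif(nb); b <- stats::runif(nb)
      wins <- sum(a > b); losses <- nb - wins
      expect_equal(friedman_compare(a, b)$friedman_chi2,
                   (wins - losses)^2 / nb, tolerance = 1e-10)
    }
  })
  expect_error(friedman_compare(1:3, 1:4), "equal length")
  expect_error(friedman_compare(1, 2), "two blocks")
})

test_that("cross-validation aggregates per-fold metrics with repetition dispersion", {
  net <- generate_network(generator_config(20, 16, 24, 55, 50, seed = 16))
  rep <- cross_validate(net, 0.5, 0.5, k = 4, repetitions = 2, L = 10,
                        seed = 17)
  expect_equal(nrow(rep$per_fold), 8)
  expect_true(all(c("e_P", "e_R", "auc", "recovery", "personalization",
                    "surprisal", "auc_sd") %in% names(rep$summary)))
  expect_gte(rep$summary$auc, 0); expect_lte(rep$summary$auc, 1)
  expect_gte(rep$summary$recovery, 0); expect_lte(rep$summary$recovery, 1)
  expect_gte(rep$summary$personalization, 0)
  expect_lte(rep$summary$personalization, 1)
  expect_gte(rep$summary$surprisal, 0)
  # same folds, same settings: identical report
  rep2 <- cross_validate(net, 0.5, 0.5, k = 4, repetitions = 2, L = 10,
                         seed = 17)
  expect_identical(rep$per_fold, rep2$per_fold)
})

test_that("lambda tuning evaluates the grid on shared folds and picks by e_R then e_P", {
  net <- generate_network(generator_config(20, 16, 24, 55, 50, seed = 18))
  single <- tune_lambdas(net, data.frame(lambda1 = 0.4, lambda2 = 0.6),
                         k = 3, repetitions = 1, L = 10, seed = 19)
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best$lambda1, 0.4)

  grid <- expand.grid(lambda1 = c(0, 1), lambda2 = c(0, 1))
  t1 <- tune_lambdas(net, grid, k = 3, repetitions = 2, L = 10, seed = 19)
  t2 <- tune_lambdas(net, grid, k = 3, repetitions = 2, L = 10, seed = 19)
  expect_identical(t1$table, t2$table)
  ord <- order(-t1$table$e_R, -t1$table$e_P)
  expect_equal(t1$best$e_R, t1$table$e_R[ord[1]])
})
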