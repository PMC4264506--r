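#' All ncRNA-disease association pairs of a network
#'
#' An association pair is an (ncRNA, disease) couple connected by at least
#' one length-2 path ncRNA -> target -> disease; these are the units that
#' cross-validation partitions.
#'
#' @param net a [tripartite_network].
#' @return Data frame with columns `ncrna`, `disease` (1-based indices) and
#'   `ncrna_name`, `disease_name`.
#' @export
association_pairs <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  idx <- which(known_matrix(net), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(
    ncrna = unname(idx[, 1L]), disease = unname(idx[, 2L]),
    ncrna_name = net$ncrna[idx[, 1L]],
    disease_name = net$disease[idx[, 2L]],
    stringsAsFactors = FALSE
  )
}

# Training network for one fold: the full network with the held-out
# associations hidden, restricted to its largest connected component. An
# ncRNA-target edge (o, t) is removed exactly when it would complete a
# length-2 path from o to one of its held-out diseases; all other edges
# (the maximal no-leak edge set) are retained, so no test pair is
# reachable in its training network by construction, and no retention
# rule could keep the network better connected without leaking. Hiding an
# edge can splinter off small target/disease fragments whose only support
# it was; predictions are only made on connected networks, so the
# training network is the giant component and fragment nodes are treated
# like the held-out information they carried.
build_train_network <- function(net, train_mask, test_mask) {
  A_OT <- net$A_OT
  A_TD <- net$A_TD
  leak <- (test_mask %*% t(A_TD)) > 0                # n x m: would leak a test pair
  train_OT <- (A_OT == 1) & !leak
  train_TD <- A_TD == 1

  n <- nrow(A_OT); m <- ncol(A_OT); p <- ncol(A_TD)
  ot <- which(train_OT, arr.ind = TRUE)
  td <- which(train_TD, arr.ind = TRUE)
  if (nrow(ot) == 0L || nrow(td) == 0L) return(NULL)
  g <- igraph::make_empty_graph(n + m + p, directed = FALSE)
  g <- igraph::add_edges(g, t(rbind(cbind(ot[, 1L], n + ot[, 2L]),
                                    cbind(n + td[, 1L], n + m + td[, 2L]))))
  comp <- igraph::components(g)
  keep <- comp$membership == which.max(comp$csize)
  ot <- ot[keep[ot[, 1L]] & keep[n + ot[, 2L]], , drop = FALSE]
  td <- td[keep[n + td[, 1L]] & keep[n + m + td[, 2L]], , drop = FALSE]
  if (nrow(ot) == 0L || nrow(td) == 0L) return(NULL)
  ot <- ot[order(ot[, 1L], ot[, 2L]), , drop = FALSE]
  td <- td[order(td[, 1L], td[, 2L]), , drop = FALSE]
  tripartite_network(
    data.frame(from = net$ncrna[ot[, 1L]], to = net$target[ot[, 2L]],
               stringsAsFactors = FALSE),
    data.frame(from = net$target[td[, 1L]], to = net$disease[td[, 2L]],
               stringsAsFactors = FALSE)
  )
}

#' Connectivity-preserving cross-validation folds
#'
#' Partitions the association pairs of `net` into `k` random folds,
#' `repetitions` times. Each fold's training network is the full network
#' with the held-out associations hidden: the ncRNA-target edges that
#' would complete a length-2 path to a held-out disease are removed,
#' every other edge is retained, and the result is restricted to its
#' largest connected component (hiding an edge can splinter off small
#' fragments whose only support it was; predictions are only made on
#' connected networks). No test pair is reachable in its training network
#' by construction. A repetition whose
#' folds do not all yield connected training networks is redrawn, up to
#' `max_retries` times.
#'
#' @param net a connected [tripartite_network].
#' @param k number of folds (default 10).
#' @param repetitions number of repeated partitions (default 30).
#' @param seed integer seed; folds are fully determined by it.
#' @param max_retries partition redraws allowed per repetition before
#'   giving up (default 100).
#' @return List of `cv_fold` objects, each with elements `train_network`,
#'   `test_pairs` (data frame of held-out pairs by name and parent index),
#'   `fold_id`, `repetition_id`, `seed`.
#' @export
make_folds <- function(net, k = 10L, repetitions = 30L, seed = 1L,
                       max_retries = 100L) {
  stopifnot(inherits(net, "tripartite_network"), k >= 2L, repetitions >= 1L)
  if (!net_is_connected(net)) {
    stop("cross-validation requires a connected network", call. = FALSE)
  }
  pairs <- association_pairs(net)
  npairs <- nrow(pairs)
  if (npairs < k) {
    stop(sprintf("only %d association pairs for %d folds", npairs, k),
         call. = FALSE)
  }
  n <- length(net$ncrna); p <- length(net$disease)
  folds <- vector("list", repetitions * k)
  withr::with_seed(seed, {
    for (rep_id in seq_len(repetitions)) {
      done <- FALSE
      for (attempt in seq_len(max_retries)) {
        assignment <- sample(rep(seq_len(k), length.out = npairs))
        candidate <- vector("list", k)
        all_ok <- TRUE
        for (f in seq_len(k)) {
          test_idx <- which(assignment == f)
          train_mask <- matrix(FALSE, n, p)
          test_mask <- matrix(FALSE, n, p)
          train_mask[cbind(pairs$ncrna[-test_idx], pairs$disease[-test_idx])] <- TRUE
          test_mask[cbind(pairs$ncrna[test_idx], pairs$disease[test_idx])] <- TRUE
          tn <- build_train_network(net, train_mask, test_mask)
          if (is.null(tn) || !net_is_connected(tn)) {
            all_ok <- FALSE
            break
          }
          candidate[[f]] <- structure(
            list(train_network = tn,
                 test_pairs = pairs[test_idx, , drop = FALSE],
                 fold_id = f, repetition_id = rep_id, seed = seed),
            class = "cv_fold")
        }
        if (all_ok) {
          folds[(rep_id - 1L) * k + seq_len(k)] <- candidate
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop(sprintf(
          "could not build connected training networks for repetition %d after %d redraws",
          rep_id, max_retries), call. = FALSE)
      }
    }
  })
  folds
}

#' Count held-out pairs reachable in their training network
#'
#' Audits a fold set for information leakage: a test pair with a length-2
#' path in its own training network would let the method see the answer.
#' The fold construction guarantees a zero count; this audit re-measures
#' it independently from the rebuilt networks.
#'
#' @param folds list of `cv_fold` objects from [make_folds()].
#' @return Integer: total leaked pairs across all folds.
#' @export
leakage_count <- function(folds) {
  total <- 0L
  for (fold in folds) {
    tn <- fold$train_network
    reach <- known_matrix(tn)
    i <- match(fold$test_pairs$ncrna_name, tn$ncrna)
    j <- match(fold$test_pairs$disease_name, tn$disease)
    ok <- !is.na(i) & !is.na(j)
    if (any(ok)) total <- total + sum(reach[cbind(i[ok], j[ok])])
  }
  total
}

# Map held-out pairs of a fold into train-network indices, dropping pairs
# whose ncRNA or disease lost all its training edges.
map_test_pairs <- function(fold) {
  tn <- fold$train_network
  i <- match(fold$test_pairs$ncrna_name, tn$ncrna)
  j <- match(fold$test_pairs$disease_name, tn$disease)
  ok <- !is.na(i) & !is.na(j)
  list(pairs = data.frame(i = i[ok], j = j[ok]), n_skipped = sum(!ok))
}

# Recommendation-shaped object with uniform random scores over the same
# candidate structure; the null scorer of the evaluation protocol.
random_recommendation <- function(net, seed) {
  known <- known_matrix(net)
  n <- nrow(known); p <- ncol(known)
  withr::with_seed(seed, {
    R <- matrix(stats::runif(n * p), n, p,
                dimnames = list(net$ncrna, net$disease))
    ranked <- lapply(seq_len(n), function(i) {
      cand <- which(!known[i, ])
      s <- R[i, cand]
      o <- order(-s, cand)
      data.frame(disease = cand[o], score = unname(s[o]))
    })
    structure(
      list(R = R, known = known, ranked = ranked,
           lambda1 = NA_real_, lambda2 = NA_real_,
           ncrna = net$ncrna, disease = net$disease),
      class = "recommendation")
  })
}

#' Precision and recall enhancement over a random null model
#'
#' Standard top-`L` precision and recall of the ranked candidate lists on
#' the held-out pairs, divided by their expectation under a null model
#' that ranks candidates uniformly at random. For ncRNA `i` with `D_i`
#' held-out diseases among `C_i` candidates, the null expectations are
#' `P_null = mean(D_i / C_i)` and `R_null = mean(min(L, C_i) / C_i)`.
#' Values above 1 mean better-than-chance reliability.
#'
#' @param rec a [recommend()]-shaped result on the training network.
#' @param test_pairs data frame with columns `i` (ncRNA index) and `j`
#'   (disease index) in the coordinates of `rec`.
#' @param L list-length cutoff (default 20).
#' @return Named numeric vector: `e_P`, `e_R`, `precision`, `recall`.
#' @export
precision_recall_enhancement <- function(rec, test_pairs, L = 20L) {
  stopifnot(inherits(rec, "recommendation"))
  if (!is.numeric(L) || length(L) != 1L || L < 1) {
    stop("L must be a positive integer", call. = FALSE)
  }
  ncs <- unique(test_pairs$i)
  if (length(ncs) == 0L) {
    stop("no test ncRNAs: enhancement is undefined", call. = FALSE)
  }
  per <- vapply(ncs, function(i) {
    rl <- rec$ranked[[i]]
    top <- rl$disease[seq_len(min(L, nrow(rl)))]
    td <- test_pairs$j[test_pairs$i == i]
    hits <- sum(td %in% top)
    C <- nrow(rl)
    c(hits / L, hits / length(td), length(td) / C, min(L, C) / C)
  }, numeric(4))
  P <- mean(per[1L, ]); Rc <- mean(per[2L, ])
  P_null <- mean(per[3L, ]); R_null <- mean(per[4L, ])
  c(e_P = P / P_null, e_R = Rc / R_null, precision = P, recall = Rc)
}

#' Global ROC AUC of held-out pairs among candidates
#'
#' Pools all candidate (ncRNA, disease) pairs across ncRNAs; positives are
#' the held-out association pairs, negatives the remaining candidates.
#' AUC uses the rank (Mann-Whitney) formulation with midranks for ties.
#'
#' @inheritParams precision_recall_enhancement
#' @param truncate_at optional per-ncRNA list cutoff: candidates ranked
#'   below it are floored to the bottom of the score scale before the
#'   global ROC is formed. `NULL` (default) uses the full ranking.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(rec, test_pairs, truncate_at = NULL) {
  stopifnot(inherits(rec, "recommendation"))
  pooled <- pooled_scores(rec, test_pairs, truncate_at)
  npos <- sum(pooled$y); nneg <- sum(!pooled$y)
  if (npos == 0L || nneg == 0L) {
    stop("ROC needs at least one positive and one negative candidate pair",
         call. = FALSE)
  }
  r <- rank(pooled$s)
  (sum(r[pooled$y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

pooled_scores <- function(rec, test_pairs, truncate_at = NULL) {
  lab <- matrix(FALSE, nrow(rec$R), ncol(rec$R))
  if (nrow(test_pairs) > 0L) {
    lab[cbind(test_pairs$i, test_pairs$j)] <- TRUE
  }
  S <- rec$R
  if (!is.null(truncate_at)) {
    floor_val <- min(S) - 1
    for (i in seq_len(nrow(S))) {
      rl <- rec$ranked[[i]]
      if (nrow(rl) > truncate_at) {
        S[i, rl$disease[-seq_len(truncate_at)]] <- floor_val
      }
    }
  }
  sel <- !rec$known
  list(s = S[sel], y = lab[sel])
}

#' ROC curve points of the pooled candidate ranking
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `fpr`, `tpr`, one row per distinct
#'   score threshold (descending), starting at (0, 0).
#' @export
roc_points <- function(rec, test_pairs) {
  pooled <- pooled_scores(rec, test_pairs)
  o <- order(-pooled$s)
  y <- pooled$y[o]
  s <- pooled$s[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(
    fpr = c(0, fp[keep] / max(fp[length(fp)], 1L)),
    tpr = c(0, tp[keep] / max(tp[length(tp)], 1L))
  )
}

#' Mean normalized rank of held-out pairs
#'
#' For each held-out pair, the 0-based rank of the disease within the
#' ncRNA's candidate list divided by `C_i - 1`; 0 means every held-out
#' disease is ranked first, 1 last, and a random ranking gives about 0.5.
#' Pairs whose candidate list has fewer than two entries are skipped with
#' a warning.
#'
#' @inheritParams precision_recall_enhancement
#' @return Mean normalized rank in `[0, 1]`.
#' @export
recovery <- function(rec, test_pairs) {
  stopifnot(inherits(rec, "recommendation"))
  vals <- numeric(0)
  skipped <- 0L
  for (r in seq_len(nrow(test_pairs))) {
    i <- test_pairs$i[r]; j <- test_pairs$j[r]
    rl <- rec$ranked[[i]]
    C <- nrow(rl)
    if (C < 2L) {
      skipped <- skipped + 1L
      next
    }
    pos <- match(j, rl$disease)
    vals <- c(vals, (pos - 1) / (C - 1))
  }
  if (skipped > 0L) {
    warning(sprintf("%d test pair(s) skipped: candidate list shorter than 2",
                    skipped))
  }
  mean(vals)
}

#' Mean pairwise dissimilarity of top-L lists
#'
#' One minus the mean top-`L` overlap over all unordered ncRNA pairs:
#' 0 when every ncRNA receives the same list, 1 when all lists are
#' disjoint. High personalization indicates recommendations tailored to
#' each ncRNA rather than global popularity.
#'
#' @inheritParams precision_recall_enhancement
#' @return Value in `[0, 1]`.
#' @export
personalization <- function(rec, L = 20L) {
  stopifnot(inherits(rec, "recommendation"))
  n <- length(rec$ranked)
  if (n < 2L) {
    stop("personalization needs at least two ncRNAs", call. = FALSE)
  }
  p <- ncol(rec$R)
  memb <- matrix(FALSE, n, p)
  for (i in seq_len(n)) {
    rl <- rec$ranked[[i]]
    memb[i, rl$disease[seq_len(min(L, nrow(rl)))]] <- TRUE
  }
  inter <- memb %*% t(memb)
  ut <- upper.tri(inter)
  mean(1 - inter[ut] / L)
}

#' Mean self-information of recommended diseases
#'
#' Averages `log2(n / k_assoc(d))` over all top-`L` recommended slots,
#' where `k_assoc(d)` is the number of ncRNAs with a known length-2 path
#' to disease `d` (floored at 1). Recommending only diseases already
#' linked to every ncRNA gives 0 bits; recommending diseases linked to a
#' single ncRNA gives `log2(n)` bits -- a novelty measure.
#'
#' @inheritParams precision_recall_enhancement
#' @return Mean surprisal in bits (`>= 0`), or `NA` if no slots exist.
#' @export
surprisal <- function(rec, L = 20L) {
  stopifnot(inherits(rec, "recommendation"))
  n <- length(rec$ranked)
  k_assoc <- pmax(colSums(rec$known), 1)
  slots <- unlist(lapply(rec$ranked, function(rl) {
    rl$disease[seq_len(min(L, nrow(rl)))]
  }))
  if (length(slots) == 0L) {
    warning("no recommended slots; surprisal undefined")
    return(NA_real_)
  }
  mean(log2(n / k_assoc[slots]))
}

#' Friedman rank-sum comparison of two paired score series
#'
#' Tests whether two methods differ systematically across paired blocks
#' (e.g. per-fold AUC values) using the Friedman rank-sum test with
#' midranks for ties (chi-square reference with 1 degree of freedom for
#' two treatments).
#'
#' @param scores_a,scores_b equal-length numeric vectors, one value per
#'   block.
#' @return A `method_comparison` list: `friedman_chi2`, `p_value`, and the
#'   per-block `ranks` matrix.
#' @export
friedman_compare <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score series must have equal length", call. = FALSE)
  }
  if (length(scores_a) < 2L) {
    stop("need at least two blocks", call. = FALSE)
  }
  y <- cbind(A = scores_a, B = scores_b)
  ranks <- t(apply(y, 1L, rank))
  if (all(scores_a == scores_b)) {
    # every block internally tied: the methods are indistinguishable
    return(structure(
      list(friedman_chi2 = 0, p_value = 1, ranks = ranks),
      class = "method_comparison"))
  }
  ft <- stats::friedman.test(y)
  structure(
    list(friedman_chi2 = unname(ft$statistic),
         p_value = unname(ft$p.value),
         ranks = ranks),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4f, p-value = %.4g (%d blocks)\n",
              x$friedman_chi2, x$p_value, nrow(x$ranks)))
  invisible(x)
}

#' Evaluate one cross-validation fold
#'
#' Scores the fold's training network (with the resource-transfer method
#' or the uniform-random null scorer), then measures every metric of the
#' protocol on the held-out pairs. Held-out pairs whose ncRNA or disease
#' lost all training edges cannot be ranked and are counted as skipped.
#'
#' @param fold a `cv_fold` from [make_folds()].
#' @param lambda1,lambda2 transfer exponents.
#' @param L list-length cutoff (default 20).
#' @param scorer `"transfer"` (the method) or `"random"` (null model).
#' @param scorer_seed seed for the random scorer (ignored otherwise).
#' @return One-row data frame of metric values for the fold.
#' @export
evaluate_fold <- function(fold, lambda1 = 0.5, lambda2 = 0.5, L = 20L,
                          scorer = c("transfer", "random"),
                          scorer_seed = 1L) {
  scorer <- match.arg(scorer)
  tn <- fold$train_network
  rec <- if (scorer == "transfer") {
    recommend(tn, lambda1, lambda2, check_connected = FALSE)
  } else {
    random_recommendation(tn, scorer_seed)
  }
  mapped <- map_test_pairs(fold)
  tp <- mapped$pairs
  enh <- precision_recall_enhancement(rec, tp, L)
  auc <- roc_auc(rec, tp)
  rec_v <- suppressWarnings(recovery(rec, tp))
  pers <- personalization(rec, L)
  surp <- surprisal(rec, L)
  data.frame(
    repetition = fold$repetition_id, fold = fold$fold_id,
    lambda1 = lambda1, lambda2 = lambda2, L = L, scorer = scorer,
    e_P = unname(enh["e_P"]), e_R = unname(enh["e_R"]),
    precision = unname(enh["precision"]), recall = unname(enh["recall"]),
    auc = auc, recovery = rec_v, personalization = pers, surprisal = surp,
    n_test = nrow(tp), n_test_skipped = mapped$n_skipped,
    stringsAsFactors = FALSE
  )
}

#' Cross-validated evaluation of the resource-transfer method
#'
#' Runs the full protocol: k-fold partitions of the association pairs,
#' repeated, each fold scored on its training network and measured on its
#' held-out pairs; metrics are averaged over all folds and repetitions,
#' with dispersion reported as the standard deviation of the
#' repetition-level means.
#'
#' @param net a connected [tripartite_network].
#' @param lambda1,lambda2 transfer exponents (defaults 0.5).
#' @param k folds (default 10); `repetitions` repeated partitions
#'   (default 30).
#' @param L list-length cutoff (default 20).
#' @param seed fold-partition seed.
#' @param scorer `"transfer"` or `"random"` (null calibration).
#' @param folds optional precomputed fold list (then `k`, `repetitions`,
#'   `seed` are ignored); lets several configurations share identical
#'   partitions.
#' @return A `cv_report` list: `per_fold` (data frame, one row per fold)
#'   and `summary` (means over folds, plus `auc_sd` and `e_R_sd` across
#'   repetition means).
#' @export
cross_validate <- function(net, lambda1 = 0.5, lambda2 = 0.5, k = 10L,
                           repetitions = 30L, L = 20L, seed = 1L,
                           scorer = c("transfer", "random"), folds = NULL) {
  scorer <- match.arg(scorer)
  if (is.null(folds)) {
    folds <- make_folds(net, k = k, repetitions = repetitions, seed = seed)
  }
  per_fold <- do.call(rbind, lapply(seq_along(folds), function(fi) {
    evaluate_fold(folds[[fi]], lambda1, lambda2, L, scorer,
                  scorer_seed = seed + fi)
  }))
  metric_cols <- c("e_P", "e_R", "precision", "recall", "auc", "recovery",
                   "personalization", "surprisal")
  means <- colMeans(per_fold[metric_cols], na.rm = TRUE)
  rep_means <- stats::aggregate(per_fold[c("auc", "e_R")],
                                by = list(repetition = per_fold$repetition),
                                FUN = mean)
  summary <- as.data.frame(as.list(means))
  summary$auc_sd <- stats::sd(rep_means$auc)
  summary$e_R_sd <- stats::sd(rep_means$e_R)
  summary$lambda1 <- lambda1
  summary$lambda2 <- lambda2
  summary$L <- L
  summary$scorer <- scorer
  structure(list(per_fold = per_fold, summary = summary),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "CV report (lambda1 = %g, lambda2 = %g, L = %d, %s scorer)\n",
    s$lambda1, s$lambda2, s$L, s$scorer))
  cat(sprintf("  AUC = %.4f +/- %.4f\n", s$auc, s$auc_sd))
  cat(sprintf("  e_P(%d) = %.4f   e_R(%d) = %.4f\n", s$L, s$e_P, s$L, s$e_R))
  cat(sprintf("  recovery = %.4f  personalization = %.4f  surprisal = %.4f\n",
              s$recovery, s$personalization, s$surprisal))
  invisible(x)
}

#' Grid search over the transfer exponents
#'
#' Evaluates every `(lambda1, lambda2)` grid point by cross-validation on
#' a shared fold set and selects the point with the largest recall
#' enhancement, breaking ties by precision enhancement (then by grid
#' order). The exponents govern prediction quality and must be chosen per
#' dataset; no universal law relates them to network structure, though
#' denser networks tend to prefer values closer to zero.
#'
#' @param net a connected [tripartite_network].
#' @param grid data frame with columns `lambda1`, `lambda2`.
#' @param k,repetitions,L,seed protocol settings as in [cross_validate()].
#' @return List with `table` (one row per grid point: lambdas, `e_P`,
#'   `e_R`, `auc`) and `best` (the selected row).
#' @export
tune_lambdas <- function(net, grid, k = 10L, repetitions = 30L, L = 20L,
                         seed = 1L) {
  grid <- as.data.frame(grid)
  stopifnot(all(c("lambda1", "lambda2") %in% names(grid)),
            nrow(grid) >= 1L)
  folds <- make_folds(net, k = k, repetitions = repetitions, seed = seed)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    rep <- cross_validate(net, grid$lambda1[g], grid$lambda2[g], L = L,
                          folds = folds)
    data.frame(lambda1 = grid$lambda1[g], lambda2 = grid$lambda2[g],
               e_P = rep$summary$e_P, e_R = rep$summary$e_R,
               auc = rep$summary$auc)
  })
  table <- do.call(rbind, rows)
  best_idx <- order(-table$e_R, -table$e_P)[1L]
  list(table = table, best = table[best_idx, , drop = FALSE])
}
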