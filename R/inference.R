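check_lambda <- function(lambda, name) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop(sprintf("%s must be a single value in [0, 1]", name), call. = FALSE)
  }
}

# Shared kernel for the two partial weight matrices. A is the adjacency
# whose columns index the nodes being weighted (ncRNA x target for the
# target level, target x disease for the disease level); k_row/k_col its
# degree vectors. Entry (i, j) is
#   (1 / (k_col[i]^(1-lambda) * k_col[j]^lambda)) * sum_l A[l,i] A[l,j] / k_row[l].
# Zero degrees contribute nothing: a zero-degree column has an empty
# numerator sum, so its entries are defined as 0 (0^0 is taken as 1).
transfer_weights <- function(A, lambda) {
  k_row <- rowSums(A)
  k_col <- colSums(A)
  S <- crossprod(A, A / pmax(k_row, 1))
  pref <- outer(k_col^(1 - lambda), k_col^lambda)
  W <- S / pref
  W[!is.finite(W)] <- 0
  W
}

#' Target-level transfer weight matrix
#'
#' Weight `W_T[i, j]` is the likelihood that an ncRNA interacting with
#' target `t_i` also interacts with target `t_j`; it grows with the number
#' of ncRNAs the two targets share, each shared ncRNA contributing its
#' resource split evenly over its targets:
#' \deqn{w^T_{ij} = \frac{1}{k'(t_i)^{1-\lambda_1}\,k'(t_j)^{\lambda_1}}
#'   \sum_l \frac{a^{OT}_{li} a^{OT}_{lj}}{k'(o_l)}}
#' `lambda1 = 1` spreads resource uniformly over a node's neighbourhood
#' (each column over positive-degree nodes sums to 1); `lambda1 = 0`
#' averages it; `lambda1 = 0.5` gives a symmetric matrix.
#'
#' @param net a [tripartite_network].
#' @param lambda1 transfer exponent in `[0, 1]`.
#' @return `m x m` nonnegative matrix with target dimnames.
#' @export
target_weights <- function(net, lambda1) {
  stopifnot(inherits(net, "tripartite_network"))
  check_lambda(lambda1, "lambda1")
  transfer_weights(net$A_OT, lambda1)
}

#' Disease-level transfer weight matrix
#'
#' Weight `W_D[i, j]` is the likelihood that a target associated with
#' disease `d_i` is also linked to disease `d_j`, driven by the targets the
#' two diseases share:
#' \deqn{w^D_{ij} = \frac{1}{k''(d_i)^{1-\lambda_2}\,k''(d_j)^{\lambda_2}}
#'   \sum_l \frac{a^{TD}_{li} a^{TD}_{lj}}{k''(t_l)}}
#'
#' @param net a [tripartite_network].
#' @param lambda2 transfer exponent in `[0, 1]`.
#' @return `p x p` nonnegative matrix with disease dimnames.
#' @export
disease_weights <- function(net, lambda2) {
  stopifnot(inherits(net, "tripartite_network"))
  check_lambda(lambda2, "lambda2")
  transfer_weights(net$A_TD, lambda2)
}

#' Combined target-disease weight matrix
#'
#' Chains the two transfer levels through the target-disease adjacency:
#' `W_C = W_T (A_TD W_D)`, i.e.
#' \deqn{w^C_{ij} = \sum_t w^T_{it} \sum_r a^{TD}_{tr} w^D_{rj}.}
#' `w^C_{ij}` scores how often a path through similar targets and similar
#' diseases links `t_i` to `d_j`.
#'
#' @param W_T `m x m` target weight matrix.
#' @param W_D `p x p` disease weight matrix.
#' @param A_TD `m x p` binary target-disease adjacency.
#' @return `m x p` nonnegative matrix.
#' @export
combined_weights <- function(W_T, W_D, A_TD) {
  if (ncol(W_T) != nrow(A_TD) || nrow(W_D) != ncol(A_TD) ||
      nrow(W_T) != ncol(W_T) || nrow(W_D) != ncol(W_D)) {
    stop("non-conformable weight/adjacency dimensions", call. = FALSE)
  }
  W_T %*% (A_TD %*% W_D)
}

#' Score and rank candidate ncRNA-disease associations
#'
#' Computes the recommendation matrix `R = A_OT W_C` and, per ncRNA, the
#' ranked list of candidate diseases. A disease is a candidate for ncRNA
#' `o_i` when no length-2 path connects them in the network; known
#' (path-connected) diseases are excluded from the list. Lists are sorted
#' by score, descending; tied scores keep ascending disease-index order so
#' the ranking is deterministic.
#'
#' @param net a [tripartite_network].
#' @param lambda1,lambda2 transfer exponents in `[0, 1]` for the target and
#'   disease level (defaults 0.5, the symmetric hybrid).
#' @param check_connected if `TRUE` (default), refuse disconnected input;
#'   set to `FALSE` to score anyway (resource then only flows within each
#'   connected component and cross-component scores are 0).
#' @return An object of class `recommendation`: list with the score matrix
#'   `R` (ncRNA x disease), logical matrix `known`, `ranked` (per ncRNA a
#'   data frame with columns `disease`, `score`), the lambdas and the node
#'   name vectors.
#' @export
recommend <- function(net, lambda1 = 0.5, lambda2 = 0.5,
                      check_connected = TRUE) {
  stopifnot(inherits(net, "tripartite_network"))
  check_lambda(lambda1, "lambda1")
  check_lambda(lambda2, "lambda2")
  if (check_connected && !net_is_connected(net)) {
    stop(paste("network is not connected; predictions are only made on",
               "connected networks (use check_connected = FALSE to score",
               "per component)"), call. = FALSE)
  }
  W_T <- transfer_weights(net$A_OT, lambda1)
  W_D <- transfer_weights(net$A_TD, lambda2)
  W_C <- W_T %*% (net$A_TD %*% W_D)
  R <- net$A_OT %*% W_C
  known <- known_matrix(net)
  ranked <- lapply(seq_along(net$ncrna), function(i) {
    cand <- which(!known[i, ])
    s <- R[i, cand]
    o <- order(-s, cand)
    data.frame(disease = cand[o], score = unname(s[o]))
  })
  structure(
    list(R = R, known = known, ranked = ranked,
         lambda1 = lambda1, lambda2 = lambda2,
         ncrna = net$ncrna, disease = net$disease),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf(
    "Recommendation: %d ncRNAs x %d diseases (lambda1 = %g, lambda2 = %g)\n",
    nrow(x$R), ncol(x$R), x$lambda1, x$lambda2))
  cat(sprintf("  candidate pairs: %d\n", sum(!x$known)))
  invisible(x)
}

#' Write ranked predictions as TSV
#'
#' One row per candidate pair: `ncRNA_id`, `disease_id`, `score`, `rank`,
#' sorted per ncRNA by descending score.
#'
#' @param rec a [recommend()] result.
#' @param file output path.
#' @return Invisibly, the data frame written.
#' @export
write_predictions <- function(rec, file) {
  stopifnot(inherits(rec, "recommendation"))
  rows <- lapply(seq_along(rec$ranked), function(i) {
    rl <- rec$ranked[[i]]
    if (nrow(rl) == 0L) return(NULL)
    data.frame(ncRNA_id = rec$ncrna[i],
               disease_id = rec$disease[rl$disease],
               score = rl$score,
               rank = seq_len(nrow(rl)),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) > 0L) {
    out <- do.call(rbind, rows)
    row.names(out) <- NULL
  } else {
    out <- data.frame(ncRNA_id = character(), disease_id = character(),
                      score = numeric(), rank = integer())
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Write the score matrix as a sparse triplet file
#'
#' Plain-text triplet dump `row<TAB>col<TAB>value` of the nonzero entries
#' of `R`, preceded by a comment line with the dimensions.
#'
#' @param rec a [recommend()] result.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_score_triplets <- function(rec, file) {
  stopifnot(inherits(rec, "recommendation"))
  nz <- which(rec$R != 0, arr.ind = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %d", nrow(rec$R), ncol(rec$R), nrow(nz)), con)
  if (nrow(nz) > 0L) {
    writeLines(paste(nz[, 1L], nz[, 2L],
                     format(rec$R[nz], digits = 17), sep = "\t"), con)
  }
  invisible(file)
}

# Instrumented variant of recommend() that tallies the scalar
# multiplications of each dense product it performs (a x b times b x c
# costs a*b*c). Used by complexity_probe().
recommend_counted <- function(net, lambda1 = 0.5, lambda2 = 0.5) {
  n <- length(net$ncrna); m <- length(net$target); p <- length(net$disease)
  W_T <- transfer_weights(net$A_OT, lambda1)
  W_D <- transfer_weights(net$A_TD, lambda2)
  X <- net$A_TD %*% W_D
  W_C <- W_T %*% X
  R <- net$A_OT %*% W_C
  flops <- c(
    target_level = n * m^2 + m^2,   # crossprod + prefactor scaling
    disease_level = m * p^2 + p^2,
    chain_td = m * p^2,             # A_TD %*% W_D
    chain_combined = m^2 * p,       # W_T %*% X  (the dominant m^2 p term)
    score = n * m * p
  )
  list(R = R, flops_total = sum(flops), flops_dominant = unname(flops["chain_combined"]),
       flops = flops)
}

#' Empirical operation-count scaling of the scoring pipeline
#'
#' Runs the full scoring pipeline on synthetic networks over a ladder of
#' `(m, p)` sizes and records the scalar-multiplication count of each dense
#' matrix product actually executed. The dominant term is the combined
#' chain `W_T (A_TD W_D)`, which costs `m^2 p`; the probe exists as a
#' regression guard that the implementation keeps the expected `O(m^2 p)`
#' scaling (targets dominating ncRNAs), not as a benchmark.
#'
#' @param sizes data frame (or list of pairs) with columns `m` and `p`.
#' @param n number of ncRNAs held fixed across the ladder (default 8).
#' @param seed generator seed.
#' @return Data frame with columns `m`, `p`, `flops_total`,
#'   `flops_dominant`.
#' @export
complexity_probe <- function(sizes, n = 8L, seed = 1L) {
  sizes <- as.data.frame(sizes)
  stopifnot(all(c("m", "p") %in% names(sizes)))
  rows <- lapply(seq_len(nrow(sizes)), function(r) {
    m <- sizes$m[r]; p <- sizes$p[r]
    cfg <- generator_config(
      n = n, m = m, p = p,
      edges_ot = min(n * m, (n + m) * 2L),
      edges_td = min(m * p, p + 2L * m),
      seed = seed + r
    )
    net <- generate_network(cfg)
    cnt <- recommend_counted(net)
    data.frame(m = m, p = p, flops_total = cnt$flops_total,
               flops_dominant = cnt$flops_dominant)
  })
  do.call(rbind, rows)
}
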