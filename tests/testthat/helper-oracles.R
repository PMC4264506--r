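# Independent reference implementations used to check the package against
# literal transcriptions of the model: nested loops only, no shared code
# with the implementation under test.

# The two-level transfer weights, combined weights and score matrix.
oracle_transfer <- function(net, lambda1, lambda2) {
  A1 <- net$A_OT; A2 <- net$A_TD
  n <- nrow(A1); m <- ncol(A1); p <- ncol(A2)
  ko <- rowSums(A1); kt <- colSums(A1)
  kt2 <- rowSums(A2); kd <- colSums(A2)
  W_T <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (kt[i] == 0 || kt[j] == 0) next
    s <- 0
    for (l in seq_len(n)) {
      if (A1[l, i] == 1 && A1[l, j] == 1) s <- s + 1 / ko[l]
    }
    W_T[i, j] <- s / (kt[i]^(1 - lambda1) * kt[j]^lambda1)
  }
  W_D <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (kd[i] == 0 || kd[j] == 0) next
    s <- 0
    for (l in seq_len(m)) {
      if (A2[l, i] == 1 && A2[l, j] == 1) s <- s + 1 / kt2[l]
    }
    W_D[i, j] <- s / (kd[i]^(1 - lambda2) * kd[j]^lambda2)
  }
  W_C <- matrix(0, m, p)
  for (i in seq_len(m)) for (j in seq_len(p)) {
    s <- 0
    for (t in seq_len(m)) {
      inner <- 0
      for (r in seq_len(p)) inner <- inner + A2[t, r] * W_D[r, j]
      s <- s + W_T[i, t] * inner
    }
    W_C[i, j] <- s
  }
  R <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    s <- 0
    for (t in seq_len(m)) s <- s + A1[i, t] * W_C[t, j]
    R[i, j] <- s
  }
  list(W_T = W_T, W_D = W_D, W_C = W_C, R = R)
}

# Connected-component count by textbook breadth-first search.
oracle_components <- function(net) {
  n <- length(net$ncrna); m <- length(net$target); p <- length(net$disease)
  N <- n + m + p
  adj <- vector("list", N)
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  ot <- which(net$A_OT == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(ot))) add_edge(ot[r, 1], n + ot[r, 2])
  td <- which(net$A_TD == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(td))) add_edge(n + td[r, 1], n + m + td[r, 2])
  comp <- integer(N)
  ncomp <- 0
  for (s in seq_len(N)) {
    if (comp[s] != 0) next
    ncomp <- ncomp + 1
    queue <- s
    comp[s] <- ncomp
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0) {
          comp[w] <- ncomp
          queue <- c(queue, w)
        }
      }
    }
  }
  ncomp
}

# Length-2-path reachable diseases by explicit path enumeration.
oracle_known <- function(net, i) {
  out <- integer(0)
  for (j in seq_along(net$disease)) {
    for (t in seq_along(net$target)) {
      if (net$A_OT[i, t] == 1 && net$A_TD[t, j] == 1) {
        out <- c(out, j)
        break
      }
    }
  }
  out
}

# AUC by exhaustive positive/negative score comparison.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
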