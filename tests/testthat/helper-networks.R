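# Build a tripartite_network directly from adjacency matrices (keeps
# zero-degree nodes, unlike the edge-list constructor).
make_net <- function(A_OT, A_TD) {
  n <- nrow(A_OT); m <- ncol(A_OT); p <- ncol(A_TD)
  nc <- paste0("o", seq_len(n))
  tg <- paste0("t", seq_len(m))
  ds <- paste0("d", seq_len(p))
  dimnames(A_OT) <- list(nc, tg)
  dimnames(A_TD) <- list(tg, ds)
  structure(list(ncrna = nc, target = tg, disease = ds,
                 A_OT = A_OT, A_TD = A_TD),
            class = "tripartite_network")
}

# The 3 + 3 edge toy network: o1-t1, o1-t2, o2-t2; t1-d1, t2-d1, t2-d2.
toy_net <- function() {
  make_net(rbind(c(1, 1), c(0, 1)), rbind(c(1, 0), c(1, 1)))
}

# Random binary tripartite network (possibly disconnected) with at least
# one edge in each layer.
random_net <- function(n, m, p, density = 0.4) {
  repeat {
    A1 <- matrix(stats::rbinom(n * m, 1, density), n, m)
    A2 <- matrix(stats::rbinom(m * p, 1, density), m, p)
    if (sum(A1) > 0 && sum(A2) > 0) break
  }
  make_net(A1, A2)
}

write_toy_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ot <- file.path(dir, "ot.tsv")
  td <- file.path(dir, "td.tsv")
  writeLines(c("# ncRNA\ttarget", "o1\tt1", "o1\tt2", "o2\tt2"), ot)
  writeLines(c("t1\td1", "t2\td1", "t2\td2"), td)
  list(ot = ot, td = td, dir = dir)
}
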