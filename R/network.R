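#' Construct a tripartite ncRNA-target-disease network
#'
#' A tripartite network couples three node classes -- non-coding RNAs
#' (ncRNAs), their molecular targets (genes, miRNAs, proteins), and
#' diseases -- through two layers of edges: ncRNA-target interactions and
#' target-disease associations. It is stored as a pair of binary adjacency
#' matrices sharing the target dimension.
#'
#' Duplicate edges collapse to a single entry. Node order is the order of
#' first appearance: ncRNAs from the ncRNA-target edges, targets from the
#' ncRNA-target edges followed by the target-disease edges, diseases from
#' the target-disease edges. Targets present in only one edge layer are
#' retained with zero degree on the other side.
#'
#' @param ot_edges data frame (or 2-column matrix) of ncRNA-target edges;
#'   first column ncRNA identifier, second column target identifier.
#' @param td_edges data frame of target-disease edges; first column target
#'   identifier, second column disease identifier.
#' @return An object of class `tripartite_network`: a list with character
#'   vectors `ncrna`, `target`, `disease` and binary matrices `A_OT`
#'   (ncRNA x target) and `A_TD` (target x disease).
#' @examples
#' ot <- data.frame(ncrna = c("o1", "o1", "o2"), target = c("t1", "t2", "t2"))
#' td <- data.frame(target = c("t1", "t2", "t2"), disease = c("d1", "d1", "d2"))
#' net <- tripartite_network(ot, td)
#' dim(net$A_OT)
#' @export
tripartite_network <- function(ot_edges, td_edges) {
  ot_edges <- as.data.frame(ot_edges, stringsAsFactors = FALSE)
  td_edges <- as.data.frame(td_edges, stringsAsFactors = FALSE)
  if (ncol(ot_edges) < 2L || ncol(td_edges) < 2L) {
    stop("edge tables must have two columns", call. = FALSE)
  }
  if (nrow(ot_edges) == 0L) {
    stop("ncRNA-target edge set is empty", call. = FALSE)
  }
  if (nrow(td_edges) == 0L) {
    stop("target-disease edge set is empty", call. = FALSE)
  }
  o <- trimws(as.character(ot_edges[[1L]]))
  t1 <- trimws(as.character(ot_edges[[2L]]))
  t2 <- trimws(as.character(td_edges[[1L]]))
  d <- trimws(as.character(td_edges[[2L]]))
  if (any(!nzchar(c(o, t1, t2, d)))) {
    stop("empty node identifier in edge table", call. = FALSE)
  }

  ncrna <- unique(o)
  target <- unique(c(t1, t2))
  disease <- unique(d)

  A_OT <- matrix(0, length(ncrna), length(target),
                 dimnames = list(ncrna, target))
  A_TD <- matrix(0, length(target), length(disease),
                 dimnames = list(target, disease))
  A_OT[cbind(match(o, ncrna), match(t1, target))] <- 1
  A_TD[cbind(match(t2, target), match(d, disease))] <- 1

  structure(
    list(ncrna = ncrna, target = target, disease = disease,
         A_OT = A_OT, A_TD = A_TD),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf(
    "Tripartite network: %d ncRNAs, %d targets, %d diseases; %d + %d edges\n",
    length(x$ncrna), length(x$target), length(x$disease),
    sum(x$A_OT), sum(x$A_TD)))
  invisible(x)
}

#' @export
dim.tripartite_network <- function(x) {
  c(length(x$ncrna), length(x$target), length(x$disease))
}

read_edge_file <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s edge file not found: %s", what, path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop(sprintf("no edges in %s (file %s)", what, path), call. = FALSE)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) {
    length(p) != 2L || any(!nzchar(trimws(p)))
  }, logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed line %d in %s: expected two non-empty tab-separated fields",
      idx[bad[1L]], path), call. = FALSE)
  }
  data.frame(
    from = vapply(parts, function(p) trimws(p[1L]), character(1)),
    to = vapply(parts, function(p) trimws(p[2L]), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a tripartite network from two TSV edge lists
#'
#' Each file holds one edge per line as two tab-separated identifiers:
#' `ncRNA<TAB>target` in the first file, `target<TAB>disease` in the
#' second. Lines starting with `#` (and blank lines) are ignored; a header,
#' if any, must be commented out. Node identity is the exact string token
#' with surrounding whitespace stripped.
#'
#' @param ot_file path to the ncRNA-target edge list.
#' @param td_file path to the target-disease edge list.
#' @return A [tripartite_network] object.
#' @seealso [write_tripartite()]
#' @export
read_tripartite <- function(ot_file, td_file) {
  ot <- read_edge_file(ot_file, "ncRNA-target")
  td <- read_edge_file(td_file, "target-disease")
  tripartite_network(ot, td)
}

#' Write a tripartite network as two TSV edge lists
#'
#' Edges are written in canonical row-major index order, so writing and
#' re-reading is idempotent. The format matches [read_tripartite()].
#'
#' @param net a [tripartite_network].
#' @param ot_file,td_file output paths.
#' @return Invisibly, `net`.
#' @export
write_tripartite <- function(net, ot_file, td_file) {
  stopifnot(inherits(net, "tripartite_network"))
  ot <- which(net$A_OT == 1, arr.ind = TRUE)
  ot <- ot[order(ot[, 1L], ot[, 2L]), , drop = FALSE]
  td <- which(net$A_TD == 1, arr.ind = TRUE)
  td <- td[order(td[, 1L], td[, 2L]), , drop = FALSE]
  writeLines(paste(net$ncrna[ot[, 1L]], net$target[ot[, 2L]], sep = "\t"),
             ot_file)
  writeLines(paste(net$target[td[, 1L]], net$disease[td[, 2L]], sep = "\t"),
             td_file)
  invisible(net)
}

#' Export the node index map of a network
#'
#' @param net a [tripartite_network].
#' @return Data frame with columns `index` (1-based within node class),
#'   `name`, and `node_class` (`"ncrna"`, `"target"` or `"disease"`).
#' @export
node_index_table <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  data.frame(
    index = c(seq_along(net$ncrna), seq_along(net$target),
              seq_along(net$disease)),
    name = c(net$ncrna, net$target, net$disease),
    node_class = rep(c("ncrna", "target", "disease"),
                     times = c(length(net$ncrna), length(net$target),
                               length(net$disease))),
    stringsAsFactors = FALSE
  )
}

#' Degree vectors of the two sub-networks
#'
#' Degrees are counted separately in each layer: `k_prime_*` in the
#' ncRNA-target sub-network, `k_dprime_*` in the target-disease
#' sub-network. A target seen in only one layer has degree 0 in the other.
#'
#' @param net a [tripartite_network].
#' @return List of four named integer vectors: `k_prime_ncrna`,
#'   `k_prime_target`, `k_dprime_target`, `k_dprime_disease`.
#' @export
degree_vectors <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  list(
    k_prime_ncrna = rowSums(net$A_OT),
    k_prime_target = colSums(net$A_OT),
    k_dprime_target = rowSums(net$A_TD),
    k_dprime_disease = colSums(net$A_TD)
  )
}

tripartite_igraph <- function(net) {
  n <- length(net$ncrna); m <- length(net$target); p <- length(net$disease)
  ot <- which(net$A_OT == 1, arr.ind = TRUE)
  td <- which(net$A_TD == 1, arr.ind = TRUE)
  edges <- rbind(
    cbind(ot[, 1L], n + ot[, 2L]),
    cbind(n + td[, 1L], n + m + td[, 2L])
  )
  g <- igraph::make_empty_graph(n = n + m + p, directed = FALSE)
  igraph::add_edges(g, t(edges))
}

#' Is the tripartite network a single connected component?
#'
#' Connectivity is assessed on the undirected graph over all
#' `n + m + p` nodes with the edges of both sub-networks; an isolated node
#' therefore makes the network disconnected. Predictions are only
#' meaningful on connected networks, where resource can reach every
#' disease from every ncRNA.
#'
#' @param net a [tripartite_network].
#' @return Logical scalar.
#' @export
net_is_connected <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  igraph::count_components(tripartite_igraph(net)) == 1L
}

#' Diseases already linked to an ncRNA
#'
#' A disease is "known" for ncRNA `i` when it is reachable by a length-2
#' path ncRNA -> target -> disease. The candidate set for prediction is
#' exactly the complement.
#'
#' @param net a [tripartite_network].
#' @param ncrna_index 1-based ncRNA index.
#' @return Integer vector of disease indices (possibly empty).
#' @export
known_diseases <- function(net, ncrna_index) {
  stopifnot(inherits(net, "tripartite_network"))
  n <- length(net$ncrna)
  if (length(ncrna_index) != 1L || is.na(ncrna_index) ||
      ncrna_index < 1L || ncrna_index > n) {
    stop(sprintf("ncrna_index must be in 1..%d", n), call. = FALSE)
  }
  which(as.vector(net$A_OT[ncrna_index, , drop = FALSE] %*% net$A_TD) > 0)
}

#' @rdname known_diseases
#' @export
candidate_diseases <- function(net, ncrna_index) {
  setdiff(seq_along(net$disease), known_diseases(net, ncrna_index))
}

known_matrix <- function(net) {
  (net$A_OT %*% net$A_TD) > 0
}
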