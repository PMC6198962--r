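# Chlorotype distance matrices, minimum spanning networks with tie
# retention, eigenvector centrality, and network export.

#' Pairwise distances between chlorotype strings
#'
#' \code{hamming}: count of differing panel positions. \code{nei}: per-site
#' haploid Nei distance, -ln(m/L) with m matching positions out of L; pairs
#' with no matching position get \code{Inf} (they are excluded from network
#' construction rather than given an invented weight).
#'
#' @param chlorotypes Character vector of equal-length strings without "?".
#' @param metric \code{"hamming"} or \code{"nei"}.
#' @return Symmetric matrix with the strings as dimnames and a
#'   \code{"metric"} attribute.
#' @export
chlorotype_distances <- function(chlorotypes, metric = c("hamming", "nei")) {
  metric <- match.arg(metric)
  chlorotypes <- unique(chlorotypes)
  if (length(unique(nchar(chlorotypes))) > 1L) {
    stop("chlorotype strings have unequal lengths")
  }
  if (any(grepl("?", chlorotypes, fixed = TRUE))) {
    stop("chlorotypes contain '?'")
  }
  mat <- do.call(rbind, strsplit(chlorotypes, ""))
  L <- ncol(mat)
  D <- matrix(0, nrow(mat), nrow(mat),
              dimnames = list(chlorotypes, chlorotypes))
  for (j in seq_len(L)) D <- D + outer(mat[, j], mat[, j], "!=")
  if (metric == "nei") {
    m <- L - D
    D <- ifelse(m == 0, Inf, -log(m / L))
    diag(D) <- 0
  }
  attr(D, "metric") <- metric
  D
}

#' Minimum spanning network over chlorotypes
#'
#' Builds a minimum spanning tree (Kruskal) and additionally retains every
#' edge whose weight ties (within \code{tie_tol}) an accepted edge and that
#' would connect the same pair of components, i.e. all equally-short
#' alternative connections are kept (MSN semantics). Edges with infinite
#' weight are excluded with a warning; if that disconnects the graph a
#' spanning forest is returned with a warning.
#'
#' @param dist Symmetric distance matrix as from
#'   \code{\link{chlorotype_distances}}.
#' @param node_freqs Optional named vector of node frequencies (counts);
#'   stored on the nodes (and used for node sizing / optional
#'   frequency-weighted centrality).
#' @param node_groups Optional named list or data frame describing per-group
#'   composition; stored as-is.
#' @param tie_tol Absolute tolerance for weight ties (integer Hamming
#'   weights tie exactly; Nei weights need a tolerance).
#' @return Object of class \code{"haplo_network"}: list with \code{nodes}
#'   (data frame label/freq) and \code{edges} (data frame from/to/weight/
#'   tie_group; tie_group numbers distinct retained weight levels).
#' @export
minimum_spanning_network <- function(dist, node_freqs = NULL,
                                     node_groups = NULL, tie_tol = 1e-9) {
  labels <- rownames(dist)
  n <- length(labels)
  if (n == 0L) stop("empty distance matrix")
  if (!isTRUE(all.equal(dist[is.finite(dist)],
                        t(dist)[is.finite(t(dist))]))) {
    stop("distance matrix must be symmetric")
  }
  E <- which(upper.tri(dist), arr.ind = TRUE)
  w <- dist[E]
  if (any(!is.finite(w))) {
    warning(sum(!is.finite(w)), " pair(s) with infinite distance excluded")
    E <- E[is.finite(w), , drop = FALSE]
    w <- w[is.finite(w)]
  }
  o <- order(w)
  E <- E[o, , drop = FALSE]
  w <- w[o]
  comp <- seq_len(n)
  keep <- logical(length(w))
  i <- 1L
  while (i <= length(w)) {
    j <- i
    while (j < length(w) && abs(w[j + 1L] - w[i]) <= tie_tol) j <- j + 1L
    comp_at_block <- comp  # component structure before this weight level
    for (k in i:j) {
      if (comp_at_block[E[k, 1]] != comp_at_block[E[k, 2]]) keep[k] <- TRUE
    }
    for (k in i:j) {
      if (keep[k]) {
        a <- comp[E[k, 1]]; b <- comp[E[k, 2]]
        if (a != b) comp[comp == b] <- a
      }
    }
    i <- j + 1L
  }
  if (length(unique(comp)) > 1L) {
    warning("network is a spanning forest (", length(unique(comp)),
            " components) after excluding non-finite distances")
  }
  kept_w <- w[keep]
  tie_group <- if (length(kept_w)) {
    cumsum(c(TRUE, diff(kept_w) > tie_tol))
  } else integer(0)
  edges <- data.frame(from = labels[E[keep, 1]], to = labels[E[keep, 2]],
                      weight = kept_w, tie_group = tie_group,
                      stringsAsFactors = FALSE)
  freqs <- if (is.null(node_freqs)) rep(1, n) else {
    as.numeric(node_freqs[labels])
  }
  nodes <- data.frame(label = labels, freq = freqs, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, metric = attr(dist, "metric"),
                 groups = node_groups),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (metric: ", x$metric %||% "unknown", ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Affinity matrix of a network: edges become affinities (1/weight by
# default; zero weights get the maximum affinity present).
affinity_matrix <- function(network, affinity = c("inverse", "max_minus")) {
  affinity <- match.arg(affinity)
  labels <- network$nodes$label
  n <- length(labels)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  e <- network$edges
  if (nrow(e)) {
    wpos <- e$weight[e$weight > 0]
    a <- switch(affinity,
      inverse = {
        base <- ifelse(e$weight > 0, 1 / e$weight, NA)
        mx <- if (length(wpos)) max(1 / wpos) else 1
        ifelse(is.na(base), mx, base)
      },
      max_minus = max(e$weight) - e$weight + min(e$weight[e$weight > 0], 1)
    )
    for (k in seq_len(nrow(e))) {
      A[e$from[k], e$to[k]] <- A[e$to[k], e$from[k]] <- a[k]
    }
  }
  A
}

#' Eigenvector centrality of a chlorotype network
#'
#' Principal eigenvector of the network's affinity matrix (edge affinity =
#' 1/weight by default, so closer chlorotypes couple more strongly),
#' computed by power iteration and normalised to a maximum of 1. With
#' \code{frequency_weighted = TRUE} each node is treated as the collapsed
#' clique of its \code{freq} identical individuals: the diagonal receives
#' \code{(f_i - 1)} couplings at the zero-distance affinity (the strongest
#' affinity present), so abundant chlorotypes anchor the centrality the way
#' they would in the individual-level network. On a disconnected network
#' scores are computed per component with a warning.
#'
#' @param network A \code{\link{minimum_spanning_network}} result.
#' @param affinity \code{"inverse"} (1/weight, default) or
#'   \code{"max_minus"} (max weight minus weight).
#' @param frequency_weighted Scale affinities by node frequencies.
#' @param tol Relative convergence tolerance of the power iteration.
#' @return Named numeric vector of scores in [0, 1].
#' @export
eigenvector_centrality <- function(network,
                                   affinity = c("inverse", "max_minus"),
                                   frequency_weighted = FALSE,
                                   tol = 1e-10) {
  A <- affinity_matrix(network, affinity)
  if (frequency_weighted) {
    f <- as.numeric(network$nodes$freq)
    diag(A) <- pmax(f - 1, 0) * max(A)
  }
  n <- nrow(A)
  scores <- stats::setNames(numeric(n), rownames(A))
  comps <- graph_components(A)
  if (length(unique(comps)) > 1L) {
    warning("network is disconnected; centrality computed per component")
  }
  for (cc in unique(comps)) {
    idx <- which(comps == cc)
    if (length(idx) == 1L) { scores[idx] <- 1; next }
    scores[idx] <- power_iteration(A[idx, idx, drop = FALSE], tol)
  }
  scores / max(scores)
}

# Connected components of a (weighted) adjacency matrix.
graph_components <- function(A) {
  n <- nrow(A)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(A[i, ] > 0)
      if (length(nb)) {
        m <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# Dominant eigenvector by power iteration, normalised to max 1.
# A positive diagonal shift makes the dominant eigenvalue strictly
# separated in modulus (bipartite graphs otherwise oscillate between
# +/- lambda_1), leaving the eigenvector unchanged; convergence is judged
# on the vector itself.
power_iteration <- function(A, tol = 1e-10, max_iter = 100000L) {
  n <- nrow(A)
  shift <- max(A)
  if (shift == 0) return(rep(1, n))  # edgeless component
  B <- A + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    nv <- as.vector(B %*% v)
    nv <- nv / sqrt(sum(nv^2))
    if (sqrt(sum((nv - v)^2)) <= tol) {
      v <- nv
      break
    }
    v <- nv
  }
  v <- abs(v)
  v / max(v)
}

#' Convert a haplotype network to an igraph object
#' @param network A \code{haplo_network}.
#' @return An \code{igraph} graph with \code{weight}, \code{tie_group} edge
#'   attributes and \code{freq} vertex attribute.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  g
}

#' Export a network as GraphML
#' @param network A \code{haplo_network}.
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export a network edge list and node table as TSV
#' @param network A \code{haplo_network}.
#' @param edge_path,node_path Output paths (skipped when NULL).
#' @export
write_network_tables <- function(network, edge_path = NULL, node_path = NULL) {
  if (!is.null(edge_path)) {
    utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(node_path)) {
    utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(network)
}
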