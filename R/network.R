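#' Directed, signed gene-gene interaction networks
#'
#' A `gene_network` is a directed graph over a fixed gene universe. Each edge
#' runs from a regulator (parent) to a target (child) and carries a sign:
#' `+1` for activation, `-1` for inhibition. Inferred networks additionally
#' carry a real-valued interaction weight per edge. Self-loops and duplicate
#' (parent, child) pairs are disallowed.
#'
#' @param genes Character vector of gene identifiers, or a single integer
#'   giving the number of genes (identifiers `g001`, `g002`, ... are created).
#' @param edges A data frame with integer columns `parent` and `child`
#'   (1-based indices into `genes`), an optional `sign` column (`+1`/`-1`),
#'   and an optional numeric `weight` column.
#' @return An object of class `gene_network` with elements `genes` and
#'   `edges`.
#' @examples
#' net <- gene_network(3, data.frame(parent = c(1, 2), child = c(2, 3),
#'                                   sign = c(1, -1)))
#' net
#' @export
gene_network <- function(genes, edges = NULL) {
  if (is.numeric(genes) && length(genes) == 1) {
    n <- as.integer(genes)
    if (n < 1) stop_mikana("a network needs at least one gene")
    genes <- sprintf("g%03d", seq_len(n))
  }
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop_mikana("duplicated gene identifiers")
  n <- length(genes)
  if (is.null(edges)) {
    edges <- data.frame(parent = integer(), child = integer(),
                        sign = integer(), weight = numeric())
  }
  edges <- as.data.frame(edges)
  if (!all(c("parent", "child") %in% names(edges))) {
    stop_mikana("edges need 'parent' and 'child' columns")
  }
  edges$parent <- as.integer(edges$parent)
  edges$child <- as.integer(edges$child)
  if (is.null(edges$sign)) edges$sign <- rep(NA_integer_, nrow(edges))
  edges$sign <- as.integer(edges$sign)
  if (is.null(edges$weight)) edges$weight <- rep(NA_real_, nrow(edges))
  edges$weight <- as.numeric(edges$weight)
  edges <- edges[, c("parent", "child", "sign", "weight")]
  rownames(edges) <- NULL
  net <- structure(list(genes = genes, edges = edges), class = "gene_network")
  validate_gene_network(net)
  net
}

validate_gene_network <- function(net) {
  n <- length(net$genes)
  e <- net$edges
  if (nrow(e)) {
    if (any(e$parent < 1 | e$parent > n | e$child < 1 | e$child > n)) {
      stop_mikana("edge indices outside [1, %d]", n)
    }
    if (any(e$parent == e$child)) stop_mikana("self-loops are not allowed")
    if (anyDuplicated(e[, c("parent", "child")])) {
      stop_mikana("duplicate (parent, child) edges")
    }
    bad <- !is.na(e$sign) & !(e$sign %in% c(-1L, 1L))
    if (any(bad)) stop_mikana("edge signs must be +1 or -1")
  }
  invisible(net)
}

#' @export
print.gene_network <- function(x, ...) {
  e <- x$edges
  n_pos <- sum(e$sign == 1L, na.rm = TRUE)
  n_neg <- sum(e$sign == -1L, na.rm = TRUE)
  cat(sprintf("gene_network: %d genes, %d edges (%d activating, %d inhibiting)\n",
              length(x$genes), nrow(e), n_pos, n_neg))
  if (nrow(e)) {
    cat(sprintf("mean total degree: %.2f\n", 2 * nrow(e) / length(x$genes)))
  }
  invisible(x)
}

#' Number of edges in a network
#' @param net A `gene_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

# In/out/total degree vectors (length n_genes).
degree_counts <- function(net, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  n <- length(net$genes)
  din <- tabulate(net$edges$child, nbins = n)
  dout <- tabulate(net$edges$parent, nbins = n)
  switch(mode, total = din + dout, "in" = din, out = dout)
}

#' Generate a scale-free directed gene network
#'
#' Grows a directed network by a thresholded preferential-attachment rule
#' until the target edge count `round(k_av * n_genes / 2)` is reached, so the
#' average total degree is approximately `k_av`. Every node starts with an
#' attachment score drawn uniformly on \[0, 1\]; the attachment probability of
#' node i is `(u_i + k_i) / max_j (u_j + k_j)` where `k_i` is its current
#' total degree. Ordered pairs (a, b) are drawn uniformly (no self-pairs) and
#' the edge a -> b is accepted when both attachment probabilities exceed
#' fresh uniform thresholds, giving rich-get-richer growth and a heavy-tailed
#' degree distribution. Signs are then assigned with activation probability
#' `p_pos` (see [assign_signs()]).
#'
#' @param n_genes Number of genes (nodes).
#' @param k_av Target average total degree (default 3, the value used for all
#'   simulated networks here).
#' @param r Nominal degree exponent of the target power law. Descriptive
#'   only: the generator does not fit or enforce it (default 0.65).
#' @param p_pos Probability that an edge is activating, in \[0, 1\].
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   network exactly.
#' @return A `gene_network` with `round(k_av * n_genes / 2)` signed edges.
#' @examples
#' net <- generate_scale_free(100, k_av = 3, seed = 1)
#' n_edges(net)  # 150
#' @export
generate_scale_free <- function(n_genes, k_av = 3, r = 0.65, p_pos = 0.5,
                                seed = NULL) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1) stop_mikana("n_genes must be >= 1")
  if (k_av < 0) stop_mikana("k_av must be >= 0")
  if (p_pos < 0 || p_pos > 1) stop_mikana("p_pos must lie in [0, 1]")
  m_target <- round(k_av * n_genes / 2)
  if (m_target > 0 && n_genes < 2) {
    stop_mikana("impossible topology: %d edges requested on %d gene(s)",
                m_target, n_genes)
  }
  if (m_target > n_genes * (n_genes - 1)) {
    stop_mikana("impossible topology: %d edges exceed the %d possible",
                m_target, n_genes * (n_genes - 1))
  }
  with_seed(seed, {
    parent <- integer(m_target)
    child <- integer(m_target)
    if (m_target > 0) {
      score <- stats::runif(n_genes)        # u_i + current total degree
      smax <- max(score)
      seen <- matrix(FALSE, n_genes, n_genes)
      m <- 0L
      while (m < m_target) {
        a <- sample.int(n_genes, 1L)
        b <- sample.int(n_genes, 1L)
        if (a == b || seen[a, b]) next
        t1 <- stats::runif(1)
        t2 <- stats::runif(1)
        if (score[a] / smax >= t1 && score[b] / smax >= t2) {
          m <- m + 1L
          parent[m] <- a
          child[m] <- b
          seen[a, b] <- TRUE
          score[a] <- score[a] + 1
          score[b] <- score[b] + 1
          smax <- max(smax, score[a], score[b])
        }
      }
    }
    net <- gene_network(n_genes, data.frame(parent = parent, child = child))
    assign_signs(net, p_pos = p_pos, seed = NULL)
  })
}

#' Assign activation/inhibition signs to network edges
#'
#' Each edge independently becomes activating (`+1`) with probability
#' `p_pos`, otherwise inhibiting (`-1`).
#'
#' @param net A `gene_network`.
#' @param p_pos Probability of an activating edge, in \[0, 1\].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return The network with every edge signed.
#' @export
assign_signs <- function(net, p_pos = 0.5, seed = NULL) {
  validate_gene_network(net)
  if (!is.numeric(p_pos) || p_pos < 0 || p_pos > 1) {
    stop_mikana("p_pos must lie in [0, 1]")
  }
  with_seed(seed, {
    m <- nrow(net$edges)
    net$edges$sign <- ifelse(stats::runif(m) < p_pos, 1L, -1L)
    net
  })
}
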