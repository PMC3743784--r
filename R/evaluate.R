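#' Score an inferred network against ground truth
#'
#' Edge-by-edge comparison of directed (parent, child) pairs, ignoring signs
#' and weights by default. Sensitivity is `TP / (TP + FN)` and the false
#' discovery rate `FP / (TP + FP)`; a rate whose denominator is zero is
#' reported as `NA` (undefined), never silently as 0.
#'
#' @param inferred,truth `gene_network`s over the same gene universe.
#' @param match_sign If `TRUE`, an inferred edge only counts as a true
#'   positive when its sign also matches (default `FALSE`).
#' @return An object of class `edge_score` with fields `tp`, `fp`, `fn`,
#'   `sensitivity`, `fdr`.
#' @export
score_edges <- function(inferred, truth, match_sign = FALSE) {
  check_same_universe(inferred, truth)
  key <- function(net, signed) {
    e <- net$edges
    if (signed) paste(e$parent, e$child, e$sign) else paste(e$parent, e$child)
  }
  ki <- key(inferred, match_sign)
  kt <- key(truth, match_sign)
  tp <- sum(ki %in% kt)
  fp <- length(ki) - tp
  fn <- length(kt) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_
  ), class = "edge_score")
}

#' @export
print.edge_score <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("edge_score: TP %d, FP %d, FN %d | Sn %s, FDR %s\n",
              x$tp, x$fp, x$fn, fmt(x$sensitivity), fmt(x$fdr)))
  invisible(x)
}

check_same_universe <- function(a, b) {
  if (!identical(a$genes, b$genes)) {
    stop_mikana("networks cover different gene universes")
  }
  invisible(TRUE)
}

#' Reverse every edge of a network
#'
#' @param net A `gene_network`.
#' @return The network with each edge (a, b) replaced by (b, a); signs and
#'   weights are preserved.
#' @export
reverse_network <- function(net) {
  e <- net$edges
  gene_network(net$genes,
               data.frame(parent = e$child, child = e$parent,
                          sign = e$sign, weight = e$weight))
}

#' Forward and reversed edge-direction proportions
#'
#' The forward proportion is the fraction of ground-truth edges recovered
#' with the correct orientation, `|truth & inferred| / |truth|`; the
#' reversed proportion uses the edge-reversed inferred network instead,
#' measuring how often an interaction is found with flipped direction.
#'
#' @param inferred,truth `gene_network`s over the same gene universe;
#'   `truth` must have at least one edge.
#' @return Named numeric vector `c(forward = ..., reversed = ...)`.
#' @export
directionality_proportions <- function(inferred, truth) {
  check_same_universe(inferred, truth)
  if (!nrow(truth$edges)) stop_mikana("truth network has no edges")
  c(forward = edge_overlap(truth, inferred) / nrow(truth$edges),
    reversed = edge_overlap(truth, reverse_network(inferred)) / nrow(truth$edges))
}

#' Count directed edges shared by two networks
#'
#' @param a,b `gene_network`s over the same gene universe.
#' @return Integer count of shared (parent, child) pairs.
#' @export
edge_overlap <- function(a, b) {
  check_same_universe(a, b)
  sum(paste(a$edges$parent, a$edges$child) %in%
        paste(b$edges$parent, b$edges$child))
}

#' Union of two networks
#'
#' Edge set is the union of directed (parent, child) pairs, so
#' `|union| = |a| + |b| - overlap`. An edge present in both keeps `a`'s sign
#' and weight; if the two signs conflict, the conflicting pairs are recorded
#' in the `sign_conflicts` attribute and a warning is raised.
#'
#' @param a,b `gene_network`s over the same gene universe.
#' @return A `gene_network`.
#' @export
union_network <- function(a, b) {
  check_same_universe(a, b)
  ea <- a$edges
  eb <- b$edges
  ka <- paste(ea$parent, ea$child)
  kb <- paste(eb$parent, eb$child)
  shared <- intersect(ka, kb)
  conflicts <- shared[vapply(shared, function(k) {
    sa <- ea$sign[ka == k]
    sb <- eb$sign[kb == k]
    !is.na(sa) && !is.na(sb) && sa != sb
  }, logical(1))]
  if (length(conflicts)) {
    warning(sprintf("%d shared edge(s) have conflicting signs", length(conflicts)))
  }
  merged <- rbind(ea, eb[!(kb %in% ka), , drop = FALSE])
  out <- gene_network(a$genes, merged)
  attr(out, "sign_conflicts") <- conflicts
  out
}

#' Rank genes by out-degree (hubs)
#'
#' Hub genes regulate many targets. Genes are ordered by out-degree in the
#' network, descending, with ties broken by gene identifier (ascending), and
#' the list truncated to `top_k`. Genes with out-degree zero are included
#' only if needed to fill `top_k`.
#'
#' @param net A `gene_network`.
#' @param top_k Number of genes to report (default 10).
#' @return Data frame with columns `gene` and `out_degree`.
#' @export
hub_ranking <- function(net, top_k = 10) {
  if (!nrow(net$edges)) {
    return(data.frame(gene = character(), out_degree = integer()))
  }
  dd <- degree_counts(net, "out")
  ord <- order(-dd, net$genes)
  out <- data.frame(gene = net$genes[ord], out_degree = dd[ord],
                    row.names = NULL)
  utils::head(out, top_k)
}
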