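test_that("edge scoring matches hand enumeration", {
  truth <- gene_network(3, data.frame(parent = c(1, 2, 3), child = c(2, 3, 1)))
  inferred <- gene_network(3, data.frame(parent = c(1, 3, 1), child = c(2, 1, 3)))
  s <- score_edges(inferred, truth)
  expect_equal(s$tp, 2)
  expect_equal(s$fp, 1)
  expect_equal(s$fn, 1)
  expect_equal(s$sensitivity, 2 / 3)
  expect_equal(s$fdr, 1 / 3)
  ident <- score_edges(truth, truth)
  expect_equal(ident$sensitivity, 1)
  expect_equal(ident$fdr, 0)
  empty <- score_edges(gene_network(3), truth)
  expect_equal(empty$sensitivity, 0)
  expect_true(is.na(empty$fdr))                 # undefined, never silently 0
  expect_error(score_edges(gene_network(4), truth), "universe")
})

test_that("sign-strict scoring is available but off by default", {
  truth <- gene_network(3, data.frame(parent = 1, child = 2, sign = 1L))
  flip <- gene_network(3, data.frame(parent = 1, child = 2, sign = -1L))
  expect_equal(score_edges(flip, truth)$tp, 1)
  expect_equal(score_edges(flip, truth, match_sign = TRUE)$tp, 0)
})

test_that("network reversal is an involution that preserves signs", {
  net <- random_network(12, 20, seed = 4)
  expect_equal(reverse_network(reverse_network(net)), net)
  sym <- gene_network(3, data.frame(parent = c(1, 2, 2, 3), child = c(2, 1, 3, 2)))
  rev_sym <- reverse_network(sym)
  expect_equal(score_edges(rev_sym, sym)$sensitivity, 1)
  # no reciprocal edges: nothing survives reversal
  acyc <- gene_network(4, data.frame(parent = c(1, 2, 3), child = c(2, 3, 4)))
  expect_equal(score_edges(reverse_network(acyc), acyc)$sensitivity, 0)
})

test_that("directionality proportions behave at their boundaries", {
  truth <- gene_network(5, data.frame(parent = c(1, 2, 4), child = c(2, 3, 5)))
  pr <- directionality_proportions(truth, truth)
  expect_equal(unname(pr), c(1, 0))
  recip <- gene_network(3, data.frame(parent = c(1, 2), child = c(2, 1)))
  some <- gene_network(3, data.frame(parent = 1, child = 2))
  pr2 <- directionality_proportions(some, recip)
  expect_equal(pr2[["forward"]], pr2[["reversed"]])
  expect_error(directionality_proportions(some, gene_network(3)), "no edges")
})

test_that("random networks recover true direction and reverse equally often", {
  truth <- random_network(15, 25, seed = 1)
  fw <- rv <- numeric(100)
  for (s in 1:100) {
    guess <- random_network(15, 25, seed = 1000 + s)
    pr <- directionality_proportions(guess, truth)
    fw[s] <- pr[["forward"]]
    rv[s] <- pr[["reversed"]]
  }
  expect_lt(abs(mean(fw) - mean(rv)), 0.02)
})

test_that("overlap and union obey inclusion-exclusion", {
  a <- random_network(10, 15, seed = 2)
  b <- random_network(10, 18, seed = 3)
  ov <- edge_overlap(a, b)
  expect_identical(ov, edge_overlap(b, a))
  un <- suppressWarnings(union_network(a, b))
  expect_equal(n_edges(un), n_edges(a) + n_edges(b) - ov)
  expect_equal(n_edges(suppressWarnings(union_network(a, a))), n_edges(a))
  expect_equal(edge_overlap(a, a), n_edges(a))
  expect_equal(edge_overlap(a, gene_network(10)), 0)
})

test_that("conflicting signs on shared union edges are flagged", {
  a <- gene_network(3, data.frame(parent = 1, child = 2, sign = 1L))
  b <- gene_network(3, data.frame(parent = 1, child = 2, sign = -1L))
  expect_warning(un <- union_network(a, b), "conflicting")
  expect_length(attr(un, "sign_conflicts"), 1)
})

test_that("scores are invariant to relabelling the gene universe", {
  truth <- random_network(8, 12, seed = 5)
  inferred <- random_network(8, 10, seed = 6)
  s0 <- score_edges(inferred, truth)
  set.seed(9)
  perm <- sample(8)
  relabel <- function(net) {
    gene_network(net$genes,                     # same ids, permuted indices
                 data.frame(parent = perm[net$edges$parent],
                            child = perm[net$edges$child],
                            sign = net$edges$sign, weight = net$edges$weight))
  }
  s1 <- score_edges(relabel(inferred), relabel(truth))
  expect_equal(s1[c("tp", "fp", "fn")], s0[c("tp", "fp", "fn")])
})

test_that("hub ranking orders by out-degree with label tie-breaks", {
  star <- gene_network(6, data.frame(parent = 1, child = 2:6))
  h <- hub_ranking(star, 3)
  expect_equal(h$gene[1], star$genes[1])
  expect_equal(h$out_degree[1], 5)
  expect_equal(nrow(hub_ranking(gene_network(4))), 0)
  # ties broken by gene identifier, ascending
  two <- gene_network(4, data.frame(parent = c(2, 3), child = c(1, 4)))
  h2 <- hub_ranking(two, 2)
  expect_equal(h2$gene, two$genes[c(2, 3)])
})
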