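test_that("centralities match closed forms on star and path graphs", {
  star <- tibble::tibble(from = "hub", to = c("a", "b", "c", "d"))
  ct <- centralities(star)
  hub <- ct[ct$node == "hub", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$betweenness, choose(4, 2))
  expect_equal(hub$stress, choose(4, 2))
  leaves <- ct[ct$node != "hub", ]
  expect_true(all(leaves$betweenness == 0 & leaves$stress == 0))
  path <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  expect_equal(cp$stress[cp$node == "b"], 1)
})

test_that("centralities equal the brute-force oracle on random graphs", {
  withr::with_seed(23, {
    for (i in 1:12) {
      n <- sample(5:12, 1)
      g <- igraph::sample_gnp(n, runif(1, 0.25, 0.6))
      igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
      edges <- tibble::as_tibble(igraph::as_edgelist(g),
                                 .name_repair = ~ c("from", "to"))
      if (nrow(edges) == 0) next
      got <- centralities(edges)
      want <- oracle_centralities(edges)
      want <- want[match(got$node, want$node), ]
      expect_equal(got$degree, want$degree)
      expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
      expect_equal(got$stress, want$stress)
    }
  })
})

test_that("centralities and MCODE are invariant to node relabeling", {
  withr::with_seed(9, {
    g <- igraph::sample_gnp(10, 0.4)
    igraph::V(g)$name <- letters[1:10]
  })
  edges <- tibble::as_tibble(igraph::as_edgelist(g),
                             .name_repair = ~ c("from", "to"))
  relab <- setNames(LETTERS[10:1], letters[1:10])
  edges2 <- tibble::tibble(from = relab[edges$from], to = relab[edges$to])
  c1 <- centralities(edges); c2 <- centralities(edges2)
  c2 <- c2[match(relab[c1$node], c2$node), ]
  expect_equal(c1$betweenness, c2$betweenness)
  expect_equal(c1$stress, c2$stress)
  m1 <- mcode(edges, score_min = 0); m2 <- mcode(edges2, score_min = 0)
  expect_equal(m1$mcode_score, m2$mcode_score)
  expect_equal(lapply(m1$nodes, function(x) sort(unname(relab[x]))),
               lapply(m2$nodes, sort))
})

test_that("hub selection merges top-k lists and keeps ties", {
  topo <- tibble::tibble(node = letters[1:6],
                         degree = c(6, 5, 4, 3, 2, 1),
                         betweenness = c(6, 5, 4, 3, 2, 1),
                         stress = c(6, 5, 4, 3, 2, 1))
  expect_equal(select_hubs(topo, k = 2), c("a", "b"))
  # disjoint lists: union of all three
  topo2 <- tibble::tibble(node = letters[1:6],
                          degree = c(9, 8, 0, 0, 0, 0),
                          betweenness = c(0, 0, 9, 8, 0, 0),
                          stress = c(0, 0, 0, 0, 9, 8))
  expect_equal(select_hubs(topo2, k = 2), letters[1:6])
  # ties at the k-th value are all included
  topo3 <- tibble::tibble(node = letters[1:5],
                          degree = c(5, 4, 4, 4, 1),
                          betweenness = c(5, 4, 4, 4, 1),
                          stress = c(5, 4, 4, 4, 1))
  expect_equal(select_hubs(topo3, k = 2), c("a", "b", "c", "d"))
})

clique_edges <- function(nodes) {
  cmb <- utils::combn(nodes, 2)
  tibble::tibble(from = cmb[1, ], to = cmb[2, ])
}

test_that("MCODE recovers isolated cliques and rejects trees", {
  # 6-clique plus a sparse tail
  edges <- dplyr::bind_rows(
    clique_edges(sprintf("c%d", 1:6)),
    tibble::tibble(from = c("c1", "t1", "t2"), to = c("t1", "t2", "t3"))
  )
  mods <- mcode(edges)
  expect_equal(nrow(mods), 1L)
  expect_equal(sort(mods$nodes[[1]]), sprintf("c%d", 1:6))
  expect_equal(mods$density, 1)
  expect_equal(mods$mcode_score, 6)
  expect_equal(mods$seed, mods$nodes[[1]][1], ignore_attr = TRUE)
  # a tree has no 2-core: no modules pass the K-score filter
  tree <- tibble::tibble(from = c("a", "a", "b", "b"),
                         to = c("b", "c", "d", "e"))
  expect_equal(nrow(mcode(tree)), 0L)
  # empty graph
  expect_equal(nrow(mcode(tibble::tibble(from = character(),
                                         to = character()))), 0L)
})

test_that("MCODE separates two planted 8-cliques in a sparse background", {
  cfg <- sim_config(seed = 19, n_modules = 2, module_size = 8,
                    n_network_nodes = 80, background_edge_p = 0.005)
  net <- simulate_ppi(cfg)
  # exact recovery is only guaranteed when the background leaves the two
  # cliques unconnected; verify that precondition on this instance
  m1 <- net$true_modules[[1]]; m2 <- net$true_modules[[2]]
  cross <- net$edges[(net$edges$from %in% m1 & net$edges$to %in% m2) |
                       (net$edges$from %in% m2 & net$edges$to %in% m1), ]
  expect_equal(nrow(cross), 0L)
  mods <- mcode(net$edges)
  expect_equal(nrow(mods), 2L)
  expect_equal(mods$mcode_score, c(8, 8))
  expect_equal(sort(c(mods$nodes[[1]], mods$nodes[[2]])), sort(c(m1, m2)))
  # modules are pairwise disjoint and contain their seeds
  expect_equal(length(intersect(mods$nodes[[1]], mods$nodes[[2]])), 0L)
  expect_true(all(mapply(function(s, m) s %in% m, mods$seed, mods$nodes)))
})

test_that("hypergeometric ORA matches closed forms and enumeration", {
  # module == term == universe -> p = 1
  u <- sprintf("g%02d", 1:20)
  r <- ora(u, list(all = u), u)
  expect_equal(r$p_hyper, 1)
  # 5 module genes all inside a 5-gene term of a 100-gene universe
  u2 <- sprintf("g%03d", 1:100)
  r2 <- ora(u2[1:5], list(term = u2[1:5]), u2)
  expect_equal(r2$p_hyper, 1 / choose(100, 5), tolerance = 1e-12)
  # empty overlap gives p = 1 under the upper-tail convention
  r3 <- ora(u2[1:5], list(term = u2[50:60]), u2)
  expect_equal(r3$p_hyper, oracle_hyper_upper(0, 11, 5, 100))
  # random cases vs enumeration, N <= 40
  withr::with_seed(6, {
    for (i in 1:25) {
      N <- sample(10:40, 1)
      uu <- sprintf("x%02d", seq_len(N))
      K <- sample(1:N, 1); n <- sample(1:N, 1)
      term <- sample(uu, K); mod <- sample(uu, n)
      k <- length(intersect(term, mod))
      expect_equal(ora(mod, list(t = term), uu)$p_hyper,
                   oracle_hyper_upper(k, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("AUC equals pairwise Mann-Whitney enumeration", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))$auc,
               0.75)
  expect_equal(roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  withr::with_seed(13, {
    for (i in 1:30) {
      n <- sample(6:20, 1)
      v <- sample(1:8, n, replace = TRUE)  # ties likely
      l <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (sum(l) == 0 || sum(l) == n) next
      expect_equal(roc_auc(v, l)$auc, oracle_auc(v, l))
      # label flip complements the AUC
      expect_equal(roc_auc(v, !l)$auc, 1 - roc_auc(v, l)$auc)
    }
  })
})

test_that("AUC agrees with the pROC oracle and screening ranks genes", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    v <- rnorm(40); l <- rep(c(TRUE, FALSE), 20)
    got <- roc_auc(v, l, orient = TRUE)$auc
    want <- as.numeric(suppressMessages(pROC::auc(pROC::roc(l, v))))
    expect_equal(got, max(want, 1 - want), tolerance = 1e-12)
  })
  expr <- rbind(good = c(1, 2, 3, 10, 11, 12), flat = rep(1, 6))
  colnames(expr) <- sprintf("s%d", 1:6)
  scr <- roc_screen(expr, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(scr$gene_id, c("good", "flat"))
  expect_equal(scr$auc, c(1, 0.5))
  expect_equal(scr$is_predictor, c(TRUE, FALSE))
})
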