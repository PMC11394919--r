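# Independent brute-force oracles used to freeze expected values.

# two-sided minlike binomial p by full pmf enumeration
oracle_binom_p <- function(ref, alt) {
  n <- ref + alt
  pm <- dbinom(0:n, n, 0.5)
  obs <- pm[ref + 1]
  min(1, sum(pm[pm <= obs * (1 + 1e-7)]))
}

# two-sided minlike Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  K <- a + c   # first-column margin
  m <- a + b   # first-row margin
  ks <- max(0, m - (n - K)):min(m, K)
  pm <- dhyper(ks, K, n - K, m)
  obs <- dhyper(a, K, n - K, m)
  min(1, sum(pm[pm <= obs * (1 + 1e-7)]))
}

# upper-tail hypergeometric p by enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(dhyper(ks, K, N - K, n))
}

# exact centralities by enumerating all shortest paths with igraph
oracle_centralities <- function(edges) {
  g <- igraph::simplify(
    igraph::graph_from_data_frame(edges, directed = FALSE))
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  btw <- stats::setNames(numeric(n), nodes)
  str <- stats::setNames(numeric(n), nodes)
  if (n >= 3) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = i, to = j)$vpaths)
      if (length(sp) == 0) next
      inner <- lapply(sp, function(p) setdiff(as.integer(p), c(i, j)))
      for (v in setdiff(seq_len(n), c(i, j))) {
        through <- sum(vapply(inner, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + through / length(sp)
        str[v] <- str[v] + through
      }
    }
  }
  tibble::tibble(node = nodes,
                 degree = as.integer(igraph::degree(g)),
                 betweenness = unname(btw), stress = unname(str))
}

# AUC by exhaustive pairwise comparison with tie half-credit
oracle_auc <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# small allele-depth builder
make_depths <- function(ind = "i1", assay = "RNA", pos = 100L,
                        ref = 10L, alt = 10L, chrom = "chr1") {
  tibble::tibble(individual_id = ind, assay = assay, chrom = chrom,
                 pos = as.integer(pos), ref_base = "A", alt_base = "G",
                 ref_count = as.integer(ref), alt_count = as.integer(alt))
}
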