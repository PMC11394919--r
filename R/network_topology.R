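as_ppi_graph <- function(edges) {
  if (igraph::is_igraph(edges)) return(igraph::simplify(edges))
  stop_if_not(is.data.frame(edges) && ncol(edges) >= 2,
              "`edges` must be an igraph object or a 2-column edge table")
  igraph::simplify(
    igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE))
}

name_vertices <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

# per-source BFS: geodesic distances and shortest-path counts
bfs_paths <- function(nbrs, s, n) {
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in nbrs[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

#' Node centralities: degree, betweenness, stress
#'
#' Exact degree, betweenness and stress centrality for a simple undirected
#' graph. Betweenness follows the unordered-pair, unnormalised convention
#' (Cytoscape/CytoNCA): for node `v` it sums `sigma_st(v)/sigma_st` over
#' unordered pairs `s < t`, both different from `v`. Stress is the plain
#' count of shortest paths through `v` over the same pairs (betweenness
#' without the fractional weighting). Betweenness is delegated to
#' [igraph::betweenness()]; stress is computed from per-source BFS
#' path counts.
#'
#' @param edges Edge tibble (`from`, `to`) or an igraph object.
#' @return A tibble: `node`, `degree`, `betweenness`, `stress`.
#' @export
#' @examples
#' star <- tibble::tibble(from = "hub", to = c("a", "b", "c", "d"))
#' centralities(star) # hub: degree 4, betweenness 6, stress 6
centralities <- function(edges) {
  g <- name_vertices(as_ppi_graph(edges))
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  nbrs <- igraph::adjacent_vertices(g, igraph::V(g))
  nbrs <- lapply(nbrs, as.integer)

  D <- matrix(Inf, n, n); S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- bfs_paths(nbrs, s, n)
    D[s, ] <- b$dist; S[s, ] <- b$sigma
  }
  stress <- vapply(seq_len(n), function(v) {
    mask <- outer(D[, v], D[v, ], "+") == D
    mask[!is.finite(D)] <- FALSE
    contrib <- outer(S[, v], S[v, ]) * mask
    contrib[v, ] <- 0; contrib[, v] <- 0; diag(contrib) <- 0
    sum(contrib) / 2
  }, numeric(1))

  tibble(
    node = nodes,
    degree = as.integer(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             normalized = FALSE)),
    stress = stress
  )
}

#' Select hub nodes by merged top-k centralities
#'
#' Takes the top `k` nodes by each of degree, betweenness and stress
#' (keeping every node tied with the k-th value) and returns the union.
#'
#' @param topology [centralities()] output.
#' @param k Per-metric list length, default 20.
#' @return Character vector of hub node names, sorted.
#' @export
select_hubs <- function(topology, k = 20) {
  top_of <- function(x) {
    if (nrow(topology) <= k) return(topology$node)
    thr <- sort(x, decreasing = TRUE)[k]
    topology$node[x >= thr]
  }
  sort(unique(c(top_of(topology$degree), top_of(topology$betweenness),
                top_of(topology$stress))))
}

mcode_node_scores <- function(g, degree_cutoff) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  scores <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    if (kmax == 0) next
    core_sub <- igraph::induced_subgraph(sub, which(cores == kmax))
    dens <- igraph::edge_density(core_sub)
    if (is.nan(dens)) dens <- 0
    scores[v] <- kmax * dens
  }
  scores
}

#' MCODE module detection
#'
#' Finds densely connected modules in a protein-protein interaction graph.
#' (i) Node scoring: for each node with degree at least `degree_cutoff`,
#' the highest k-core of the subgraph induced by the node and its
#' neighbours is found and the node's score is that core's k multiplied by
#' its density; lower-degree nodes score 0. (ii) Complex prediction:
#' starting from the highest-scoring unassigned node, neighbours are
#' included breadth-first (to `max_depth`) when their score is at least
#' `seed_score * (1 - node_score_cutoff)`; each node joins at most one
#' complex. (iii) Complexes lacking a k-core of order `kscore` are
#' discarded. (iv) Complexes are reported when
#' `mcode_score = density * n_nodes` reaches `score_min`, ranked by score.
#' Optional `haircut` removes degree-1 nodes from a complex; `fluff` is the
#' neighbour-expansion variant (both off by default).
#'
#' @param edges Edge tibble or igraph object.
#' @param max_depth,degree_cutoff,node_score_cutoff,kscore,score_min
#'   Algorithm parameters; defaults 100, 2, 0.2, 2, 4.
#' @param haircut,fluff Post-processing toggles, default off.
#' @param fluff_density Density threshold used when `fluff = TRUE`.
#' @return A tibble, one row per reported module: `module`, `seed`,
#'   `nodes` (list column), `n_nodes`, `n_edges`, `density`, `mcode_score`.
#' @export
mcode <- function(edges, max_depth = 100, degree_cutoff = 2,
                  node_score_cutoff = 0.2, kscore = 2, score_min = 4,
                  haircut = FALSE, fluff = FALSE, fluff_density = 0.5) {
  g <- name_vertices(as_ppi_graph(edges))
  n <- igraph::vcount(g)
  if (n == 0) {
    return(tibble(module = integer(), seed = character(), nodes = list(),
                  n_nodes = integer(), n_edges = integer(),
                  density = numeric(), mcode_score = numeric()))
  }
  names_v <- igraph::V(g)$name
  scores <- mcode_node_scores(g, degree_cutoff)
  assigned <- rep(FALSE, n)
  # deterministic seed order: score descending, then node name
  order_idx <- order(-scores, names_v)

  complexes <- list()
  for (seed in order_idx) {
    if (assigned[seed] || scores[seed] <= 0) next
    thr <- scores[seed] * (1 - node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in as.integer(igraph::neighbors(g, v))) {
          if (!assigned[w] && scores[w] >= thr) {
            assigned[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    complexes[[length(complexes) + 1]] <- list(seed = seed,
                                               members = members)
  }

  rows <- purrr::map(complexes, function(cx) {
    sub <- igraph::induced_subgraph(g, cx$members)
    if (haircut) {
      keep <- igraph::degree(sub) >= 2
      if (!any(keep)) return(NULL)
      sub <- igraph::induced_subgraph(sub, which(keep))
    }
    if (fluff) {
      ids <- match(igraph::V(sub)$name, names_v)
      extra <- setdiff(unique(unlist(
        lapply(ids, function(v) as.integer(igraph::neighbors(g, v))))), ids)
      extra <- extra[vapply(extra, function(w) {
        nb <- c(w, as.integer(igraph::neighbors(g, w)))
        d <- igraph::edge_density(igraph::induced_subgraph(g, nb))
        !is.nan(d) && d >= fluff_density
      }, logical(1))]
      if (length(extra) > 0)
        sub <- igraph::induced_subgraph(g, c(ids, extra))
    }
    if (max(igraph::coreness(sub)) < kscore) return(NULL)
    nv <- igraph::vcount(sub); ne <- igraph::ecount(sub)
    dens <- if (nv > 1) 2 * ne / (nv * (nv - 1)) else 0
    tibble(seed = names_v[cx$seed],
           nodes = list(sort(igraph::V(sub)$name)),
           n_nodes = nv, n_edges = ne, density = dens,
           mcode_score = dens * nv)
  }) |> purrr::compact() |> bind_rows()

  if (nrow(rows) == 0) {
    return(tibble(module = integer(), seed = character(), nodes = list(),
                  n_nodes = integer(), n_edges = integer(),
                  density = numeric(), mcode_score = numeric()))
  }
  rows |>
    filter(.data$mcode_score >= score_min, .data$n_nodes >= 3) |>
    arrange(desc(.data$mcode_score)) |>
    mutate(module = row_number()) |>
    select("module", "seed", "nodes", "n_nodes", "n_edges", "density",
           "mcode_score")
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of a gene list against each
#' term of a gene-set collection, restricted to a stated universe, with
#' Benjamini-Hochberg adjustment across tested terms.
#'
#' @param genes Character vector (e.g. a module's genes).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @param alpha Significance threshold on `p_adj`, default 0.05.
#' @return A tibble: `term`, `k` (genes in term), `K` (term size in
#'   universe), `n` (genes in universe), `N` (universe size), `p_hyper`,
#'   `p_adj`, `significant`; sorted by `p_hyper`.
#' @export
ora <- function(genes, gene_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  genes <- intersect(unique(genes), universe)
  N <- length(universe); n <- length(genes)
  rows <- purrr::imap(gene_sets, function(members, term) {
    K <- length(intersect(unique(members), universe))
    k <- length(intersect(genes, members))
    tibble(term = term, k = k, K = K, n = n, N = N,
           p_hyper = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }) |> bind_rows()
  rows |>
    mutate(p_adj = bh_adjust(.data$p_hyper),
           significant = .data$p_adj < alpha) |>
    arrange(.data$p_hyper)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (term, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}

#' ROC AUC by the rank (Mann-Whitney) formula
#'
#' `AUC = U / (n_pos * n_neg)` with half-credit for ties, computed from
#' midranks. With `orient = TRUE` the AUC is reflected to be at least 0.5.
#'
#' @param values Numeric score per sample (e.g. normalised expression of
#'   one gene).
#' @param labels Logical vector (TRUE = positive/disease class), or a
#'   two-level vector with `positive` naming the positive level.
#' @param positive Positive class label when `labels` is not logical.
#' @param threshold Predictor call threshold on the AUC, default 0.7.
#' @param orient Reflect AUC below 0.5, default FALSE.
#' @return A one-row tibble: `auc`, `n_pos`, `n_neg`, `is_predictor`.
#' @export
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))$auc # 0.75
roc_auc <- function(values, labels, positive = NULL, threshold = 0.7,
                    orient = FALSE) {
  if (!is.logical(labels)) {
    stop_if_not(!is.null(positive), "`positive` required for factor labels")
    labels <- labels == positive
  }
  stop_if_not(length(values) == length(labels) && !anyNA(values) &&
                !anyNA(labels), "values and labels must match, no NAs")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  stop_if_not(n_pos > 0 && n_neg > 0, "both classes must be present")
  r <- rank(values) # midranks give tie half-credit
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (orient) auc <- max(auc, 1 - auc)
  tibble(auc = auc, n_pos = n_pos, n_neg = n_neg,
         is_predictor = auc > threshold)
}

#' Screen genes as ROC predictors
#'
#' Applies [roc_auc()] to each row of a normalised expression matrix.
#'
#' @param expr Genes x samples numeric matrix (or tibble with `gene_id`
#'   first).
#' @param labels,positive,threshold,orient As in [roc_auc()].
#' @return A tibble, one row per gene: `gene_id`, `auc`, `n_pos`, `n_neg`,
#'   `is_predictor`, sorted by `auc` descending.
#' @export
roc_screen <- function(expr, labels, positive = NULL, threshold = 0.7,
                       orient = FALSE) {
  m <- as_count_matrix(expr)
  purrr::map(rownames(m), function(gid) {
    roc_auc(m[gid, ], labels, positive = positive, threshold = threshold,
            orient = orient) |>
      mutate(gene_id = gid, .before = 1)
  }) |>
    bind_rows() |>
    arrange(desc(.data$auc))
}
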