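#' Labelled graph: an undirected simple graph with optional communities
#'
#' Thin container pairing an igraph graph with an optional node->community
#' partition. All simulation entry points accept either a `labelled_graph` or
#' a bare igraph object. Graphs must be simple (no loops or multi-edges) and
#' connected, since the dynamics require reachable neighbours.
#'
#' @param graph an undirected igraph graph.
#' @param communities optional integer vector, one community id (1-based) per
#'   vertex.
#' @return An object of class `labelled_graph`.
#' @export
labelled_graph <- function(graph, communities = NULL) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (!igraph::is_simple(graph)) stop("graph must be simple (no loops/multi-edges)")
  if (!is.null(communities)) {
    if (length(communities) != igraph::vcount(graph)) {
      stop("`communities` must have one entry per vertex")
    }
    communities <- as.integer(as.factor(communities))
  }
  structure(list(graph = graph, communities = communities),
            class = "labelled_graph")
}

#' @export
print.labelled_graph <- function(x, ...) {
  cat("Labelled graph:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges")
  if (!is.null(x$communities)) {
    cat(",", length(unique(x$communities)), "communities")
  }
  cat("\n")
  invisible(x)
}

as_igraph <- function(g) {
  if (inherits(g, "labelled_graph")) g$graph else g
}

graph_communities <- function(g) {
  if (inherits(g, "labelled_graph")) g$communities else NULL
}

# regenerate until connected; generators below rely on this
retry_connected <- function(gen, max_tries = 100L, what = "graph") {
  for (i in seq_len(max_tries)) {
    g <- gen()
    g <- igraph::simplify(g)
    if (igraph::vcount(g) > 1L && igraph::is_connected(g)) return(g)
  }
  stop("failed to generate a connected ", what, " in ", max_tries, " attempts")
}

#' Watts-Strogatz small-world network
#'
#' Ring lattice over `n` nodes with each node tied to its `k` nearest
#' neighbours, each edge rewired with probability `p_rewire`. `p_rewire = 0`
#' returns the regular lattice; rewired realizations are regenerated until
#' simple and connected. Uses the session RNG.
#'
#' @param n number of nodes.
#' @param k even number of nearest neighbours (`k < n`).
#' @param p_rewire rewiring probability in `[0, 1]`.
#' @return A [labelled_graph()] (no communities).
#' @export
make_ws <- function(n, k, p_rewire) {
  if (k %% 2 != 0 || k >= n || k < 2) stop("`k` must be even and in [2, n)")
  if (p_rewire < 0 || p_rewire > 1) stop("`p_rewire` must lie in [0, 1]")
  g <- retry_connected(function() {
    igraph::sample_smallworld(1, n, k / 2, p_rewire)
  }, what = "WS graph")
  labelled_graph(g)
}

#' Erdos-Renyi random network
#'
#' `G(n, p)` graph, regenerated until connected.
#'
#' @param n number of nodes.
#' @param p_edge edge creation probability in `(0, 1]`.
#' @return A [labelled_graph()].
#' @export
make_er <- function(n, p_edge) {
  if (p_edge <= 0 || p_edge > 1) stop("`p_edge` must lie in (0, 1]")
  g <- retry_connected(function() igraph::sample_gnp(n, p_edge),
                       what = "ER graph")
  labelled_graph(g)
}

#' Barabasi-Albert scale-free network
#'
#' Preferential-attachment growth; each new node attaches `n_attach` edges to
#' existing nodes (early nodes necessarily attach fewer, so the final edge
#' count is `sum(pmin(0:(n-1), n_attach))`).
#'
#' @param n number of nodes.
#' @param n_attach edges attached from each new node.
#' @return A [labelled_graph()].
#' @export
make_ba <- function(n, n_attach) {
  if (n_attach < 1 || n_attach >= n) stop("`n_attach` must lie in [1, n)")
  g <- retry_connected(function() {
    igraph::sample_pa(n, power = 1, m = n_attach, directed = FALSE)
  }, what = "BA graph")
  labelled_graph(g)
}

#' Tunable-heterogeneity network family (Gomez-Gardenes-Moreno)
#'
#' One-parameter interpolation between scale-free and random topologies at a
#' fixed node and edge count. A fully connected core of `m = mean_degree / 2`
#' nodes is laid down; every remaining node is then attached with `m` links,
#' each link going to a uniformly random other node with probability `kappa`
#' and by preferential attachment (probability proportional to current
#' degree among already-attached nodes) with probability `1 - kappa`. Thus
#' `kappa = 0` grows a BA-like scale-free network and `kappa = 1` an ER-like
#' homogeneous one, with identical edge counts for every `kappa`.
#'
#' @param n number of nodes.
#' @param mean_degree target average degree (even; `m = mean_degree / 2`).
#' @param kappa mixing parameter in `[0, 1]`.
#' @return A [labelled_graph()].
#' @export
make_gm <- function(n, mean_degree, kappa) {
  if (kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]")
  m <- as.integer(round(mean_degree / 2))
  if (m < 1 || m + 1 > n) stop("`mean_degree` incompatible with `n`")
  g <- retry_connected(function() gm_once(n, m, kappa), what = "GM graph")
  labelled_graph(g)
}

gm_once <- function(n, m, kappa) {
  deg <- integer(n)
  attached <- logical(n)
  core <- seq_len(m)
  el <- if (m > 1) t(utils::combn(core, 2)) else matrix(0L, 0, 2)
  deg[core] <- m - 1L
  attached[core] <- TRUE
  adj <- vector("list", n)
  for (q in seq_len(nrow(el))) {
    adj[[el[q, 1]]] <- c(adj[[el[q, 1]]], el[q, 2])
    adj[[el[q, 2]]] <- c(adj[[el[q, 2]]], el[q, 1])
  }
  new_edges <- matrix(0L, (n - m) * m, 2)
  q <- 0L
  for (v in seq(m + 1L, n)) {
    chosen <- integer(0)
    while (length(chosen) < m) {
      if (runif(1) < kappa) {
        tgt <- sample.int(n, 1L)
      } else {
        pool <- which(attached)
        tgt <- pool[sample.int(length(pool), 1L, prob = deg[pool])]
      }
      if (tgt == v || tgt %in% chosen || tgt %in% adj[[v]]) next
      chosen <- c(chosen, tgt)
    }
    for (tgt in chosen) {
      q <- q + 1L
      new_edges[q, ] <- c(v, tgt)
      deg[v] <- deg[v] + 1L
      deg[tgt] <- deg[tgt] + 1L
      adj[[v]] <- c(adj[[v]], tgt)
      adj[[tgt]] <- c(adj[[tgt]], v)
    }
    attached[v] <- TRUE
  }
  igraph::graph_from_edgelist(rbind(el, new_edges), directed = FALSE)
}

#' LFR-style community benchmark network
#'
#' Generates a benchmark graph with power-law degrees (exponent `tau1`,
#' truncated to `[k_min, max_deg]` with `k_min` chosen to hit `avg_deg`),
#' power-law community sizes (exponent `tau2`, truncated to
#' `[min_comm, max_comm]`), and a target fraction `mu` of inter-community
#' edges per node. Each node's degree is split into `(1 - mu) d` internal and
#' `mu d` external stubs; internal stubs are paired within the community and
#' external stubs across communities by configuration-model matching, after
#' which loops, multi-edges, and internal "external" pairs are discarded.
#' Realizations are regenerated until the required number of communities,
#' simplicity and connectedness hold.
#'
#' @param n number of nodes.
#' @param tau1 degree-distribution exponent.
#' @param tau2 community-size-distribution exponent.
#' @param mu mixing fraction in `[0, 1]`.
#' @param avg_deg,max_deg average and maximum degree.
#' @param min_comm,max_comm community-size bounds.
#' @param n_comm required number of communities (realizations with any other
#'   count are rejected).
#' @param max_tries bound on regeneration attempts.
#' @return A [labelled_graph()] with its community partition.
#' @export
make_lfr <- function(n = 100, tau1 = 3, tau2 = 1.1, mu = 0.1,
                     avg_deg = 10, max_deg = 50, min_comm = 30, max_comm = 50,
                     n_comm = 3, max_tries = 200L) {
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  if (n_comm * min_comm > n || n_comm * max_comm < n) {
    stop("no ", n_comm, "-part composition of ", n, " nodes with sizes in [",
         min_comm, ", ", max_comm, "]")
  }
  k_min <- lfr_kmin(tau1, avg_deg, max_deg)
  for (try in seq_len(max_tries)) {
    sizes <- lfr_sizes(n, tau2, min_comm, max_comm, n_comm)
    if (is.null(sizes)) next
    g <- lfr_once(n, tau1, mu, k_min, max_deg, sizes)
    if (is.null(g)) next
    # mu = 0 makes communities mutually unreachable by construction; require
    # each community connected instead of the whole graph
    if (mu > 0) {
      if (!igraph::is_connected(g$graph)) next
    } else {
      parts_ok <- all(vapply(unique(g$communities), function(k) {
        sub <- igraph::induced_subgraph(g$graph, which(g$communities == k))
        igraph::is_connected(sub)
      }, logical(1)))
      if (!parts_ok) next
    }
    return(labelled_graph(g$graph, g$communities))
  }
  stop("LFR-style generator did not converge in ", max_tries, " attempts")
}

# smallest k_min whose truncated power-law mean reaches avg_deg
lfr_kmin <- function(tau1, avg_deg, max_deg) {
  best <- 1L; best_gap <- Inf
  for (k0 in seq_len(max_deg)) {
    ks <- k0:max_deg
    p <- ks^(-tau1); p <- p / sum(p)
    gap <- abs(sum(ks * p) - avg_deg)
    if (gap < best_gap) { best <- k0; best_gap <- gap }
  }
  best
}

lfr_sizes <- function(n, tau2, min_comm, max_comm, n_comm) {
  ss <- min_comm:max_comm
  p <- ss^(-tau2); p <- p / sum(p)
  for (i in 1:500) {
    sizes <- sample(ss, n_comm, replace = TRUE, prob = p)
    if (sum(sizes) == n) return(sizes)
  }
  NULL
}

# Configuration-model stub matching with iterative rewiring: bad pairs
# (loops, duplicates, pairs failing `valid`) are re-shuffled among themselves
# rather than dropped, so realized degrees track the drawn sequence closely.
match_stubs <- function(stubs, valid = NULL, existing = NULL, max_iter = 200L) {
  if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
  if (length(stubs) < 2) return(NULL)
  pairs <- matrix(sample(stubs), ncol = 2, byrow = TRUE)
  seen <- new.env(hash = TRUE)
  if (!is.null(existing)) {
    for (q in seq_len(nrow(existing))) {
      key <- paste(sort(existing[q, ]), collapse = "-")
      assign(key, TRUE, envir = seen)
    }
  }
  keep <- matrix(0L, 0, 2)
  for (iter in seq_len(max_iter)) {
    a <- pairs[, 1]; b <- pairs[, 2]
    key <- paste(pmin(a, b), pmax(a, b), sep = "-")
    bad <- a == b | duplicated(key) |
      vapply(key, exists, logical(1), envir = seen, inherits = FALSE)
    if (!is.null(valid)) bad <- bad | !valid(a, b)
    good <- which(!bad)
    if (length(good)) {
      for (kk in key[good]) assign(kk, TRUE, envir = seen)
      keep <- rbind(keep, pairs[good, , drop = FALSE])
    }
    if (!any(bad)) return(keep)
    rest <- c(pairs[bad, 1], pairs[bad, 2])
    if (length(rest) < 2) return(keep)
    pairs <- matrix(sample(rest), ncol = 2, byrow = TRUE)
  }
  keep  # a handful of unmatched stubs is tolerated
}

lfr_once <- function(n, tau1, mu, k_min, max_deg, sizes) {
  ks <- k_min:max_deg
  p <- ks^(-tau1); p <- p / sum(p)
  deg <- sample(ks, n, replace = TRUE, prob = p)

  # split degrees into internal/external stubs so the realized global mixing
  # matches mu: total external stubs = round(mu * total degree), distributed
  # by largest remainder of mu * d
  frac <- mu * deg
  d_ext <- floor(frac)
  extra <- round(mu * sum(deg)) - sum(d_ext)
  if (extra > 0) {
    ord <- order(frac - d_ext, decreasing = TRUE)
    d_ext[ord[seq_len(extra)]] <- d_ext[ord[seq_len(extra)]] + 1L
  }
  d_int <- deg - d_ext

  # capacity-aware assignment: high-internal-degree nodes go to communities
  # that can host them (internal degree <= size - 1)
  comm <- integer(n)
  slots <- sizes
  for (i in order(d_int, decreasing = TRUE)) {
    ok <- which(slots > 0 & sizes - 1L >= d_int[i])
    if (length(ok) == 0) ok <- which(slots > 0)
    k <- if (length(ok) == 1) ok else sample(ok, 1, prob = slots[ok])
    comm[i] <- k
    slots[k] <- slots[k] - 1L
  }
  # any leftover capacity violation: trim internal stubs, keep mixing intact
  # by discarding (not externalizing) the excess when mu = 0
  over <- pmax(d_int - (sizes[comm] - 1L), 0L)
  d_int <- d_int - over
  if (mu > 0) d_ext <- d_ext + over

  el <- matrix(0L, 0, 2)
  for (k in seq_along(sizes)) {
    members <- which(comm == k)
    got <- match_stubs(rep(members, d_int[members]))
    if (!is.null(got)) el <- rbind(el, got)
  }
  ext <- match_stubs(rep(seq_len(n), d_ext),
                     valid = function(a, b) comm[a] != comm[b],
                     existing = el)
  if (!is.null(ext)) el <- rbind(el, ext)
  if (nrow(el) == 0) return(NULL)
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  list(graph = g, communities = comm)
}

#' Bundled network fixtures
#'
#' `"karate"` returns Zachary's karate club (34 members, 78 friendship ties)
#' with the two post-split factions as communities. `"football"` (the American
#' college football schedule with its 12 conferences) is not bundled for
#' licensing/provenance reasons: supply the GML file via `path` and the
#' conference labels are read from the node `value` attribute.
#'
#' @param name `"karate"` or `"football"`.
#' @param path path to a user-supplied GML file (football only).
#' @return A [labelled_graph()] with communities.
#' @export
load_fixture <- function(name = c("karate", "football"), path = NULL) {
  name <- match.arg(name)
  if (name == "karate") {
    g <- igraph::make_graph("Zachary")
    faction1 <- c(1:9, 11:14, 17, 18, 20, 22)
    comm <- ifelse(seq_len(34) %in% faction1, 1L, 2L)
    return(labelled_graph(g, comm))
  }
  if (is.null(path)) {
    stop("the football network is not bundled; download the GML file ",
         "(115 nodes, 12 conferences) and pass its location as `path`")
  }
  g <- igraph::read_graph(path, format = "gml")
  val <- igraph::vertex_attr(g, "value")
  if (is.null(val)) stop("football GML must carry conference ids in `value`")
  labelled_graph(igraph::as_undirected(igraph::simplify(g)),
                 as.integer(val) + 1L)
}

#' Read a graph (and optional communities) from files
#'
#' Reads an edge list (whitespace-separated pairs, 0-based or arbitrary
#' integer ids) or a GML file, remapping node ids to 1..N; the id mapping is
#' attached as the vertex attribute `orig_id`. An optional two-column TSV
#' (node id, community id) supplies the partition; ids must resolve to graph
#' nodes.
#'
#' @param path graph file path.
#' @param format `"edgelist"` or `"gml"`.
#' @param communities_path optional TSV path.
#' @return A [labelled_graph()].
#' @export
read_graph_file <- function(path, format = c("edgelist", "gml"),
                            communities_path = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    tab <- tryCatch(read.table(path, header = FALSE),
                    error = function(e) stop("malformed edge list: ", conditionMessage(e)))
    if (ncol(tab) < 2) stop("edge list must have two columns")
    ids <- sort(unique(c(tab[[1]], tab[[2]])))
    el <- cbind(match(tab[[1]], ids), match(tab[[2]], ids))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "orig_id", value = ids)
  } else {
    g <- igraph::read_graph(path, format = "gml")
    g <- igraph::as_undirected(g)
    ids <- seq_len(igraph::vcount(g)) - 1L
    if (!is.null(igraph::vertex_attr(g, "id"))) {
      ids <- igraph::vertex_attr(g, "id")
    }
    g <- igraph::set_vertex_attr(g, "orig_id", value = ids)
  }
  g <- igraph::simplify(g)
  comm <- NULL
  if (!is.null(communities_path)) {
    ct <- read.table(communities_path, header = FALSE, sep = "\t")
    if (ncol(ct) < 2) stop("community TSV must have columns node_id, community_id")
    pos <- match(ct[[1]], igraph::vertex_attr(g, "orig_id"))
    if (anyNA(pos)) {
      bad <- which(is.na(pos))
      stop("community TSV line(s) ", paste(bad, collapse = ", "),
           ": node id not present in the graph")
    }
    comm <- integer(igraph::vcount(g))
    comm[pos] <- as.integer(as.factor(ct[[2]]))
    if (any(comm == 0L)) stop("community TSV must label every node")
  }
  labelled_graph(g, comm)
}

#' Write a graph (and optional communities) to files
#'
#' Writes the edge list (0-based ids, whitespace-separated) or GML, plus an
#' optional community TSV.
#'
#' @param g a [labelled_graph()] or igraph graph.
#' @param path output graph path.
#' @param format `"edgelist"` or `"gml"`.
#' @param communities_path optional TSV output path.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "gml"),
                             communities_path = NULL) {
  format <- match.arg(format)
  ig <- as_igraph(g)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(ig, names = FALSE) - 1L
    write.table(el, path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    for (a in igraph::graph_attr_names(ig)) {
      ig <- igraph::delete_graph_attr(ig, a)  # generator metadata, not topology
    }
    igraph::write_graph(ig, path, format = "gml")
  }
  comm <- graph_communities(g)
  if (!is.null(communities_path)) {
    if (is.null(comm)) stop("graph has no communities to write")
    write.table(cbind(seq_len(igraph::vcount(ig)) - 1L, comm),
                communities_path, sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
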