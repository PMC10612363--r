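# Median-joining haplotype networks for multistate STR data.
#
# Distance between haplotype vectors is the weighted Manhattan (single-step
# mutation) distance d(u,v) = sum_l w_l |u_l - v_l|. The network starts from
# the epsilon-relaxed minimum spanning network (all links within epsilon of
# the minimax/bottleneck connection cost are admissible), repeatedly adds
# median (Steiner) vectors -- the per-locus middle order statistic of node
# triples -- whenever they strictly reduce the local connection cost, then
# deletes obsolete median nodes. Maximum-parsimony post-processing removes
# links and medians that participate in no minimum-length spanning structure
# of the sampled haplotypes.

.pairwise_manhattan <- function(V, w) {
  n <- nrow(V)
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    diffs <- abs(sweep(V[(i + 1):n, , drop = FALSE], 2, V[i, ]))
    D[i, (i + 1):n] <- D[(i + 1):n, i] <- as.numeric(diffs %*% w)
  }
  D
}

# Prim MST with deterministic lowest-index tie-breaking.
# Returns edge list matrix (from, to) of row indices.
.mst_edges <- function(D) {
  n <- nrow(D)
  if (n < 2) return(matrix(integer(0), 0, 2))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best_d <- D[, 1]; best_from <- rep(1L, n)
  edges <- matrix(integer(0), 0, 2)
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[order(best_d[cand], cand)][1]
    edges <- rbind(edges, c(best_from[v], v))
    in_tree[v] <- TRUE
    upd <- !in_tree & D[, v] < best_d
    best_d[upd] <- D[upd, v]
    best_from[upd] <- v
  }
  edges
}

# Bottleneck (minimax path) distances: max edge weight on the MST path.
.bottleneck_matrix <- function(D) {
  n <- nrow(D)
  B <- matrix(0, n, n)
  if (n < 2) return(B)
  mst <- .mst_edges(D)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mst))) {
    i <- mst[k, 1]; j <- mst[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    # DFS from s tracking max edge weight
    stack <- s; maxw <- rep(-1, n); maxw[s] <- 0
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (v in adj[[u]]) if (maxw[v] < 0) {
        maxw[v] <- max(maxw[u], D[u, v])
        stack <- c(stack, v)
      }
    }
    B[s, ] <- maxw
  }
  (B + t(B)) / 2
}

# Feasible links of the epsilon-relaxed minimum spanning network:
# (u,v) admissible iff d(u,v) <= bottleneck(u,v) + epsilon.
.feasible_links <- function(D, epsilon) {
  B <- .bottleneck_matrix(D)
  F <- D <= B + epsilon + 1e-9
  diag(F) <- FALSE
  F
}

.floyd <- function(W) {
  n <- nrow(W)
  for (k in seq_len(n)) {
    Wk <- outer(W[, k], W[k, ], `+`)
    W <- pmin(W, Wk)
  }
  W
}

.shortest_paths_graph <- function(D, F) {
  W <- ifelse(F, D, Inf)
  diag(W) <- 0
  .floyd(W)
}

.node_order <- function(V) do.call(order, as.data.frame(V))

#' Prepare haplotype vectors for network construction
#'
#' Dual-copy loci are excluded, microvariant repeat numbers are rounded
#' half-up to the nearest integer, records with a null (or duplicated) allele
#' at an included locus are excluded and logged, and identical vectors are
#' collapsed with summed multiplicity and pooled population/haplogroup
#' tallies.
#'
#' @param sample A `ystr_sample`.
#' @param markers Single-copy markers to use (default: all single-copy).
#' @param dys389_adjust Passed to [repeat_score_matrix()]: subtract DYS389I
#'   from DYS389II before computing step distances.
#' @return List with `vectors` (distinct integer matrix, lexicographic row
#'   order), `multiplicity`, `labels` (per-vector named population tallies),
#'   `excluded` (data frame), `markers`.
#' @export
prepare_network_input <- function(sample, markers = NULL,
                                  dys389_adjust = FALSE) {
  rs <- repeat_score_matrix(sample, markers, microvariants = "round",
                            dys389_adjust = dys389_adjust)
  if (!nrow(rs$scores)) stop("all records excluded; nothing to build")
  keys <- apply(rs$scores, 1, paste, collapse = "|")
  pops <- sample$data$population[match(rownames(rs$scores),
                                       sample$data$sample_id)]
  uk <- !duplicated(keys)
  V <- rs$scores[uk, , drop = FALSE]
  mult <- as.integer(table(keys)[keys[uk]])
  labs <- lapply(keys[uk], function(k) table(pops[keys == k]))
  o <- .node_order(V)
  list(vectors = unname(V[o, , drop = FALSE]),
       multiplicity = mult[o],
       labels = labs[o],
       excluded = rs$excluded,
       markers = colnames(rs$scores))
}

.make_network <- function(V, kind, mult, labels, loci, epsilon, weights,
                          D = NULL, F = NULL, meta = list()) {
  if (is.null(D)) D <- .pairwise_manhattan(V, weights)
  if (is.null(F)) F <- .feasible_links(D, epsilon)
  n <- nrow(V)
  ids <- character(n)
  ids[kind == "sampled"] <- paste0("H", seq_len(sum(kind == "sampled")))
  ids[kind == "median"] <- paste0("M", seq_len(sum(kind == "median")))
  edges <- which(F & upper.tri(F), arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  edf <- data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                    weight = D[edges], stringsAsFactors = FALSE)
  structure(list(
    ids = ids, vectors = V, kind = kind, multiplicity = mult,
    labels = labels, loci = loci, epsilon = epsilon, weights = weights,
    edges = edf, edge_idx = edges, dist = D,
    total_length = sum(D[edges]), meta = meta
  ), class = "ystr_network")
}

#' @export
print.ystr_network <- function(x, ...) {
  cat("Haplotype network: ", sum(x$kind == "sampled"), " sampled + ",
      sum(x$kind == "median"), " median nodes, ", nrow(x$edges),
      " links, total length ", x$total_length, "\n", sep = "")
  invisible(x)
}

# Remove obsolete medians: degree <= 2 in the feasible graph and lying on no
# shortest path between a pair of sampled nodes. Iterates to a fixed point.
.drop_obsolete_medians <- function(V, kind, mult, labels, weights, epsilon) {
  repeat {
    D <- .pairwise_manhattan(V, weights)
    F <- .feasible_links(D, epsilon)
    SP <- .shortest_paths_graph(D, F)
    sampled <- which(kind == "sampled")
    drop <- NA_integer_
    for (x in which(kind == "median")) {
      if (sum(F[x, ]) > 2) next
      on_path <- FALSE
      for (u in sampled) {
        if (on_path) break
        for (v in sampled) {
          if (u >= v) next
          if (SP[u, x] + SP[x, v] <= SP[u, v] + 1e-9) { on_path <- TRUE; break }
        }
      }
      if (!on_path) { drop <- x; break }
    }
    if (is.na(drop)) return(list(V = V, kind = kind, mult = mult,
                                 labels = labels, D = D, F = F))
    V <- V[-drop, , drop = FALSE]; kind <- kind[-drop]
    mult <- mult[-drop]; labels <- labels[-drop]
  }
}

#' Median-joining network construction
#'
#' Builds the epsilon-relaxed minimum spanning network over the distinct
#' haplotype vectors, then iteratively adds median vectors (per-locus middle
#' order statistic of node triples reachable through the current feasible
#' links) whenever they strictly reduce the cost of connecting the triple,
#' until no further median helps; finally, median nodes of degree at most two
#' lying on no shortest sampled-pair path are deleted.
#'
#' @param vectors Integer matrix of distinct haplotype vectors (rows), or the
#'   result of [prepare_network_input()].
#' @param multiplicity Per-vector sample multiplicities (default 1).
#' @param epsilon Relaxation of the minimum-spanning criterion (weight
#'   units); 0 keeps exactly the union-of-MSTs links.
#' @param weights Per-locus weights (default 10 for every locus, the usual
#'   convention for STR network software).
#' @param labels Optional per-vector label tallies carried into the nodes.
#' @param max_iter Safety cap on median-addition passes.
#' @return A `ystr_network`: nodes (`ids`, `vectors`, `kind`,
#'   `multiplicity`), feasible `edges` with weights, per-locus `weights`,
#'   `epsilon` and `total_length`.
#' @export
median_joining <- function(vectors, multiplicity = NULL, epsilon = 0,
                           weights = NULL, labels = NULL, max_iter = 25) {
  if (is.list(vectors) && !is.null(vectors$vectors)) {
    prep <- vectors
    vectors <- prep$vectors
    if (is.null(multiplicity)) multiplicity <- prep$multiplicity
    if (is.null(labels)) labels <- prep$labels
    loci <- prep$markers
  } else loci <- colnames(vectors)
  V <- as.matrix(vectors)
  storage.mode(V) <- "double"
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(V)))
  if (anyDuplicated(apply(V, 1, paste, collapse = "|")))
    stop("haplotype vectors must be distinct; collapse multiplicities first")
  n0 <- nrow(V)
  if (is.null(multiplicity)) multiplicity <- rep(1L, n0)
  if (is.null(weights)) weights <- rep(10, ncol(V))
  stopifnot(all(weights > 0), length(weights) == ncol(V),
            length(multiplicity) == n0)
  if (is.null(labels)) labels <- vector("list", n0)
  kind <- rep("sampled", n0)
  mult <- as.integer(multiplicity)

  if (n0 == 1L)
    return(.make_network(V, kind, mult, labels, loci, epsilon, weights))

  for (iter in seq_len(max_iter)) {
    D <- .pairwise_manhattan(V, weights)
    F <- .feasible_links(D, epsilon)
    keyset <- new.env(hash = TRUE)
    for (i in seq_len(nrow(V)))
      assign(paste(V[i, ], collapse = "|"), TRUE, envir = keyset)
    links <- which(F & upper.tri(F), arr.ind = TRUE)
    # candidate medians of (linked pair, third node) triples that strictly
    # reduce the triple's connection cost; per pass only the candidates of
    # minimal connection cost are added (the usual lambda-minimality rule,
    # which keeps median growth controlled on widely separated clusters)
    cand_med <- list(); cand_cost <- numeric(0)
    n_cur <- nrow(V)
    for (k in seq_len(nrow(links))) {
      u <- links[k, 1]; v <- links[k, 2]
      # per-locus median of (u, v, w) is w clamped to [min(u,v), max(u,v)]
      lo <- pmin(V[u, ], V[v, ]); hi <- pmax(V[u, ], V[v, ])
      meds <- pmin(pmax(V, matrix(lo, n_cur, ncol(V), byrow = TRUE)),
                   matrix(hi, n_cur, ncol(V), byrow = TRUE))
      dmu <- abs(sweep(meds, 2, V[u, ])) %*% weights
      dmv <- abs(sweep(meds, 2, V[v, ])) %*% weights
      dmw <- abs(meds - V) %*% weights
      c_med <- as.numeric(dmu + dmv + dmw)
      c_direct <- pmin(D[u, v] + D[u, ], D[u, v] + D[v, ],
                       D[u, ] + D[v, ])
      ok <- which(c_med < c_direct - 1e-9)
      ok <- setdiff(ok, c(u, v))
      for (w_ in ok) {
        mkey <- paste(meds[w_, ], collapse = "|")
        if (exists(mkey, envir = keyset, inherits = FALSE)) next
        assign(mkey, TRUE, envir = keyset)
        cand_med[[length(cand_med) + 1L]] <- meds[w_, ]
        cand_cost <- c(cand_cost, c_med[w_])
      }
    }
    if (!length(cand_med)) break
    keep <- which(cand_cost <= min(cand_cost) + 1e-9)
    add <- do.call(rbind, cand_med[keep])
    V <- rbind(V, add)
    kind <- c(kind, rep("median", nrow(add)))
    mult <- c(mult, rep(0L, nrow(add)))
    labels <- c(labels, vector("list", nrow(add)))
  }

  pruned <- .drop_obsolete_medians(V, kind, mult, labels, weights, epsilon)
  # deterministic ordering: sampled first (lexicographic), then medians
  o <- with(pruned, order(kind != "sampled", .node_order_rank(V)))
  V <- pruned$V[o, , drop = FALSE]
  .make_network(V, pruned$kind[o], pruned$mult[o], pruned$labels[o],
                loci, epsilon, weights)
}

.node_order_rank <- function(V) {
  o <- .node_order(V)
  r <- integer(nrow(V)); r[o] <- seq_len(nrow(V)); r
}

# MST total length over a restricted node set using only network edges.
# Returns list(length, edges) or NULL if disconnected; `all_mst_edges` marks
# every edge participating in at least one MST (bottleneck criterion).
.restricted_mst <- function(W) {
  n <- nrow(W)
  if (n == 1) return(list(length = 0, in_some_mst = matrix(FALSE, 1, 1)))
  # Prim on W (Inf = no edge)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best_d <- W[, 1]
  total <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[order(best_d[cand], cand)][1]
    if (!is.finite(best_d[v])) return(NULL)
    total <- total + best_d[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & W[, v] < best_d
    best_d[upd] <- W[upd, v]
  }
  # union of all MSTs: edge (i,j) with finite weight is in some MST iff its
  # weight equals the bottleneck distance between i and j in the graph
  Wd <- W; diag(Wd) <- 0
  D2 <- ifelse(is.finite(Wd), Wd, 0)
  # bottleneck on graph with missing edges: run on shortest... use minimax
  # via Floyd-style recursion on max
  Bm <- W; diag(Bm) <- 0
  for (k in seq_len(n)) {
    Bk <- pmax(matrix(Bm[, k], n, n), matrix(Bm[k, ], n, n, byrow = TRUE))
    Bm <- pmin(Bm, Bk)
  }
  in_some <- is.finite(W) & abs(W - Bm) <= 1e-9
  diag(in_some) <- FALSE
  list(length = total, in_some_mst = in_some)
}

#' Maximum-parsimony post-processing of a haplotype network
#'
#' Removes links and median nodes that participate in no minimum-total-length
#' spanning structure connecting all sampled nodes. When the candidate link
#' count is at most `exhaustive_bound` (and median count at most 14) all
#' median subsets are enumerated; otherwise a shortest-path-union heuristic
#' keeps every link on some shortest sampled-pair path (flagged in
#' `meta$mp`).
#'
#' @param network A `ystr_network`.
#' @param exhaustive_bound Max candidate links for the exhaustive search.
#' @return A pruned `ystr_network` with `meta$mp` set to `"exhaustive"` or
#'   `"heuristic"`; total length never increases.
#' @export
mp_prune <- function(network, exhaustive_bound = 20) {
  stopifnot(inherits(network, "ystr_network"))
  V <- network$vectors; kind <- network$kind
  D <- network$dist
  n <- nrow(V)
  E <- network$edge_idx
  W <- matrix(Inf, n, n)
  for (k in seq_len(nrow(E))) {
    W[E[k, 1], E[k, 2]] <- W[E[k, 2], E[k, 1]] <- D[E[k, 1], E[k, 2]]
  }
  sampled <- which(kind == "sampled")
  medians <- which(kind == "median")

  if (nrow(E) <= exhaustive_bound && length(medians) <= 14) {
    best_len <- Inf
    opt <- list()
    for (mask in 0:(2^length(medians) - 1)) {
      sub <- c(sampled, medians[bitwAnd(bitwShiftR(mask,
                 seq_along(medians) - 1L), 1L) == 1L])
      res <- .restricted_mst(W[sub, sub, drop = FALSE])
      if (is.null(res)) next
      if (res$length < best_len - 1e-9) {
        best_len <- res$length; opt <- list(list(sub = sub, res = res))
      } else if (res$length <= best_len + 1e-9) {
        opt[[length(opt) + 1L]] <- list(sub = sub, res = res)
      }
    }
    if (!is.finite(best_len)) stop("sampled nodes not connected")
    keep_node <- rep(FALSE, n); keep_node[sampled] <- TRUE
    keep_edge <- matrix(FALSE, n, n)
    for (o in opt) {
      sub <- o$sub
      ins <- o$res$in_some_mst
      keep_edge[sub, sub] <- keep_edge[sub, sub] | ins
      used <- sub[colSums(ins) > 0 | rowSums(ins) > 0]
      keep_node[used] <- TRUE
      keep_node[sub[seq_along(sampled)]] <- TRUE
    }
    meta <- list(mp = "exhaustive", optimal_length = best_len)
  } else {
    SP <- .floyd(W)
    keep_edge <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(E))) {
      x <- E[k, 1]; y <- E[k, 2]; wxy <- W[x, y]
      on_path <- FALSE
      for (u in sampled) {
        if (on_path) break
        for (v in sampled) {
          if (u >= v && length(sampled) > 1) next
          if (min(SP[u, x] + wxy + SP[y, v],
                  SP[u, y] + wxy + SP[x, v]) <= SP[u, v] + 1e-9) {
            on_path <- TRUE; break
          }
        }
      }
      if (on_path) keep_edge[x, y] <- keep_edge[y, x] <- TRUE
    }
    keep_node <- rep(FALSE, n); keep_node[sampled] <- TRUE
    keep_node[medians[vapply(medians, function(m) any(keep_edge[m, ]),
                             TRUE)]] <- TRUE
    meta <- list(mp = "heuristic")
  }

  idx <- which(keep_node)
  V2 <- V[idx, , drop = FALSE]
  F2 <- keep_edge[idx, idx, drop = FALSE]
  o <- order(kind[idx] != "sampled", .node_order_rank(V2))
  .make_network(V2[o, , drop = FALSE], kind[idx][o],
                network$multiplicity[idx][o], network$labels[idx][o],
                network$loci, network$epsilon, network$weights,
                D = D[idx, idx, drop = FALSE][o, o, drop = FALSE],
                F = F2[o, o, drop = FALSE], meta = meta)
}

#' Export a haplotype network as node/edge tables
#'
#' Writes a TSV node table (id, kind, multiplicity, label tallies, allele
#' vector) and a TSV edge table (endpoints, weight, per-locus mutation
#' steps, e.g. `"DYS19:+1"`); optionally a GML file.
#'
#' @param network A `ystr_network`.
#' @param nodes_path,edges_path Output paths for the two TSV tables.
#' @param format `"tsv"` or `"gml"` (GML written to `nodes_path`).
#' @return Paths, invisibly.
#' @export
export_network <- function(network, nodes_path, edges_path = NULL,
                           format = c("tsv", "gml")) {
  stopifnot(inherits(network, "ystr_network"))
  format <- match.arg(format)
  lab_str <- vapply(network$labels, function(t) {
    if (is.null(t) || !length(t)) return("")
    paste(paste0(names(t), ":", as.integer(t)), collapse = ",")
  }, character(1))
  vec_df <- as.data.frame(network$vectors)
  names(vec_df) <- network$loci
  nodes <- cbind(data.frame(id = network$ids, kind = network$kind,
                            multiplicity = network$multiplicity,
                            labels = lab_str, stringsAsFactors = FALSE),
                 vec_df)
  steps <- vapply(seq_len(nrow(network$edges)), function(k) {
    i <- network$edge_idx[k, 1]; j <- network$edge_idx[k, 2]
    delta <- network$vectors[j, ] - network$vectors[i, ]
    nz <- which(delta != 0)
    paste(paste0(network$loci[nz], ":", ifelse(delta[nz] > 0, "+", ""),
                 delta[nz]), collapse = ";")
  }, character(1))
  edges <- cbind(network$edges, steps = steps)
  if (format == "gml") {
    con <- file(nodes_path, "w")
    on.exit(close(con))
    writeLines("graph [", con)
    for (i in seq_along(network$ids))
      writeLines(sprintf('  node [ id %d label "%s" kind "%s" mult %d ]',
                         i - 1L, network$ids[i], network$kind[i],
                         network$multiplicity[i]), con)
    for (k in seq_len(nrow(network$edges)))
      writeLines(sprintf('  edge [ source %d target %d weight %s ]',
                         match(network$edges$from[k], network$ids) - 1L,
                         match(network$edges$to[k], network$ids) - 1L,
                         format(network$edges$weight[k])), con)
    writeLines("]", con)
    return(invisible(nodes_path))
  }
  if (is.null(edges_path)) stop("edges_path required for TSV export")
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Import a network from exported TSV tables
#'
#' @param nodes_path,edges_path Paths written by [export_network()].
#' @param epsilon,weights Parameters to attach (weights default 10).
#' @return A `ystr_network` (feasible links recomputed from the node set are
#'   replaced by the imported edge list).
#' @export
import_network <- function(nodes_path, edges_path, epsilon = 0,
                           weights = NULL) {
  nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  loci <- setdiff(names(nodes), c("id", "kind", "multiplicity", "labels"))
  V <- as.matrix(nodes[loci])
  if (is.null(weights)) weights <- rep(10, length(loci))
  labs <- lapply(nodes$labels, function(s) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) as.integer(p[2]), 1L),
                    vapply(parts, `[`, "", 1))
  })
  n <- nrow(V)
  F <- matrix(FALSE, n, n)
  ei <- cbind(match(edges$from, nodes$id), match(edges$to, nodes$id))
  F[ei] <- TRUE; F[ei[, 2:1, drop = FALSE]] <- TRUE
  net <- .make_network(unname(V), nodes$kind, nodes$multiplicity, labs,
                       loci, epsilon, weights, F = F)
  net
}
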