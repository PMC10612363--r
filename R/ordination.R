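# Ordination and clustering of population distance matrices: classical
# (Torgerson) metric MDS and a UPGMA dendrogram with Newick export.

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers -D^2/2, eigendecomposes, and returns the top-k coordinates
#' scaled by the square root of the eigenvalues. Exact Euclidean distance
#' matrices are reproduced to numerical tolerance; negative eigenvalues
#' (non-Euclidean input) are dropped with a diagnostic.
#'
#' @param D A `ystr_dist` or symmetric numeric matrix with labels.
#' @param k Number of dimensions requested (reduced with a warning if fewer
#'   positive eigenvalues exist).
#' @return List with `labels`, `points` (n x k matrix, centroid at origin),
#'   `eigenvalues` (all, descending) and `explained` (fraction of the
#'   positive-eigenvalue total per retained axis).
#' @export
classical_mds <- function(D, k = 2) {
  if (inherits(D, "ystr_dist")) {
    labels <- D$labels; M <- D$values
  } else {
    M <- as.matrix(D)
    labels <- rownames(M)
    if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(M)))
  }
  stopifnot(k >= 1, nrow(M) >= 2)
  n <- nrow(M)
  A <- -0.5 * M^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 0)
  if (!length(pos)) stop("no positive eigenvalues; degenerate input")
  if (k > length(pos)) {
    warning("only ", length(pos), " positive eigenvalues; reducing k from ",
            k, " to ", length(pos))
    k <- length(pos)
  }
  pts <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  rownames(pts) <- labels
  colnames(pts) <- paste0("dim", seq_len(k))
  list(labels = labels, points = pts, eigenvalues = e$values,
       explained = e$values[pos[seq_len(k)]] / sum(e$values[pos]))
}

#' UPGMA dendrogram with Newick export
#'
#' Average-linkage agglomerative clustering of a population distance matrix,
#' giving an ultrametric tree (every leaf equidistant from the root). Ties
#' are broken deterministically by the position of each cluster's first
#' member in the input label order. Branch lengths: a cluster formed at
#' distance d sits at height d/2.
#'
#' @param D A `ystr_dist` or symmetric numeric matrix with labels.
#' @return A string: the Newick representation, terminated by `";"`.
#' @examples
#' m <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), NULL))
#' upgma_tree(m)  # "(A:0.2,B:0.2);"
#' @export
upgma_tree <- function(D) {
  if (inherits(D, "ystr_dist")) {
    labels <- D$labels; M <- D$values
  } else {
    M <- as.matrix(D)
    labels <- rownames(M)
    if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(M)))
  }
  n <- nrow(M)
  stopifnot(n >= 2)
  safe <- gsub("[^A-Za-z0-9_.]+", "_", labels)
  # active clusters: member index sets, sizes, heights, newick fragments
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  frags <- safe
  d <- M
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL; best_d <- Inf; best_key <- c(Inf, Inf)
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      dij <- d[i, j]
      key <- sort(c(min(members[[i]]), min(members[[j]])))
      if (dij < best_d - 1e-15 ||
          (abs(dij - best_d) <= 1e-15 &&
           (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best_d <- dij; best <- c(i, j); best_key <- key
      }
    }
    i <- best[1]; j <- best[2]
    # child order: cluster containing the earlier input label comes first
    if (min(members[[j]]) < min(members[[i]])) { t <- i; i <- j; j <- t }
    h <- best_d / 2
    new_frag <- paste0("(", frags[i], ":", format(h - heights[i],
                                                  digits = 10),
                       ",", frags[j], ":", format(h - heights[j],
                                                  digits = 10), ")")
    # average linkage update: weighted by cluster sizes
    k <- length(members) + 1L
    members[[k]] <- c(members[[i]], members[[j]])
    sizes[k] <- sizes[i] + sizes[j]
    heights[k] <- h
    frags[k] <- new_frag
    d <- rbind(cbind(d, 0), 0)
    for (o in active) {
      if (o == i || o == j) next
      d[k, o] <- d[o, k] <-
        (sizes[i] * d[i, o] + sizes[j] * d[j, o]) / (sizes[i] + sizes[j])
    }
    active <- c(setdiff(active, c(i, j)), k)
  }
  paste0(frags[active], ";")
}
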