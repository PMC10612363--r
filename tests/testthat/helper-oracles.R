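# Independent oracle implementations used to cross-check the package.
# These deliberately take the definitional (brute-force) route, not the
# closed-form/algorithmic route used by the package code.

# --- spectra / haplotype-level parameters ------------------------------

# HMP by counting matching ordered pairs (self-pairs included) / n^2
oracle_hmp <- function(keys) {
  n <- length(keys)
  matches <- sum(outer(keys, keys, `==`))
  matches / n^2
}

# unordered distinct-pair match probability: sum n_i (n_i - 1) / (n (n-1))
oracle_pair_match <- function(keys) {
  n <- length(keys)
  cnt <- table(keys)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

# random multiplicity spectrum as a key vector
random_keys <- function(n_max = 60) {
  n <- sample(2:n_max, 1)
  k <- sample(1:n, 1)
  paste0("h", sample(k, n, replace = TRUE))
}

# --- RST: definitional pair-sum variance components --------------------

# One-level haploid AMOVA from explicit pairwise squared distances.
oracle_rst <- function(pops) {
  # pops: list of numeric matrices (records x loci)
  Z <- do.call(rbind, pops)
  sizes <- vapply(pops, nrow, 1L)
  N <- sum(sizes); P <- length(pops)
  d2 <- function(M) {
    tot <- 0
    n <- nrow(M)
    if (n < 2) return(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      tot <- tot + sum((M[i, ] - M[j, ])^2)
    tot
  }
  ssd_total <- d2(Z) / N
  ssd_within <- sum(vapply(pops, function(M) d2(M) / nrow(M), 0))
  sigma_w <- ssd_within / (N - P)
  msd_a <- (ssd_total - ssd_within) / (P - 1)
  n_prime <- (N - sum(sizes^2) / N) / (P - 1)
  sigma_a <- (msd_a - sigma_w) / n_prime
  if (sigma_a + sigma_w <= 0) return(0)
  min(max(sigma_a / (sigma_a + sigma_w), 0), 1)
}

# --- Nei standard distance: per-locus brute accumulation ---------------

oracle_nei <- function(freq_x, freq_y) {
  # freq_x / freq_y: lists (per locus) of named frequency vectors
  jx <- jy <- jxy <- 0
  for (l in seq_along(freq_x)) {
    fx <- freq_x[[l]]; fy <- freq_y[[l]]
    jx <- jx + sum(fx^2); jy <- jy + sum(fy^2)
    for (a in names(fx)) if (a %in% names(fy))
      jxy <- jxy + fx[[a]] * fy[[a]]
  }
  -log(jxy / sqrt(jx * jy))
}

# --- UPGMA: naive O(n^3) with explicit cluster sets --------------------

# Returns the cophenetic distance matrix implied by naive UPGMA on D.
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  coph <- matrix(0, n, n)
  d <- D
  while (length(active) > 1) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (x in clusters[[i]]) for (y in clusters[[j]])
      coph[x, y] <- coph[y, x] <- best_d
    k <- length(clusters) + 1L
    clusters[[k]] <- c(clusters[[i]], clusters[[j]])
    d <- rbind(cbind(d, 0), 0)
    for (o in active) {
      if (o %in% best) next
      # unweighted average over original member pairs
      d[k, o] <- d[o, k] <- mean(D[clusters[[k]], clusters[[o]],
                                   drop = FALSE])
    }
    active <- c(setdiff(active, best), k)
  }
  coph
}

# --- MST / Steiner oracles for networks --------------------------------

oracle_mst_length <- function(V, w = rep(1, ncol(V))) {
  n <- nrow(V)
  D <- as.matrix(dist(sweep(V, 2, w, `*`), method = "manhattan"))
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[, 1]
  tot <- 0
  for (s in seq_len(n - 1)) {
    v <- which(!in_tree)[which.min(best[!in_tree])]
    tot <- tot + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, D[, v])
    best[in_tree] <- Inf
  }
  unname(tot)
}

# Brute-force Steiner minimum over the allele bounding box: tries every
# subset of candidate box points up to `max_steiner` and takes the best MST.
oracle_steiner_length <- function(V, w = rep(1, ncol(V)), max_steiner = 3) {
  rng <- apply(V, 2, range)
  grid <- as.matrix(expand.grid(lapply(seq_len(ncol(V)), function(j)
    rng[1, j]:rng[2, j])))
  keys_v <- apply(V, 1, paste, collapse = "|")
  cand <- grid[!(apply(grid, 1, paste, collapse = "|") %in% keys_v), ,
               drop = FALSE]
  best <- oracle_mst_length(V, w)
  m <- nrow(cand)
  for (k in seq_len(min(max_steiner, m))) {
    combos <- utils::combn(m, k)
    for (c_i in seq_len(ncol(combos))) {
      len <- oracle_mst_length(rbind(V, cand[combos[, c_i], ,
                                             drop = FALSE]), w)
      if (len < best) best <- len
    }
  }
  best
}

# --- misc helpers ------------------------------------------------------

# tiny 3-marker test panel (2 standard single-copy + 1 dual-copy)
tiny_panel <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("marker\tcopy_number\tmutation_class\tmin_allele\tmax_allele",
               "DYS19\t1\tstandard\t5\t30",
               "DYS458\t1\trapidly_mutating\t5\t30",
               "DYS385\t2\tstandard\t5\t30"), f)
  read_panel_config(f)
}

# build a haplotype table text from rows of tokens
table_text <- function(header, rows) {
  c(paste(header, collapse = "\t"),
    vapply(rows, paste, "", collapse = "\t"))
}

# total network length recomputed from scratch from vectors + edges
network_length_from_edges <- function(net) {
  sum(vapply(seq_len(nrow(net$edges)), function(k) {
    i <- match(net$edges$from[k], net$ids)
    j <- match(net$edges$to[k], net$ids)
    sum(net$weights * abs(net$vectors[i, ] - net$vectors[j, ]))
  }, 0))
}

# build a ystr_sample from an integer score matrix over ad-hoc single-copy
# markers (L1..Lk), population label attached
sample_from_scores <- function(M, pop = "pop", ids = NULL) {
  L <- ncol(M)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("marker\tcopy_number\tmutation_class\tmin_allele\tmax_allele",
               paste0("L", seq_len(L), "\t1\tstandard\t1\t99")), f)
  panel <- read_panel_config(f)
  if (is.null(ids)) ids <- paste0(pop, "_", seq_len(nrow(M)))
  hdr <- c("sample_id", "population", paste0("L", seq_len(L)))
  rows <- lapply(seq_len(nrow(M)), function(i)
    c(ids[i], pop, as.character(M[i, ])))
  parse_haplotype_table(table_text(hdr, rows), panel, name = pop)
}
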