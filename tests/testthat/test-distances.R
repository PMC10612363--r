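test_that("RST limit cases: full separation and identity", {
  A <- sample_from_scores(matrix(c(10, 10), ncol = 1), "A")
  B <- sample_from_scores(matrix(c(12, 12), ncol = 1), "B")
  D <- rst_pairwise(list(A = A, B = B))
  expect_equal(D$values["A", "B"], 1)

  Bsame <- sample_from_scores(matrix(c(10, 10), ncol = 1), "B")
  D0 <- rst_pairwise(list(A = A, B = Bsame))
  expect_equal(D0$values["A", "B"], 0)

  # identical multisets with internal variance also give 0 (clamped)
  M <- matrix(c(10, 12, 14, 11, 12, 13), ncol = 2)
  D1 <- rst_pairwise(list(A = sample_from_scores(M, "A"),
                          B = sample_from_scores(M, "B")))
  expect_equal(D1$values["A", "B"], 0)
})

test_that("RST equals the definitional variance-component oracle", {
  set.seed(101)
  for (rep in 1:15) {
    P <- sample(2:4, 1)
    mats <- lapply(seq_len(P), function(k) {
      n <- sample(4:12, 1)
      base <- sample(10:20, 3, replace = TRUE)
      t(replicate(n, base + sample(-2:2, 3, replace = TRUE)))
    })
    samples <- lapply(seq_len(P), function(k)
      sample_from_scores(mats[[k]], paste0("p", k)))
    names(samples) <- paste0("p", seq_len(P))
    D <- rst_pairwise(samples)
    expect_true(max(abs(D$values - t(D$values))) < 1e-12)
    expect_true(all(diag(D$values) == 0))
    for (i in 1:(P - 1)) for (j in (i + 1):P) {
      expect_equal(D$values[i, j], oracle_rst(mats[c(i, j)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("RST is permutation-equivariant in population order", {
  set.seed(55)
  mats <- lapply(1:3, function(k)
    matrix(sample(10:15, 12, replace = TRUE), ncol = 2))
  samples <- lapply(1:3, function(k)
    sample_from_scores(mats[[k]], paste0("p", k)))
  names(samples) <- paste0("p", 1:3)
  D <- rst_pairwise(samples)
  Dp <- rst_pairwise(samples[c(3, 1, 2)])
  expect_equal(Dp$values[Dp$labels, Dp$labels][D$labels, D$labels],
               D$values)
})

test_that("RST preconditions and exclusions", {
  A <- sample_from_scores(matrix(10, 1, 1), "A")
  B <- sample_from_scores(matrix(c(10, 11), 2, 1), "B")
  expect_error(rst_pairwise(list(A = A, B = B)), "fewer than 2")
  # null-bearing records are excluded and logged
  p3 <- tiny_panel()
  hdr <- c("sample_id", "population", "DYS19", "DYS458", "DYS385")
  s <- parse_haplotype_table(table_text(hdr, list(
    c("a1", "A", "10", "17", "11-14"), c("a2", "A", "11", "17", "11-14"),
    c("a3", "A", "-", "17", "11-14"),
    c("b1", "B", "12", "17", "11-14"), c("b2", "B", "13", "17", "11-14"))),
    p3)
  D <- rst_pairwise(s, by = "population")
  excl <- attr(D, "excluded")
  expect_equal(excl$A$sample_id, "a3")
  expect_match(excl$A$reason, "null@DYS19")
})

test_that("Nei standard distance: identity, hand case, oracle", {
  X <- sample_from_scores(matrix(c(10, 10, 10, 10), ncol = 1), "X")
  Y <- sample_from_scores(matrix(c(10, 10, 11, 11), ncol = 1), "Y")
  D <- nei_standard_distance(list(X = X, Y = Y))
  expect_equal(D$values["X", "Y"], -log(0.5 / sqrt(0.5)))
  expect_equal(round_half_up(D$values["X", "Y"], 4), 0.3466)

  D0 <- nei_standard_distance(list(A = X, B = X))
  expect_equal(D0$values["A", "B"], 0)

  set.seed(77)
  for (rep in 1:10) {
    MX <- matrix(sample(10:14, 24, replace = TRUE), ncol = 3)
    MY <- matrix(sample(10:14, 18, replace = TRUE), ncol = 3)
    sx <- sample_from_scores(MX, "X"); sy <- sample_from_scores(MY, "Y")
    D <- nei_standard_distance(list(X = sx, Y = sy))
    fx <- lapply(paste0("L", 1:3), function(m)
      allele_frequencies(sx, m)$frequencies)
    fy <- lapply(paste0("L", 1:3), function(m)
      allele_frequencies(sy, m)$frequencies)
    expect_equal(D$values["X", "Y"], max(oracle_nei(fx, fy), 0))
    expect_gte(D$values["X", "Y"], 0)
  }
})

test_that("disjoint allele sets give a flagged Inf distance", {
  X <- sample_from_scores(matrix(c(10, 10), ncol = 1), "X")
  Y <- sample_from_scores(matrix(c(20, 20), ncol = 1), "Y")
  expect_warning(D <- nei_standard_distance(list(X = X, Y = Y)),
                 "zero between-population")
  expect_equal(D$values["X", "Y"], Inf)
})

test_that("distance matrices round-trip through TSV", {
  vals <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3)
  D <- ystrkit:::new_distance_matrix(c("a", "b", "c"), vals, "nei")
  f <- tempfile()
  write_distance_matrix(D, f)
  D2 <- read_distance_matrix(f, "nei")
  expect_equal(D2$labels, D$labels)
  expect_equal(D2$values, D$values, tolerance = 1e-12)
})

test_that("classical MDS inverts exact Euclidean distances", {
  # collinear points: distances (1,1,2)
  M <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), NULL))
  res <- classical_mds(M, 1)
  got <- as.matrix(dist(res$points))
  expect_equal(unname(got), unname(M), tolerance = 1e-9)
  # centroid at origin
  expect_equal(colSums(res$points), c(dim1 = 0), tolerance = 1e-9)

  # random 5 points in 2D, recovery up to rotation/reflection
  set.seed(13)
  for (rep in 1:10) {
    X <- matrix(rnorm(10), 5, 2)
    D5 <- as.matrix(dist(X))
    rownames(D5) <- paste0("p", 1:5)
    res5 <- classical_mds(D5, 2)
    expect_equal(unname(as.matrix(dist(res5$points))), unname(D5),
                 tolerance = 1e-9)
    pr <- vegan::procrustes(X, res5$points, symmetric = FALSE)
    expect_lt(sqrt(sum(pr$residuals^2)), 1e-8)
  }

  # 2-population matrix: two points separated by exactly D(1,2)
  M2 <- matrix(c(0, .42, .42, 0), 2, dimnames = list(c("x", "y"), NULL))
  r2 <- classical_mds(M2, 1)
  expect_equal(abs(r2$points[1] - r2$points[2]), .42, tolerance = 1e-12)
})

test_that("MDS reduces k with a warning when eigenvalues run out", {
  M <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), NULL))
  expect_warning(res <- classical_mds(M, 3), "reducing k")
  expect_lt(ncol(res$points), 3)
})

test_that("UPGMA: exact small cases and deterministic join order", {
  M <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), NULL))
  expect_equal(upgma_tree(M), "(A:0.2,B:0.2);")

  M3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
               dimnames = list(c("A", "B", "C"), NULL))
  nwk <- upgma_tree(M3)
  expect_match(nwk, "^\\(\\(A:0.1,B:0.1\\):0.2,C:0.3\\);$")
})

test_that("UPGMA matches naive oracle and is ultrametric", {
  set.seed(19)
  for (rep in 1:8) {
    n <- 6
    X <- matrix(rnorm(n * 3), n)
    D <- as.matrix(dist(X))
    rownames(D) <- colnames(D) <- paste0("t", 1:n)
    nwk <- upgma_tree(D)
    tr <- ape::read.tree(text = nwk)
    # ultrametric: equal root-to-leaf depths
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
    # cophenetic distances equal the naive UPGMA oracle
    coph <- ape::cophenetic.phylo(tr)
    oracle <- oracle_upgma_cophenetic(D)
    dimnames(oracle) <- dimnames(D)
    expect_equal(coph[rownames(D), rownames(D)], oracle,
                 tolerance = 1e-9)
  }
})

test_that("Nei Da variant and RST permutation p-values behave sanely", {
  X <- sample_from_scores(matrix(c(10, 10, 10, 10), ncol = 1), "X")
  Y <- sample_from_scores(matrix(c(10, 10, 11, 11), ncol = 1), "Y")
  Dda <- nei_standard_distance(list(X = X, Y = Y), variant = "da")
  # Da = 1 - sum sqrt(p_x p_y) over the single locus
  expect_equal(Dda$values["X", "Y"], 1 - sqrt(1 * 0.5))
  expect_equal(Dda$method, "nei_da")
  Dsame <- nei_standard_distance(list(A = X, B = X), variant = "da")
  expect_equal(Dsame$values["A", "B"], 0)

  set.seed(3)
  A <- sample_from_scores(matrix(sample(10:11, 10, TRUE), ncol = 1), "A")
  B <- sample_from_scores(matrix(sample(14:15, 10, TRUE), ncol = 1), "B")
  D <- rst_pairwise(list(A = A, B = B), permutations = 49)
  p <- attr(D, "p_values")
  expect_equal(dim(p), c(2, 2))
  expect_lt(p[1, 2], 0.1)   # complete separation: smallest possible p
})

test_that("DYS389II adjustment subtracts the DYS389I stretch", {
  p <- build_panel("single_copy_23")
  sim <- simulate_sample(simulation_config(
    p, seed = 2, subpops = list(list(name = "a", n = 5))))
  raw <- repeat_score_matrix(sim$combined)
  adj <- repeat_score_matrix(sim$combined, dys389_adjust = TRUE)
  expect_equal(adj$scores[, "DYS389II"],
               raw$scores[, "DYS389II"] - raw$scores[, "DYS389I"])
  expect_equal(adj$scores[, "DYS19"], raw$scores[, "DYS19"])
})
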