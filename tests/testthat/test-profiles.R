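test_that("normalization matches the element-wise log relative expression", {
  set.seed(1)
  cts <- matrix(rpois(12, 6), 4, 3)
  sc <- SpatialCounts(cts)
  norm <- normalizeCounts(sc)
  # independent per-entry recomputation
  for (i in 1:4) for (j in 1:3)
    expect_equal(norm[i, j], log(cts[i, j] / sum(cts[i, ]) + 1))
  # single spot with counts (2, 2): relative levels 0.5 each before log
  one <- normalizeCounts(SpatialCounts(matrix(c(2, 2), 1, 2)))
  expect_equal(unname(one[1, ]), log1p(c(0.5, 0.5)))
})

test_that("all-zero spots are dropped with a warning and recorded mask", {
  cts <- rbind(a = c(3, 1), b = c(0, 0), c = c(2, 5))
  expect_warning(norm <- normalizeCounts(SpatialCounts(cts)), "zero total")
  expect_equal(rownames(norm), c("a", "c"))
  expect_equal(attr(norm, "kept"), c(a = TRUE, b = FALSE, c = TRUE))
})

test_that("highly variable gene selection agrees with brute-force ranking", {
  set.seed(2)
  m <- matrix(rnorm(80), 8, 10)
  m[, 4] <- 1                       # constant gene: zero variance, last
  idx <- selectHVG(m, 10)
  expect_equal(idx, order(apply(m, 2, var), decreasing = TRUE))
  expect_equal(idx[10], 4)
  # full set when nTop = P
  expect_length(selectHVG(m, 10), 10)
  expect_error(selectHVG(m, 11), "11.*10|exceeds")
})

test_that("PCA reduction matches an eigendecomposition oracle up to sign", {
  set.seed(3)
  m <- matrix(rnorm(120), 20, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  mp <- reducePCA(m, pPrime = 3)
  Y <- molecularY(mp)
  # oracle: eigenvectors of the covariance of the centered matrix
  mc <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(cov(mc))
  for (p in 1:3) {
    oracle <- mc %*% ev$vectors[, p]
    expect_equal(abs(as.numeric(cor(Y[, p], oracle))), 1,
                 tolerance = 1e-10)
  }
  # orthogonality of score columns
  ip <- crossprod(Y)
  expect_lt(max(abs(ip[upper.tri(ip)])), 1e-8)
})

test_that("rank-1 data put all variance on PC1 and non-finite input errors", {
  u <- seq_len(15)
  m <- cbind(u, 2 * u, -u) + 0       # exactly rank 1 after centering
  Y <- molecularY(reducePCA(m, pPrime = 2))
  expect_gt(var(Y[, 1]), 0)
  expect_equal(var(Y[, 2]), 0, tolerance = 1e-20)
  m[1, 1] <- NA
  expect_error(reducePCA(m, 2), "non-finite")
})

test_that("reduction pipeline is invariant to gene and spot order", {
  set.seed(4)
  cts <- matrix(rpois(200, 8), 10, 20)
  run <- function(x) {
    norm <- normalizeCounts(SpatialCounts(x))
    molecularY(reducePCA(norm[, selectHVG(norm, 12)], 2))
  }
  Y1 <- run(cts)
  gperm <- sample(20)
  Y2 <- run(cts[, gperm])
  for (p in 1:2)
    expect_equal(abs(as.numeric(cor(Y1[, p], Y2[, p]))), 1,
                 tolerance = 1e-8)
  sperm <- sample(10)
  Y3 <- run(cts[sperm, ])
  for (p in 1:2)
    expect_equal(abs(as.numeric(cor(Y1[sperm, p], Y3[, p]))), 1,
                 tolerance = 1e-8)
})

test_that("square and triangular lattices give 4 and 6 interior neighbors", {
  gsq <- buildAdjacency(squareCoords(3, 3), "square")
  deg <- Matrix::rowSums(adjacencyMatrix(gsq))
  expect_equal(deg[[5]], 4)          # center of the 3x3 block
  gtr <- buildAdjacency(triCoords(5, 5), "triangular")
  degt <- Matrix::rowSums(adjacencyMatrix(gtr))
  expect_equal(degt[[13]], 6)        # interior spot of the offset lattice
  # adjacency is symmetric with zero diagonal
  G <- adjacencyMatrix(gtr)
  expect_true(Matrix::isSymmetric(G))
  expect_true(all(Matrix::diag(G) == 0))
})

test_that("isolated spots get empty rows and duplicates are rejected", {
  g <- buildAdjacency(cbind(c(0, 100), c(0, 0)), "square", threshold = 2)
  expect_equal(unname(Matrix::rowSums(adjacencyMatrix(g))), c(0, 0))
  expect_error(buildAdjacency(cbind(c(1, 1), c(2, 2)), "square"),
               "duplicate")
})

test_that("image profile matches a brute-force nearest-center assignment", {
  geo <- buildAdjacency(squareCoords(4, 4), "square")
  # no cells: all zero
  empty <- buildImageProfile(
    data.frame(cell_id = character(), x = numeric(), y = numeric(),
               cell_type = character()), geo, cellTypes = c("a", "b"))
  expect_true(all(imageV(empty) == 0))
  expect_true(all(cellTotals(empty) == 0))
  # one cell exactly on a spot center
  one <- buildImageProfile(
    data.frame(cell_id = "c1", x = 2, y = 3, cell_type = "a"),
    geo, cellTypes = c("a", "b"))
  expect_equal(sum(imageV(one)), 1)
  expect_equal(imageV(one)[which(spotCoords(geo)[, 1] == 2 &
                                 spotCoords(geo)[, 2] == 3), "a"], 1)
  # 50 random cells vs exhaustive assignment
  set.seed(5)
  cells <- data.frame(cell_id = paste0("c", 1:50),
                      x = runif(50, 0.5, 4.5), y = runif(50, 0.5, 4.5),
                      cell_type = sample(c("a", "b", "c"), 50, TRUE))
  V <- imageV(buildImageProfile(cells, geo))
  oracle <- matrix(0, 16, 3, dimnames = list(geo@spotIds, c("a", "b", "c")))
  for (r in seq_len(50)) {
    d <- (spotCoords(geo)[, 1] - cells$x[r])^2 + (spotCoords(geo)[, 2] - cells$y[r])^2
    oracle[which.min(d), cells$cell_type[r]] <-
      oracle[which.min(d), cells$cell_type[r]] + 1
  }
  expect_equal(unname(V), unname(oracle))
  # conservation
  expect_equal(sum(V), 50)
  expect_equal(unname(rowSums(V)), unname(cellTotals(
    buildImageProfile(cells, geo))))
  # vocabulary enforcement
  expect_error(buildImageProfile(cells, geo, cellTypes = c("a", "b")),
               "c")
})

test_that("grid binning matches brute-force unit assignment", {
  set.seed(6)
  n <- 200
  cells <- data.frame(cell_id = paste0("c", 1:n),
                      x = runif(n, 0, 3), y = runif(n, 0, 3),
                      cell_type = sample(c("t1", "t2"), n, TRUE))
  cts <- matrix(rpois(n * 20, 5), n, 20)
  rownames(cts) <- cells$cell_id
  out <- gridBinSingleCell(SpatialCounts(cts), cells, gridSize = 1,
                           nTop = 20, pPrime = 2)
  # brute-force binning oracle
  ux <- floor((cells$x - min(cells$x)) / 1)
  uy <- floor((cells$y - min(cells$y)) / 1)
  oracle <- table(paste0("u", ux, "_", uy))
  totals <- cellTotals(out$image)
  expect_equal(sort(unname(totals)), sort(unname(c(oracle))))
  expect_equal(sum(totals), n)
  # rook adjacency on the full 3x3 grid: center unit has 4 neighbors
  deg <- Matrix::rowSums(adjacencyMatrix(out$geo))
  expect_equal(unname(deg[match("u1_1", spotIds(out$geo))]), 4)
})

test_that("grid binning handles degenerate layouts deterministically", {
  cells <- data.frame(cell_id = c("a", "b"), x = c(0.1, 0.2),
                      y = c(0.1, 0.2), cell_type = c("t1", "t2"))
  cts <- matrix(rpois(2 * 5, 4) + 1, 2, 5)
  rownames(cts) <- cells$cell_id
  expect_warning(
    out <- gridBinSingleCell(SpatialCounts(cts), cells, gridSize = 10,
                             nTop = 5, pPrime = 1),
    "one unit")
  expect_equal(nrow(molecularY(out$molecular)), 1)
  # a cell exactly on an interior grid line belongs to the upper unit
  cells2 <- data.frame(cell_id = c("a", "b", "c"),
                       x = c(0, 1, 1.5), y = c(0, 0.2, 0.2),
                       cell_type = "t1")
  ux <- floor((cells2$x - min(cells2$x)) / 1)
  expect_equal(ux, c(0, 1, 1))       # the boundary cell is in exactly one unit
})
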