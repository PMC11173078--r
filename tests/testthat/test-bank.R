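test_that("buildBank counts, orders and indexes vectors per position", {
  grids <- lapply(1:3, function(i) randomGrid(4, 4, 6, seed = i))
  bank <- buildBank(grids)
  expect_identical(nrow(bankVectors(bank)), 48L)
  expect_false(isCoreset(bank))
  # every position holds exactly one vector per training grid
  tally <- table(paste(bankPositions(bank)[, 1], bankPositions(bank)[, 2]))
  expect_true(all(tally == 3L))
  # ordering: grid order then row-major; entry 2 of grid 1 is cell (1, 2)
  expect_equal(bankVectors(bank)[2, ], embeddings(grids[[1]])[1, 2, ])
  expect_equal(bankVectors(bank)[16 + 5, ], embeddings(grids[[2]])[2, 1, ])

  one <- buildBank(list(randomGrid(1, 1, 3, seed = 9)))
  expect_identical(nrow(bankVectors(one)), 1L)
  expect_identical(bankPositions(one)[1, ], c(1L, 1L))

  bad <- list(randomGrid(4, 4, 6, 1), randomGrid(4, 4, 5, 2))
  expect_error(buildBank(bad), class = "octanomaly_input_error")
})

test_that("knnAvgDistance matches the exhaustive oracle on random instances", {
  set.seed(100)
  for (i in 1:40) {
    n <- sample(6:80, 1); d <- sample(1:10, 1); k <- sample(1:5, 1)
    k <- min(k, n)
    x <- matrix(rnorm(n * d), n, d)
    q <- rnorm(d)
    expect_equal(knnAvgDistance(q, vectorBank(x), knnConfig(k)),
                 bruteKnnAvg(q, x, k), tolerance = 1e-9)
  }
  # identity and hand-worked cases
  q <- c(1, 2)
  expect_lt(knnAvgDistance(q, vectorBank(matrix(q, 5, 2, byrow = TRUE)),
                           knnConfig(5)), 1e-7)
  b1 <- vectorBank(matrix(c(0, 1, 2, 3, 4, 10), 6, 1))
  expect_equal(knnAvgDistance(0, b1, knnConfig(5)), 2.0)
  expect_error(knnAvgDistance(0, b1, knnConfig(7)),
               class = "octanomaly_config_error")
})

test_that("global and aligned scoring match brute-force oracles", {
  set.seed(200)
  for (i in 1:8) {
    h <- sample(2:4, 1); w <- sample(2:4, 1); d <- sample(2:6, 1)
    g <- sample(6:10, 1)  # training grids; aligned slices of size g
    k <- sample(1:4, 1)
    grids <- lapply(seq_len(g), function(j) randomGrid(h, w, d, seed = 1000 + j))
    bank <- buildBank(grids)
    q <- randomGrid(h, w, d, seed = 77 + i)
    glob <- scoreRegionsGlobal(q, bank, knnConfig(k))
    alig <- scoreRegionsAligned(q, bank, knnConfig(k))
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      v <- embeddings(q)[r, cc, ]
      expect_equal(scores(glob)[r, cc],
                   bruteKnnAvg(v, bankVectors(bank), k), tolerance = 1e-9)
      rows <- bankPositions(bank)[, 1] == r & bankPositions(bank)[, 2] == cc
      expect_equal(scores(alig)[r, cc],
                   bruteKnnAvg(v, bankVectors(bank)[rows, , drop = FALSE], k),
                   tolerance = 1e-9)
    }
    # k smallest over a superset are pointwise <= those over the subset
    expect_true(all(scores(glob) <= scores(alig) + 1e-12))
  }
})

test_that("aligned scoring is exact on replicated grids and checks slices", {
  g0 <- randomGrid(3, 3, 4, seed = 5)
  bank <- buildBank(rep(list(g0), 6))
  out <- scoreRegionsAligned(g0, bank, knnConfig(5))
  expect_equal(max(scores(out)), 0)
  expect_error(scoreRegionsAligned(g0, bank, knnConfig(7)),
               class = "octanomaly_config_error")
})

test_that("greedy coreset keeps the contract and the 2-approximation", {
  # full budget returns the same vector set
  bank <- buildBank(list(randomGrid(4, 4, 3, seed = 1)))
  cs <- greedyCoreset(bank, coresetConfig(fraction = 1, seed = 3))
  expect_true(isCoreset(cs))
  expect_error(greedyCoreset(cs, coresetConfig(1)),
               class = "octanomaly_config_error")
  expect_equal(nrow(bankVectors(cs)), nrow(bankVectors(bank)))
  reorder <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(reorder(bankVectors(cs)), reorder(bankVectors(bank)),
               ignore_attr = TRUE)

  # 1-D {0, 1, 10}, budget 2: optimal min-max radius is 1; greedy attains it
  b3 <- vectorBank(matrix(c(0, 1, 10), 3, 1))
  cs3 <- greedyCoreset(b3, coresetConfig(fraction = 2 / 3, seed = 1))
  expect_equal(coverRadius(bankVectors(b3), match(bankVectors(cs3),
                                                  bankVectors(b3))), 1)

  # covering radius <= 2x brute-force optimum, across seeds and instances
  set.seed(300)
  for (i in 1:25) {
    n <- sample(6:12, 1); d <- sample(1:3, 1)
    budget <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n, d)
    bk <- vectorBank(x)
    opt <- min(apply(utils::combn(n, budget), 2, coverRadius, x = x))
    cs <- greedyCoreset(bk, coresetConfig(fraction = budget / n, seed = i))
    sel <- match(data.frame(t(bankVectors(cs))),
                 data.frame(t(x)))
    expect_lte(coverRadius(x, sel), 2 * opt + 1e-9)
  }
})

test_that("coreset scores dominate full-bank scores and runs are seeded", {
  grids <- lapply(1:5, function(i) randomGrid(5, 5, 8, seed = i))
  bank <- buildBank(grids)
  cs1 <- greedyCoreset(bank, coresetConfig(fraction = 0.2, seed = 11))
  cs2 <- greedyCoreset(bank, coresetConfig(fraction = 0.2, seed = 11))
  cs3 <- greedyCoreset(bank, coresetConfig(fraction = 0.2, seed = 12))
  expect_identical(bankVectors(cs1), bankVectors(cs2))
  expect_false(identical(bankVectors(cs1), bankVectors(cs3)))
  set.seed(42)
  for (i in 1:20) {
    q <- rnorm(8)
    expect_gte(knnAvgDistance(q, cs1, knnConfig(3)),
               knnAvgDistance(q, bank, knnConfig(3)) - 1e-12)
  }
  # positions are preserved for the selected vectors
  key <- function(b) apply(bankVectors(b), 1, paste, collapse = ",")
  expect_identical(bankPositions(cs1),
                   bankPositions(bank)[match(key(cs1), key(bank)), ])
})

test_that("random projection changes only the selection, not the distances", {
  grids <- lapply(1:4, function(i) randomGrid(4, 4, 12, seed = 40 + i))
  bank <- buildBank(grids)
  cs <- greedyCoreset(bank, coresetConfig(fraction = 0.25, seed = 2,
                                          projectionDim = 4))
  expect_identical(ncol(bankVectors(cs)), 12L)  # full dimension retained
  expect_identical(nrow(bankVectors(cs)), 16L)
})
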