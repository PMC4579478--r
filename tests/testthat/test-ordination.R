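test_that("Bray-Curtis reproduces hand-computed toys", {
  x <- toy_table(list(c(2, 0), c(0, 2), c(1, 1), c(2, 2)))
  d <- bray_curtis(x)
  expect_equal(d["S1", "S2"], 1)            # disjoint supports
  expect_equal(d["S3", "S4"], 1 / 3)        # (|1-2|+|1-2|) / 6
  expect_equal(d["S4", "S4"], 0)
  y <- toy_table(list(c(3, 1, 0), c(3, 1, 0)))
  expect_equal(bray_curtis(y)["S1", "S2"], 0)
})

test_that("Bray-Curtis is symmetric, bounded and matches vegan", {
  skip_if_not_installed("vegan")
  set.seed(41)
  x <- random_table(12, 40)
  d <- bray_curtis(x)
  expect_equal(unclass(d), t(unclass(d)))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(unclass(d)) == 0))
  ref <- as.matrix(vegan::vegdist(unclass(x), method = "bray"))
  expect_equal(unclass(d), ref, tolerance = 1e-12, ignore_attr = TRUE)
  ## relative = TRUE equals vegdist on row-normalized data
  dr <- bray_curtis(x, relative = TRUE)
  refr <- as.matrix(vegan::vegdist(unclass(x) / rowSums(unclass(x)),
                                   method = "bray"))
  expect_equal(unclass(dr), refr, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Bray-Curtis rejects undefined all-zero pairs", {
  m <- matrix(c(0, 0, 0, 0, 1, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("o1", "o2")))
  x <- structure(m, class = c("otu_table", "matrix", "array"))
  expect_error(bray_curtis(x), "all-zero")
})

test_that("PCoA closed form for two samples and Euclidean recovery", {
  d <- matrix(c(0, 0.6, 0.6, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  pc <- pcoa(d)
  expect_equal(sort(pc$coordinates[, 1]), c(-0.3, 0.3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pc$eigenvalues[1], 0.6^2 / 2, tolerance = 1e-12)

  ## Euclidean-embeddable distances are reconstructed exactly
  set.seed(42)
  pts <- matrix(stats::rnorm(7 * 3), 7, 3,
                dimnames = list(sprintf("s%d", 1:7), NULL))
  d2 <- as.matrix(stats::dist(pts))
  pc2 <- pcoa(d2)
  rec <- as.matrix(stats::dist(pc2$coordinates))
  expect_equal(rec, d2, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pc2$negative_eigenvalue_mass, 0, tolerance = 1e-8)
  ## eigenvalue sum equals the trace of the centered matrix
  g <- nichecore:::gower_center(d2)
  expect_equal(sum(pc2$eigenvalues), sum(diag(g)), tolerance = 1e-10)
  ## agrees with classical scaling up to axis sign
  ref <- stats::cmdscale(d2, k = 3)
  for (k in 1:3)
    expect_equal(abs(pc2$coordinates[, k]), abs(ref[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCoA handles degenerate and invalid inputs", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  pc <- pcoa(z)
  expect_equal(ncol(pc$coordinates), 0)
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(bad), "not symmetric")
})

test_that("PERMANOVA partitions variance and matches vegan adonis2", {
  skip_if_not_installed("vegan")
  set.seed(43)
  x <- random_table(16, 30)
  md <- two_group_metadata(sample_ids(x),
                           depth = round(stats::runif(16, 5, 40)))
  d <- bray_curtis(x)
  pv <- permanova(d, md, c("niche", "depth"), n_perm = 99, seed = 1)
  expect_equal(sum(pv$table$R2[1:3]), 1, tolerance = 1e-12)
  ref <- vegan::adonis2(stats::as.dist(unclass(d)) ~ niche + depth,
                        data = as.data.frame(md), permutations = 99,
                        by = "terms")
  expect_equal(pv$table["niche", "F"], ref["niche", "F"],
               tolerance = 1e-10)
  expect_equal(pv$table["depth", "F"], ref["depth", "F"],
               tolerance = 1e-10)
  expect_equal(pv$table["niche", "R2"], ref["niche", "R2"],
               tolerance = 1e-10)
  expect_equal(pv$table["Residual", "SumOfSqs"],
               ref["Residual", "SumOfSqs"], tolerance = 1e-10)
})

test_that("PERMANOVA p is exact on a tiny two-group instance", {
  ## two tight groups, far apart: observed F is the maximum over all
  ## permutations, attained only by permutations reproducing the same
  ## partition (8 of 24), so p converges to 1/3
  d <- matrix(c(0, .1, .9, .9,
                .1, 0, .9, .9,
                .9, .9, 0, .1,
                .9, .9, .1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  md <- sample_metadata(letters[1:4], "sp",
                        c("holobiont", "holobiont", "tissue", "tissue"),
                        5, "x")
  pv <- permanova(d, md, "niche", n_perm = 1999, seed = 7)
  expect_lt(abs(pv$table["niche", "Pr(>F)"] - 1 / 3), 0.05)
  ## statistics are invariant under consistent sample relabeling
  perm <- c(3, 1, 4, 2)
  d2 <- d[perm, perm]
  md2 <- md[perm, ]
  pv2 <- permanova(d2, md2, "niche", n_perm = 99, seed = 7)
  expect_equal(pv2$table["niche", "F"], pv$table["niche", "F"],
               tolerance = 1e-12)
  expect_equal(pv2$table["niche", "R2"], pv$table["niche", "R2"],
               tolerance = 1e-12)
})

test_that("PERMANOVA rejects degenerate designs and missing seeds", {
  d <- matrix(c(0, .5, .5, 0), 2, dimnames = list(c("a", "b"),
                                                  c("a", "b")))
  md <- sample_metadata(c("a", "b"), "sp", c("tissue", "tissue"), 5, "x")
  expect_error(permanova(d, md, "niche", n_perm = 99, seed = 1),
               "single level")
  expect_error(permanova(d, md, "niche", n_perm = 99), "seed")
  expect_error(permanova(d, md, "niche", n_perm = 10, seed = 1),
               "at least 99")
})

test_that("ANOSIM hits its closed-form extremes", {
  ## perfect separation: all within < all between
  d <- matrix(c(0, .1, .8, .9,
                .1, 0, .85, .95,
                .8, .85, 0, .15,
                .9, .95, .15, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  g <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  an <- anosim(d, g, n_perm = 99, seed = 2)
  expect_equal(an$R, 1)
  ## all distances equal: grouping is irrelevant, R = 0
  deq <- matrix(0.5, 4, 4, dimnames = dimnames(d)); diag(deq) <- 0
  expect_equal(anosim(deq, g, n_perm = 99, seed = 2)$R, 0)
  expect_error(anosim(d, c(a = "g1", b = "g1", c = "g1", d = "g2"),
                      n_perm = 99, seed = 2), "at least two samples")
})

test_that("ANOSIM matches vegan on random instances", {
  skip_if_not_installed("vegan")
  set.seed(44)
  for (rep in 1:3) {
    x <- random_table(8, 25)
    g <- rep(c("g1", "g2"), each = 4)
    d <- bray_curtis(x)
    mine <- anosim(d, stats::setNames(g, sample_ids(x)), n_perm = 99,
                   seed = 3)
    ref <- vegan::anosim(stats::as.dist(unclass(d)), grouping = g,
                         permutations = 0)
    expect_equal(mine$R, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("permutation tests are exactly reproducible given a seed", {
  set.seed(45)
  x <- random_table(10, 20)
  md <- two_group_metadata(sample_ids(x))
  d <- bray_curtis(x)
  p1 <- permanova(d, md, "niche", n_perm = 99, seed = 9)
  p2 <- permanova(d, md, "niche", n_perm = 99, seed = 9)
  expect_identical(p1$table, p2$table)
  a1 <- anosim(d, stats::setNames(as.character(md$niche), md$sample_id),
               n_perm = 99, seed = 9)
  a2 <- anosim(d, stats::setNames(as.character(md$niche), md$sample_id),
               n_perm = 99, seed = 9)
  expect_identical(a1$p, a2$p)
})
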