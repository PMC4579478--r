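test_that("prevalence is the exact occupancy fraction", {
  x <- toy_table(list(c(1, 0), c(2, 0), c(5, 0), c(0, 0), c(1, 0),
                      c(0, 0), c(0, 0), c(0, 0), c(0, 0), c(0, 0)))
  p <- prevalence(x)
  expect_equal(unname(p), c(0.4, 0))
  expect_error(prevalence(x, character(0)), "empty|not in table")
  expect_error(prevalence(x, "nope"), "not in table")
})

test_that("prevalence matches a brute-force per-column loop", {
  set.seed(21)
  x <- random_table(40, 300)
  p <- prevalence(x)
  m <- unclass(x)
  oracle <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    k <- 0L
    for (i in seq_len(nrow(m))) if (m[i, j] > 0) k <- k + 1L
    oracle[j] <- k / nrow(m)
  }
  expect_equal(unname(p), oracle)
})

test_that("core membership uses exact integer boundary arithmetic", {
  k <- c(a = 5L, b = 4L, c = 0L, d = 16L)
  cs30 <- core_at_threshold(k, 30, n_samples = 16)
  expect_true("a" %in% cs30$members)    # 500 >= 480
  expect_false("b" %in% cs30$members)   # 400 <  480
  expect_false("c" %in% cs30$members)   # never observed
  cs0 <- core_at_threshold(k, 0, n_samples = 16)
  expect_setequal(cs0$members, c("a", "b", "d"))   # all observed OTUs
  cs100 <- core_at_threshold(k, 100, n_samples = 16)
  expect_equal(cs100$members, "d")      # only ubiquitous OTUs
  expect_error(core_at_threshold(k, 101, n_samples = 16), "\\[0, 100\\]")
})

test_that("prevalence sweep enumerates the curve on the 2% grid", {
  ## 5 OTUs at prevalences 100, 100, 60, 40, 20 % over n = 10
  rows <- lapply(1:10, function(i)
    c(1, 1, as.integer(i <= 6), as.integer(i <= 4), as.integer(i <= 2)))
  x <- toy_table(rows)
  cv <- prevalence_sweep(x)
  sz <- function(t) unname(cv$core_size[as.character(t)])
  expect_true(all(vapply(seq(0, 20, 2), sz, 0L) == 5))
  expect_true(all(vapply(seq(22, 40, 2), sz, 0L) == 4))
  expect_true(all(vapply(seq(42, 60, 2), sz, 0L) == 3))
  expect_true(all(vapply(seq(62, 100, 2), sz, 0L) == 2))

  one <- toy_table(lapply(1:10, function(i) 1), otu_prefix = "only")
  expect_true(all(prevalence_sweep(one)$core_size == 1))
})

test_that("sweep curves are non-increasing and anchored at observed OTUs", {
  set.seed(22)
  for (rep in 1:30) {
    x <- random_table(sample(5:25, 1), sample(20:80, 1))
    cv <- prevalence_sweep(x)
    expect_true(all(diff(cv$core_size) <= 0))
    expect_equal(unname(cv$core_size[1]), sum(colSums(unclass(x) > 0) > 0))
  }
})

test_that("threshold monotonicity: lower thresholds give supersets", {
  set.seed(23)
  x <- random_table(20, 100)
  thresholds <- c(10, 30, 50, 75, 90)
  cores <- lapply(thresholds, function(t) core_at_threshold(x, t)$members)
  for (i in seq_len(length(cores) - 1))
    expect_true(all(cores[[i + 1]] %in% cores[[i]]))
})

test_that("stabilization finds the first zero-change step after a drop", {
  ## sizes for prevalences (100,100,60,40,20)%: flat 5 to t=20, drops at
  ## 22 and 42 and 62; first zero-change step after the first drop is 24
  sizes <- c(rep(5, 11), rep(4, 10), rep(3, 10), rep(2, 20))
  expect_equal(stabilization_threshold(fake_curve(sizes)), 24)

  ## joint rule: both curves must have stabilized at the same grid point
  a <- c(rep(9, 11), rep(4, 40))            # drops at 22, zero from 24
  b <- c(rep(9, 14), rep(5, 37))            # drops at 28, zero from 30
  expect_equal(stabilization_threshold(list(fake_curve(a),
                                            fake_curve(b))), 30)

  strictly <- seq(102, 2, by = -2)
  expect_warning(t0 <- stabilization_threshold(fake_curve(strictly)),
                 "no stabilization")
  expect_true(is.na(t0))

  flat <- rep(7, 51)                         # never changes at all
  expect_warning(tf <- stabilization_threshold(fake_curve(flat)),
                 "no stabilization")
  expect_true(is.na(tf))

  short <- structure(list(scope = NULL, thresholds = seq(0L, 100L, 4L),
                          core_size = rep(1L, 26), n_samples = 10L),
                     class = "prevalence_curve")
  expect_error(stabilization_threshold(list(fake_curve(sizes), short)),
               "mismatched")
})

test_that("stabilization equals an exhaustive grid scan on random curves", {
  set.seed(24)
  oracle <- function(sizes) {
    d <- diff(sizes)
    for (i in seq_along(d))
      if (d[i] == 0 && any(d[seq_len(i)] != 0)) return(seq(0, 100, 2)[i + 1])
    NA_integer_
  }
  for (rep in 1:200) {
    sizes <- rev(cumsum(c(sample(0:3, 50, TRUE, prob = c(.6, .2, .1, .1)),
                          5)))
    expected <- oracle(sizes)
    got <- if (is.na(expected))
      suppressWarnings(stabilization_threshold(fake_curve(sizes)))
    else stabilization_threshold(fake_curve(sizes))
    expect_equal(got, expected)
  }
})

test_that("combined cores union members with niche provenance", {
  cores <- list(n1 = fake_core(c("A", "B")), n2 = fake_core(c("B", "C")),
                n3 = fake_core(c("C", "D")))
  cc <- combine_cores(cores)
  expect_setequal(cc$members, c("A", "B", "C", "D"))
  expect_equal(cc$provenance[["B"]], c("n1", "n2"))
  expect_equal(unname(cc$n_unique), c(1L, 0L, 1L))

  same <- combine_cores(list(a = fake_core(c("X", "Y")),
                             b = fake_core(c("X", "Y"))))
  expect_setequal(same$members, c("X", "Y"))

  expect_error(combine_cores(list(fake_core("A", 30), fake_core("B", 50))),
               "mixed thresholds")
})

test_that("inclusion-exclusion matches direct union on random sets", {
  set.seed(25)
  for (rep in 1:50) {
    sets <- lapply(1:3, function(i)
      sample(sprintf("o%02d", 1:30), sample(0:20, 1)))
    v <- venn_summary(sets[[1]], sets[[2]], sets[[3]])
    expect_equal(sum(v$regions), length(unique(unlist(sets))))
    ## each set total is the sum of its four regions
    expect_equal(unname(v$totals[1]),
                 sum(v$regions[c("100", "110", "101", "111")]))
    expect_equal(unname(v$totals[2]),
                 sum(v$regions[c("010", "110", "011", "111")]))
    expect_equal(unname(v$totals[3]),
                 sum(v$regions[c("001", "101", "011", "111")]))
    cc <- combine_cores(lapply(sets[lengths(sets) > 0], fake_core))
    expect_equal(length(cc$members), length(unique(unlist(sets))))
  }
})

test_that("venn regions enumerate correctly and ignore input order", {
  v <- venn_summary(c("1", "2", "3"), c("2", "3", "4"), c("3", "4", "5"))
  expect_equal(unname(v$regions[c("111", "100", "010", "001")]),
               c(1L, 1L, 0L, 1L))
  expect_equal(unname(v$regions[c("110", "011", "101")]), c(1L, 1L, 0L))

  d <- venn_summary(c("a", "b"), c("x"), character(0))
  expect_equal(unname(d$regions[c("110", "101", "011", "111")]),
               rep(0L, 4))

  ## order invariance: regions permute with the sets
  v2 <- venn_summary(c("3", "4", "5"), c("1", "2", "3"), c("2", "3", "4"))
  expect_equal(v2$regions[["111"]], v$regions[["111"]])
  expect_equal(v2$regions[["100"]], v$regions[["001"]])
  expect_equal(v2$regions[["010"]], v$regions[["100"]])
})

test_that("universal core intersects taxon labels, never OTU ids", {
  tax <- taxonomy_map(
    c("s1o1", "s1o2", "s2o1", "s2o2", "s3o1", "s3o2", "s3o3"),
    c("k__B; p__; c__; o__; f__; g__Ralstonia",
      "k__B; p__; c__; o__; f__; g__X",
      "k__B; p__; c__; o__; f__; g__Ralstonia",
      "k__B; p__; c__; o__; f__; g__Y",
      "k__B; p__; c__; o__; f__; g__Ralstonia",
      "k__B; p__; c__; o__; f__; g__Z",
      "k__B; p__; c__; o__; f__; g__"))
  cores <- list(c("s1o1", "s1o2"), c("s2o1", "s2o2"),
                c("s3o1", "s3o2", "s3o3"))
  expect_equal(universal_core(cores, tax), "Ralstonia")
  ## unclassified labels never match; empty core gives empty intersection
  expect_equal(universal_core(list(c("s1o1"), character(0)), tax),
               character(0))
  expect_warning(u <- universal_core(list(c("s1o1", "ghost"), c("s2o1")),
                                     tax),
                 "no taxonomy")
  expect_equal(u, "Ralstonia")
})

test_that("rare-core summary bands members by whole-community abundance", {
  ## 3 members with mean relabs 0.001, 0.02, 0.2 across 2 samples
  x <- toy_table(list(c(1, 20, 200, 779), c(1, 20, 200, 779)))
  bands <- rare_core_summary(c("OTU1", "OTU2", "OTU3"), x)
  expect_equal(unname(bands), c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(names(bands), c("<1%", "1%-5%", ">5%"))
  expect_equal(sum(bands), 3L)

  expect_warning(b2 <- rare_core_summary(c("OTU1", "missing"), x),
                 "absent")
  expect_equal(unname(b2), c(2L, 0L, 0L), ignore_attr = TRUE)
  expect_error(rare_core_summary("OTU1", x, cutoffs = c(0.05, 0.01)),
               "ascending")
})

test_that("core_microbiome fits an end-to-end species summary", {
  sim <- generate_community(small_spec(26))
  fit <- core_microbiome(sim$otu_table, sim$metadata)
  expect_s3_class(fit, "core_microbiome")
  expect_equal(sort(fit$niches),
               sort(c("holobiont", "tissue", "endosymbiotic")))
  ## combined core is exactly the union of the per-niche cores
  expect_setequal(fit$combined$members,
                  unique(unlist(lapply(fit$cores, `[[`, "members"))))
  ## venn totals agree with per-niche core sizes
  expect_equal(unname(fit$venn$totals),
               unname(vapply(fit$cores[fit$venn$set_names],
                             function(cs) length(cs$members), 1L)))
  ## an explicit threshold overrides the stabilization rule
  fit50 <- core_microbiome(sim$otu_table, sim$metadata, threshold = 50)
  expect_equal(fit50$threshold, 50L)
  expect_true(all(fit50$combined$members %in% fit$combined$members) ||
                fit$threshold >= 50)
  expect_output(print(fit), "Core microbiome")
  expect_output(print(summary(fit)), "annotation level")
})
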