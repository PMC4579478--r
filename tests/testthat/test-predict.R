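ref_toy <- function() {
  ssu <- c(A = 2, B = 4, C = 1)
  gc <- matrix(c(3, 0, 0,
                 1, 2, 0,
                 0, 8, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("f1", "f2", "f3")))
  gene_copy_table(ssu, gc, list(f1 = "P", f2 = c("P", "Q")))
}

test_that("metagenome prediction is the copy-number-normalized product", {
  x <- toy_table(list(c(4, 0, 0)), otu_prefix = "")
  colnames(x) <- c("A", "B", "C")
  fp <- predict_metagenome(otu_table(unclass(x)), ref_toy())
  ## count 4 / ssu 2 * copy 3 = 6; zero-copy families contribute 0
  expect_equal(unname(fp$counts[1, ]), c(6, 0, 0))
})

test_that("prediction is linear, non-negative and order-invariant", {
  set.seed(61)
  m <- matrix(stats::rpois(60, 8), nrow = 5,
              dimnames = list(sprintf("s%d", 1:5), sprintf("o%02d", 1:12)))
  ssu <- stats::setNames(sample(1:10, 12, TRUE), colnames(m))
  gc <- matrix(stats::rpois(12 * 4, 1), nrow = 12,
               dimnames = list(colnames(m), sprintf("f%d", 1:4)))
  ref <- gene_copy_table(ssu, gc)
  fp <- predict_metagenome(otu_table(m), ref)
  expect_true(all(fp$counts >= 0))
  fp2 <- predict_metagenome(otu_table(m * 2), ref)
  expect_equal(fp2$counts, fp$counts * 2, tolerance = 1e-12)
  ## doubling the reference copies also doubles the profile
  ref2 <- gene_copy_table(ssu, gc * 2)
  expect_equal(predict_metagenome(otu_table(m), ref2)$counts,
               fp$counts * 2, tolerance = 1e-12)
  ## permuting OTU columns changes nothing
  perm <- sample(ncol(m))
  expect_equal(predict_metagenome(otu_table(m[, perm]), ref)$counts,
               fp$counts, tolerance = 1e-12)
  ## an all-zero copy family predicts exactly zero
  gc0 <- gc; gc0[, "f3"] <- 0
  expect_true(all(predict_metagenome(otu_table(m),
                                     gene_copy_table(ssu, gc0))$counts[, "f3"] == 0))
})

test_that("uncovered OTUs are excluded and their read fraction reported", {
  m <- matrix(c(6, 4, 2, 8), nrow = 2,
              dimnames = list(c("s1", "s2"), c("A", "ghost")))
  fp <- predict_metagenome(otu_table(m), ref_toy())
  expect_equal(fp$uncovered_otus, "ghost")
  ## ghost reads: 2 of 8 in s1, 8 of 12 in s2
  expect_equal(unname(fp$excluded_fraction), c(2 / 8, 8 / 12))
  ## only the covered OTU contributes: 6/2*3 and 4/2*3
  expect_equal(unname(fp$counts[, "f1"]), c(9, 6))
})

test_that("pathway aggregation follows the many-to-many convention", {
  x <- otu_table(matrix(c(4, 8, 1), nrow = 1,
                        dimnames = list("s1", c("A", "B", "C"))))
  fp <- predict_metagenome(x, ref_toy())
  pp <- aggregate_pathways(fp, ref_toy()$pathway_map)
  ## f1 -> P; f2 -> P and Q; f3 unmapped
  expect_equal(unname(pp$counts[1, "P"]),
               unname(fp$counts[1, "f1"] + fp$counts[1, "f2"]))
  expect_equal(unname(pp$counts[1, "Q"]), unname(fp$counts[1, "f2"]))
  expect_equal(unname(pp$counts[1, "UNMAPPED"]),
               unname(fp$counts[1, "f3"]))
  ## conservation: pathway total = sum of family counts x multiplicity
  mult <- c(f1 = 1, f2 = 2, f3 = 1)
  expect_equal(sum(pp$counts), sum(fp$counts[1, ] * mult),
               tolerance = 1e-12)
})

test_that("taxon contribution shares partition the family total", {
  tax <- taxonomy_map(c("A", "B", "C"),
                      c("k__K; p__; c__; o__; f__; g__Gx",
                        "k__K; p__; c__; o__; f__; g__Gy",
                        "k__K; p__; c__; o__; f__; g__Gy"))
  x <- otu_table(matrix(c(4, 8, 3), nrow = 1,
                        dimnames = list("s1", c("A", "B", "C"))))
  sh <- taxon_contribution(x, ref_toy(), tax, "f1")
  ## f1 contributions: A (Gx): 4/2*3 = 6 ; B (Gy): 8/4*1 = 2 -> 0.75/0.25
  expect_equal(unname(sh[c("Gx", "Gy")]), c(0.75, 0.25))
  sh2 <- taxon_contribution(x, ref_toy(), tax, c("f1", "f2"))
  ## f1+f2: A: 4/2*3 = 6 ; B: 8/4*3 = 6 ; C: 3/1*8 = 24
  expect_equal(unname(sh2[c("Gx", "Gy")]), c(6, 30) / 36)
  expect_equal(sum(sh2), 1, tolerance = 1e-12)
  expect_warning(s0 <- taxon_contribution(x, ref_toy(), tax, "f3"),
                 "zero")
  expect_length(s0, 0)
  expect_error(taxon_contribution(x, ref_toy(), tax, character(0)),
               "empty")
  expect_error(taxon_contribution(x, ref_toy(), tax, "nope"),
               "unknown gene family")
})

test_that("pathway group tests match a closed-form two-group ANOVA", {
  set.seed(62)
  counts <- rbind(matrix(stats::rpois(20, 50), 4),
                  matrix(stats::rpois(20, 50), 4))
  counts[5:8, 1] <- counts[5:8, 1] + 120     # enrich pathway 1 in group 2
  rownames(counts) <- sprintf("S%d", 1:8)
  colnames(counts) <- sprintf("pw%d", 1:5)
  pp <- structure(list(counts = counts), class = "pathway_profile")
  md <- two_group_metadata(rownames(counts))
  res <- pathway_group_test(pp, md)
  expect_equal(res$pathway[1], "pw1")        # planted enrichment ranks first
  rel <- counts / rowSums(counts)
  for (pw in colnames(counts)) {
    y <- rel[, pw]
    m1 <- mean(y[1:4]); m2 <- mean(y[5:8]); mg <- mean(y)
    ssb <- 4 * ((m1 - mg)^2 + (m2 - mg)^2)
    ssw <- sum((y[1:4] - m1)^2) + sum((y[5:8] - m2)^2)
    f_hand <- ssb / (ssw / 6)
    expect_equal(res$F[res$pathway == pw], f_hand, tolerance = 1e-8)
  }
  ## identical profiles: all F exactly 0
  same <- matrix(rep(c(10, 20, 30), each = 6), nrow = 6,
                 dimnames = list(sprintf("S%d", 1:6), sprintf("pw%d", 1:3)))
  pp0 <- structure(list(counts = same), class = "pathway_profile")
  md0 <- two_group_metadata(rownames(same))
  expect_true(all(pathway_group_test(pp0, md0)$F == 0))
  expect_error(pathway_group_test(pp0, sample_metadata(
    rownames(same), "sp", rep("tissue", 6), 5, "x")), "single level")
})

test_that("simulated transporter enrichment is detected in pathway tests", {
  spec <- small_spec(63, samples_per_niche = 10)
  sim <- generate_community(spec)
  ref <- generate_gene_reference(spec)
  fp <- predict_metagenome(sim$otu_table, ref)
  pp <- aggregate_pathways(fp, ref$pathway_map)
  res <- pathway_group_test(pp, sim$metadata)
  ## the transporter-carrying pathways are the top-ranked by F
  expect_true(all(c("Transporters", "Membrane_transport") %in%
                    res$pathway[1:3]))
  expect_lt(res$q[res$pathway == "Transporters"], 0.01)
})
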