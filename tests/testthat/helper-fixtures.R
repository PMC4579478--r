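## Shared fixture builders: everything is generated in code at test time.

## small table from a samples x OTUs matrix given as rows
toy_table <- function(rows, sample_prefix = "S", otu_prefix = "OTU") {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0(sample_prefix, seq_len(nrow(m))),
                      paste0(otu_prefix, seq_len(ncol(m))))
  otu_table(m)
}

random_table <- function(n_samples, n_otus, max_count = 20,
                         zero_prob = 0.5) {
  m <- matrix(stats::rbinom(n_samples * n_otus, max_count,
                            0.3) * (stats::runif(n_samples * n_otus) >
                                      zero_prob),
              nrow = n_samples,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              sprintf("OTU%04d", seq_len(n_otus))))
  ## no all-zero samples: give each sample one guaranteed count
  m[cbind(seq_len(n_samples),
          sample.int(n_otus, n_samples, replace = TRUE))] <- 1
  otu_table(m)
}

## a presence-count core_set without going through a table
fake_core <- function(members, threshold = 30L, scope = NULL) {
  structure(list(scope = scope, threshold = as.integer(threshold),
                 members = members,
                 prevalence = stats::setNames(rep(1, length(members)),
                                              members),
                 n_samples = 10L),
            class = "core_set")
}

## a prevalence_curve directly from a vector of core sizes on the 2% grid
fake_curve <- function(core_size, scope = NULL) {
  thresholds <- seq(0L, 100L, by = 2L)
  stopifnot(length(core_size) == length(thresholds))
  structure(list(scope = scope, thresholds = thresholds,
                 core_size = stats::setNames(as.integer(core_size),
                                             thresholds),
                 n_samples = 10L),
            class = "prevalence_curve")
}

## two-group metadata for n samples (first half "holobiont", rest "tissue")
two_group_metadata <- function(ids, depth = NULL) {
  n <- length(ids)
  sample_metadata(ids,
                  species = "sp",
                  niche = rep(c("holobiont", "tissue"), each = ceiling(n / 2))[seq_len(n)],
                  depth = if (is.null(depth)) rep(10, n) else depth,
                  site = "site1")
}

## small single-species spec for fast simulator-backed tests
small_spec <- function(seed, niches = c("holobiont", "tissue",
                                        "endosymbiotic"),
                       samples_per_niche = 8, n_otus = 250, n_core = 25,
                       ...) {
  synthetic_spec(species = "coral",
                 niches = list(coral = niches),
                 depth_range = list(coral = c(5, 40)),
                 samples_per_niche = samples_per_niche, n_otus = n_otus,
                 n_core = n_core, seed = seed, ...)
}
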