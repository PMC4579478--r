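## Synthetic multi-species, multi-niche communities with planted structure.
##
## The default specification emulates a three-species mesophotic coral study:
## one deeper-water species sampled as holobiont / tissue / endosymbiotic
## preparations and two species sampled as holobiont / tissue / skeletal,
## ~1500 OTUs per species dominated by a rare log-normal tail, a planted core
## per (species, niche), and two universal intracellular symbiont phylotypes
## (shared genus labels across species) at high relative abundance in the
## endosymbiotic niche but rare in the whole community.

default_symbionts <- function() {
  list(
    list(genus = "Propionibacterium",
         lineage = paste("k__Bacteria; p__Actinobacteria; c__Actinobacteria;",
                         "o__Actinomycetales; f__Propionibacteriaceae;",
                         "g__Propionibacterium; s__"),
         niche_mean_relab = c(holobiont = 0.003, tissue = 0.10,
                              endosymbiotic = 0.42, skeletal = 0.01)),
    list(genus = "Ralstonia",
         lineage = paste("k__Bacteria; p__Proteobacteria;",
                         "c__Betaproteobacteria; o__Burkholderiales;",
                         "f__Ralstoniaceae; g__Ralstonia; s__"),
         niche_mean_relab = c(holobiont = 0.04, tissue = 0.08,
                              endosymbiotic = 0.22, skeletal = 0.02))
  )
}

#' Specification of a synthetic multi-species community
#'
#' Collects every tunable of the simulator with defaults that encode the
#' emulated study design: three coral species, three niches each, ~1500 OTUs
#' per species, a planted core per niche, and two universal symbionts whose
#' endosymbiotic-niche mean relative abundances are 0.42 and 0.22 against
#' whole-community (holobiont) means of 0.003 and 0.04.
#'
#' @param species character vector of species labels
#' @param niches named list: species -> character vector of niches (from
#'   `"holobiont"`, `"tissue"`, `"endosymbiotic"`, `"skeletal"`)
#' @param samples_per_niche samples drawn per (species, niche)
#' @param n_otus background OTUs per species (planted symbionts are added on
#'   top of these)
#' @param n_core planted core OTUs per (species, niche)
#' @param core_prevalence presence probability of a planted core OTU within
#'   its niche; must exceed `noise_prevalence_max`
#' @param noise_prevalence_max background per-OTU presence probabilities are
#'   drawn uniformly from (0, `noise_prevalence_max`]
#' @param planted_symbionts list of symbiont descriptors (`genus`, `lineage`,
#'   `niche_mean_relab`); see `nichecore:::default_symbionts()`
#' @param lognormal_sigma sigma of the log-normal base-abundance weights that
#'   generate the rare-biosphere tail
#' @param library_size reads per sample (multinomial total)
#' @param depth_range named list: species -> c(min, max) collection depth (m)
#' @param n_gene_families number of gene families (besides the transporter
#'   family) in the synthetic copy-number reference
#' @param transporter_share_target expected fraction of transporter-family
#'   predicted counts contributed by the planted symbionts in the
#'   endosymbiotic niche (used to calibrate their copy numbers)
#' @param seed integer seed; every draw of the generator derives from it
#' @return a validated `synthetic_spec` object
#' @export
synthetic_spec <- function(species = c("A_granulosa", "Leptoseris_sp",
                                       "M_capitata"),
                           niches = NULL,
                           samples_per_niche = 11L,
                           n_otus = 1500L,
                           n_core = 70L,
                           core_prevalence = 0.9,
                           noise_prevalence_max = 0.2,
                           planted_symbionts = default_symbionts(),
                           lognormal_sigma = 2.0,
                           library_size = 10000L,
                           depth_range = NULL,
                           n_gene_families = 19L,
                           transporter_share_target = 0.70,
                           seed = 1L) {
  if (is.null(niches)) {
    niches <- list(c("holobiont", "tissue", "endosymbiotic"),
                   c("holobiont", "tissue", "skeletal"),
                   c("holobiont", "tissue", "skeletal"))[seq_along(species)]
    names(niches) <- species
  }
  if (is.null(depth_range)) {
    depth_range <- list(c(5, 40), c(65, 125), c(56, 56))[seq_along(species)]
    names(depth_range) <- species
  }
  stopifnot(length(species) >= 1, !anyDuplicated(species),
            identical(sort(names(niches)), sort(species)),
            identical(sort(names(depth_range)), sort(species)))
  if (!all(unlist(niches) %in% NICHE_LEVELS))
    stop("niches must be drawn from: ", paste(NICHE_LEVELS, collapse = ", "),
         call. = FALSE)
  if (samples_per_niche < 1L) stop("samples_per_niche must be >= 1",
                                   call. = FALSE)
  if (library_size < 1L) stop("library_size must be a positive integer",
                              call. = FALSE)
  if (n_core > n_otus) stop("n_core cannot exceed n_otus", call. = FALSE)
  if (!(core_prevalence > 0 && core_prevalence <= 1))
    stop("core_prevalence must be in (0, 1]", call. = FALSE)
  if (!(noise_prevalence_max > 0 && noise_prevalence_max < core_prevalence))
    stop("need 0 < noise_prevalence_max < core_prevalence", call. = FALSE)
  if (lognormal_sigma <= 0) stop("lognormal_sigma must be positive",
                                 call. = FALSE)
  for (nv in NICHE_LEVELS) {
    tot <- sum(vapply(planted_symbionts,
                      function(s) unname(s$niche_mean_relab[nv] %||% 0),
                      0), na.rm = TRUE)
    if (tot >= 1)
      stop("planted symbiont mean relative abundances sum to >= 1 in niche ",
           nv, call. = FALSE)
  }
  if (seed != round(seed) || seed < 0 || seed > 2^20)
    stop("seed must be a non-negative integer <= 2^20", call. = FALSE)
  structure(list(species = species, niches = niches,
                 samples_per_niche = as.integer(samples_per_niche),
                 n_otus = as.integer(n_otus), n_core = as.integer(n_core),
                 core_prevalence = core_prevalence,
                 noise_prevalence_max = noise_prevalence_max,
                 planted_symbionts = planted_symbionts,
                 lognormal_sigma = lognormal_sigma,
                 library_size = as.integer(library_size),
                 depth_range = depth_range,
                 n_gene_families = as.integer(n_gene_families),
                 transporter_share_target = transporter_share_target,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## all draws derive deterministically from the spec seed
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919 + 1) %% 2147483647)
}

## Structural parameters of the community (OTU ids, core assignments,
## presence probabilities, base weights, taxonomy) -- deterministic in
## spec$seed and shared by generate_community() and
## generate_gene_reference().
community_params <- function(spec) {
  set.seed(derive_seed(spec$seed, 1L))
  phyla <- c("Proteobacteria", "Actinobacteria", "Bacteroidetes",
             "Firmicutes", "Cyanobacteria", "Planctomycetes")
  out <- list()
  for (si in seq_along(spec$species)) {
    sp <- spec$species[si]
    abbr <- sprintf("Sp%d", si)
    niches <- spec$niches[[sp]]
    n_bg <- spec$n_otus
    bg_ids <- sprintf("%s_OTU%04d", abbr, seq_len(n_bg))
    sym_ids <- sprintf("%s_SYM%d", abbr,
                       seq_along(spec$planted_symbionts))
    otu_ids <- c(bg_ids, sym_ids)

    ## planted core: a block shared by all niches plus per-niche draws
    n_shared <- max(1L, round(0.2 * spec$n_core))
    shared <- sample(n_bg, n_shared)
    core_idx <- lapply(niches, function(nv) {
      extra <- sample(setdiff(seq_len(n_bg), shared),
                      spec$n_core - n_shared)
      sort(c(shared, extra))
    })
    names(core_idx) <- niches

    p_bg <- stats::runif(n_bg, 0, spec$noise_prevalence_max)
    p_bg[p_bg == 0] <- spec$noise_prevalence_max / 2   # open interval
    w <- stats::rlnorm(n_bg, 0, spec$lognormal_sigma)

    ## presence probability per (OTU, niche); symbionts always present
    P <- matrix(rep(p_bg, length(niches)), ncol = length(niches),
                dimnames = list(bg_ids, niches))
    for (nv in niches) P[core_idx[[nv]], nv] <- spec$core_prevalence
    sym_relab <- vapply(spec$planted_symbionts, function(s)
      vapply(niches, function(nv) unname(s$niche_mean_relab[nv] %||% 0), 0),
      numeric(length(niches)))
    sym_relab <- matrix(sym_relab, nrow = length(niches),
                        dimnames = list(niches, sym_ids))

    ## background taxonomy: species-private genus labels so that only the
    ## planted symbiont genera can match across species
    n_groups <- 25L
    grp <- sample(n_groups, n_bg, replace = TRUE)
    genus <- sprintf("%s_genus%02d", abbr, grp)
    genus[stats::runif(n_bg) < 0.2] <- "unclassified"
    fam <- sprintf("%s_family%02d", abbr, ((grp - 1L) %/% 2L) + 1L)
    phy <- phyla[(grp %% length(phyla)) + 1L]
    lineage <- paste0("k__Bacteria; p__", phy, "; c__", phy, "_class; o__",
                      phy, "_order; f__", fam, "; g__",
                      ifelse(genus == "unclassified", "", genus), "; s__")
    sym_lineage <- vapply(spec$planted_symbionts, `[[`, "", "lineage")
    tax <- taxonomy_map(otu_ids, c(lineage, sym_lineage))

    ## expected background relative abundance per niche (first-order):
    ## E[relab_j] ~ (1 - S_niche) * w_j p_j / sum_k w_k p_k
    exp_relab <- matrix(0, nrow = length(otu_ids), ncol = length(niches),
                        dimnames = list(otu_ids, niches))
    for (nv in niches) {
      S <- sum(sym_relab[nv, ])
      load <- w * P[, nv]
      exp_relab[bg_ids, nv] <- (1 - S) * load / sum(load)
      exp_relab[sym_ids, nv] <- sym_relab[nv, ]
    }

    out[[sp]] <- list(abbr = abbr, niches = niches, otu_ids = otu_ids,
                      bg_ids = bg_ids, sym_ids = sym_ids,
                      core_idx = core_idx, p_bg = p_bg, w = w,
                      presence_prob = P, sym_relab = sym_relab,
                      taxonomy = tax, exp_relab = exp_relab)
  }
  out
}

#' Generate a synthetic multi-species community
#'
#' Draws, for every sample of every (species, niche): OTU presence
#' indicators (planted core OTUs with probability `core_prevalence` in their
#' niche, background OTUs with their per-OTU probability, planted symbionts
#' always), relative abundances (symbionts at their declared niche means, the
#' remaining mass split over present background OTUs in proportion to their
#' log-normal base weights) and multinomial counts at `library_size`.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [synthetic_spec()]
#' @return a list with elements `otu_table` (an [otu_table()]; per-sample
#'   counts sum to `library_size` exactly), `taxonomy` ([taxonomy_map()]),
#'   `metadata` ([sample_metadata()]) and `ground_truth` (planted core ids
#'   per (species, niche), symbiont ids, per-OTU presence probabilities and
#'   expected niche mean relative abundances).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- community_params(spec)
  set.seed(derive_seed(spec$seed, 2L))
  sites <- sprintf("site%d", 1:5)

  counts_blocks <- list()
  meta_rows <- list()
  for (sp in spec$species) {
    pp <- params[[sp]]
    n_all <- length(pp$otu_ids)
    n_bg <- length(pp$bg_ids)
    for (nv in pp$niches) {
      for (k in seq_len(spec$samples_per_niche)) {
        sid <- sprintf("%s_%s_%02d", pp$abbr, substr(nv, 1, 4), k)
        present_bg <- stats::runif(n_bg) < pp$presence_prob[, nv]
        if (!any(present_bg)) present_bg[which.max(pp$w)] <- TRUE
        sym_means <- pp$sym_relab[nv, ]
        rel <- numeric(n_all)
        S <- sum(sym_means)
        wsum <- sum(pp$w[present_bg])
        rel[seq_len(n_bg)][present_bg] <-
          (1 - S) * pp$w[present_bg] / wsum
        rel[n_bg + seq_along(sym_means)] <- sym_means
        rel <- rel / sum(rel)
        ## every present OTU gets one guaranteed detection read; the rest
        ## of the library is multinomial with mean-preserving adjusted
        ## probabilities (so presence == observation, by construction)
        present <- which(rel > 0)
        L <- spec$library_size
        if (L < length(present))
          stop("library_size (", L, ") smaller than the number of ",
               "present OTUs (", length(present), ")", call. = FALSE)
        q <- pmax(L * rel[present] - 1, 0)
        cnt <- numeric(n_all)
        cnt[present] <- 1
        if (L > length(present) && sum(q) > 0)
          cnt[present] <- cnt[present] +
            stats::rmultinom(1L, L - length(present), q)[, 1]
        counts_blocks[[sid]] <- stats::setNames(cnt, pp$otu_ids)
        dr <- spec$depth_range[[sp]]
        meta_rows[[sid]] <- data.frame(
          sample_id = sid, species = sp, niche = nv,
          depth = round(stats::runif(1, dr[1], dr[2]), 1),
          site = sample(sites, 1L), stringsAsFactors = FALSE)
      }
    }
  }
  all_otus <- unlist(lapply(params, `[[`, "otu_ids"), use.names = FALSE)
  m <- matrix(0, nrow = length(counts_blocks), ncol = length(all_otus),
              dimnames = list(names(counts_blocks), all_otus))
  for (sid in names(counts_blocks)) {
    v <- counts_blocks[[sid]]
    m[sid, names(v)] <- v
  }
  meta <- do.call(rbind, meta_rows)
  metadata <- sample_metadata(meta$sample_id, meta$species, meta$niche,
                              meta$depth, meta$site)
  tax <- do.call(rbind, lapply(params, `[[`, "taxonomy"))
  rownames(tax) <- tax$otu_id
  class(tax) <- c("taxonomy_map", "data.frame")

  gt <- lapply(params, function(pp) {
    list(core_ids = lapply(pp$core_idx, function(ix) pp$bg_ids[ix]),
         symbiont_ids = pp$sym_ids,
         symbiont_genera = vapply(spec$planted_symbionts, `[[`, "", "genus"),
         presence_prob = pp$presence_prob,
         sym_relab = pp$sym_relab,
         exp_relab = pp$exp_relab)
  })
  list(otu_table = otu_table(m), taxonomy = tax, metadata = metadata,
       ground_truth = structure(gt, class = "ground_truth"))
}

#' Generate a synthetic gene-family copy-number reference
#'
#' Assigns every OTU of the community implied by `spec` a 16S copy number in
#' 1..10 and sparse copy numbers over `n_gene_families` gene families plus a
#' designated transporter family.  The planted symbionts receive transporter
#' copy numbers calibrated (from the generator's own expected relative
#' abundances) so that their expected contribution share of
#' transporter-family predicted counts in the endosymbiotic niche equals
#' `spec$transporter_share_target`.
#'
#' @param spec a [synthetic_spec()]
#' @return a [gene_copy_table()] whose pathway map sends the transporter
#'   family to the `"Transporters"` and `"Membrane_transport"` pathways and
#'   most other families to one or two of six generic pathways (two families
#'   are left unmapped).
#' @export
generate_gene_reference <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- community_params(spec)
  set.seed(derive_seed(spec$seed, 3L))
  fams <- c(sprintf("F%02d", seq_len(spec$n_gene_families)), "K_transport")
  all_otus <- unlist(lapply(params, `[[`, "otu_ids"), use.names = FALSE)
  n <- length(all_otus)
  ssu <- stats::setNames(sample(1:10, n, replace = TRUE), all_otus)
  gc <- matrix(0, nrow = n, ncol = length(fams),
               dimnames = list(all_otus, fams))
  present <- matrix(stats::runif(n * length(fams)) < 0.4, nrow = n)
  gc[present] <- 1 + stats::rpois(sum(present), 2)

  ## calibrate symbiont transporter copies against the expected background
  ## transporter load in the (first) endosymbiotic niche
  target <- spec$transporter_share_target
  endo_sp <- Filter(function(pp) "endosymbiotic" %in% pp$niches, params)
  if (length(endo_sp) && target > 0 && target < 1) {
    pp <- endo_sp[[1]]
    bg_load <- sum(pp$exp_relab[pp$bg_ids, "endosymbiotic"] /
                     ssu[pp$bg_ids] * gc[pp$bg_ids, "K_transport"])
    sym_per_copy <- sum(pp$sym_relab["endosymbiotic", ] / ssu[pp$sym_ids])
    cval <- (target / (1 - target)) * bg_load / sym_per_copy
    for (qq in params) gc[qq$sym_ids, "K_transport"] <- cval
  }
  pathways <- sprintf("P%d", 1:6)
  pm <- stats::setNames(vector("list", length(fams)), fams)
  for (i in seq_len(spec$n_gene_families)) {
    pm[[i]] <- pathways[(i %% 6) + 1]
    if (i %% 5 == 0) pm[[i]] <- c(pm[[i]], pathways[((i + 2) %% 6) + 1])
  }
  pm[["K_transport"]] <- c("Transporters", "Membrane_transport")
  if (spec$n_gene_families >= 2) {
    pm[[1]] <- character(0)            # deliberately unmapped families
    pm[[2]] <- character(0)
  }
  gene_copy_table(ssu, gc, pm)
}
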