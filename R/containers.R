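#' @keywords internal
"_PACKAGE"

## Closed vocabulary of host micro-habitats ("preparation types").  The
## holobiont is the whole crushed colony; tissue is dissected polyp tissue;
## endosymbiotic is laser-microdissected, dinoflagellate-hosting cell
## clusters; skeletal is washed skeleton-associated (endolithic) tissue.
NICHE_LEVELS <- c("holobiont", "tissue", "endosymbiotic", "skeletal")

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
GG_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                 order = "o__", family = "f__", genus = "g__",
                 species = "s__")

#' OTU count table
#'
#' Construct a validated OTU table: a non-negative integer count matrix with
#' samples as rows and OTUs as columns.  This is the canonical in-memory
#' orientation; the on-disk classic formats are OTU x sample and are
#' transposed on load.
#'
#' @param counts numeric matrix of counts, samples x OTUs, with unique row
#'   (sample) and column (OTU) dimnames.  Values must be finite, whole and
#'   non-negative.
#' @return an object of class `otu_table` (a classed matrix).
#' @examples
#' m <- matrix(c(1, 0, 2, 5, 0, 3), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("OTU1", "OTU2")))
#' x <- otu_table(m)
#' library_sizes(x)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("an OTU table needs at least one sample and one OTU", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample (row) and OTU (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(counts)))
    stop("counts must be finite", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be whole numbers", call. = FALSE)
  storage.mode(counts) <- "double"
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs\n", nrow(x), ncol(x)))
  ls <- library_sizes(x)
  cat(sprintf("library sizes: min %s, median %s, max %s\n",
              format(min(ls)), format(stats::median(ls)), format(max(ls))))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x)

#' @rdname otu_table
#' @export
library_sizes <- function(x) rowSums(unclass(x))

## strip the class so that arithmetic and subsetting behave like a matrix
otu_counts <- function(x) {
  y <- unclass(x)
  attr(y, "taxonomy") <- NULL
  y
}

#' Drop samples with zero library size
#'
#' Removes samples in which no OTU was observed; each removal is reported via
#' a warning.  No count value is ever altered.
#'
#' @param x an `otu_table`
#' @return an `otu_table` with only positive-library-size samples.
#' @export
drop_empty_samples <- function(x) {
  ls <- library_sizes(x)
  if (all(ls > 0)) return(x)
  dropped <- rownames(x)[ls == 0]
  warning("dropping ", length(dropped), " sample(s) with zero library size: ",
          paste(dropped, collapse = ", "), call. = FALSE)
  if (all(ls == 0))
    stop("all samples have zero library size", call. = FALSE)
  otu_table(unclass(x)[ls > 0, , drop = FALSE])
}

#' Sample metadata
#'
#' Per-sample study covariates: host species, niche (preparation type),
#' collection depth and site.  Extra columns are preserved verbatim.
#'
#' @param sample_id character vector of unique sample identifiers
#' @param species host species label per sample
#' @param niche preparation type per sample; one of
#'   `"holobiont"`, `"tissue"`, `"endosymbiotic"`, `"skeletal"`
#' @param depth collection depth in meters, non-negative
#' @param site collection site label (optional)
#' @param extra optional data.frame of additional columns, preserved verbatim
#' @return a `sample_metadata` data.frame
#' @export
sample_metadata <- function(sample_id, species, niche, depth,
                            site = NA_character_, extra = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  niche <- as.character(niche)
  bad <- setdiff(unique(niche), NICHE_LEVELS)
  if (length(bad))
    stop("unknown niche level(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(NICHE_LEVELS, collapse = ", "),
         call. = FALSE)
  depth <- as.numeric(depth)
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depth must be finite, non-negative meters", call. = FALSE)
  out <- data.frame(sample_id = sample_id,
                    species = as.character(species),
                    niche = factor(niche, levels = NICHE_LEVELS),
                    depth = depth,
                    site = as.character(site),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(out))
    out <- cbind(out, extra)
  }
  rownames(out) <- out$sample_id
  class(out) <- c("sample_metadata", "data.frame")
  out
}

## every table sample must have a metadata record
check_metadata_covers <- function(x, metadata) {
  missing <- setdiff(sample_ids(x), metadata$sample_id)
  if (length(missing))
    stop("samples without metadata record: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

## metadata rows aligned to the table's samples
metadata_for <- function(x, metadata) {
  check_metadata_covers(x, metadata)
  metadata[match(sample_ids(x), metadata$sample_id), , drop = FALSE]
}

#' Taxonomy map
#'
#' Ranked lineages per OTU.  Each of the seven ranks (kingdom ... species) is
#' a character label, with `"unclassified"` for missing assignments.
#'
#' @param otu_id character vector of unique OTU identifiers
#' @param lineage either a character vector of GreenGenes-style lineage
#'   strings (`k__...; p__...; ...`), parsed with [parse_lineage()], or a
#'   data.frame/matrix with columns named by rank
#' @return a `taxonomy_map` data.frame with one row per OTU and one column
#'   per rank.
#' @export
taxonomy_map <- function(otu_id, lineage) {
  otu_id <- as.character(otu_id)
  if (anyDuplicated(otu_id))
    stop("duplicate OTU identifiers in taxonomy", call. = FALSE)
  if (is.character(lineage)) {
    ranks <- parse_lineage(lineage)
  } else {
    ranks <- as.data.frame(lineage, stringsAsFactors = FALSE)
    missing <- setdiff(TAX_RANKS, names(ranks))
    for (r in missing) ranks[[r]] <- "unclassified"
    ranks <- ranks[TAX_RANKS]
  }
  stopifnot(nrow(ranks) == length(otu_id))
  out <- cbind(data.frame(otu_id = otu_id, stringsAsFactors = FALSE), ranks)
  rownames(out) <- otu_id
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Parse GreenGenes-style lineage strings
#'
#' Splits `k__...; p__...; c__...; o__...; f__...; g__...; s__...` strings
#' into the seven canonical ranks.  Missing or empty ranks become
#' `"unclassified"`; a token with an unknown rank prefix is kept at its
#' positional rank with a warning.
#'
#' @param lineage character vector of lineage strings
#' @return data.frame with columns `kingdom` ... `species`
#' @export
parse_lineage <- function(lineage) {
  out <- matrix("unclassified", nrow = length(lineage),
                ncol = length(TAX_RANKS),
                dimnames = list(NULL, TAX_RANKS))
  for (i in seq_along(lineage)) {
    s <- lineage[i]
    if (is.na(s) || !nzchar(trimws(s))) next
    tokens <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    if (length(tokens) > length(TAX_RANKS)) {
      warning("lineage has more than ", length(TAX_RANKS),
              " ranks; extras dropped: ", s, call. = FALSE)
      tokens <- tokens[seq_along(TAX_RANKS)]
    }
    for (j in seq_along(tokens)) {
      tok <- tokens[j]
      if (!nzchar(tok)) next
      pref <- substr(tok, 1L, 3L)
      hit <- match(pref, GG_PREFIXES)
      if (!is.na(hit)) {
        name <- substr(tok, 4L, nchar(tok))
        if (nzchar(name)) out[i, hit] <- name
      } else {
        warning("unknown rank prefix in token '", tok,
                "'; kept at positional rank ", TAX_RANKS[j], call. = FALSE)
        out[i, j] <- tok
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Format ranked lineages back to GreenGenes strings
#'
#' The inverse of [parse_lineage()] on its canonical form: all seven
#' prefixes, `"; "` separated, empty after the prefix for unclassified ranks.
#'
#' @param ranks data.frame with columns `kingdom` ... `species` (e.g. a
#'   `taxonomy_map`)
#' @return character vector of lineage strings
#' @export
format_lineage <- function(ranks) {
  ranks <- as.data.frame(ranks, stringsAsFactors = FALSE)[TAX_RANKS]
  apply(ranks, 1L, function(r) {
    r <- ifelse(r == "unclassified", "", r)
    paste0(GG_PREFIXES, r, collapse = "; ")
  })
}

#' Gene-family copy-number reference
#'
#' Per-OTU 16S (SSU) copy numbers and gene-family copy numbers, plus a
#' gene-family to pathway map, used for predicted-metagenome projection.
#'
#' @param ssu_copies named numeric vector (names = OTU ids), all >= 1
#' @param gene_copy numeric matrix, OTUs x gene families, finite and
#'   non-negative, rownames matching `names(ssu_copies)`
#' @param pathway_map named list: gene family id -> character vector of
#'   pathway ids (may be empty for unmapped families)
#' @return a `gene_copy_table` object
#' @export
gene_copy_table <- function(ssu_copies, gene_copy, pathway_map = list()) {
  if (is.null(names(ssu_copies)) || anyDuplicated(names(ssu_copies)))
    stop("ssu_copies must be uniquely named by OTU id", call. = FALSE)
  if (any(!is.finite(ssu_copies)) || any(ssu_copies < 1))
    stop("ssu_copies must be finite and >= 1", call. = FALSE)
  gene_copy <- as.matrix(gene_copy)
  if (!identical(rownames(gene_copy), names(ssu_copies)))
    stop("gene_copy rownames must match names(ssu_copies)", call. = FALSE)
  if (any(!is.finite(gene_copy)) || any(gene_copy < 0))
    stop("gene copy numbers must be finite and non-negative", call. = FALSE)
  structure(list(ssu_copies = ssu_copies, gene_copy = gene_copy,
                 pathway_map = pathway_map),
            class = "gene_copy_table")
}

#' @export
print.gene_copy_table <- function(x, ...) {
  cat(sprintf("gene copy reference: %d OTUs x %d gene families (%d mapped to pathways)\n",
              length(x$ssu_copies), ncol(x$gene_copy),
              sum(lengths(x$pathway_map) > 0)))
  invisible(x)
}
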