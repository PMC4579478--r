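## Readers and writers for the classic tab-separated microbiome formats.
## On disk the tables are OTU x sample (the field-standard layout); in memory
## the canonical orientation is sample x OTU, so loading transposes.

#' Read an OTU table
#'
#' Reads a classic tab-separated OTU table (first column OTU id, header row
#' sample ids, one row per OTU) or its BIOM-classic dialect (same layout
#' preceded by a `# Constructed from biom file` comment line, optionally with
#' a trailing `taxonomy` column holding GreenGenes lineage strings).
#'
#' Samples with zero library size are dropped with a warning; no count value
#' is otherwise changed.  If a taxonomy column is present, the parsed
#' [taxonomy_map()] is attached as attribute `"taxonomy"`.
#'
#' @param path path to a readable TSV file
#' @param dialect `"classic_tsv"` or `"biom_classic"`
#' @return an [otu_table()] (samples x OTUs)
#' @export
read_otu_table <- function(path, dialect = c("classic_tsv", "biom_classic")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lineno <- 0L
  if (dialect == "biom_classic") {
    if (!length(lines) || !startsWith(lines[1], "#"))
      stop("malformed BIOM-classic file: expected a leading comment line, ",
           "got line 1: ", if (length(lines)) lines[1] else "<empty>",
           call. = FALSE)
    if (startsWith(lines[1], "# ")) {
      lines <- lines[-1]
      lineno <- 1L
    }
  }
  if (!length(lines))
    stop("empty OTU table file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header at line ", lineno + 1L,
         ": need an OTU id column plus at least one sample column",
         call. = FALSE)
  has_tax <- identical(tolower(header[length(header)]), "taxonomy")
  samples <- header[-1]
  if (has_tax) samples <- samples[-length(samples)]
  if (!length(samples))
    stop("malformed header at line ", lineno + 1L, ": no sample columns",
         call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header", call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) stop("OTU table has no data rows", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- 1L + length(samples) + has_tax
  lens <- lengths(parts)
  if (any(lens != nfield))
    stop("malformed row at line ", lineno + 1L + which(lens != nfield)[1],
         ": expected ", nfield, " fields, found ",
         lens[which(lens != nfield)[1]], call. = FALSE)
  otus <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(otus))
    stop("duplicate OTU identifier: ",
         otus[duplicated(otus)][1], call. = FALSE)
  m <- matrix(0, nrow = length(otus), ncol = length(samples),
              dimnames = list(otus, samples))
  for (i in seq_along(parts)) {
    vals <- suppressWarnings(as.numeric(parts[[i]][2:(1L + length(samples))]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop("non-numeric count at row '", otus[i], "', sample '",
           samples[j], "'", call. = FALSE)
    }
    if (any(vals < 0)) {
      j <- which(vals < 0)[1]
      stop("negative count at row '", otus[i], "', sample '",
           samples[j], "'", call. = FALSE)
    }
    m[i, ] <- vals
  }
  x <- drop_empty_samples(otu_table(t(m)))
  if (has_tax) {
    lineages <- vapply(parts, `[[`, "", nfield)
    attr(x, "taxonomy") <- taxonomy_map(otus, lineages)
  }
  x
}

#' Write an OTU table
#'
#' @param x an [otu_table()]
#' @param path output path
#' @param dialect `"classic_tsv"` or `"biom_classic"`
#' @param taxonomy optional [taxonomy_map()]; when given with
#'   `dialect = "biom_classic"`, lineage strings are written as a trailing
#'   `taxonomy` column
#' @return `path`, invisibly
#' @export
write_otu_table <- function(x, path,
                            dialect = c("classic_tsv", "biom_classic"),
                            taxonomy = NULL) {
  dialect <- match.arg(dialect)
  m <- t(otu_counts(x))                       # OTU x sample on disk
  header <- c("#OTU ID", colnames(m))
  lines <- character(0)
  if (dialect == "biom_classic")
    lines <- "# Constructed from biom file"
  tax_col <- NULL
  if (!is.null(taxonomy) && dialect == "biom_classic") {
    idx <- match(rownames(m), taxonomy$otu_id)
    if (anyNA(idx))
      stop("taxonomy does not cover all OTUs", call. = FALSE)
    tax_col <- format_lineage(taxonomy[idx, , drop = FALSE])
    header <- c(header, "taxonomy")
  }
  rows <- vapply(seq_len(nrow(m)), function(i) {
    fields <- c(rownames(m)[i], format(m[i, ], scientific = FALSE,
                                       trim = TRUE))
    if (!is.null(tax_col)) fields <- c(fields, tax_col[i])
    paste(fields, collapse = "\t")
  }, "")
  writeLines(c(lines, paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a two-column taxonomy assignment file
#'
#' @param path TSV file with columns otu_id, lineage string (no header, or a
#'   `#`-prefixed header line which is skipped)
#' @return a [taxonomy_map()]
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 1L)
  otus <- vapply(parts, `[[`, "", 1L)
  lineages <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
                     "")
  taxonomy_map(otus, lineages)
}

#' Write a taxonomy map as a two-column TSV
#'
#' @param tax a [taxonomy_map()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_taxonomy <- function(tax, path) {
  writeLines(paste(tax$otu_id, format_lineage(tax), sep = "\t"), path)
  invisible(path)
}

#' Read a QIIME-style mapping (metadata) file
#'
#' Tab-separated with a `#SampleID` first header column and required columns
#' `Species`, `Niche`, `Depth`; `Site` and any extra columns are preserved.
#'
#' @param path mapping file path
#' @return a [sample_metadata()] data.frame
#' @export
read_metadata <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1], "#SampleID"))
    stop("malformed mapping header: first column must be '#SampleID', got '",
         header[1], "'", call. = FALSE)
  need <- c("Species", "Niche", "Depth")
  missing <- setdiff(need, header)
  if (length(missing))
    stop("mapping file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  df <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
    length(p) <- length(header)
    p
  })), stringsAsFactors = FALSE)
  names(df) <- header
  extra_cols <- setdiff(header, c("#SampleID", "Species", "Niche", "Depth",
                                  "Site"))
  sample_metadata(df[["#SampleID"]], df$Species, df$Niche,
                  as.numeric(df$Depth),
                  site = if ("Site" %in% header) df$Site else NA_character_,
                  extra = if (length(extra_cols))
                    df[extra_cols] else NULL)
}

#' Write a QIIME-style mapping file
#'
#' @param metadata a [sample_metadata()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metadata <- function(metadata, path) {
  core <- data.frame("#SampleID" = metadata$sample_id,
                     Species = metadata$species,
                     Niche = as.character(metadata$niche),
                     Depth = format(metadata$depth, scientific = FALSE,
                                    trim = TRUE),
                     Site = metadata$site,
                     check.names = FALSE, stringsAsFactors = FALSE)
  extra_cols <- setdiff(names(metadata),
                        c("sample_id", "species", "niche", "depth", "site"))
  if (length(extra_cols)) core <- cbind(core, metadata[extra_cols])
  lines <- c(paste(names(core), collapse = "\t"),
             apply(core, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-family copy-number reference
#'
#' TSV with columns `otu_id`, `ssu_copies`, then one column per gene family.
#'
#' @param path reference TSV path
#' @param pathway_path optional two-column TSV (gene family id, pathway id;
#'   one row per mapping, families may map to several pathways)
#' @return a [gene_copy_table()]
#' @export
read_gene_copy_table <- function(path, pathway_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("otu_id", "ssu_copies") %in% names(df)))
    stop("gene copy reference needs 'otu_id' and 'ssu_copies' columns",
         call. = FALSE)
  fams <- setdiff(names(df), c("otu_id", "ssu_copies"))
  gc <- as.matrix(df[fams])
  rownames(gc) <- df$otu_id
  ssu <- stats::setNames(as.numeric(df$ssu_copies), df$otu_id)
  pm <- list()
  if (!is.null(pathway_path)) pm <- read_pathway_map(pathway_path)
  gene_copy_table(ssu, gc, pm)
}

#' @rdname read_gene_copy_table
#' @param x a [gene_copy_table()]
#' @export
write_gene_copy_table <- function(x, path, pathway_path = NULL) {
  df <- data.frame(otu_id = names(x$ssu_copies),
                   ssu_copies = x$ssu_copies,
                   as.data.frame(x$gene_copy, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pathway_path)) write_pathway_map(x$pathway_map, pathway_path)
  invisible(path)
}

#' Read / write a gene-family to pathway map
#'
#' @param path two-column TSV: gene family id, pathway id (one mapping per
#'   row; many-to-many allowed)
#' @return named list, gene family id -> character vector of pathway ids
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family", "pathway"))
  split(df$pathway, df$family)
}

#' @rdname read_pathway_map
#' @param pathway_map named list, family -> pathways
#' @export
write_pathway_map <- function(pathway_map, path) {
  fam <- rep(names(pathway_map), lengths(pathway_map))
  pw <- unlist(pathway_map, use.names = FALSE)
  writeLines(paste(fam, pw, sep = "\t"), path)
  invisible(path)
}

## Newick labels must avoid the format's reserved characters
sanitize_newick_label <- function(x) gsub("[^A-Za-z0-9_.|-]", "_", x)

#' Export a taxonomy as a rank-nested Newick tree
#'
#' Builds a tree nesting kingdom through genus, with the requested OTU ids as
#' tips and taxon names (GreenGenes-prefixed) as internal node labels.  The
#' output is valid Newick: balanced parentheses, terminating semicolon, and
#' exactly `length(tip_set)` leaves.
#'
#' @param tax a [taxonomy_map()]
#' @param tip_set character vector of OTU ids to place as tips; must all be
#'   mapped in `tax`
#' @return a single Newick string
#' @export
export_taxonomy_newick <- function(tax, tip_set) {
  if (!length(tip_set)) stop("tip_set is empty", call. = FALSE)
  missing <- setdiff(tip_set, tax$otu_id)
  if (length(missing))
    stop("tip(s) not in taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sub <- tax[match(tip_set, tax$otu_id), , drop = FALSE]
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  ## returns a subtree string; levels with a single child collapse so the
  ## tree has no singleton internal chains (which some readers reject)
  build <- function(rows, level) {
    if (level > length(ranks)) {
      tips <- sanitize_newick_label(rows$otu_id)
      if (length(tips) == 1L) return(tips)
      return(paste0("(", paste(tips, collapse = ","), ")"))
    }
    groups <- split(rows, rows[[ranks[level]]])
    children <- vapply(names(groups), function(g) {
      inner <- build(groups[[g]], level + 1L)
      if (startsWith(inner, "("))
        paste0(inner, sanitize_newick_label(
          paste0(GG_PREFIXES[[ranks[level]]], g)))
      else inner                       # lone tip: no degenerate clade
    }, "")
    if (length(children) == 1L) return(children[[1]])
    paste0("(", paste(children, collapse = ","), ")")
  }
  inner <- build(sub, 1L)
  if (startsWith(inner, "(") && endsWith(inner, ")"))
    paste0(inner, "root;")
  else paste0("(", inner, ")root;")
}
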