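# Parsing of annotations and orthogroup tables, the fuzzy single-copy
# filter, and construction of the ortholog x species allocation matrix.

#' Load gene loci from per-species GFF3 annotations
#'
#' Reads gene features from one GFF3 per species and returns a single locus
#' table. An optional scaffold-alias table merges co-assembled scaffolds
#' into one chromosome unit (e.g. two scaffolds of a single chromosome),
#' preserving native coordinates and recording the concatenation order.
#' Files without `gene` features fall back to top-level `mRNA`/`transcript`
#' features, with a warning.
#'
#' @param gff3_paths Named character vector of GFF3 paths; names are species.
#' @param alias Optional alias table: data.frame with columns `scaffold`,
#'   `chromosome_unit`, `order_index` and (when aliases differ by species)
#'   `species`; or a path to such a TSV.
#' @param strict If `TRUE`, a scaffold absent from a supplied alias table is
#'   an error; otherwise unknown scaffolds pass through unaliased.
#' @return data.frame of class `nigon_loci`: `gene_id`, `species`,
#'   `chromosome` (post-aliasing), `start`, `end` (1-based inclusive),
#'   `strand`, `scaffold` (pre-aliasing), `alias_order`.
#' @examples
#' \dontrun{
#' loci <- load_annotations(c(sp1 = "sp1.gff3", sp2 = "sp2.gff3"))
#' }
#' @export
load_annotations <- function(gff3_paths, alias = NULL, strict = FALSE) {
  .assert(length(gff3_paths) >= 1, "no GFF3 paths given")
  if (is.null(names(gff3_paths)) || any(!nzchar(names(gff3_paths))))
    names(gff3_paths) <- sub("\\.gff3?$", "", basename(gff3_paths))
  alias <- .read_alias(alias)

  out <- list()
  for (sp in names(gff3_paths)) {
    gr <- rtracklayer::import(gff3_paths[[sp]], format = "gff3")
    sel <- gr[gr$type == "gene"]
    if (length(sel) == 0) {
      sel <- gr[gr$type %in% c("mRNA", "transcript")]
      if (length(sel) > 0)
        warning(sprintf("%s: no gene features; falling back to %d transcript features",
                        sp, length(sel)), call. = FALSE)
    }
    .assert(length(sel) > 0, "%s: no usable gene features", sp)
    ids <- sel$ID
    if (is.null(ids)) ids <- sel$Name
    .assert(!is.null(ids) && all(!is.na(ids)),
            "%s: gene features lack ID attributes", sp)
    dup <- unique(ids[duplicated(ids)])
    .assert(length(dup) == 0, "%s: duplicate gene IDs: %s", sp,
            paste(head(dup, 5), collapse = ", "))
    out[[sp]] <- data.frame(
      gene_id = ids, species = sp,
      chromosome = as.character(GenomicRanges::seqnames(sel)),
      start = GenomicRanges::start(sel), end = GenomicRanges::end(sel),
      strand = as.character(GenomicRanges::strand(sel)),
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, out)
  rownames(loci) <- NULL
  loci$scaffold <- loci$chromosome
  loci$alias_order <- 1L
  loci <- apply_alias(loci, alias, strict = strict)
  class(loci) <- c("nigon_loci", "data.frame")
  loci
}

.read_alias <- function(alias) {
  if (is.null(alias)) return(NULL)
  if (is.character(alias) && length(alias) == 1) {
    alias <- read.delim(alias, stringsAsFactors = FALSE)
  }
  .assert(all(c("scaffold", "chromosome_unit") %in% names(alias)),
          "alias table needs columns scaffold, chromosome_unit")
  if (is.null(alias$order_index)) alias$order_index <- 1L
  alias
}

#' Apply a scaffold-to-chromosome alias map to a locus table
#'
#' Idempotent: applying the same map twice equals applying it once
#' (already-aliased rows are matched through their recorded scaffold).
#'
#' @param loci A locus table as from [load_annotations()].
#' @param alias Alias table (see [load_annotations()]); `NULL` is a no-op.
#' @param strict Error on scaffolds missing from the table.
#' @return The locus table with `chromosome` and `alias_order` rewritten.
#' @export
apply_alias <- function(loci, alias, strict = FALSE) {
  alias <- .read_alias(alias)
  if (is.null(alias)) return(loci)
  if (is.null(loci$scaffold)) loci$scaffold <- loci$chromosome
  key <- if ("species" %in% names(alias)) {
    paste(loci$species, loci$scaffold)
  } else loci$scaffold
  akey <- if ("species" %in% names(alias)) {
    paste(alias$species, alias$scaffold)
  } else alias$scaffold
  idx <- match(key, akey)
  if (strict) {
    missing <- unique(loci$scaffold[is.na(idx)])
    .assert(length(missing) == 0, "scaffolds missing from alias table: %s",
            paste(head(missing, 5), collapse = ", "))
  }
  hit <- !is.na(idx)
  loci$chromosome[hit] <- alias$chromosome_unit[idx[hit]]
  loci$alias_order[hit] <- alias$order_index[idx[hit]]
  loci
}

#' Read an orthogroup membership table
#'
#' Tab-separated, one orthogroup per row; column 1 is the orthogroup ID and
#' each further column lists that species' member gene IDs, comma-joined
#' (empty when absent) — the layout produced by standard orthology
#' inference.
#'
#' @param path TSV path.
#' @return data.frame with column `Orthogroup` then one column per species.
#' @export
read_orthogroups <- function(path) {
  og <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = NULL)
  .assert(ncol(og) >= 2, "orthogroup table needs >= 2 columns")
  names(og)[1] <- "Orthogroup"
  dup <- unique(og$Orthogroup[duplicated(og$Orthogroup)])
  .assert(length(dup) == 0, "duplicate orthogroup IDs: %s",
          paste(head(dup, 5), collapse = ", "))
  og[is.na(og)] <- ""
  og
}

# Per-row, per-species copy counts for an orthogroup table.
.og_counts <- function(og) {
  species <- names(og)[-1]
  counts <- sapply(species, function(sp) {
    cells <- og[[sp]]
    n <- lengths(strsplit(cells, ",", fixed = TRUE))
    n[!nzchar(trimws(cells))] <- 0L
    n
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(og))
  colnames(counts) <- species
  counts
}

#' Filter orthogroups to fuzzy single-copy status
#'
#' Retains orthogroups that have exactly one member gene in at least
#' `min_single_copy_species` of the roster species. Species contributing
#' zero or multiple copies to a retained group yield missing cells
#' downstream.
#'
#' @param og Orthogroup table ([read_orthogroups()] layout).
#' @param min_single_copy_species Minimum number of species with exactly one
#'   copy (default 12, against a 15-species roster).
#' @param roster Optional character vector restricting/ordering the species
#'   columns considered.
#' @return The filtered orthogroup table (same layout), with attribute
#'   `single_copy_species` (per-row counts).
#' @export
filter_fuzzy_single_copy <- function(og, min_single_copy_species = 12,
                                     roster = NULL) {
  species <- names(og)[-1]
  if (!is.null(roster)) {
    .assert(all(roster %in% species), "roster species missing from table")
    og <- og[, c("Orthogroup", roster)]
    species <- roster
  }
  .assert(min_single_copy_species >= 1 &&
            min_single_copy_species <= length(species),
          "min_single_copy_species must be in 1..%d", length(species))
  counts <- .og_counts(og)
  n_single <- rowSums(counts == 1L)
  keep <- n_single >= min_single_copy_species
  out <- og[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "single_copy_species") <- n_single[keep]
  out
}

#' Construct a nigon_alloc allocation matrix from a character matrix
#'
#' @param M Character matrix, orthologs x species, `NA` for missing cells.
#' @param source_genes Optional parallel matrix of source gene IDs.
#' @return Object of class `nigon_alloc`.
#' @export
new_allocation_matrix <- function(M, source_genes = NULL) {
  .assert(is.matrix(M) && is.character(M), "M must be a character matrix")
  .assert(!is.null(rownames(M)) && !is.null(colnames(M)),
          "M needs row (ortholog) and column (species) names")
  structure(M, source_genes = source_genes, class = c("nigon_alloc", "matrix"))
}

#' Build the ortholog x species chromosomal allocation matrix
#'
#' For every retained orthogroup and species, records the chromosome of the
#' species' unique member gene; species with zero or multiple copies are
#' missing. Every single-copy gene ID must resolve to a locus.
#'
#' @param loci Locus table from [load_annotations()].
#' @param og Filtered orthogroup table ([filter_fuzzy_single_copy()]).
#' @return A `nigon_alloc` character matrix with attributes `source_genes`
#'   (gene IDs behind each cell) and `summary` (rows, per-species missing
#'   fraction).
#' @export
build_allocation_matrix <- function(loci, og) {
  species <- names(og)[-1]
  counts <- .og_counts(og)
  n <- nrow(og)
  M <- matrix(NA_character_, n, length(species),
              dimnames = list(og$Orthogroup, species))
  src <- M
  for (sp in species) {
    sp_loci <- loci[loci$species == sp, ]
    lookup <- setNames(sp_loci$chromosome, sp_loci$gene_id)
    single <- which(counts[, sp] == 1L)
    ids <- trimws(og[[sp]][single])
    chrom <- lookup[ids]
    bad <- which(is.na(chrom))
    .assert(length(bad) == 0,
            "unresolvable gene ID(s) for species %s in orthogroup(s): %s",
            sp, paste(head(og$Orthogroup[single[bad]], 5), collapse = ", "))
    M[single, sp] <- unname(chrom)
    src[single, sp] <- ids
  }
  out <- new_allocation_matrix(M, source_genes = src)
  attr(out, "summary") <- list(
    n_orthogroups = n,
    missing_fraction = colMeans(is.na(M)))
  out
}

#' @export
print.nigon_alloc <- function(x, ...) {
  cat("Allocation matrix:", nrow(x), "orthologs x", ncol(x), "species\n")
  mf <- colMeans(is.na(x))
  cat("missing per species:",
      paste(sprintf("%s %.1f%%", colnames(x), 100 * mf), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an allocation matrix as TSV
#'
#' Row = orthogroup, columns = species, missing cells empty.
#' @param alloc A `nigon_alloc` matrix.
#' @param path TSV path.
#' @return `write_allocation_matrix` the path, invisibly;
#'   `read_allocation_matrix` a `nigon_alloc`.
#' @export
write_allocation_matrix <- function(alloc, path) {
  df <- data.frame(Orthogroup = rownames(alloc),
                   as.data.frame(unclass(alloc), stringsAsFactors = FALSE),
                   check.names = FALSE)
  df[is.na(df)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_allocation_matrix
#' @export
read_allocation_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = "")
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  mode(M) <- "character"
  new_allocation_matrix(M)
}
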