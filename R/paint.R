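# Window-based chromosome painting, RBH label projection, gene-neighborhood
# divergence and feature-density tracks.

#' Paint chromosomes by element content in fixed windows
#'
#' Counts element-labeled loci in non-overlapping windows along each
#' chromosome. Windows are 1-based inclusive `[w*(i-1)+1, w*i]`; a locus is
#' counted in exactly one window by its start coordinate; the final window
#' may be short. Loci whose orthogroup is unassigned (or absent from the
#' assignment) count into the `UNASSIGNED` column.
#'
#' @param assignment A `nigon_assignment` (or data.frame with `orthogroup`,
#'   `element`).
#' @param loci Locus table with columns `species`, `chromosome`, `start`,
#'   and `orthogroup` (e.g. a [realize_genomes()] species table, or
#'   [load_annotations()] output merged with orthogroup membership).
#' @param window_bp Window width in bp (default 500000, i.e. 0.5 Mb).
#' @param chrom_lengths Optional named vector of chromosome lengths; loci
#'   starting beyond the declared length are an error, and windows tile the
#'   full declared length.
#' @return data.frame of class `nigon_painting`: `species`, `chromosome`,
#'   `window_start`, `window_end`, one count column per element label, and
#'   `UNASSIGNED`.
#' @export
paint_chromosomes <- function(assignment, loci, window_bp = 500000,
                              chrom_lengths = NULL) {
  .assert(all(c("chromosome", "start") %in% names(loci)),
          "loci must have chromosome and start columns")
  .assert("orthogroup" %in% names(loci),
          "loci must carry an `orthogroup` column to join the assignment")
  if (is.null(loci$species)) loci$species <- "genome"
  el <- assignment$element[match(loci$orthogroup, assignment$orthogroup)]
  el[is.na(el)] <- "UNASSIGNED"
  labels <- sort(setdiff(unique(assignment$element), "UNASSIGNED"))

  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[loci$chromosome]
    bad <- which(!is.na(len) & loci$start > len)
    .assert(length(bad) == 0,
            "locus start beyond declared chromosome length (e.g. %s:%d)",
            loci$chromosome[bad[1]], loci$start[bad[1]])
  }

  win <- (loci$start - 1L) %/% as.integer(window_bp) + 1L
  key <- data.frame(species = loci$species, chromosome = loci$chromosome,
                    window = win, element = el, stringsAsFactors = FALSE)
  counts <- aggregate(cbind(n = rep(1L, nrow(key))) ~
                        species + chromosome + window + element,
                      data = key, FUN = sum)

  out <- list()
  for (grp in split(counts, paste(counts$species, counts$chromosome))) {
    sp <- grp$species[1]; chrom <- grp$chromosome[1]
    max_win <- max(grp$window)
    declared <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
      chrom_lengths[[chrom]] else NA
    if (!is.na(declared)) max_win <- max(max_win, (declared - 1) %/% window_bp + 1)
    wtab <- data.frame(species = sp, chromosome = chrom,
                       window_start = (seq_len(max_win) - 1) * window_bp + 1,
                       window_end = seq_len(max_win) * window_bp,
                       stringsAsFactors = FALSE)
    if (!is.na(declared)) wtab$window_end <- pmin(wtab$window_end, declared)
    for (lab in c(labels, "UNASSIGNED")) {
      v <- integer(max_win)
      sub <- grp[grp$element == lab, ]
      v[sub$window] <- sub$n
      wtab[[lab]] <- v
    }
    out[[paste(sp, chrom)]] <- wtab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("nigon_painting", "data.frame")
  res
}

# Standard 12-column BLAST tabular (outfmt 6) reader with line validation.
.read_blast6 <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 12)
  .assert(length(bad) == 0, "%s: malformed BLAST tabular line %d (%d fields)",
          path, if (length(bad)) bad[1] else 0L,
          if (length(bad)) nf[bad[1]] else 0L)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  df
}

# Best hit per query: lowest e-value, then higher bit score, then longer
# subject scaffold, then lexicographic subject ID.
.best_hits <- function(df, scaffold_of = NULL, scaffold_lengths = NULL) {
  slen <- rep(0, nrow(df))
  if (!is.null(scaffold_of) && !is.null(scaffold_lengths)) {
    scaf <- scaffold_of[df$sseqid]
    slen <- scaffold_lengths[scaf]
    slen[is.na(slen)] <- 0
  }
  ord <- order(df$qseqid, df$evalue, -df$bitscore, -slen, df$sseqid)
  df <- df[ord, ]
  df[!duplicated(df$qseqid), c("qseqid", "sseqid", "evalue", "bitscore")]
}

#' Project element labels onto a genome via reciprocal best BLAST hits
#'
#' Pairs query and reference genes that are each other's best hit in
#' two-directional BLAST tabular output (best = lowest e-value; ties broken
#' by higher bit score, then by the protein on the longer scaffold, then
#' lexicographically), requires both e-values below `max_evalue`, and lets
#' each paired query gene inherit the element label of its reference
#' partner.
#'
#' @param blast_ab Path to (or data.frame of) query-vs-reference BLAST
#'   tabular, 12 columns (outfmt 6).
#' @param blast_ba Reference-vs-query direction.
#' @param reference_assignment Named character vector (reference gene ->
#'   element label) or a `nigon_assignment` keyed by reference gene IDs.
#' @param max_evalue E-value ceiling (default `1e-6`; hits must be strictly
#'   below it).
#' @param scaffold_of,scaffold_lengths Optional named vectors (gene ->
#'   scaffold; scaffold -> length) enabling the longer-scaffold tie-break.
#' @return data.frame: `query`, `reference`, `evalue_fwd`, `evalue_rev`,
#'   `element` (`NA` when the reference gene has no label).
#' @export
project_labels_rbh <- function(blast_ab, blast_ba, reference_assignment,
                               max_evalue = 1e-6,
                               scaffold_of = NULL, scaffold_lengths = NULL) {
  .assert(max_evalue > 0, "max_evalue must be > 0")
  ab <- if (is.character(blast_ab)) .read_blast6(blast_ab) else blast_ab
  ba <- if (is.character(blast_ba)) .read_blast6(blast_ba) else blast_ba

  best_ab <- .best_hits(ab, scaffold_of, scaffold_lengths)
  best_ba <- .best_hits(ba, scaffold_of, scaffold_lengths)

  m <- merge(best_ab, best_ba,
             by.x = c("qseqid", "sseqid"), by.y = c("sseqid", "qseqid"),
             suffixes = c("_fwd", "_rev"))
  m <- m[m$evalue_fwd < max_evalue & m$evalue_rev < max_evalue, ]

  if (inherits(reference_assignment, "nigon_assignment")) {
    reference_assignment <- setNames(reference_assignment$element,
                                     reference_assignment$orthogroup)
  }
  out <- data.frame(query = m$qseqid, reference = m$sseqid,
                    evalue_fwd = m$evalue_fwd, evalue_rev = m$evalue_rev,
                    element = unname(reference_assignment[m$sseqid]),
                    stringsAsFactors = FALSE)
  out[order(out$query), ]
}

#' Gene-neighborhood divergence between two genomes
#'
#' For consecutive reference-genome gene pairs with 1:1 orthologs, compares
#' the inter-gene distance (absolute difference of start coordinates) in
#' the reference against the distance between their orthologs in the query
#' genome, per reference chromosome, via Spearman rank correlation. Operon
#' member genes are removed before pairing. Pairs farther apart than
#' `max_sep` in the reference — or whose query orthologs sit on different
#' chromosomes — are excluded from the correlation and counted in `m`.
#'
#' @param pairs data.frame with columns `ref_gene`, `query_gene` (1:1).
#' @param loci_ref,loci_query Locus tables (`gene_id`, `chromosome`,
#'   `start`).
#' @param operon_genes Reference gene IDs to drop before pairing.
#' @param max_sep Maximum reference separation in bp (default 50000).
#' @return data.frame of class `nigon_neighbors`: per reference chromosome,
#'   `rho` (Spearman; `NA` with fewer than 3 usable pairs), `p_value`, `n`
#'   (pairs including excluded), `m` (excluded pairs). Exact p-values are
#'   used below 20 pairs, the t-approximation otherwise.
#' @export
neighborhood_divergence <- function(pairs, loci_ref, loci_query,
                                    operon_genes = character(0),
                                    max_sep = 50000) {
  .assert(all(c("ref_gene", "query_gene") %in% names(pairs)),
          "pairs needs ref_gene and query_gene columns")
  .assert(!any(duplicated(pairs$ref_gene)) && !any(duplicated(pairs$query_gene)),
          "orthologs must be 1:1")
  pairs <- pairs[!(pairs$ref_gene %in% operon_genes), ]

  ri <- match(pairs$ref_gene, loci_ref$gene_id)
  qi <- match(pairs$query_gene, loci_query$gene_id)
  ok <- !is.na(ri) & !is.na(qi)
  pairs <- pairs[ok, ]; ri <- ri[ok]; qi <- qi[ok]
  tab <- data.frame(chrom = loci_ref$chromosome[ri],
                    ref_start = loci_ref$start[ri],
                    q_chrom = loci_query$chromosome[qi],
                    q_start = loci_query$start[qi])

  res <- lapply(split(tab, tab$chrom), function(g) {
    g <- g[order(g$ref_start), ]
    if (nrow(g) < 2) {
      return(data.frame(chromosome = g$chrom[1], rho = NA_real_,
                        p_value = NA_real_, n = 0L, m = 0L))
    }
    d_ref <- abs(diff(g$ref_start))
    d_query <- abs(diff(g$q_start))
    same_chrom <- g$q_chrom[-1] == g$q_chrom[-nrow(g)]
    n <- length(d_ref)
    use <- d_ref <= max_sep & same_chrom
    m <- sum(!use)
    if (sum(use) < 3) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(
        cor.test(d_ref[use], d_query[use], method = "spearman",
                 exact = sum(use) < 20))
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(chromosome = g$chrom[1], rho = rho, p_value = p,
               n = n, m = m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("nigon_neighbors", "data.frame")
  out
}

#' Feature-density track in fixed windows
#'
#' For sequence input, reports the GC proportion per non-overlapping window
#' (ambiguous bases excluded from the denominator). For interval input
#' (data.frame `chromosome`, `start`, `end`), reports the fraction of each
#' window covered by intervals (clipped to the window).
#'
#' @param x A [Biostrings::DNAStringSet], a FASTA path, or an interval
#'   data.frame.
#' @param window_bp Window width (e.g. 500000 for 0.5 Mb tracks, 10000 for
#'   10 kb GC tracks).
#' @param chrom_lengths Required for interval input: named vector of
#'   chromosome lengths.
#' @return data.frame: `chromosome`, `window_start`, `window_end`, and
#'   `gc` or `coverage`.
#' @export
feature_density <- function(x, window_bp, chrom_lengths = NULL) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
    names(x) <- sub("\\s.*", "", names(x))
  }
  if (inherits(x, "DNAStringSet")) {
    return(.gc_track(x, window_bp))
  }
  .assert(is.data.frame(x) &&
            all(c("chromosome", "start", "end") %in% names(x)),
          "interval input needs chromosome, start, end columns")
  .assert(!is.null(chrom_lengths), "interval input needs chrom_lengths")
  .coverage_track(x, window_bp, chrom_lengths)
}

.gc_track <- function(seqs, window_bp) {
  .assert(all(Biostrings::width(seqs) > 0), "empty sequence")
  out <- list()
  for (i in seq_along(seqs)) {
    len <- Biostrings::width(seqs)[i]
    starts <- seq(1L, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1L, len)
    v <- Biostrings::Views(seqs[[i]], start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
    out[[i]] <- data.frame(chromosome = names(seqs)[i] %||% as.character(i),
                           window_start = starts, window_end = ends,
                           gc = gc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.coverage_track <- function(iv, window_bp, chrom_lengths) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    sub <- iv[iv$chromosome == chrom, , drop = FALSE]
    cov <- IRanges::coverage(
      IRanges::reduce(IRanges::IRanges(start = pmax(sub$start, 1L),
                                       end = pmin(sub$end, len))),
      width = len)
    starts <- seq(1L, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1L, len)
    covered <- vapply(seq_along(starts), function(j) {
      sum(S4Vectors::window(cov, start = starts[j], end = ends[j]))
    }, numeric(1))
    out[[chrom]] <- data.frame(chromosome = chrom, window_start = starts,
                               window_end = ends,
                               coverage = covered / (ends - starts + 1),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
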