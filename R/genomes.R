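#' Instantiate gene loci on a simulated karyotype history
#'
#' Places concrete gene loci on every terminal chromosome of a
#' [simulate_history()] result. Each ancestral element carries
#' `genes_per_element` genes in a fixed ancestral order; a chromosome block
#' covering fractions `[lo, hi)` of an element receives the corresponding
#' slice of gene ranks. Gene loss, duplication and within-chromosome order
#' shuffling are applied per species.
#'
#' @param history A `nigon_history`.
#' @param genes_per_element Genes per ancestral element (single integer).
#' @param gene_len,spacing Gene length and mean start-to-start spacing in
#'   bp; loci are non-overlapping, 1-based inclusive.
#' @param spacing_jitter In `[0, 1)`: relative uniform jitter of inter-gene
#'   spacing (0 = perfectly even spacing; 0.8 draws each gap from
#'   `spacing * U(0.2, 1.8)`).
#' @param loss_rate Per-gene, per-species probability of loss, in `[0, 1)`.
#' @param dup_rate Per-gene, per-species probability of duplication (a second
#'   copy inserted at a random position on the same chromosome), in `[0, 1)`.
#' @param shuffle_intensity In `[0, 1]`: fraction of gene positions per
#'   chromosome drawn into a random permutation. 0 keeps ancestral order; 1
#'   fully randomises order (chromosome membership is never changed).
#'   Chromosomes flagged by a `shuffle` history event are always fully
#'   shuffled.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return An object of class `nigon_genomes`: list with `species` (named
#'   list of per-species locus data.frames: `gene_id`, `orthogroup`,
#'   `chromosome`, `start`, `end`, `strand`, `element`), `truth` (gene ->
#'   element table across species), `element_ids`, and the generating
#'   parameters.
#' @examples
#' h <- simulate_history("(sp1,sp2);", n_elements = 3)
#' g <- realize_genomes(h, genes_per_element = 10, seed = 1)
#' head(g$species$sp1)
#' @export
realize_genomes <- function(history, genes_per_element = 100,
                            gene_len = 1000, spacing = 5000,
                            spacing_jitter = 0,
                            loss_rate = 0, dup_rate = 0,
                            shuffle_intensity = 0, seed = NULL) {
  .assert(inherits(history, "nigon_history"), "`history` must be a nigon_history")
  .assert(genes_per_element >= 1, "genes_per_element must be >= 1")
  for (r in c(loss_rate, dup_rate))
    .assert(r >= 0 && r < 1, "rates must be in [0, 1)")
  .assert(shuffle_intensity >= 0 && shuffle_intensity <= 1,
          "shuffle_intensity must be in [0, 1]")
  .assert(spacing_jitter >= 0 && spacing_jitter < 1,
          "spacing_jitter must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  G <- as.integer(genes_per_element)
  el <- history$element_ids
  anc_ids <- lapply(el, function(e) sprintf("N%s_g%04d", e, seq_len(G)))
  names(anc_ids) <- el

  block_ranks <- function(b) {
    lo <- max(0, min(1, b$lo)); hi <- max(0, min(1, b$hi))
    r <- seq.int(floor(lo * G) + 1L, floor(hi * G))
    r[r >= 1 & r <= G]
  }

  species_tables <- list()
  for (sp in names(history$compositions)) {
    chroms <- history$compositions[[sp]]
    rows <- list()
    for (cn in names(chroms)) {
      blocks <- chroms[[cn]]
      ogs <- character(0); els <- character(0)
      for (i in seq_len(nrow(blocks))) {
        rk <- block_ranks(blocks[i, ])
        if (!length(rk)) next
        ogs <- c(ogs, anc_ids[[blocks$element[i]]][rk])
        els <- c(els, rep(blocks$element[i], length(rk)))
      }
      if (!length(ogs)) next

      n <- length(ogs)
      intensity <- if (isTRUE(attr(blocks, "shuffled"))) 1 else shuffle_intensity
      if (intensity > 0 && n > 1) {
        k <- round(intensity * n)
        if (k >= 2) {
          pos <- sort(sample.int(n, k))
          perm <- seq_len(n)
          perm[pos] <- pos[sample.int(k)]
          ogs <- ogs[perm]; els <- els[perm]
        }
      }

      keep <- runif(n) >= loss_rate
      ogs <- ogs[keep]; els <- els[keep]
      if (!length(ogs)) next

      dup <- runif(length(ogs)) < dup_rate
      gene_ids <- paste0(sp, "_", ogs)
      if (any(dup)) {
        ins_og <- ogs[dup]; ins_el <- els[dup]
        ins_id <- paste0(sp, "_", ins_og, "_2")
        for (j in seq_along(ins_og)) {
          at <- sample.int(length(ogs) + 1L, 1L) - 1L
          ogs <- append(ogs, ins_og[j], after = at)
          els <- append(els, ins_el[j], after = at)
          gene_ids <- append(gene_ids, ins_id[j], after = at)
        }
      }

      m <- length(ogs)
      gaps <- if (spacing_jitter > 0) {
        round(spacing * runif(m, 1 - spacing_jitter, 1 + spacing_jitter))
      } else rep(spacing, m)
      gaps <- pmax(gaps, gene_len + 1L)  # keep loci non-overlapping
      start <- cumsum(c(1L, gaps[-m]))
      rows[[cn]] <- data.frame(
        gene_id = gene_ids, orthogroup = ogs, chromosome = cn,
        start = start, end = start + gene_len - 1L,
        strand = sample(c("+", "-"), m, replace = TRUE),
        element = els, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    species_tables[[sp]] <- tab
  }

  truth <- do.call(rbind, lapply(names(species_tables), function(sp) {
    t <- species_tables[[sp]]
    data.frame(gene_id = t$gene_id, orthogroup = t$orthogroup, species = sp,
               chromosome = t$chromosome, element = t$element,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  structure(list(species = species_tables, truth = truth,
                 element_ids = el,
                 orthogroup_elements = setNames(
                   rep(el, each = G), unlist(anc_ids, use.names = FALSE)),
                 params = list(genes_per_element = G, gene_len = gene_len,
                               spacing = spacing,
                               spacing_jitter = spacing_jitter,
                               loss_rate = loss_rate,
                               dup_rate = dup_rate,
                               shuffle_intensity = shuffle_intensity,
                               seed = seed)),
            class = "nigon_genomes")
}

#' Build an orthogroup membership table from simulated genomes
#'
#' One row per ancestral gene (the orthogroup), one column per species,
#' cells holding comma-joined gene IDs (empty when the gene was lost).
#'
#' @param genomes A `nigon_genomes` object.
#' @return data.frame with column `Orthogroup` followed by one column per
#'   species, in the layout produced by standard orthology inference.
#' @export
orthogroup_table <- function(genomes) {
  .assert(inherits(genomes, "nigon_genomes"), "`genomes` must be nigon_genomes")
  ogs <- names(genomes$orthogroup_elements)
  out <- data.frame(Orthogroup = ogs, stringsAsFactors = FALSE)
  for (sp in names(genomes$species)) {
    t <- genomes$species[[sp]]
    joined <- vapply(split(t$gene_id, factor(t$orthogroup, levels = ogs)),
                     paste, character(1), collapse = ",")
    out[[sp]] <- unname(joined)
  }
  out
}

#' Write simulated genomes to standard per-species files
#'
#' Emits, under `out_dir`: one GFF3 of gene features per species
#' (`<species>.gff3`), a combined orthogroup TSV (`orthogroups.tsv`), a
#' scaffold-alias TSV (`alias.tsv`, identity mapping), and the ground-truth
#' table (`truth.tsv`). The files round-trip through [load_annotations()] /
#' [read_orthogroups()] / [build_allocation_matrix()] without loss.
#'
#' @param genomes A `nigon_genomes` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of written file paths.
#' @export
write_species_files <- function(genomes, out_dir) {
  .assert(inherits(genomes, "nigon_genomes"), "`genomes` must be nigon_genomes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(gff3 = character(0))
  for (sp in names(genomes$species)) {
    t <- genomes$species[[sp]]
    gr <- GenomicRanges::GRanges(
      seqnames = t$chromosome,
      ranges = IRanges::IRanges(start = t$start, end = t$end),
      strand = t$strand)
    gr$type <- "gene"
    gr$source <- "nigontools"
    gr$ID <- t$gene_id
    gr$Name <- t$gene_id
    p <- file.path(out_dir, paste0(sp, ".gff3"))
    rtracklayer::export(gr, p, format = "gff3")
    paths$gff3 <- c(paths$gff3, setNames(p, sp))
  }

  og <- orthogroup_table(genomes)
  paths$orthogroups <- file.path(out_dir, "orthogroups.tsv")
  write.table(og, paths$orthogroups, sep = "\t", quote = FALSE,
              row.names = FALSE)

  scafs <- do.call(rbind, lapply(names(genomes$species), function(sp) {
    chroms <- unique(genomes$species[[sp]]$chromosome)
    data.frame(species = sp, scaffold = chroms, chromosome_unit = chroms,
               order_index = 1L, stringsAsFactors = FALSE)
  }))
  paths$alias <- file.path(out_dir, "alias.tsv")
  write.table(scafs, paths$alias, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$truth <- file.path(out_dir, "truth.tsv")
  write.table(genomes$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Simulate an ortholog-by-species chromosomal allocation matrix directly
#'
#' Convenience wrapper that realizes genomes from a history and collates the
#' chromosome label of each ortholog in each species, optionally perturbing
#' a fraction of placements (reassignment to a random other chromosome of
#' the same species) and dropping a fraction as missing. The ground-truth
#' element of every ortholog is attached as attribute `truth`.
#'
#' @param history A `nigon_history`.
#' @param genes_per_element Genes per ancestral element.
#' @param noise Fraction of non-missing cells reassigned to a random wrong
#'   chromosome (placement noise), in `[0, 1)`.
#' @param missing_rate Per-cell probability of a missing placement.
#' @param seed Optional integer seed.
#' @return A `nigon_alloc` character matrix (orthologs x species, `NA` for
#'   missing) with attribute `truth` (named element vector over rows).
#' @export
simulate_allocation_matrix <- function(history, genes_per_element = 100,
                                       noise = 0, missing_rate = 0,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genomes <- realize_genomes(history, genes_per_element,
                             loss_rate = missing_rate)
  ogs <- names(genomes$orthogroup_elements)
  species <- names(genomes$species)
  M <- matrix(NA_character_, length(ogs), length(species),
              dimnames = list(ogs, species))
  for (sp in species) {
    t <- genomes$species[[sp]]
    one <- t[!duplicated(t$orthogroup) & !(t$orthogroup %in%
              t$orthogroup[duplicated(t$orthogroup)]), ]
    M[one$orthogroup, sp] <- one$chromosome
  }
  if (noise > 0) {
    for (sp in species) {
      chroms <- unique(genomes$species[[sp]]$chromosome)
      if (length(chroms) < 2) next
      placed <- which(!is.na(M[, sp]))
      hit <- placed[runif(length(placed)) < noise]
      for (i in hit) {
        M[i, sp] <- sample(setdiff(chroms, M[i, sp]), 1L)
      }
    }
  }
  out <- new_allocation_matrix(M)
  attr(out, "truth") <- genomes$orthogroup_elements
  out
}

#' Preset describing the collapsed ribosomal RNA cistron repeat
#'
#' Parameters of the collapsed rRNA repeat used by the gap-sizing and
#' copy-number operations: a 6,848 bp repeat unit present in 117 copies, of
#' which 111 are missing from the assembled sequence and are represented by
#' an N-run gap of 760,128 characters.
#'
#' @return Named list with `unit_len_bp`, `copies`, `extra_copies`,
#'   `gap_n_chars`.
#' @export
nigon_preset_rrna <- function() {
  list(unit_len_bp = 6848L, copies = 117L, extra_copies = 111L,
       gap_n_chars = 760128L)
}

#' Simulate a per-base sequencing depth track with a collapsed repeat
#'
#' Draws Poisson per-base depths at `background_mean`, elevated by factor
#' `ratio` inside the repeat interval — the signature of a tandem repeat
#' collapsed to a single copy in an assembly.
#'
#' @param length_bp Track length.
#' @param background_mean Mean background depth (> 0).
#' @param repeat_start,repeat_end 1-based inclusive bounds of the collapsed
#'   repeat interval.
#' @param ratio True copy-number ratio of repeat to background depth.
#' @param seed Optional integer seed.
#' @return List with `depth` (integer vector), `repeat_interval`, and
#'   `background_intervals` (flanks).
#' @export
sim_depth_track <- function(length_bp = 1e5, background_mean = 30,
                            repeat_start = 50001, repeat_end = 56848,
                            ratio = 117, seed = NULL) {
  .assert(background_mean > 0, "background_mean must be > 0")
  .assert(repeat_start >= 1 && repeat_end <= length_bp &&
            repeat_start <= repeat_end, "repeat interval out of range")
  if (!is.null(seed)) set.seed(seed)
  lambda <- rep(background_mean, length_bp)
  lambda[repeat_start:repeat_end] <- background_mean * ratio
  bg <- list()
  if (repeat_start > 1) bg <- c(bg, list(c(1, repeat_start - 1)))
  if (repeat_end < length_bp) bg <- c(bg, list(c(repeat_end + 1, length_bp)))
  list(depth = rpois(length_bp, lambda),
       repeat_interval = c(repeat_start, repeat_end),
       background_intervals = bg)
}
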