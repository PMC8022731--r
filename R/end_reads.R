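# Simulation of chromosome-end long reads drawn from a two-form
# (short/long) telomere mixture, emitting FASTA + SAM with soft-clipped
# telomeric tails at the planted addition sites.

#' Configuration for chromosome-end read simulation
#'
#' The reference chromosome end is built left-arm style as
#' `[external telomere][subtelomeric extension][core]`. Short-form
#' chromosome copies lack the extension and carry telomeric repeat added at
#' the internal site (the first core base); long-form copies carry the
#' extension with repeat added at the external site (the first extension
#' base).
#'
#' @param core_len Core (always-present) sequence length in bp.
#' @param extension_len Subtelomeric extension length in bp (must be at
#'   least one motif length).
#' @param telomere_len External telomere repeat length on the reference.
#' @param motif Telomere repeat unit; must be a hexamer (default `TTAGGC`).
#' @param short_form_fraction Fraction of chromosome copies that are
#'   short-form (default 0.8 — the majority form observed at roughly 80%
#'   of coverage depth).
#' @param depth Number of end-spanning reads to simulate.
#' @param read_len_mean,read_len_sd Normal read-length model (bp).
#' @param min_unique Minimum unique (non-telomeric) bases per read, so every
#'   read anchors in unique sequence.
#' @param error_rate Uniform per-base substitution rate applied to the
#'   unique portion of each read.
#' @param noisy_tails If `TRUE`, the error model also mutates telomeric
#'   tails; by default tails are error-free so site detection has an exact
#'   mode.
#' @param chrom_name Reference sequence name.
#' @param seed Optional integer seed; identical seed and configuration give
#'   byte-identical output files.
#' @return List of class `sim_end_config`.
#' @export
sim_end_config <- function(core_len = 20000, extension_len = 5000,
                           telomere_len = 600, motif = "TTAGGC",
                           short_form_fraction = 0.8, depth = 500,
                           read_len_mean = 8000, read_len_sd = 2000,
                           min_unique = 200, error_rate = 0,
                           noisy_tails = FALSE, chrom_name = "chrEnd",
                           seed = NULL) {
  .assert(nchar(motif) == 6, "telomere motif must be a hexamer")
  .assert(short_form_fraction >= 0 && short_form_fraction <= 1,
          "short_form_fraction must be in [0, 1]")
  .assert(depth > 0, "depth must be > 0")
  .assert(extension_len >= nchar(motif),
          "extension_len must be at least the motif length")
  .assert(core_len >= min_unique, "core_len must be >= min_unique")
  .assert(telomere_len >= 3 * nchar(motif),
          "telomere_len must allow >= 3 motif copies")
  structure(as.list(environment()), class = "sim_end_config")
}

#' Simulate chromosome-end reads from a two-form telomere mixture
#'
#' Writes a reference FASTA (`ref.fasta`), a read FASTA (`reads.fasta`) and
#' a SAM alignment (`reads.sam`) under `out_dir`. Each read represents one
#' chromosome copy: with probability `short_form_fraction` it is
#' short-form, aligning from the internal addition site with its telomeric
#' tail soft-clipped there; otherwise long-form, aligning from the external
#' addition site. Planted site coordinates are returned as ground truth
#' using the same convention as [detect_addition_sites()] (first aligned
#' base adjacent to the clipped repeat).
#'
#' @param cfg A [sim_end_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `paths` (ref, reads, sam), `truth` (internal_site,
#'   external_site, n_short, n_long, short_fraction_realized), and `cfg`.
#' @examples
#' \dontrun{
#' sim <- simulate_end_reads(sim_end_config(depth = 100, seed = 1), tempdir())
#' detect_addition_sites(sim$paths$sam)
#' }
#' @export
simulate_end_reads <- function(cfg, out_dir) {
  .assert(inherits(cfg, "sim_end_config"), "`cfg` must be a sim_end_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  mlen <- nchar(cfg$motif)
  telo_len <- (cfg$telomere_len %/% mlen) * mlen
  extension <- .random_dna(cfg$extension_len)
  core <- .random_dna(cfg$core_len)
  ref <- paste0(.repeat_tail(cfg$motif, telo_len), extension, core)
  external_site <- telo_len + 1L                      # first extension base
  internal_site <- telo_len + cfg$extension_len + 1L  # first core base
  ref_len <- nchar(ref)
  unique_from_external <- paste0(extension, core)

  n <- cfg$depth
  short <- runif(n) < cfg$short_form_fraction
  qnames <- sprintf("read%05d", seq_len(n))

  fasta <- character(2 * n)
  sam <- character(n)
  for (i in seq_len(n)) {
    tail_len <- (sample(3:(telo_len %/% mlen), 1L)) * mlen
    rl <- max(cfg$min_unique + tail_len,
              round(rnorm(1, cfg$read_len_mean, cfg$read_len_sd)))
    avail <- if (short[i]) cfg$core_len else nchar(unique_from_external)
    ulen <- min(rl - tail_len, avail)
    ulen <- max(ulen, cfg$min_unique)
    uniq <- if (short[i]) substr(core, 1L, ulen)
            else substr(unique_from_external, 1L, ulen)
    uniq <- .mutate_dna(uniq, cfg$error_rate)
    tail_seq <- .repeat_tail(cfg$motif, tail_len)
    if (cfg$noisy_tails) tail_seq <- .mutate_dna(tail_seq, cfg$error_rate)
    seq <- paste0(tail_seq, uniq)
    pos <- if (short[i]) internal_site else external_site
    cigar <- sprintf("%dS%dM", tail_len, ulen)
    fasta[2 * i - 1] <- paste0(">", qnames[i])
    fasta[2 * i] <- seq
    sam[i] <- paste(qnames[i], 0L, cfg$chrom_name, pos, 60L, cigar,
                    "*", 0L, 0L, seq, "*", sep = "\t")
  }

  paths <- list(ref = file.path(out_dir, "ref.fasta"),
                reads = file.path(out_dir, "reads.fasta"),
                sam = file.path(out_dir, "reads.sam"))
  writeLines(c(paste0(">", cfg$chrom_name), ref), paths$ref)
  writeLines(fasta, paths$reads)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom_name, ref_len),
               sam), paths$sam)

  list(paths = paths,
       truth = list(internal_site = internal_site,
                    external_site = external_site,
                    n_short = sum(short), n_long = sum(!short),
                    short_fraction_realized = mean(short)),
       cfg = cfg)
}
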