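# Telomere-repeat scanning, addition-site detection from soft-clipped
# long-read alignments, and the extension/gap/copy-number arithmetic that
# characterises short- and long-form chromosome ends.

#' Telomere analysis configuration
#'
#' @param motif Telomere repeat unit (default nematode `TTAGGC`).
#' @param min_tandem Minimum tandem motif copies for a run or clip to count
#'   as telomeric (default 3).
#' @param max_mismatch Maximum mismatch fraction tolerated in a clipped
#'   telomeric tail (default 0.1).
#' @param min_site_support Minimum supporting reads per reported addition
#'   site (default 5).
#' @param cluster_radius Sites within this many bp are merged (default 5).
#' @param min_anchor Minimum aligned reference span (bp) required for a read
#'   to anchor a clip in unique sequence (default 50).
#' @return List of class `telomere_config`.
#' @export
telomere_config <- function(motif = "TTAGGC", min_tandem = 3,
                            max_mismatch = 0.1, min_site_support = 5,
                            cluster_radius = 5, min_anchor = 50) {
  .assert(nchar(motif) >= 2, "motif must have length >= 2")
  .assert(min_tandem >= 1 && min_site_support >= 1 && cluster_radius >= 0 &&
            min_anchor >= 0, "thresholds must be positive")
  .assert(max_mismatch >= 0 && max_mismatch < 1, "max_mismatch must be in [0,1)")
  structure(list(motif = toupper(motif), min_tandem = min_tandem,
                 max_mismatch = max_mismatch,
                 min_site_support = min_site_support,
                 cluster_radius = cluster_radius, min_anchor = min_anchor),
            class = "telomere_config")
}

#' Scan sequences for tandem telomere-repeat runs
#'
#' Finds maximal exact tandem runs of the motif (plus-strand) and of its
#' reverse complement (minus-strand) with at least `min_tandem` copies, and
#' summarises motif-copy counts in fixed windows.
#'
#' @param x A [Biostrings::DNAStringSet] or FASTA path.
#' @param cfg A [telomere_config()].
#' @param track_window_bp Window width of the per-window copy-count track
#'   (default 10 kb).
#' @return List with `intervals` (data.frame `seqname`, `start`, `end`,
#'   `strand`, `copies`) and `track` (`seqname`, `window_start`,
#'   `window_end`, `count` of motif copies starting in the window).
#' @export
scan_telomere_repeats <- function(x, cfg = telomere_config(),
                                  track_window_bp = 10000) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
    names(x) <- sub("\\s.*", "", names(x))
  }
  .assert(inherits(x, "DNAStringSet"), "input must be a DNAStringSet or FASTA path")
  motifs <- c(`+` = cfg$motif, `-` = .revcomp(cfg$motif))
  mlen <- nchar(cfg$motif)

  rows <- list()
  for (i in seq_along(x)) {
    s <- as.character(x[[i]])
    nm <- names(x)[i] %||% as.character(i)
    for (strand in names(motifs)) {
      pat <- sprintf("(?:%s){%d,}", motifs[[strand]], cfg$min_tandem)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = nm, start = as.integer(m), end = as.integer(m) + len - 1L,
        strand = strand, copies = len %/% mlen, stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqname = character(0), start = integer(0), end = integer(0),
               strand = character(0), copies = integer(0))
  rownames(intervals) <- NULL
  intervals <- intervals[order(intervals$seqname, intervals$start), ]

  track <- do.call(rbind, lapply(seq_along(x), function(i) {
    nm <- names(x)[i] %||% as.character(i)
    len <- Biostrings::width(x)[i]
    starts <- seq(1L, len, by = track_window_bp)
    cnt <- integer(length(starts))
    sub <- intervals[intervals$seqname == nm, , drop = FALSE]
    if (nrow(sub)) {
      pos <- unlist(lapply(seq_len(nrow(sub)), function(j)
        sub$start[j] + (seq_len(sub$copies[j]) - 1L) * mlen))
      tb <- table((pos - 1L) %/% track_window_bp + 1L)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    data.frame(seqname = nm, window_start = starts,
               window_end = pmin(starts + track_window_bp - 1L, len),
               count = cnt, stringsAsFactors = FALSE)
  }))
  rownames(track) <- NULL
  list(intervals = intervals, track = track)
}

# Mismatch fraction of `s` against the best-phase tandem repeat of any of
# the given motifs (forward and reverse complement are passed separately).
.periodic_mismatch <- function(s, motifs) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  best <- 1
  for (motif in motifs) {
    m <- nchar(motif)
    mv <- strsplit(motif, "")[[1]]
    for (p in seq_len(m) - 1L) {
      expect <- mv[((seq_len(n) - 1L + p) %% m) + 1L]
      best <- min(best, sum(ch != expect) / n)
    }
  }
  best
}

# Is a soft-clipped tail telomeric under the config?
.clip_is_telomeric <- function(s, cfg) {
  if (nchar(s) < cfg$min_tandem * nchar(cfg$motif)) return(FALSE)
  .periodic_mismatch(toupper(s), c(cfg$motif, .revcomp(cfg$motif))) <=
    cfg$max_mismatch
}

# Cluster sorted positions: split where the gap exceeds the radius; the
# cluster position is the modal coordinate (ties -> smallest).
.cluster_positions <- function(pos, radius) {
  pos <- sort(pos)
  grp <- cumsum(c(1L, as.integer(diff(pos) > radius)))
  lapply(split(pos, grp), function(p) {
    tb <- table(p)
    list(position = as.integer(names(tb)[which.max(tb)]), support = length(p))
  })
}

#' Detect telomere-repeat addition sites from soft-clipped alignments
#'
#' Reads a SAM file of long-read alignments against a chromosome-end
#' reference and locates the reference coordinates at which telomeric
#' repeat begins. A read contributes a candidate site when its soft-clipped
#' tail is telomeric (at least `min_tandem` motif copies at no more than
#' `max_mismatch` mismatch fraction against the best-phase tandem repeat of
#' the motif or its reverse complement) and its aligned block spans at
#' least `min_anchor` bp of reference. Leading clips yield left-arm sites
#' at the first aligned base; trailing clips yield right-arm sites at the
#' last aligned base. Candidate coordinates are clustered within
#' `cluster_radius` bp; clusters with at least `min_site_support` reads are
#' reported, with support fractions relative to all telomere-bearing reads
#' on that chromosome arm. When an arm carries more than one site, the one
#' nearest the chromosome midpoint is designated `internal` and the one
#' farthest `external` (others `intermediate`); single-site arms get `NA`.
#'
#' @param sam Path to a SAM file with `@SQ` reference lengths in the header.
#' @param cfg A [telomere_config()].
#' @return data.frame of class `nigon_sites`: `chromosome`, `arm` (`L`/`R`),
#'   `position`, `support`, `fraction`, `designation`; attribute
#'   `total_reads` (telomere-bearing reads per chromosome arm). Empty, with
#'   a warning, when no telomere-bearing reads are found.
#' @export
detect_addition_sites <- function(sam, cfg = telomere_config()) {
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  .assert(length(targets) > 0, "SAM header lacks @SQ reference lengths")
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "seq"))
  .assert(length(aln) > 0, "no alignments in %s", sam)

  cig <- GenomicAlignments::cigar(aln)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  seqs <- S4Vectors::mcols(aln)$seq
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  starts <- GenomicAlignments::start(aln)
  chroms <- as.character(GenomicAlignments::seqnames(aln))

  cand <- list()
  for (i in seq_along(aln)) {
    if (refw[i] < cfg$min_anchor) next
    o <- ops[[i]]; l <- lens[[i]]
    qlen <- sum(l[o %in% c("M", "I", "S", "=", "X")])
    if (o[1] == "S") {
      clip <- as.character(Biostrings::subseq(seqs[[i]], 1L, l[1]))
      if (.clip_is_telomeric(clip, cfg)) {
        cand[[length(cand) + 1L]] <-
          data.frame(chromosome = chroms[i], arm = "L",
                     position = starts[i], stringsAsFactors = FALSE)
      }
    }
    if (length(o) > 1 && o[length(o)] == "S") {
      clip <- as.character(Biostrings::subseq(
        seqs[[i]], qlen - l[length(l)] + 1L, qlen))
      if (.clip_is_telomeric(clip, cfg)) {
        cand[[length(cand) + 1L]] <-
          data.frame(chromosome = chroms[i], arm = "R",
                     position = starts[i] + refw[i] - 1L,
                     stringsAsFactors = FALSE)
      }
    }
  }

  empty_sites <- function(totals = NULL) {
    out <- data.frame(chromosome = character(0), arm = character(0),
                      position = integer(0), support = integer(0),
                      fraction = numeric(0), designation = character(0))
    attr(out, "total_reads") <- totals
    class(out) <- c("nigon_sites", "data.frame")
    out
  }
  if (!length(cand)) {
    warning("no telomere-bearing reads found", call. = FALSE)
    return(empty_sites())
  }
  cand <- do.call(rbind, cand)

  out <- list()
  totals <- list()
  for (key in unique(paste(cand$chromosome, cand$arm))) {
    sub <- cand[paste(cand$chromosome, cand$arm) == key, ]
    chrom <- sub$chromosome[1]; arm <- sub$arm[1]
    total <- nrow(sub)
    totals[[key]] <- total
    cl <- .cluster_positions(sub$position, cfg$cluster_radius)
    cl <- Filter(function(c) c$support >= cfg$min_site_support, cl)
    if (!length(cl)) next
    df <- data.frame(
      chromosome = chrom, arm = arm,
      position = vapply(cl, `[[`, integer(1), "position"),
      support = vapply(cl, `[[`, integer(1), "support"),
      stringsAsFactors = FALSE)
    df$fraction <- df$support / total
    mid <- unname(targets[chrom]) / 2
    if (nrow(df) == 1) {
      df$designation <- NA_character_
    } else {
      dist_mid <- abs(df$position - mid)
      df$designation <- "intermediate"
      df$designation[which.min(dist_mid)] <- "internal"
      df$designation[which.max(dist_mid)] <- "external"
    }
    out[[key]] <- df[order(df$position), ]
  }
  if (!length(out)) return(empty_sites(unlist(totals)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "total_reads") <- unlist(totals)
  class(res) <- c("nigon_sites", "data.frame")
  res
}

#' Subtelomeric extension spans from addition-site coordinates
#'
#' Recomputes extension spans from per-arm coordinate pairs using the
#' arm-dependent convention of chromosome-end coordinate tables: on a left
#' arm the extension occupies `[external_addition_site,
#' extension_start_site]` so `span = start - site + 1` and the external
#' telomere repeat spans `site - 1` bp; on a right arm
#' `span = start - site`, and the external repeat span (which requires the
#' full chromosome length) is taken from input, not derived. The
#' `extension_start_site` is the internal site — the coordinate at which
#' telomeric repeat is added in short-form chromosomes.
#'
#' @param x data.frame with columns `chromosome`, `arm` (`"L"`/`"R"`),
#'   `extension_start_site`, `external_addition_site`, and optionally
#'   `external_repeat_span` (right arms).
#' @return data.frame of class `nigon_extensions`: input columns plus
#'   `extension_span` and `external_repeat_span`.
#' @examples
#' compute_extension_spans(data.frame(
#'   chromosome = "Otip_I", arm = "L",
#'   extension_start_site = 27184, external_addition_site = 10363))
#' @export
compute_extension_spans <- function(x) {
  .assert(all(c("chromosome", "arm", "extension_start_site",
                "external_addition_site") %in% names(x)),
          "need chromosome, arm, extension_start_site, external_addition_site")
  .assert(all(x$arm %in% c("L", "R")), "arm must be L or R")
  .assert(all(x$extension_start_site != x$external_addition_site),
          "degenerate arm: internal and external sites coincide")
  left <- x$arm == "L"
  span <- ifelse(left,
                 x$extension_start_site - x$external_addition_site + 1,
                 x$extension_start_site - x$external_addition_site)
  .assert(all(span > 0), "non-positive extension span; check site columns")
  repeat_span <- ifelse(left, x$external_addition_site - 1,
                        if (!is.null(x$external_repeat_span))
                          x$external_repeat_span else NA_real_)
  out <- data.frame(chromosome = x$chromosome, arm = x$arm,
                    extension_span = span,
                    extension_start_site = x$extension_start_site,
                    external_addition_site = x$external_addition_site,
                    external_repeat_span = repeat_span,
                    stringsAsFactors = FALSE)
  class(out) <- c("nigon_extensions", "data.frame")
  out
}

#' Size the N-run gap representing a collapsed tandem repeat
#'
#' A repeat collapsed in an assembly is represented by a gap of
#' `extra_copies * unit_len_bp` N characters.
#'
#' @param extra_copies Number of repeat copies missing from the assembly
#'   (>= 0).
#' @param unit_len_bp Repeat unit length in bp (> 0).
#' @return Integer N-run length.
#' @examples
#' size_collapsed_repeat_gap(111, 6848)  # 760128
#' @export
size_collapsed_repeat_gap <- function(extra_copies, unit_len_bp) {
  .assert(is.numeric(extra_copies) && extra_copies >= 0,
          "extra_copies must be >= 0")
  .assert(is.numeric(unit_len_bp) && unit_len_bp > 0,
          "unit_len_bp must be > 0")
  as.integer(round(extra_copies) * round(unit_len_bp))
}

#' Splice an N-run gap into a FASTA sequence
#'
#' Inserts `n` N characters immediately after position `at` of sequence
#' `seqname`, writing the result to `fasta_out`.
#'
#' @param fasta_in,fasta_out Input/output FASTA paths.
#' @param seqname Sequence to modify.
#' @param at 1-based position after which the gap is inserted.
#' @param n Number of N characters (e.g. from
#'   [size_collapsed_repeat_gap()]).
#' @return `fasta_out`, invisibly.
#' @export
splice_gap_fasta <- function(fasta_in, fasta_out, seqname, at, n) {
  seqs <- Biostrings::readDNAStringSet(fasta_in)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  .assert(seqname %in% names(seqs), "sequence %s not in %s", seqname, fasta_in)
  s <- seqs[[seqname]]
  .assert(at >= 0 && at <= length(s), "`at` out of range")
  seqs[[seqname]] <- Biostrings::xscat(
    Biostrings::subseq(s, 1L, at),
    Biostrings::DNAString(strrep("N", n)),
    if (at < length(s)) Biostrings::subseq(s, at + 1L, length(s))
    else Biostrings::DNAString(""))
  Biostrings::writeXStringSet(seqs, fasta_out)
  invisible(fasta_out)
}

#' Estimate collapsed-repeat copy number from read depth
#'
#' Divides mean read depth over the repeat interval by the mean depth over
#' background intervals and scales by the number of copies present in the
#' assembly.
#'
#' @param depth Per-base depth: numeric vector or the `depth` element of
#'   [sim_depth_track()].
#' @param repeat_interval Length-2 vector `c(start, end)` (1-based
#'   inclusive).
#' @param background_intervals List of length-2 vectors excluding the
#'   repeat.
#' @param collapsed_copies Copies present in the assembled sequence
#'   (default 1).
#' @return List with `copies` (rounded estimate) and `ratio` (unrounded
#'   depth ratio).
#' @export
estimate_repeat_copies <- function(depth, repeat_interval,
                                   background_intervals,
                                   collapsed_copies = 1) {
  .assert(is.numeric(depth) && length(depth) > 0, "empty depth track")
  ri <- repeat_interval
  .assert(length(ri) == 2 && ri[1] >= 1 && ri[2] <= length(depth) &&
            ri[1] <= ri[2], "repeat interval out of range")
  bg <- unlist(lapply(background_intervals, function(iv) {
    .assert(length(iv) == 2 && iv[1] >= 1 && iv[2] <= length(depth),
            "background interval out of range")
    depth[iv[1]:iv[2]]
  }))
  .assert(length(bg) > 0 && mean(bg) > 0, "zero background depth")
  ratio <- mean(depth[ri[1]:ri[2]]) / mean(bg)
  list(copies = as.integer(round(ratio) * collapsed_copies), ratio = ratio)
}
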