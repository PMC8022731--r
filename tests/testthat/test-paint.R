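# Chromosome painting, RBH projection, neighborhood divergence and
# feature-density tracks.

mk_assignment <- function(orthogroups, elements) {
  structure(data.frame(orthogroup = orthogroups, cluster = 1L,
                       agreement = 9L, element = elements,
                       stringsAsFactors = FALSE),
            class = c("nigon_assignment", "data.frame"))
}

test_that("loci are binned into 0.5 Mb windows by start coordinate", {
  asn <- mk_assignment(paste0("og", 1:4), c("A", "A", "A", "B"))
  loci <- data.frame(species = "sp", chromosome = "chr1",
                     start = c(1, 2, 499999, 500001),
                     orthogroup = paste0("og", 1:4))
  pt <- paint_chromosomes(asn, loci)
  expect_equal(pt$window_start, c(1, 500001))
  expect_equal(pt$window_end, c(500000, 1000000))
  expect_equal(pt$A, c(3L, 0L))
  expect_equal(pt$B, c(0L, 1L))

  # declared chromosome length truncates the last window and bounds starts
  pt2 <- paint_chromosomes(asn, loci, chrom_lengths = c(chr1 = 700000))
  expect_equal(pt2$window_end, c(500000, 700000))
  expect_error(paint_chromosomes(asn, loci, chrom_lengths = c(chr1 = 400000)),
               "beyond")
})

test_that("painting conserves labeled locus counts per chromosome", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 200
    loci <- data.frame(
      species = "sp",
      chromosome = sample(c("c1", "c2", "c3"), n, replace = TRUE),
      start = sample.int(3e6, n), orthogroup = paste0("og", 1:n))
    asn <- mk_assignment(paste0("og", 1:n),
                         sample(c("A", "B", "X", "UNASSIGNED"), n, TRUE))
    pt <- paint_chromosomes(asn, loci)
    cols <- setdiff(names(pt), c("species", "chromosome",
                                 "window_start", "window_end"))
    for (chrom in unique(loci$chromosome)) {
      expect_equal(sum(pt[pt$chromosome == chrom, cols]),
                   sum(loci$chromosome == chrom))
    }
  }
})

test_that("a recent unmixed fusion paints as two contiguous blocks", {
  h <- nigon_preset_figure6()
  g <- realize_genomes(h, genes_per_element = 60, seed = 15)
  ppa <- g$species$P_pacificus
  truth <- g$orthogroup_elements
  asn <- mk_assignment(names(truth), unname(truth))
  chr1 <- ppa[ppa$chromosome == "chrI", ]
  pt <- paint_chromosomes(asn, chr1, window_bp = 50000)
  el_cols <- intersect(c("A", "N"), names(pt))
  purity <- apply(pt[rowSums(pt[el_cols]) > 0, el_cols], 1,
                  function(r) max(r) / sum(r))
  expect_gte(mean(purity >= 0.95), 0.95)
  # A precedes N along the fused chromosome
  firstN <- min(which(pt$N > 0))
  lastA <- max(which(pt$A > 0))
  expect_lte(lastA, firstN)
})

test_that("RBH projection keeps mutual best hits under the e-value ceiling", {
  ab <- data.frame(
    qseqid = c("q1", "q1", "q2", "q3"),
    sseqid = c("r1", "r2", "r2", "r3"),
    pident = 90, length = 100, mismatch = 5, gapopen = 0,
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-8, 1e-3, 1e-9, 1e-5), bitscore = c(200, 50, 220, 80))
  ba <- data.frame(
    qseqid = c("r1", "r2", "r3"),
    sseqid = c("q1", "q2", "q3"),
    pident = 90, length = 100, mismatch = 5, gapopen = 0,
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-8, 1e-9, 1e-5), bitscore = c(200, 220, 80))
  ref <- c(r1 = "A", r2 = "B", r3 = "C")
  proj <- project_labels_rbh(ab, ba, ref)
  # q3/r3 rejected: e-value 1e-5 is not below 1e-6
  expect_equal(proj$query, c("q1", "q2"))
  expect_equal(proj$element, c("A", "B"))
})

test_that("RBH pairing is symmetric in its two inputs", {
  set.seed(16)
  genes_a <- paste0("a", 1:20); genes_b <- paste0("b", 1:20)
  mk <- function(q, s) data.frame(
    qseqid = q, sseqid = s, pident = 90, length = 100, mismatch = 0,
    gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = 10^-sample(7:40, length(q), replace = TRUE),
    bitscore = sample(100:300, length(q), replace = TRUE))
  ab <- mk(rep(genes_a, each = 3), sample(genes_b, 60, replace = TRUE))
  ba <- mk(rep(genes_b, each = 3), sample(genes_a, 60, replace = TRUE))
  ref <- setNames(rep("A", 20), genes_b)
  fwd <- project_labels_rbh(ab, ba, ref)
  rev <- project_labels_rbh(ba, ab, setNames(rep("A", 20), genes_a))
  expect_setequal(paste(fwd$query, fwd$reference),
                  paste(rev$reference, rev$query))
})

test_that("scaffold length breaks exact ties among query proteins", {
  mkrow <- function(q, s, e, b) data.frame(
    qseqid = q, sseqid = s, pident = 90, length = 100, mismatch = 0,
    gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = e, bitscore = b)
  # reference r1's two candidate partners tie on e-value and bit score
  ba <- rbind(mkrow("r1", "qLong", 1e-10, 200), mkrow("r1", "qShort", 1e-10, 200))
  ab <- rbind(mkrow("qLong", "r1", 1e-10, 200), mkrow("qShort", "r1", 1e-10, 200))
  scaffold_of <- c(qLong = "scafL", qShort = "scafS", r1 = "ref1")
  scaffold_lengths <- c(scafL = 5e6, scafS = 1e4, ref1 = 1e6)
  proj <- project_labels_rbh(ab, ba, c(r1 = "A"),
                             scaffold_of = scaffold_of,
                             scaffold_lengths = scaffold_lengths)
  expect_equal(proj$query, "qLong")
})

test_that("malformed BLAST tabular lines are reported by line number", {
  f <- tempfile()
  writeLines(c(paste(c("q1", "r1", 90, 100, 0, 0, 1, 100, 1, 100, "1e-9", 200),
                     collapse = "\t"),
               "q2\tr2\tbroken"), f)
  expect_error(project_labels_rbh(f, f, c(r1 = "A")), "line 2")
})

test_that("neighborhood divergence is exact on identical genomes", {
  set.seed(17)
  loci <- data.frame(gene_id = paste0("g", 1:30),
                     chromosome = rep(c("c1", "c2"), each = 15),
                     start = rep(sort(sample.int(3e5, 15)), 2) +
                       rep(c(0, 5e5), each = 15))
  pairs <- data.frame(ref_gene = loci$gene_id, query_gene = loci$gene_id)
  rep_ <- neighborhood_divergence(pairs, loci, loci, max_sep = 1e9)
  expect_equal(rep_$rho, c(1, 1))
  expect_equal(rep_$m, c(0L, 0L))
})

test_that("reference pairs beyond 50 kb are excluded and counted", {
  loci_ref <- data.frame(gene_id = paste0("g", 1:5), chromosome = "c1",
                         start = c(1, 10000, 20000, 90000, 100000))
  loci_q <- data.frame(gene_id = paste0("h", 1:5), chromosome = "q1",
                       start = c(1, 12000, 22000, 93000, 101000))
  pairs <- data.frame(ref_gene = paste0("g", 1:5),
                      query_gene = paste0("h", 1:5))
  rep_ <- neighborhood_divergence(pairs, loci_ref, loci_q)
  # the 20 kb -> 90 kb gap (70 kb) is the single excluded pair
  expect_equal(rep_$n, 4L)
  expect_equal(rep_$m, 1L)
})

test_that("operon genes are dropped before pairing", {
  loci_ref <- data.frame(gene_id = paste0("g", 1:4), chromosome = "c1",
                         start = c(1000, 2000, 3000, 4000))
  loci_q <- data.frame(gene_id = paste0("h", 1:4), chromosome = "q1",
                       start = c(1000, 2000, 3000, 4000))
  pairs <- data.frame(ref_gene = paste0("g", 1:4),
                      query_gene = paste0("h", 1:4))
  rep_ <- neighborhood_divergence(pairs, loci_ref, loci_q,
                                  operon_genes = c("g2", "g3"))
  expect_equal(rep_$n, 1L)  # only the g1-g4 pair remains
})

test_that("shuffled gene order shows no neighborhood correlation", {
  h <- simulate_history("(ref,query);", n_elements = 1, events = list(
    list(branch = "query", kind = "shuffle", chrom = "chrA")))
  rhos <- vapply(1:20, function(s) {
    g <- realize_genomes(h, genes_per_element = 80, spacing_jitter = 0.8,
                         seed = s)
    ref <- g$species$ref; q <- g$species$query
    pairs <- data.frame(ref_gene = ref$gene_id,
                        query_gene = paste0("query_", ref$orthogroup))
    out <- neighborhood_divergence(pairs, ref, q, max_sep = 1e9)
    out$rho
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.2)
})

test_that("GC and interval densities follow their definitions", {
  seqs <- Biostrings::DNAStringSet(c(w1 = "GGCCATAT"))
  gc <- feature_density(seqs, window_bp = 4)
  expect_equal(gc$gc, c(1, 0))
  # ambiguous bases leave the denominator
  gcn <- feature_density(Biostrings::DNAStringSet(c(x = "GCNN")), 4)
  expect_equal(gcn$gc, 1)

  iv <- data.frame(chromosome = "c1", start = 1, end = 250000)
  cov <- feature_density(iv, window_bp = 500000,
                         chrom_lengths = c(c1 = 500000))
  expect_equal(cov$coverage, 0.5)
})

test_that("per-window GC is invariant under reverse complement", {
  set.seed(18)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
             collapse = "")
  fwd <- feature_density(Biostrings::DNAStringSet(c(chr = s)), 1000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev_ <- feature_density(Biostrings::DNAStringSet(c(chr = rc)), 1000)
  expect_equal(fwd$gc, rev(rev_$gc))
})
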