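# Independent oracles and fixture builders used across the suite.

# Brute-force Dice similarity for two rows of an allocation matrix.
oracle_dice_pair <- function(vi, vj) {
  ni <- sum(!is.na(vi))
  nj <- sum(!is.na(vj))
  a <- 0L
  for (s in seq_along(vi)) {
    if (!is.na(vi[s]) && !is.na(vj[s]) && vi[s] == vj[s]) a <- a + 1L
  }
  2 * a / (ni + nj)
}

# Exhaustive k-medoids optimum by enumerating every medoid set.
oracle_kmedoids_cost <- function(d, k) {
  n <- nrow(d)
  combos <- utils::combn(n, k)
  best <- Inf
  for (i in seq_len(ncol(combos))) {
    med <- combos[, i]
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# O(n^2) silhouette widths by direct looping over the definition.
oracle_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- Inf
    for (c in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == c]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Random metric distance matrix: Euclidean distances of points in the plane.
random_distance <- function(n) {
  pts <- cbind(runif(n), runif(n))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("p", seq_len(n)), paste0("p", seq_len(n)))
  d
}

# Points around `k` well-separated centers in 1-D; returns distance + labels.
separated_clusters <- function(k = 3, per = 5, gap = 100) {
  x <- unlist(lapply(seq_len(k), function(c) c * gap + runif(per)))
  labels <- rep(seq_len(k), each = per)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("p", seq_along(x)), paste0("p", seq_along(x)))
  list(d = d, labels = labels)
}

# Write a minimal SAM file from a record data.frame
# (qname, flag, rname, pos, cigar, seq).
write_sam <- function(records, ref_name, ref_len, path = tempfile(fileext = ".sam")) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len),
             apply(records, 1, function(r) {
               paste(r[["qname"]], r[["flag"]], r[["rname"]], r[["pos"]], 60,
                     r[["cigar"]], "*", 0, 0, r[["seq"]], "*", sep = "\t")
             }))
  writeLines(lines, path)
  path
}

# Minimal GFF3 writer for gene features.
write_gff3 <- function(df, path = tempfile(fileext = ".gff3"),
                       type = "gene") {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     df$chromosome, type, df$start, df$end,
                     df$strand %||% "+", df$gene_id))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Anchor list (element -> ortholog IDs) built from simulator truth, using a
# few orthologs per element.
truth_anchors <- function(truth, n_per_element = 3) {
  split(names(truth), unname(truth)) |>
    lapply(function(ids) head(ids, n_per_element))
}
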