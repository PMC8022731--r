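#' Dice colocation similarity between orthologs
#'
#' For orthologs i and j placed on chromosomes across species, the Dice
#' similarity is `2a / (n_i + n_j)`, where `n_i` is the number of species in
#' which i has a placement and `a` the number of species in which both are
#' placed on the same chromosome. A pair found on the same chromosome in all
#' species scores 1; a pair on different chromosomes in all species scores
#' 0. The companion distance is `1 - similarity`.
#'
#' @param alloc A `nigon_alloc` allocation matrix (or plain character matrix
#'   with dimnames), `NA` marking missing placements. Orthologs placed in no
#'   species are excluded with a warning.
#' @return Object of class `nigon_dice`: list with symmetric matrices
#'   `similarity` and `distance` and the vector `n_placed`.
#' @examples
#' M <- rbind(o1 = c("chr1", "chr1"), o2 = c("chr1", "chr2"))
#' colnames(M) <- c("sp1", "sp2")
#' dice_similarity(M)$similarity["o1", "o2"]  # 0.5
#' @export
dice_similarity <- function(alloc) {
  M <- unclass(alloc)
  .assert(is.matrix(M) && nrow(M) >= 2, "need an allocation matrix with >= 2 orthologs")
  n_placed <- rowSums(!is.na(M))
  if (any(n_placed == 0)) {
    drop <- rownames(M)[n_placed == 0]
    warning(sprintf("excluding %d ortholog(s) placed in no species: %s",
                    length(drop), paste(head(drop, 5), collapse = ", ")),
            call. = FALSE)
    M <- M[n_placed > 0, , drop = FALSE]
    n_placed <- n_placed[n_placed > 0]
  }
  n <- nrow(M)
  a <- matrix(0, n, n)
  for (s in seq_len(ncol(M))) {
    v <- M[, s]
    eq <- outer(v, v, "==")
    eq[is.na(eq)] <- FALSE
    a <- a + eq
  }
  sim <- (2 * a) / outer(n_placed, n_placed, "+")
  dimnames(sim) <- list(rownames(M), rownames(M))
  # exact symmetry and bounds by construction; enforce on the diagonal
  diag(sim) <- 1
  structure(list(similarity = sim, distance = 1 - sim, n_placed = n_placed),
            class = "nigon_dice")
}

#' @export
print.nigon_dice <- function(x, ...) {
  cat("Dice colocation similarity:", nrow(x$similarity), "orthologs\n")
  invisible(x)
}
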