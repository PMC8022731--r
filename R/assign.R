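#' Assign clustered orthologs to labeled Nigon elements
#'
#' Labels each ortholog's cluster with an ancestral element and retains an
#' ortholog only when at least `min_agree_taxa` species agree on its
#' colocation with the cluster medoid and its cluster holds at least
#' `min_cluster_size` orthologs. Agreement is counted against the cluster
#' medoid: the number of species in which the ortholog and the medoid are
#' both placed, on the same chromosome. Clusters map to element labels by
#' majority vote of anchor orthologs and/or a reference-species chromosome
#' map; the mapping must be injective. Clusters left unlabeled receive
#' synthetic labels `U1, U2, ...`.
#'
#' @param clustering A `nigon_pam` (or `nigon_silscan$best_fit`) covering
#'   every row of `alloc`.
#' @param alloc The `nigon_alloc` allocation matrix that was clustered.
#' @param anchors Cluster labeling evidence: a list with either/both of
#'   \describe{
#'     \item{genes}{named list, element label -> anchor ortholog IDs.}
#'     \item{species, map}{a reference species name plus a named vector
#'       chromosome -> element label; clusters vote by the majority
#'       chromosome of their members in that species.}
#'   }
#'   A plain named list is taken as `genes`.
#' @param min_agree_taxa Minimum agreeing species (default 7).
#' @param min_cluster_size Minimum cluster size for labeling (default 21,
#'   i.e. clusters of more than 20 orthologs).
#' @param agreement One of `"medoid"` (default) or `"majority"`: count
#'   agreement against the cluster medoid, or against the per-species
#'   majority chromosome of the cluster's members.
#' @return Object of class `nigon_assignment`: data.frame with columns
#'   `orthogroup`, `cluster`, `agreement`, `element` (`"UNASSIGNED"` when
#'   thresholds are not met), plus attributes `cluster_labels` and
#'   `cluster_sizes`.
#' @export
assign_elements <- function(clustering, alloc, anchors = NULL,
                            min_agree_taxa = 7, min_cluster_size = 21,
                            agreement = c("medoid", "majority")) {
  agreement <- match.arg(agreement)
  .assert(inherits(clustering, "nigon_pam"), "`clustering` must be a nigon_pam")
  M <- unclass(alloc)
  labs <- clustering$clustering
  .assert(all(rownames(M) %in% names(labs)),
          "clustering does not cover all allocation matrix rows")
  labs <- labs[rownames(M)]
  .assert(min_agree_taxa <= ncol(M),
          "min_agree_taxa exceeds the species roster size")

  k <- clustering$k
  sizes <- tabulate(labs, nbins = k)

  agree <- integer(nrow(M))
  if (agreement == "medoid") {
    med_rows <- match(clustering$medoids, rownames(M))
    .assert(all(!is.na(med_rows)), "medoids missing from allocation matrix")
    for (c in seq_len(k)) {
      members <- which(labs == c)
      if (!length(members)) next
      medv <- M[med_rows[c], ]
      eq <- sweep(M[members, , drop = FALSE], 2, medv, "==")
      eq[is.na(eq)] <- FALSE
      agree[members] <- rowSums(eq)
      # the medoid itself agrees with itself wherever it is placed
      self <- members[members == med_rows[c]]
      if (length(self)) agree[self] <- sum(!is.na(medv))
    }
  } else {
    for (c in seq_len(k)) {
      members <- which(labs == c)
      if (!length(members)) next
      ref <- apply(M[members, , drop = FALSE], 2, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return(NA_character_)
        names(sort(table(col), decreasing = TRUE))[1]
      })
      eq <- sweep(M[members, , drop = FALSE], 2, ref, "==")
      eq[is.na(eq)] <- FALSE
      agree[members] <- rowSums(eq)
    }
  }

  cluster_labels <- .label_clusters(labs, k, rownames(M), M, anchors)

  eligible <- agree >= min_agree_taxa & sizes[labs] >= min_cluster_size
  element <- ifelse(eligible, cluster_labels[labs], "UNASSIGNED")

  out <- data.frame(orthogroup = rownames(M), cluster = as.integer(labs),
                    agreement = agree, element = element,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, cluster_labels = cluster_labels, cluster_sizes = sizes,
            params = list(min_agree_taxa = min_agree_taxa,
                          min_cluster_size = min_cluster_size,
                          agreement = agreement),
            class = c("nigon_assignment", "data.frame"))
}

# Map clusters to element labels via anchor orthologs and/or a reference-
# species chromosome map; unresolved clusters get U1, U2, ...
.label_clusters <- function(labs, k, ortho_ids, M, anchors) {
  labels <- rep(NA_character_, k)
  if (!is.null(anchors)) {
    if (is.null(anchors$genes) && is.null(anchors$map) &&
        is.list(anchors) && !is.null(names(anchors))) {
      anchors <- list(genes = anchors)
    }
    if (!is.null(anchors$genes)) {
      anchor_el <- rep(names(anchors$genes), lengths(anchors$genes))
      anchor_id <- unlist(anchors$genes, use.names = FALSE)
      hit <- anchor_id %in% ortho_ids
      anchor_el <- anchor_el[hit]
      cl <- labs[match(anchor_id[hit], ortho_ids)]
      for (c in seq_len(k)) {
        votes <- table(anchor_el[cl == c])
        if (!length(votes)) next
        top <- votes[votes == max(votes)]
        if (length(top) == 1L) labels[c] <- names(top)
      }
    }
    if (!is.null(anchors$map)) {
      .assert(!is.null(anchors$species) && anchors$species %in% colnames(M),
              "anchors$species must name a column of the allocation matrix")
      refcol <- M[, anchors$species]
      for (c in which(is.na(labels))) {
        chroms <- refcol[labs == c]
        chroms <- chroms[!is.na(chroms)]
        if (!length(chroms)) next
        topc <- names(sort(table(chroms), decreasing = TRUE))[1]
        if (topc %in% names(anchors$map)) labels[c] <- anchors$map[[topc]]
      }
    }
    dup <- unique(labels[!is.na(labels)][duplicated(labels[!is.na(labels)])])
    .assert(length(dup) == 0,
            "anchor evidence labels multiple clusters identically: %s",
            paste(dup, collapse = ", "))
  }
  un <- which(is.na(labels))
  labels[un] <- paste0("U", seq_along(un))
  labels
}

#' @export
print.nigon_assignment <- function(x, ...) {
  tab <- table(x$element)
  cat("Element assignment:", nrow(x), "orthologs;",
      sum(x$element != "UNASSIGNED"), "assigned\n")
  print(tab)
  invisible(x)
}
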