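#' Default Nigon element labels
#'
#' The seven ancestral rhabditid linkage groups: five autosomal elements
#' (A--E), element N, and the X-associated element X.
#' @export
NIGON_ELEMENTS <- c("A", "B", "C", "D", "E", "N", "X")

# A chromosome is an ordered list of blocks; each block is a slice of one
# ancestral element's gene complement, given as fractions [lo, hi) of gene
# rank. A composition is a named list of such block data.frames.
.new_block <- function(element, lo = 0, hi = 1) {
  data.frame(element = element, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

.blocks <- function(...) {
  do.call(rbind, list(...))
}

# Gene "mass" of a chromosome, assuming equal gene complements per element.
.chrom_mass <- function(chrom) sum(chrom$hi - chrom$lo)

#' Simulate a karyotype-evolution history over a species tree
#'
#' Evolves a set of ancestral linkage elements along a rooted species tree
#' under a scripted list of fusion, fission, translocation and shuffle
#' events, producing a fully determined terminal chromosome composition for
#' every leaf species. At the root each element is a single chromosome named
#' `chr<element>`. Events are applied in pre-order along the tree; events
#' listed for the same branch are applied in their listed order.
#'
#' Each event is a list with fields:
#' \describe{
#'   \item{branch}{tip or node label identifying the branch (applied on the
#'     edge leading into that node; descendants inherit the result).}
#'   \item{kind}{one of `"fusion"`, `"fission"`, `"translocation"`,
#'     `"shuffle"`.}
#'   \item{chroms}{for `fusion`: two or more chromosome names, joined in
#'     order. For the other kinds use `chrom` (and `to` for translocation).}
#'   \item{at}{for `fission`/`translocation`: breakpoint as a fraction of the
#'     chromosome's gene rank (0 < at < 1).}
#'   \item{name,names}{optional name(s) for the product chromosome(s).}
#' }
#'
#' @param tree A rooted species tree: an [ape::phylo] object or a Newick
#'   string. Must have at least two leaves.
#' @param n_elements Number of ancestral elements (labels are taken from
#'   [NIGON_ELEMENTS] when `n_elements <= 7`, otherwise `E1, E2, ...`).
#' @param events List of scripted events (see Details); may be empty.
#' @param element_ids Optional explicit element labels.
#' @param seed Optional integer seed (recorded; scripted histories are
#'   deterministic regardless).
#' @return An object of class `nigon_history`: a list with `tree`,
#'   `n_elements`, `element_ids`, `events`, and `compositions` (named list
#'   species -> named list of chromosome block tables).
#' @examples
#' h <- simulate_history("(sp1,sp2);", n_elements = 7,
#'   events = list(list(branch = "sp1", kind = "fusion",
#'                      chroms = c("chrX", "chrN"), name = "chrXN")))
#' length(h$compositions$sp1) # 6
#' length(h$compositions$sp2) # 7
#' @seealso [nigon_preset_figure6()], [realize_genomes()]
#' @export
simulate_history <- function(tree, n_elements = 7, events = list(),
                             element_ids = NULL, seed = NULL) {
  if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree),
                     error = function(e) stop("malformed Newick tree: ",
                                              conditionMessage(e), call. = FALSE))
    if (is.null(tree)) stop("malformed Newick tree", call. = FALSE)
  }
  .assert(inherits(tree, "phylo"), "`tree` must be a phylo object or Newick string")
  .assert(length(tree$tip.label) >= 2, "tree must have at least 2 leaves")
  .assert(n_elements >= 1, "n_elements must be >= 1")
  if (is.null(element_ids)) {
    element_ids <- if (n_elements <= length(NIGON_ELEMENTS)) {
      NIGON_ELEMENTS[seq_len(n_elements)]
    } else {
      paste0("E", seq_len(n_elements))
    }
  }
  .assert(length(element_ids) == n_elements,
          "element_ids must have length n_elements")

  root_state <- lapply(element_ids, .new_block)
  names(root_state) <- paste0("chr", element_ids)

  # Node labels addressable by events: tips by tip.label, internal nodes by
  # node.label (if present) or their integer index.
  ntip <- length(tree$tip.label)
  node_names <- c(tree$tip.label,
                  if (!is.null(tree$node.label) && any(nzchar(tree$node.label)))
                    tree$node.label else as.character(ntip + seq_len(tree$Nnode)))

  events_by_node <- split(events,
                          vapply(events, function(e) {
                            .assert(!is.null(e$branch), "event lacks a `branch` field")
                            as.character(e$branch)
                          }, character(1)))
  unknown <- setdiff(names(events_by_node), node_names)
  .assert(length(unknown) == 0,
          "event branch label(s) not in tree: %s", paste(unknown, collapse = ", "))

  states <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  states[[root]] <- .apply_events(root_state, events_by_node[[node_names[root]]])

  # Pre-order traversal (parents before children).
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(ord))) {
    parent <- ord[i, 1]; child <- ord[i, 2]
    st <- states[[parent]]
    states[[child]] <- .apply_events(st, events_by_node[[node_names[child]]])
  }

  compositions <- states[seq_len(ntip)]
  names(compositions) <- tree$tip.label

  structure(list(tree = tree, n_elements = n_elements,
                 element_ids = element_ids, events = events,
                 compositions = compositions, seed = seed),
            class = "nigon_history")
}

# Apply a list of events to a chromosome-composition state.
.apply_events <- function(state, evs) {
  for (e in evs %||% list()) {
    kind <- match.arg(e$kind, c("fusion", "fission", "translocation", "shuffle"))
    state <- switch(kind,
      fusion = .ev_fusion(state, e),
      fission = .ev_fission(state, e),
      translocation = .ev_translocation(state, e),
      shuffle = .ev_shuffle(state, e))
  }
  state
}

.ev_get <- function(state, nm, e) {
  .assert(nm %in% names(state),
          "event %s refers to chromosome '%s' absent at event time (present: %s)",
          e$kind, nm, paste(names(state), collapse = ", "))
  state[[nm]]
}

.ev_fusion <- function(state, e) {
  chroms <- e$chroms
  .assert(length(chroms) >= 2, "fusion needs >= 2 chromosomes")
  merged <- do.call(rbind, lapply(chroms, .ev_get, state = state, e = e))
  nm <- e$name %||% paste(sub("^chr", "", chroms), collapse = "")
  nm <- if (grepl("^chr", nm)) nm else paste0("chr", nm)
  state[chroms] <- NULL
  state[[nm]] <- merged
  state
}

# Split a block table at a given fraction of total gene mass.
.split_blocks <- function(blocks, at) {
  total <- .chrom_mass(blocks)
  target <- at * total
  acc <- 0
  left <- list(); right <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    w <- b$hi - b$lo
    if (acc + w <= target + 1e-12) {
      left[[length(left) + 1L]] <- b
    } else if (acc >= target - 1e-12) {
      right[[length(right) + 1L]] <- b
    } else {
      cut <- b$lo + (target - acc)
      left[[length(left) + 1L]] <- .new_block(b$element, b$lo, cut)
      right[[length(right) + 1L]] <- .new_block(b$element, cut, b$hi)
    }
    acc <- acc + w
  }
  list(do.call(rbind, left), do.call(rbind, right))
}

.ev_fission <- function(state, e) {
  nm <- e$chrom
  blocks <- .ev_get(state, nm, e)
  at <- e$at
  .assert(is.numeric(at) && at > 0 && at < 1, "fission `at` must be in (0,1)")
  parts <- .split_blocks(blocks, at)
  nms <- e$names %||% paste0(nm, c("_1", "_2"))
  .assert(length(nms) == 2, "fission `names` must have length 2")
  state[[nm]] <- NULL
  state[[nms[1]]] <- parts[[1]]
  state[[nms[2]]] <- parts[[2]]
  state
}

.ev_translocation <- function(state, e) {
  from <- .ev_get(state, e$chrom, e)
  to <- .ev_get(state, e$to, e)
  at <- e$at
  .assert(is.numeric(at) && at > 0 && at < 1, "translocation `at` must be in (0,1)")
  parts <- .split_blocks(from, at)
  state[[e$chrom]] <- parts[[1]]
  state[[e$to]] <- rbind(to, parts[[2]])
  state
}

.ev_shuffle <- function(state, e) {
  blocks <- .ev_get(state, e$chrom, e)
  attr(blocks, "shuffled") <- TRUE
  state[[e$chrom]] <- blocks
  state
}

#' Terminal chromosome compositions emulating rhabditid karyotype evolution
#'
#' Returns a `nigon_history` whose ten leaf species carry chromosomes that
#' are mosaics of the seven ancestral elements, reproducing the documented
#' fusion/fission landscape of chromosomally assembled Rhabditida: the
#' N+X fused X of *C. elegans* and *H. contortus*, the E+X fused X of
#' *O. tipulae*, the A+N fused chromosome I of *P. pacificus*, the
#' B+D+X X chromosomes of *S. ratti* and *S. carpocapsae*, the C+X fused X of
#' *B. xylophilus*, the A+N fused OM1 of *O. volvulus*, the D+X(+N) X of
#' *B. malayi*, and the blocky A/C/N autosome mosaic of *A. rhodensis*.
#' Compositions are encoded directly as terminal states (the histories of
#' some fusions are not ordered in time); block boundaries within mosaic
#' chromosomes are fixed, documented choices.
#'
#' @param include_mhapla Add *M. hapla* as an 11th species whose 17 small
#'   chromosomes scatter every element; intended for high-noise stress tests
#'   (its real assembly did not yield definitive element assignments).
#' @return A `nigon_history` object (see [simulate_history()]).
#' @examples
#' h <- nigon_preset_figure6()
#' names(h$compositions)
#' h$compositions$C_elegans$chrX  # N + X fusion
#' @export
nigon_preset_figure6 <- function(include_mhapla = FALSE) {
  el <- NIGON_ELEMENTS
  comp <- list(
    C_elegans = list(
      chrI = .new_block("A"), chrII = .new_block("B"), chrIII = .new_block("C"),
      chrIV = .new_block("D"), chrV = .new_block("E"),
      # N and X loci intermixed on the X
      chrX = .blocks(.new_block("N"), .new_block("X"))),
    H_contortus = list(
      chr1 = .new_block("A"), chr2 = .new_block("B"), chr3 = .new_block("C"),
      chr4 = .new_block("D"), chr5 = .new_block("E"),
      chrX = .blocks(.new_block("N"), .new_block("X"))),
    O_tipulae = list(
      Otip_I = .new_block("A"), Otip_II = .new_block("B"),
      Otip_III = .new_block("C"), Otip_IV = .new_block("D"),
      Otip_V = .new_block("N"),
      Otip_X = .blocks(.new_block("E"), .new_block("X"))),
    A_rhodensis = list(
      chr1 = .new_block("B"),
      chr2 = .blocks(.new_block("A", 0, 0.5), .new_block("C", 0, 0.5)),
      chr3 = .blocks(.new_block("C", 0.5, 1), .new_block("N", 0, 0.5)),
      chr4 = .blocks(.new_block("N", 0.5, 1), .new_block("A", 0.5, 1)),
      chr6 = .new_block("D"), chr7 = .new_block("E"),
      chrX = .new_block("X")),
    P_pacificus = list(
      chrI = .blocks(.new_block("A"), .new_block("N")),
      chrII = .new_block("B"), chrIII = .new_block("C"),
      chrIV = .new_block("D"), chrV = .new_block("E"),
      chrX = .new_block("X")),
    S_ratti = list(
      chr1 = .blocks(.new_block("A", 0, 0.5), .new_block("C", 0, 0.5),
                     .new_block("E", 0, 0.5), .new_block("N", 0, 0.5)),
      chr2 = .blocks(.new_block("A", 0.5, 1), .new_block("C", 0.5, 1),
                     .new_block("E", 0.5, 1), .new_block("N", 0.5, 1)),
      chrX = .blocks(.new_block("B"), .new_block("D"), .new_block("X"))),
    S_carpocapsae = list(
      chr1 = .new_block("A"), chr2 = .new_block("C"),
      chr3 = .new_block("E"), chr4 = .new_block("N"),
      chrX = .blocks(.new_block("B"), .new_block("X"), .new_block("D"))),
    B_xylophilus = list(
      chr1 = .new_block("A"), chr2 = .new_block("B"), chr3 = .new_block("D"),
      chr4 = .new_block("E"), chr5 = .new_block("N"),
      chrX = .blocks(.new_block("C"), .new_block("X"))),
    B_malayi = list(
      chr1 = .new_block("B"), chr2 = .new_block("C"),
      chr3 = .new_block("A"), chr4 = .new_block("E"),
      chrX = .blocks(.new_block("D"), .new_block("X"), .new_block("N"))),
    O_volvulus = list(
      OM1 = .blocks(.new_block("A"), .new_block("N")),
      OM2 = .new_block("B"), OM3 = .new_block("C"),
      OM4 = .blocks(.new_block("E"), .new_block("D"), .new_block("X")))
  )

  if (include_mhapla) {
    # 17 small chromosomes; every element fragmented across 2-3 of them.
    cuts <- list(c(0, .4, 1), c(0, .5, 1), c(0, .3, .7, 1), c(0, .6, 1),
                 c(0, .5, 1), c(0, .4, .8, 1), c(0, .5, 1))
    mh <- list(); k <- 0L
    for (i in seq_along(NIGON_ELEMENTS)) {
      cc <- cuts[[i]]
      for (j in seq_len(length(cc) - 1L)) {
        k <- k + 1L
        mh[[sprintf("scf%02d", k)]] <-
          .new_block(NIGON_ELEMENTS[i], cc[j], cc[j + 1])
      }
    }
    comp$M_hapla <- mh
  }

  tip_newick <- paste0(
    "(((((C_elegans,(A_rhodensis,(O_tipulae,H_contortus)))),P_pacificus),",
    "((S_ratti,S_carpocapsae),B_xylophilus)),(B_malayi,O_volvulus));")
  tree <- ape::read.tree(text = tip_newick)
  if (include_mhapla) {
    tree <- ape::read.tree(text = sub("B_xylophilus",
                                      "(B_xylophilus,M_hapla)", tip_newick))
  }
  comp <- comp[tree$tip.label]

  structure(list(tree = tree, n_elements = 7, element_ids = el,
                 events = list(), compositions = comp, seed = NULL,
                 preset = "figure6"),
            class = "nigon_history")
}

#' @export
print.nigon_history <- function(x, ...) {
  cat("Karyotype-evolution history:", length(x$compositions), "species,",
      x$n_elements, "ancestral elements\n")
  for (sp in names(x$compositions)) {
    chroms <- x$compositions[[sp]]
    desc <- vapply(chroms, function(b)
      paste(unique(b$element), collapse = "+"), character(1))
    cat(sprintf("  %-14s %s\n", sp,
                paste(sprintf("%s{%s}", names(chroms), desc), collapse = " ")))
  }
  invisible(x)
}
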