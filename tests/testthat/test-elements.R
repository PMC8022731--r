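# Dice similarity, PAM/CLARA clustering, silhouette selection, and element
# assignment.

test_that("Dice similarity matches brute-force set counting", {
  # fully co-chromosomal and never co-chromosomal endpoints
  M <- rbind(o1 = rep("chr1", 9), o2 = rep("chr1", 9), o3 = rep("chr2", 9))
  colnames(M) <- paste0("sp", 1:9)
  dd <- dice_similarity(M)
  expect_identical(dd$similarity["o1", "o2"], 1)
  expect_identical(dd$similarity["o1", "o3"], 0)

  # i placed in 9, j in 8, co-chromosomal in all 8 shared -> 16/17
  M2 <- rbind(i = rep("chr1", 9), j = c(rep("chr1", 8), NA))
  colnames(M2) <- paste0("sp", 1:9)
  d2 <- dice_similarity(M2)
  expect_equal(d2$similarity["i", "j"], 16 / 17)
  expect_equal(d2$similarity["i", "j"], oracle_dice_pair(M2["i", ], M2["j", ]))

  # random matrices against the pairwise oracle; bounds and symmetry
  set.seed(42)
  for (rep in 1:5) {
    n <- 8
    R <- matrix(sample(c(paste0("c", 1:3), NA), n * 6, replace = TRUE), n, 6,
                dimnames = list(paste0("o", 1:n), paste0("s", 1:6)))
    R[, 1] <- "c1"  # ensure every ortholog is placed somewhere
    dd <- dice_similarity(R)
    S <- dd$similarity
    expect_identical(S, t(S))
    expect_true(all(S >= 0 & S <= 1))
    expect_true(all(diag(S) == 1))
    for (i in 1:3) for (j in 4:6) {
      expect_equal(S[i, j], oracle_dice_pair(R[i, ], R[j, ]))
    }
    expect_equal(dd$distance, 1 - S)
  }
})

test_that("orthologs placed nowhere are excluded with a warning", {
  M <- rbind(o1 = c("c1", "c2"), o2 = c(NA, NA), o3 = c("c1", "c1"))
  colnames(M) <- c("s1", "s2")
  expect_warning(dd <- dice_similarity(M), "o2")
  expect_equal(rownames(dd$similarity), c("o1", "o3"))
})

test_that("PAM solves small instances exactly", {
  # k = n: every point its own medoid, zero cost
  d <- random_distance(5)
  fit <- nigon_pam(d, 5)
  expect_equal(fit$cost, 0)
  expect_setequal(fit$medoid_index, 1:5)

  # 3 points, d(a,b) = 1, d(a,c) = 1, d(b,c) = 2: medoid a, cost 2
  d3 <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit3 <- nigon_pam(d3, 1)
  expect_equal(fit3$medoids, "a")
  expect_equal(fit3$cost, 2)
  expect_equal(fit3$cost, oracle_kmedoids_cost(d3, 1))

  # two well-separated pairs: one medoid per pair, enumeration optimum
  x <- c(0, 0.1, 10, 10.1)
  d4 <- as.matrix(dist(x)); dimnames(d4) <- list(letters[1:4], letters[1:4])
  fit4 <- nigon_pam(d4, 2)
  expect_equal(sort(fit4$clustering), sort(c(a = 1L, b = 1L, c = 2L, d = 2L)))
  expect_equal(fit4$cost, oracle_kmedoids_cost(d4, 2))
})

test_that("PAM agrees with the reference k-medoids on separated clusters", {
  skip_if_not_installed("cluster")
  set.seed(7)
  for (rep in 1:10) {
    inst <- separated_clusters(k = 3, per = 5)
    mine <- nigon_pam(inst$d, 3)
    ref <- cluster::pam(as.dist(inst$d), 3, diss = TRUE)
    # identical partitions up to label permutation
    expect_equal(length(unique(paste(mine$clustering, ref$clustering))), 3)
    expect_equal(mine$cost, sum(ref$objective["swap"] * nrow(inst$d)),
                 tolerance = 1e-8)
  }
})

test_that("PAM input validation rejects bad k and asymmetric matrices", {
  d <- random_distance(4)
  expect_error(nigon_pam(d, 0), "positive")
  expect_error(nigon_pam(d, 5), "exceeds")
  bad <- d; bad[1, 2] <- 9
  expect_error(nigon_pam(bad, 2), "symmetric")
})

test_that("CLARA reduces to PAM with one full subsample and is deterministic", {
  set.seed(3)
  d <- random_distance(20)
  full <- nigon_clara(d, 3, n_subsamples = 1, fraction = 1, seed = 1)
  pam <- nigon_pam(d, 3)
  expect_equal(full$medoids, pam$medoids)
  expect_equal(full$clustering, pam$clustering)
  expect_equal(full$cost, pam$cost)

  c1 <- nigon_clara(d, 3, seed = 99, fraction = 0.5)
  c2 <- nigon_clara(d, 3, seed = 99, fraction = 0.5)
  expect_identical(c1$medoids, c2$medoids)

  expect_error(nigon_clara(d, 5, fraction = 0.1), "increase")
})

test_that("CLARA recovers the PAM partition on well-separated clusters", {
  set.seed(11)
  inst <- separated_clusters(k = 4, per = 10)
  cl <- nigon_clara(inst$d, 4, n_subsamples = 5, fraction = 0.5, seed = 2)
  pam <- nigon_pam(inst$d, 4)
  expect_equal(cl$clustering, pam$clustering)
  expect_equal(length(unique(paste(cl$clustering, inst$labels))), 4)
})

test_that("silhouette widths match the quadratic oracle and the reference", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    d <- random_distance(n)
    labels <- sample(1:3, n, replace = TRUE)
    labels[1:3] <- 1:3  # every cluster non-empty
    mine <- silhouette_widths(d, labels)
    expect_equal(mine, oracle_silhouette(d, labels), tolerance = 1e-12)
    if (requireNamespace("cluster", quietly = TRUE) &&
        all(tabulate(labels) > 0)) {
      ref <- cluster::silhouette(labels, dmatrix = d)
      expect_equal(mine, unname(ref[, "sil_width"]), tolerance = 1e-12)
    }
  }
})

test_that("silhouette scan selects the planted number of clusters", {
  set.seed(6)
  inst <- separated_clusters(k = 2, per = 8, gap = 50)
  scan <- silhouette_scan(inst$d, k_range = 1:5, method = "pam")
  expect_equal(scan$best_k, 2)
  expect_gt(max(scan$table$avg_silhouette, na.rm = TRUE), 0.9)
  expect_true(is.na(scan$table$avg_silhouette[scan$table$k == 1]))

  # all distances equal: silhouette ~ 0 everywhere
  n <- 9
  d <- matrix(1, n, n); diag(d) <- 0
  dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
  flat <- silhouette_scan(d, k_range = 2:4, method = "pam")
  expect_true(all(abs(flat$table$avg_silhouette) < 1e-9))
})

test_that("element assignment honors agreement and cluster-size thresholds", {
  # 3 clusters of sizes 21 / 21 / 5 over 9 species; one ortholog of cluster 1
  # disagrees with its medoid in 3 species (agreement 6 -> unassigned)
  species <- paste0("sp", 1:9)
  rows <- c(sprintf("a%02d", 1:21), sprintf("b%02d", 1:21), sprintf("c%02d", 1:5))
  M <- matrix("x", length(rows), 9, dimnames = list(rows, species))
  M[grep("^a", rows), ] <- "chr1"
  M[grep("^b", rows), ] <- "chr2"
  M[grep("^c", rows), ] <- "chr3"
  M["a21", 1:3] <- "chr9"
  dd <- dice_similarity(M)
  fit <- nigon_pam(dd$distance, 3)
  asn <- assign_elements(fit, new_allocation_matrix(M),
                         anchors = list(genes = list(A = c("a01", "a02"),
                                                     B = c("b01", "b02"))),
                         min_agree_taxa = 7, min_cluster_size = 21)
  tab <- setNames(asn$element, asn$orthogroup)
  expect_equal(unname(tab["a01"]), "A")
  expect_equal(unname(tab["b05"]), "B")
  expect_equal(unname(tab["a21"]), "UNASSIGNED")       # 6 agreeing taxa
  expect_true(all(tab[grep("^c", rows)] == "UNASSIGNED"))  # size 5 cluster
  expect_equal(setNames(asn$agreement, asn$orthogroup)[["a21"]], 6L)

  # a cluster of exactly 20 loci stays unassigned (> 20 required)
  rows20 <- c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:21))
  M20 <- matrix("x", length(rows20), 9, dimnames = list(rows20, species))
  M20[grep("^a", rows20), ] <- "chr1"
  M20[grep("^b", rows20), ] <- "chr2"
  fit20 <- nigon_pam(dice_similarity(M20)$distance, 2)
  asn20 <- assign_elements(fit20, new_allocation_matrix(M20),
                           anchors = list(genes = list(A = "a01", B = "b01")))
  t20 <- setNames(asn20$element, asn20$orthogroup)
  expect_true(all(t20[grep("^a", rows20)] == "UNASSIGNED"))
  expect_true(all(t20[grep("^b", rows20)] == "B"))
})

test_that("anchor evidence must label clusters injectively", {
  species <- paste0("sp", 1:9)
  rows <- c(sprintf("a%02d", 1:21), sprintf("b%02d", 1:21))
  M <- matrix("x", length(rows), 9, dimnames = list(rows, species))
  M[grep("^a", rows), ] <- "chr1"
  M[grep("^b", rows), ] <- "chr2"
  fit <- nigon_pam(dice_similarity(M)$distance, 2)
  expect_error(
    assign_elements(fit, new_allocation_matrix(M),
                    anchors = list(genes = list(A = c("a01", "a02")))),
    NA)  # one labeled cluster, one synthetic U label: fine
  expect_error(
    assign_elements(fit, new_allocation_matrix(M),
                    anchors = list(genes = list(A = "a01", B = "a02"))),
    NA)  # tied vote within one cluster resolves to a synthetic label
  expect_error(
    assign_elements(fit, new_allocation_matrix(M),
                    anchors = list(genes = list(Z = c("a01", "b01")))),
    "identical")  # the same label winning two clusters is rejected
})

test_that("reference-species chromosome maps label clusters", {
  h <- nigon_preset_figure6()
  M <- simulate_allocation_matrix(h, genes_per_element = 25, seed = 31)
  dd <- dice_similarity(M)
  fit <- nigon_clara(dd$distance, 7, seed = 31, fraction = 0.3)
  # O. tipulae autosomes map A-D plus N; its X is a fusion and is left to
  # anchor genes for the two X-resident clusters
  truth <- attr(M, "truth")
  anchors <- list(
    species = "O_tipulae",
    map = c(Otip_I = "A", Otip_II = "B", Otip_III = "C", Otip_IV = "D",
            Otip_V = "N"),
    genes = truth_anchors(truth[truth %in% c("E", "X")]))
  asn <- assign_elements(fit, M, anchors = anchors)
  ok <- asn$element != "UNASSIGNED"
  expect_gt(mean(ok), 0.95)
  expect_equal(unname(asn$element[ok]), unname(truth[asn$orthogroup[ok]]))
})

test_that("clustering recovers simulated element truth", {
  skip_if_not_installed("mclust")
  h <- nigon_preset_figure6()
  # noise-free: clustering at the element count is an exact recovery
  M0 <- simulate_allocation_matrix(h, genes_per_element = 40, noise = 0,
                                   seed = 8)
  fit0 <- nigon_clara(dice_similarity(M0)$distance, 7, seed = 8)
  truth0 <- attr(M0, "truth")[rownames(M0)]
  expect_gte(mclust::adjustedRandIndex(fit0$clustering, truth0), 0.99)
  # under realistic placement noise the silhouette scan finds k = 7 itself
  M <- simulate_allocation_matrix(h, genes_per_element = 40, noise = 0.05,
                                  seed = 8)
  scan <- silhouette_scan(dice_similarity(M)$distance, k_range = 2:10,
                          seed = 8)
  expect_equal(scan$best_k, 7)
  truth <- attr(M, "truth")[rownames(M)]
  expect_gte(mclust::adjustedRandIndex(scan$best_fit$clustering, truth), 0.95)
})
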