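test_that("euclidean/complete clustering recovers separated groups", {
  set.seed(51)
  # two well-separated sample groups over 5 genes
  g1 <- matrix(rnorm(5 * 6, mean = 0), 5, 6)
  g2 <- matrix(rnorm(5 * 6, mean = 8), 5, 6)
  vals <- cbind(g1, g2)
  dimnames(vals) <- list(paste0("G", 1:5), paste0("S", 1:12))
  cl <- hierarchical_cluster(vals, axis = "samples", scale_genes = FALSE)
  cut <- cut_clusters(cl, 2)
  expect_equal(length(unique(cut[1:6])), 1)
  expect_equal(length(unique(cut[7:12])), 1)
  expect_false(cut[1] == cut[7])

  # merge of two items happens at their euclidean distance
  two <- vals[, 1:2]
  cl2 <- hierarchical_cluster(two, axis = "samples", scale_genes = FALSE)
  expect_equal(cl2$hclust$height, sqrt(sum((two[, 1] - two[, 2])^2)))

  # a duplicated item merges first at height zero
  dup <- cbind(vals, S1copy = vals[, 1])
  cld <- hierarchical_cluster(dup, axis = "samples", scale_genes = FALSE)
  expect_equal(min(cld$hclust$height), 0)
  expect_error(hierarchical_cluster(vals[, 1, drop = FALSE], "samples"),
               "at least 2")
})

test_that("clustering partition is invariant to input order", {
  set.seed(53)
  vals <- matrix(rnorm(6 * 10), 6, 10,
                 dimnames = list(paste0("G", 1:6), paste0("S", 1:10)))
  cl <- hierarchical_cluster(vals, "samples", scale_genes = FALSE)
  perm <- sample(10)
  clp <- hierarchical_cluster(vals[, perm], "samples", scale_genes = FALSE)
  c1 <- cut_clusters(cl, 3); c2 <- cut_clusters(clp, 3)
  # same partition up to cluster relabeling
  expect_equal(length(unique(paste(c1[names(c2)], c2))), 3)
})

test_that("co-clustering agreement reproduces the all-but-one pattern", {
  set.seed(55)
  sens <- matrix(rnorm(4 * 5, mean = 0), 4, 5)
  res <- matrix(rnorm(4 * 5, mean = 6), 4, 5)
  vals <- cbind(sens, res)
  dimnames(vals) <- list(paste0("G", 1:4), paste0("S", 1:10))
  labels <- rep(c("sensitive", "resistant"), each = 5)
  cl <- hierarchical_cluster(vals, "samples", scale_genes = FALSE)
  expect_equal(coclustering_agreement(cl, labels), 1.0)

  # plant one outlier: a sensitive line that looks resistant
  vals[, 1] <- rnorm(4, mean = 6)
  cl_out <- hierarchical_cluster(vals, "samples", scale_genes = FALSE)
  expect_equal(coclustering_agreement(cl_out, labels), 0.9)

  swapped <- ifelse(labels == "sensitive", "resistant", "sensitive")
  expect_equal(coclustering_agreement(cl_out, swapped), 0.9)
})

test_that("wilcoxon exact path equals full enumeration for small groups", {
  # complete separation of 3 vs 3: two-sided p = 2 / C(6,3)
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$p, 0.1)

  # perfectly interleaved tiny groups are indistinguishable
  expect_equal(wilcoxon_rank_sum(c(1, 4), c(2, 3))$p, 1)

  enum_p <- function(a, b) {
    # enumerate all assignments of the pooled ranks to group A
    pool <- c(a, b); n <- length(pool); ra <- rank(pool)
    u_obs <- sum(ra[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    combos <- utils::combn(n, length(a))
    m <- length(a) * length(b)
    us <- apply(combos, 2, function(ix)
      sum(ra[ix]) - length(a) * (length(a) + 1) / 2)
    mean(abs(us - m / 2) >= abs(u_obs - m / 2))
  }
  set.seed(57)
  for (na in c(3, 5, 6)) for (nb in c(4, 6)) {
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    expect_equal(wilcoxon_rank_sum(a, b)$p, enum_p(a, b), tolerance = 1e-12,
                 label = sprintf("exact p at %d vs %d", na, nb))
  }

  # approximation accuracy on a moderately separated n = 8 fixture
  set.seed(58)
  a <- rnorm(8); b <- rnorm(8, 0.3)
  approx_p <- wilcoxon_rank_sum(c(a, 0.123), c(b, 0.123))  # tie forces approx
  expect_true(approx_p$p > 0 && approx_p$p <= 1)
  exact8 <- enum_p(a, b)
  forced <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE)$p.value)
  expect_lt(abs(forced - exact8) / exact8, 0.10)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "nonempty")
})

test_that("list overlap reports the shared fraction both ways", {
  a <- sprintf("G%03d", 1:200)
  expect_equal(list_overlap(a, a)$fraction_a, 1)
  b <- c(sprintf("G%03d", 1:78), sprintf("H%03d", 1:122))
  ov <- list_overlap(a, b)
  expect_length(ov$intersection, 78)
  expect_equal(ov$fraction_a, 0.39)
  expect_equal(ov$fraction_b, 0.39)
  expect_equal(list_overlap(a, paste0("X", 1:10))$fraction_b, 0)
})

test_that("hypergeometric enrichment matches exact combinatorics and Fisher", {
  universe <- sprintf("U%02d", 1:20)
  sets <- gene_set_collection(list(HIT = universe[1:5],
                                   MISS = universe[16:20]))
  res <- enrichment_test(universe[1:5], sets, universe, 0.05)
  # P(overlap = 5 of 5 drawn) = 1 / C(20,5), by direct enumeration count
  expect_equal(res$p[res$set == "HIT"], 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap can never be enriched
  expect_gte(res$p[res$set == "MISS"], 0.5)
  expect_false(res$significant[res$set == "MISS"])

  # agreement with the one-sided Fisher exact test on the 2x2 table
  set.seed(61)
  for (i in 1:10) {
    s <- sample(universe, sample(3:8, 1))
    q <- sample(universe, sample(3:8, 1))
    p_pkg <- enrichment_test(q, gene_set_collection(list(S = s)),
                             universe)$p
    k <- length(intersect(s, q))
    tab <- matrix(c(k, length(s) - k, length(q) - k,
                    20 - length(s) - length(q) + k), 2)
    p_fisher <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_pkg, p_fisher, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up rule and significance is monotone", {
  sets <- gene_set_collection(list(A = "G1", B = "G2", C = "G3"))
  # hand-applied BH on p = {0.01, 0.02, 0.04} gives {0.03, 0.03, 0.04}
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))

  set.seed(63)
  universe <- sprintf("U%02d", 1:40)
  setlist <- gene_set_collection(lapply(
    stats::setNames(1:6, paste0("S", 1:6)),
    function(i) sample(universe, 8)))
  q <- sample(universe, 10)
  res <- enrichment_test(q, setlist, universe, 0.25)
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_equal(order(res$p), order(res$p[order(res$fdr, res$p)]))
  strict <- enrichment_test(q, setlist, universe, 0.01)
  expect_lte(sum(strict$significant), sum(res$significant))

  expect_warning(enrichment_test(c(q, "NOT_IN_UNIVERSE"), setlist, universe),
                 "outside the universe")
  expect_error(enrichment_test(character(), setlist, universe), "empty query")
})

test_that("dendrograms export as readable Newick", {
  dir <- withr::local_tempdir()
  vals <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
  cl <- hierarchical_cluster(vals, "samples")
  path <- export_newick(cl, file.path(dir, "tree.nwk"))
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, paste0("S", 1:6))
})
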