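test_that("pearson_screen matches a brute-force per-gene computation", {
  set.seed(42)
  vals <- matrix(rnorm(20 * 30), 20, 30,
                 dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:30)))
  y <- rnorm(30)
  res <- pearson_screen(vals, y)
  for (i in 1:20) {
    ct <- cor.test(vals[i, ], y)
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-10)
  }
  expect_true(all(res$n == 30))
})

test_that("worked 5-sample example equals direct arithmetic", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  vals <- matrix(x, 1, 5, dimnames = list("GX", paste0("S", 1:5)))
  res <- pearson_screen(vals, y)
  # product-moment formula by hand
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
})

test_that("a gene identical to the target gets r = 1 with a positive p", {
  y <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  vals <- rbind(COPY = y, OTHER = c(1, 1, 2, 2, 3))
  colnames(vals) <- paste0("S", 1:5)
  res <- pearson_screen(vals, y)
  expect_equal(res$r[res$gene == "COPY"], 1)
  expect_gt(res$p[res$gene == "COPY"], 0)
})

test_that("the t-transform p-value reproduces the driver-correlation order of magnitude", {
  # construct vectors with exact r = 0.775 at n = 52
  set.seed(1)
  n <- 52; r <- 0.775
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x))
  y <- r * x / sd(x) + sqrt(1 - r^2) * e / sd(e)
  vals <- matrix(x, 1, n, dimnames = list("DRIVER", paste0("S", 1:n)))
  res <- pearson_screen(vals, y)
  expect_equal(res$r, 0.775, tolerance = 1e-9)
  expect_equal(res$p, 1.539e-11, tolerance = 0.05)
})

test_that("t-transform p agrees with a permutation p within Monte-Carlo error", {
  set.seed(7)
  n <- 10
  x <- rnorm(n); y <- x + rnorm(n, sd = 1.5)
  vals <- matrix(x, 1, n, dimnames = list("G", paste0("S", 1:n)))
  p_t <- pearson_screen(vals, y)$p
  r_obs <- abs(cor(x, y))
  B <- 10000
  r_perm <- replicate(B, abs(cor(x, sample(y))))
  p_perm <- (1 + sum(r_perm >= r_obs)) / (B + 1)
  expect_lt(abs(p_t - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / B) + 1e-3)
})

test_that("significance selection is inclusive at the threshold and matches brute force", {
  corr <- structure(data.frame(gene = c("A", "B", "C", "D"),
                               r = c(0.9, 0.5, -0.8, 0.1),
                               p = c(0.01, 0.05, 0.049, 0.9),
                               n = 10, sign = c("positive", "positive",
                                                "negative", "positive")),
                    class = c("correlation_result", "data.frame"))
  sel <- select_significant(corr, 0.05)
  expect_setequal(sel, corr$gene[corr$p <= 0.05])
  expect_true("B" %in% sel)  # p exactly at alpha retained
  corr$p <- rep(1, 4)
  expect_length(select_significant(corr, 0.05), 0)
})

test_that("top-correlate selection returns both tails and truncates with warning", {
  set.seed(3)
  vals <- matrix(rnorm(500 * 20), 500, 20,
                 dimnames = list(sprintf("G%03d", 1:500), sprintf("S%02d", 1:20)))
  y <- rnorm(20)
  corr <- pearson_screen(vals, y)
  top20 <- select_top_correlates(corr, 10, 10)
  expect_length(top20, 20)
  top200 <- select_top_correlates(corr, 100, 100)
  expect_length(top200, 200)
  rs <- corr$r[match(top20, corr$gene)]
  expect_true(all(rs[1:10] > 0) && all(rs[11:20] < 0))
  expect_equal(max(corr$r), rs[1])
  small <- corr[1:5, ]
  w <- capture_warnings(out <- select_top_correlates(small, 100, 100))
  expect_match(w, "available", all = TRUE)
  expect_length(out, 5)
})

test_that("pathway filter equals an exhaustive membership check and is idempotent", {
  sets <- gene_set_collection(list(S1 = c("T1", "A", "B"),
                                   S2 = c("C", "D"),
                                   S3 = c("T2", "D", "E")))
  genes <- c("A", "B", "C", "D", "E", "F")
  targets <- c("T1", "T2")
  got <- pathway_filter(genes, sets, targets)
  # brute force over all (gene, set, target) triples
  expected <- Filter(function(g) any(vapply(sets, function(s)
    g %in% s && any(targets %in% s), TRUE)), genes)
  expect_equal(got, expected)
  expect_equal(pathway_filter(got, sets, targets), got)
  expect_error(pathway_filter(genes, sets, "NOT_THERE"), "no target gene")
})

test_that("network filter adds exactly the distance-1 neighborhood", {
  net <- suppressWarnings(interaction_network(
    from = c("HUB", "HUB", "HUB", "X"),
    to = c("L1", "L2", "L3", "Y")))
  measured <- c("HUB", "L1", "L2", "L3", "X", "Y", "ISOLATED")
  expect_equal(network_filter("ISOLATED", net, measured), "ISOLATED")
  star <- network_filter("HUB", net, measured)
  expect_setequal(star, c("HUB", "L1", "L2", "L3"))
  # brute-force adjacency oracle on a random graph
  set.seed(9)
  g <- sprintf("G%02d", 1:15)
  rnd <- suppressWarnings(interaction_network(sample(g, 30, TRUE),
                                              sample(g, 30, TRUE)))
  input <- sample(g, 4)
  got <- network_filter(input, rnd, g)
  adj <- unique(c(input, unlist(lapply(input, function(v)
    c(rnd$to[rnd$from == v], rnd$from[rnd$to == v])))))
  expect_setequal(got, adj)
  # restricted to measured genes, and the result is a bounded superset
  expect_true(all(input %in% got))
  expect_true(all(got %in% g))
})

test_that("RReliefF puts a deterministic driver first and near-zero noise at the bottom", {
  set.seed(11)
  n <- 40
  driver <- rnorm(n)
  vals <- rbind(DRIVER = driver, noise_matrix(6, n, "NS")[1:6, , drop = FALSE])
  rownames(vals) <- c("DRIVER", sprintf("NS%03d", 1:6))
  colnames(vals) <- paste0("S", 1:n)
  y <- 2 * driver + 0.5   # monotone noiseless function of the driver
  rk <- relieff_rank(vals, y, k_neighbors = 10)
  expect_equal(rk$gene[1], "DRIVER")
  expect_gt(rk$weight[1], max(rk$weight[-1]))
})

test_that("RReliefF is permutation-equivariant with lexicographic tie-breaks", {
  set.seed(13)
  vals <- matrix(rnorm(8 * 30), 8, 30,
                 dimnames = list(sprintf("G%02d", 1:8), paste0("S", 1:30)))
  y <- vals[1, ] + rnorm(30, sd = 0.2)
  rk1 <- relieff_rank(vals, y)
  perm <- sample(8)
  rk2 <- relieff_rank(vals[perm, ], y)
  expect_equal(rk1, rk2)  # output order is weight- then id-sorted

  copies <- vals[rep(1, 3), ]
  rownames(copies) <- c("B_COPY", "A_COPY", "C_COPY")
  rkc <- relieff_rank(copies, y)
  expect_equal(length(unique(rkc$weight)), 1)
  expect_equal(rkc$gene, sort(rkc$gene))
})

test_that("pure-noise RReliefF weights are centered near zero", {
  ws <- vapply(1:20, function(s) {
    set.seed(100 + s)
    vals <- t(noise_matrix(30, 5))
    colnames(vals) <- paste0("S", 1:30)
    mean(relieff_rank(vals, rnorm(30))$weight)
  }, 0)
  se <- sd(ws) / sqrt(length(ws))
  expect_lt(abs(mean(ws)), 3 * se + 0.01)
})

test_that("take_top truncates and warns appropriately", {
  rk <- structure(data.frame(gene = sprintf("G%03d", 1:150),
                             weight = seq(1, 0, length.out = 150)),
                  class = c("ranked_genes", "data.frame"))
  expect_length(take_top(rk, 100), 100)
  expect_warning(out <- take_top(rk[1:50, ], 100), "50")
  expect_length(out, 50)
  expect_length(take_top(rk, 0), 0)
})

test_that("the funnel only narrows: each stage output is within its input", {
  set.seed(21)
  ds <- generate_dataset(small_config(seed = 21))
  keep <- ds$sensitivity$lineage == "solid"
  y <- ds$sensitivity$neglog10[keep]
  expr <- ds$expression$values[, keep]
  corr <- pearson_screen(expr, y)
  sig <- select_significant(corr)
  expect_true(all(sig %in% corr$gene))
  rk <- relieff_rank(expr[sig, , drop = FALSE], y)
  top <- suppressWarnings(take_top(rk, 100))
  expect_true(all(top %in% sig))
  expect_lte(length(top), length(sig))
})
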