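test_that("Shannon index matches closed forms and hand computation", {
  m <- rbind(
    single = c(10, 0, 0, 0),
    equal4 = c(25, 25, 25, 25),
    hand = c(50, 25, 25, 0)
  )
  h <- shannon_index(m)
  expect_equal(h$shannon[1], 0, tolerance = 1e-9)
  expect_equal(h$shannon[2], log(4), tolerance = 1e-9)
  # -(0.5 ln 0.5 + 2 * 0.25 ln 0.25)
  expect_equal(h$shannon[3], -(0.5 * log(0.5) + 0.5 * log(0.25)),
               tolerance = 1e-9)

  empty <- rbind(a = c(1, 1), b = c(0, 0))
  expect_true(is.na(shannon_index(empty)$shannon[2]))
})

test_that("Shannon is bounded by log richness with equality iff uniform", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    x <- matrix(rgamma(k, 1), 1)
    h <- shannon_index(x)$shannon
    expect_lte(h, log(k) + 1e-12)
  }
  expect_equal(shannon_index(matrix(rep(7, 6), 1))$shannon, log(6),
               tolerance = 1e-12)
})

test_that("Bray-Curtis matches hand-computed dissimilarities", {
  m <- rbind(a = c(2, 1), b = c(1, 3), a2 = c(2, 1), disj = c(0, 0))
  m["disj", ] <- c(0, 0)
  m <- rbind(a = c(2, 1), b = c(1, 3), a2 = c(2, 1), d = c(0, 5))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 1 - 4 / 7, tolerance = 1e-9)  # 3/7
  expect_equal(d["a", "a2"], 0, tolerance = 1e-12)
  # disjoint supports: a has nothing in column 2-only sample? construct one
  m2 <- rbind(x = c(5, 0), y = c(0, 3))
  expect_equal(as.matrix(bray_curtis(m2))["x", "y"], 1)
  expect_error(bray_curtis(m[1, , drop = FALSE]), "two samples")
})

test_that("CLR PCA satisfies the CLR identity and separates clusters", {
  set.seed(6)
  base1 <- c(60, 20, 10, 5, 5)
  base2 <- c(5, 5, 10, 20, 60)
  m <- rbind(
    t(replicate(4, base1 * exp(rnorm(5, 0, 0.1)))),
    t(replicate(4, base2 * exp(rnorm(5, 0, 0.1))))
  )
  rownames(m) <- sprintf("s%d", 1:8)
  p <- clr_pca(m)
  expect_true(all(abs(rowSums(p$clr)) < 1e-9))

  # duplicate samples map to identical scores
  dup <- rbind(m, m[1, , drop = FALSE])
  rownames(dup) <- c(rownames(m), "s1b")
  pd <- clr_pca(dup)
  expect_equal(unlist(pd$scores[9, -1]), unlist(pd$scores[1, -1]),
               tolerance = 1e-9)

  # two constructed clusters separate on PC1
  pc1 <- p$scores$PC1
  g <- rep(c(1, 2), each = 4)
  within <- c(pc1[1:4] - mean(pc1[1:4]), pc1[5:8] - mean(pc1[5:8]))
  expect_gt(abs(mean(pc1[1:4]) - mean(pc1[5:8])), 2 * stats::sd(within))
  expect_error(clr_pca(m, pseudocount = -1), "pseudocount")
})

test_that("ward.D2 clustering reproduces the exhaustive agglomeration oracle", {
  # two identical rows merge at height zero
  m0 <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 5))
  wc0 <- ward_cluster(m0, log_transform = FALSE)
  expect_equal(wc0$hclust$height[1], 0, tolerance = 1e-12)

  # three points on a line: nearest pair merges first
  m1 <- matrix(c(0, 1, 10), dimnames = list(c("A", "B", "C"), NULL))
  wc1 <- ward_cluster(m1, log_transform = FALSE)
  expect_equal(sort(hclust_partition_at(wc1$hclust, 1)[[
    which(lengths(hclust_partition_at(wc1$hclust, 1)) == 2)]]), c(1, 2))

  # 6-point toys: merge heights and partitions equal the oracle at each step
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(rnorm(6 * 3), 6, dimnames = list(sprintf("p%d", 1:6), NULL))
    wc <- ward_cluster(m, log_transform = FALSE)
    oracle <- ward_oracle(m)
    expect_equal(wc$hclust$height, oracle$heights, tolerance = 1e-9)
    for (s in 1:4) {
      expect_identical(canon_partition(hclust_partition_at(wc$hclust, s)),
                       canon_partition(oracle$partitions[[s]]))
    }
  }

  # Newick string parses back to the same topology
  wc <- ward_cluster(matrix(rnorm(8), 4, dimnames = list(letters[1:4], NULL)),
                     log_transform = FALSE)
  tree <- ape::read.tree(text = wc$newick)
  expect_setequal(tree$tip.label, letters[1:4])

  expect_error(ward_cluster(matrix(c(-1, 2, 3, 4), 2), log_transform = TRUE,
                            pseudocount = 0.5),
               "Non-finite")
})

test_that("PERMANOVA matches the brute-force and vegan partitions", {
  set.seed(8)
  for (rep in 1:4) {
    n <- sample(6:8, 1)
    m <- matrix(abs(rnorm(n * 4)), n)
    rownames(m) <- sprintf("s%d", seq_len(n))
    meta <- data.frame(
      sample_id = rownames(m),
      f1 = sample(rep(c("a", "b"), length.out = n)),
      f2 = sample(rep(c("x", "y"), length.out = n)),
      stringsAsFactors = FALSE
    )
    d <- bray_curtis(m)
    mine <- permanova(d, meta, c("f1", "f2"), n_permutations = 49, seed = rep)
    oracle <- permanova_oracle(as.matrix(d), meta, c("f1", "f2"))
    tab <- tidy(mine)
    expect_equal(tab$SumOfSqs[1:2], unname(oracle$ss), tolerance = 1e-9)
    expect_equal(tab$R2[1:2], unname(oracle$r2), tolerance = 1e-9)
    expect_equal(tab$F[1:2], unname(oracle$f), tolerance = 1e-9)
    expect_equal(tab$SumOfSqs[3], oracle$ss_res, tolerance = 1e-9)

    ad <- vegan::adonis2(d ~ f1 + f2, data = meta, by = "terms",
                         permutations = 19)
    expect_equal(tab$SumOfSqs[1:2], ad$SumOfSqs[1:2], tolerance = 1e-9)
  }
})

test_that("PERMANOVA handles degenerate and invariance cases", {
  set.seed(9)
  m <- matrix(abs(rnorm(24)), 6)
  rownames(m) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample_id = rownames(m),
                     const = "same",
                     grp = rep(c("a", "b"), 3))
  d <- bray_curtis(m)

  # constant factor explains nothing (0 df, SS 0)
  expect_warning(res <- permanova(d, meta, c("const", "grp"),
                                  n_permutations = 19, seed = 1),
                 "0 df")
  tab <- tidy(res)
  expect_equal(tab$df[1], 0)
  expect_equal(tab$SumOfSqs[1], 0, tolerance = 1e-9)

  # two tight groups: R2 equals the brute-force partition value
  g <- rbind(matrix(0, 3, 2), matrix(1, 3, 2)) + matrix(rnorm(12, 0, 1e-6), 6)
  rownames(g) <- sprintf("s%d", 1:6)
  meta2 <- data.frame(sample_id = rownames(g), grp = rep(c("lo", "hi"), each = 3))
  dg <- dist(g)
  r2 <- tidy(permanova(dg, meta2, "grp", n_permutations = 19, seed = 1))$R2[1]
  expect_equal(r2, permanova_oracle(as.matrix(dg), meta2, "grp")$r2[[1]],
               tolerance = 1e-9)
  expect_gt(r2, 0.999)

  # joint relabeling of samples leaves R2 and F unchanged
  meta3 <- data.frame(sample_id = rownames(m), grp = rep(c("a", "b"), 3))
  base <- tidy(permanova(d, meta3, "grp", n_permutations = 19, seed = 1))
  p <- sample(6)
  dmp <- as.matrix(d)[p, p]
  meta_p <- meta3[p, ]
  perm <- tidy(permanova(dmp, meta_p, "grp", n_permutations = 19, seed = 1))
  expect_equal(perm$R2, base$R2, tolerance = 1e-12)
  expect_equal(perm$F, base$F, tolerance = 1e-12)

  expect_error(permanova(d, meta3, "grp", n_permutations = 0), "n_permutations")
})

test_that("pairwise PERMANOVA ranks divergent groups and adjusts with BH", {
  set.seed(10)
  centers <- list(a = c(5, 1, 1), b = c(5, 1.2, 1), c = c(1, 1, 8))
  m <- do.call(rbind, purrr::imap(centers, function(mu, nm) {
    t(replicate(4, mu * exp(rnorm(3, 0, 0.05))))
  }))
  rownames(m) <- sprintf("s%d", 1:12)
  meta <- data.frame(sample_id = rownames(m), diet = rep(c("a", "b", "c"), each = 4))
  res <- pairwise_permanova(bray_curtis(m), meta, "diet",
                            n_permutations = 99, seed = 2)
  expect_equal(nrow(res), 3)
  # the divergent diet c is in the two lowest-q pairs
  worst <- res[order(res$q), ][1:2, ]
  expect_true(all(grepl("c", paste(worst$group_a, worst$group_b))))
  # q is monotone in p
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))

  # a single-sample group is skipped with a warning
  meta_small <- meta[c(1:4, 5:8, 9), ]
  m_small <- m[meta_small$sample_id, ]
  warns <- testthat::capture_warnings(
    res2 <- pairwise_permanova(bray_curtis(m_small), meta_small, "diet",
                               n_permutations = 49, seed = 3)
  )
  expect_true(length(warns) == 2 && all(grepl("< 2 samples", warns)))
  expect_equal(nrow(res2), 1)
})

test_that("permutation p-values are honest under group identity", {
  set.seed(11)
  # identical group centroids: expect a large p most of the time; single run
  # sanity check that p is not extreme
  m <- matrix(abs(rnorm(8 * 3, 5)), 8)
  rownames(m) <- sprintf("s%d", 1:8)
  meta <- data.frame(sample_id = rownames(m), grp = rep(c("a", "b"), 4))
  res <- tidy(permanova(bray_curtis(m), meta, "grp",
                        n_permutations = 199, seed = 4))
  expect_gt(res$p[1], 0.004)  # minimum attainable is 1/200
  expect_lte(res$R2[1], 1)
})
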