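# Rarefaction, Bray-Curtis, PCoA, PERMANOVA, the DA screen, and the
# correlation map.

test_that("rarefaction preserves depth exactly and is hypergeometric in
           expectation", {
  m <- random_counts(20, 6, seed = 41, lambda = 80)
  r <- rarefy_counts(m, depth = 200, seed = 7)
  expect_true(all(colSums(r) == 200))
  expect_identical(r, rarefy_counts(m, depth = 200, seed = 7))
  # depth equal to the column sum returns the same multiset
  j <- 1
  r_full <- rarefy_counts(m[, j, drop = FALSE], depth = sum(m[, j]))
  expect_identical(as.vector(r_full), as.vector(m[, j]))
  # single-OTU sample gets the full depth on that OTU
  one <- matrix(c(500L, 0L), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(as.vector(rarefy_counts(one, depth = 50)), c(50, 0))
  # expectation depth * count / total over repeated draws (2%)
  col <- m[, 1, drop = FALSE]
  draws <- sapply(1:100, function(s) rarefy_counts(col, 200, seed = s))
  big <- rowSums(col) > 50
  expect_equal(rowMeans(draws)[big],
               (200 * col / sum(col))[big], tolerance = 0.02)
  expect_warning(rarefy_counts(m, depth = sum(m[, 1]) + 10), "dropping")
  expect_error(rarefy_counts(m, depth = 0), "> 0")
})

test_that("Bray-Curtis matches the definition and an independent oracle", {
  a <- c(0.5, 0.5, 0)
  b <- c(0.25, 0.25, 0.5)
  d <- bray_curtis(cbind(s1 = a, s2 = b))
  expect_equal(d["s1", "s2"], 0.5)
  x <- cbind(u = c(1, 2, 0), v = c(1, 2, 0), w = c(0, 0, 5))
  dx <- bray_curtis(x)
  expect_equal(dx["u", "v"], 0)   # identical samples
  expect_equal(dx["u", "w"], 1)   # disjoint supports
  # random tables against a brute-force evaluation of the formula
  m <- random_counts(5, 8, seed = 42)
  dm <- bray_curtis(m)
  rel <- sweep(m, 2, colSums(m), "/")
  for (i in 1:7) for (j in (i + 1):8) {
    bc <- 1 - 2 * sum(pmin(rel[, i], rel[, j])) /
      sum(rel[, i] + rel[, j])
    expect_equal(dm[i, j], bc, tolerance = 1e-12)
  }
  expect_true(all(abs(dm - t(dm)) < 1e-12))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
  skip_if_not_installed("vegan")
  dv <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  expect_equal(unclass(dm), dv, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(bray_curtis(cbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("PCoA reconstructs Euclidean configurations", {
  # collinear points: axis 1 must reproduce all pairwise distances
  x <- c(0, 1, 2, 4, 7)
  d <- as.matrix(dist(x))
  p <- pcoa(d, k = 1)
  rec <- as.matrix(dist(p$points[, 1]))
  expect_equal(rec, d, tolerance = 1e-8, ignore_attr = TRUE)
  # two samples at d = 0.6 embed at +/- 0.3
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  p2 <- pcoa(d2, k = 1)
  expect_equal(sort(as.vector(p2$points)), c(-0.3, 0.3), tolerance = 1e-12)
  # eigenvalue sum equals the trace of the centered matrix
  m <- random_counts(6, 5, seed = 43)
  dm <- bray_curtis(m)
  p3 <- pcoa(dm, k = 2)
  b <- -0.5 * (diag(5) - 1 / 5) %*% (unclass(dm)^2) %*% (diag(5) - 1 / 5)
  expect_equal(sum(p3$eigenvalues), sum(diag(b)), tolerance = 1e-10)
  expect_error(pcoa(d2, k = 2), "positive eigenvalues")
  # agreement with classical MDS up to sign
  cm <- cmdscale(dm, k = 2)
  expect_equal(abs(unname(p3$points)), abs(unname(cm)), tolerance = 1e-8)
})

test_that("PERMANOVA recovers the exact enumeration p on a separated toy", {
  d <- block_dissimilarity(3, 3, between = 1)
  f <- data.frame(grp = rep(c("a", "b"), each = 3))
  res <- permanova(d, f, terms = "grp", n_perm = "exact")
  expect_equal(res$p[res$term == "grp"], 1 / 10)
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-12)
  # sampled permutations agree within Monte-Carlo error
  res_mc <- permanova(d, f, terms = "grp", n_perm = 999, seed = 5)
  expect_lt(abs(res_mc$p[1] - 0.1), 3 * sqrt(0.1 * 0.9 / 999) + 1e-3)
  expect_error(permanova(d, data.frame(grp = c("a", rep("b", 5))),
                         terms = "grp"), "singleton")
})

test_that("PERMANOVA matches vegan::adonis2 on random two-factor data", {
  skip_if_not_installed("vegan")
  m <- random_counts(25, 12, seed = 44)
  dm <- bray_curtis(m)
  f <- data.frame(a = rep(c("x", "y"), each = 6),
                  b = rep(c("p", "q", "r"), times = 4))
  res <- permanova(dm, f, terms = c("a", "b"), n_perm = 199, seed = 1)
  ad <- vegan::adonis2(as.dist(dm) ~ a + b, data = f, permutations = 199,
                       by = "terms")
  expect_equal(res$SumOfSqs[1:2], ad$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$F[1:2], ad$F[1:2], tolerance = 1e-8)
  expect_equal(res$R2[1:2], ad$R2[1:2], tolerance = 1e-8)
})

test_that("PERMANOVA p-values are uniform under a null of no effect", {
  # many small null datasets; Kolmogorov-Smirnov against U(0,1]
  ps <- sapply(1:120, function(s) {
    m <- random_counts(15, 8, seed = 1000 + s)
    f <- data.frame(grp = rep(c("x", "y"), each = 4))
    permanova(bray_curtis(m), f, terms = "grp", n_perm = 99,
              seed = s)$p[1]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("within-block permutation preserves block structure", {
  m <- random_counts(15, 8, seed = 45)
  f <- data.frame(grp = rep(c("x", "y"), each = 4))
  blocks <- rep(1:4, times = 2)
  res <- permanova(bray_curtis(m), f, terms = "grp", n_perm = 99,
                   seed = 2, blocks = blocks)
  expect_true(res$p[1] > 0 && res$p[1] <= 1)
})

test_that("the enrichment screen behaves on degenerate and toy inputs", {
  # identical groups: every fold-change is zero
  m <- random_counts(10, 4, seed = 46)
  mm <- cbind(m, m)
  sc <- enrichment_screen(mm, rep(c("g1", "g2"), each = 4))
  expect_equal(sc$log2fc, rep(0, 10))
  expect_true(all(!sc$significant))
  # BH adjustment is monotone in the raw-p ranking and >= raw p
  m2 <- random_counts(30, 8, seed = 47)
  m2[1:3, 5:8] <- m2[1:3, 5:8] * 8L
  sc2 <- enrichment_screen(m2, rep(c("g1", "g2"), each = 4))
  expect_true(all(sc2$padj >= sc2$p - 1e-15))
  o <- order(sc2$p)
  expect_true(all(diff(sc2$padj[o]) >= -1e-15))
  expect_equal(sc2$padj, p.adjust(sc2$p, "BH"))
  expect_error(enrichment_screen(m2, rep("g1", 8)), "two levels")
  # permutation mode: p-values bounded below by the arrangement count
  sc3 <- enrichment_screen(m2, rep(c("g1", "g2"), each = 4),
                           p_method = "permutation", pool_null = FALSE)
  expect_true(all(sc3$p >= 1 / 71))
})

test_that("the screen recovers strongly planted taxa and flags direction", {
  d <- small_design(seed = 48, n_replicates = 4)
  tr <- synthetic_truth(d, n_enriched = 10, enriched_log2fc = 4)
  o <- simulate_otu_table(d, tr, n_taxa = 80, depth = 8000)
  idx <- o$samples$management == "ORG" &
    o$samples$fraction %in% c("13C-light", "13C-heavy")
  sc <- enrichment_screen(o$counts[, idx],
                          factor(o$samples$fraction[idx],
                                 levels = c("13C-light", "13C-heavy")))
  hits <- sc$otu[sc$significant & sc$direction == "up"]
  expect_gte(sum(o$enriched_taxa %in% hits), 7)
})

test_that("Spearman correlation maps order rows by fold-change and
           propagate NA for constant variables", {
  d <- small_design(seed = 49, n_replicates = 4)
  tr <- synthetic_truth(d, n_enriched = 8, enriched_log2fc = 4)
  o <- simulate_otu_table(d, tr, n_taxa = 60, depth = 6000)
  idx <- o$samples$fraction == "13C-heavy"
  sc <- enrichment_screen(o$counts[, idx],
                          factor(o$samples$management[idx],
                                 levels = c("CON", "ORG")), fdr = 0.05)
  skip_if(sum(sc$significant) < 2)  # needs some discoveries to correlate
  units_of <- paste(o$samples$treatment[idx],
                    paste0("R", o$samples$replicate[idx]), sep = "-")
  soil <- simulate_soil_chemistry(d)
  soil$unit_id <- paste(soil$treatment, paste0("R", soil$replicate),
                        sep = "-")
  soil$constant_var <- 1
  rho <- otu_soil_correlations(sc, o$counts[, idx], units_of, soil,
                               fdr = 0.05)
  lfc <- attr(rho, "log2fc")
  expect_true(all(diff(lfc) <= 0))
  expect_identical(rownames(rho), names(lfc))
  expect_true(all(is.na(rho[, "constant_var"])))
  expect_true(all(abs(rho[!is.na(rho)]) <= 1 + 1e-12))
  # a variable equal to an OTU's own ranks correlates perfectly
  top <- rownames(rho)[1]
  rel <- sweep(o$counts[, idx], 2, colSums(o$counts[, idx]), "/")
  soil2 <- soil
  soil2$mirror <- rel[top, ][match(soil$unit_id, units_of)]
  rho2 <- otu_soil_correlations(sc, o$counts[, idx], units_of, soil2,
                                fdr = 0.05)
  expect_equal(unname(rho2[top, "mirror"]), 1, tolerance = 1e-12)
})

test_that("Spearman values match the explicit rank formula on a toy", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  # midrank-based Spearman computed from first principles
  rx <- rank(x); ry <- rank(y)
  rho_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(cor(x, y, method = "spearman"), rho_manual,
               tolerance = 1e-12)
  expect_equal(cor(x, -x, method = "spearman"), -1)
})
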