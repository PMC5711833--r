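# Native SIP-fraction community analysis: rarefaction, Bray-Curtis, PCoA,
# PERMANOVA, a permutation differential-abundance screen, and Spearman
# correlation maps.

#' Rarefy an OTU count table to equal depth
#'
#' Subsamples each sample (column) without replacement to exactly `depth`
#' reads. Samples with fewer than `depth` reads are dropped with a
#' warning. Reproducible from `seed`.
#'
#' @param counts Nonnegative integer matrix, OTUs x samples.
#' @param depth Target depth (> 0). Defaults to the minimum column sum.
#' @param seed Integer seed.
#' @return Rarefied count matrix; every column sums exactly to `depth`.
#' @export
rarefy_counts <- function(counts, depth = min(colSums(counts)), seed = 1L) {
  if (depth <= 0) stop("`depth` must be > 0")
  if (any(counts < 0)) stop("counts must be nonnegative")
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " sample(s) shallower than depth ",
            depth, ": ", paste(colnames(counts)[!keep], collapse = ", "))
    counts <- counts[, keep, drop = FALSE]
  }
  n_otu <- nrow(counts)
  with_seed(seed, {
    out <- vapply(seq_len(ncol(counts)), function(j) {
      pool <- rep.int(seq_len(n_otu), counts[, j])
      tabulate(pool[sample.int(length(pool), depth)], nbins = n_otu)
    }, integer(n_otu))
  })
  dimnames(out) <- dimnames(counts)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = 1 - 2 * sum(min(a_i, b_i)) / sum(a_i + b_i)` on per-sample
#' relative abundances. Counts are normalized per sample first.
#'
#' @param x Numeric matrix, OTUs x samples (columns are samples).
#' @return Square symmetric matrix of class `bray_curtis` with zero
#'   diagonal and entries in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  totals <- colSums(x)
  if (any(totals == 0)) stop("all-zero sample(s): ",
                             paste(colnames(x)[totals == 0], collapse = ", "))
  rel <- sweep(x, 2, totals, "/")
  n <- ncol(rel)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- rel[, i]; b <- rel[, j]
      dij <- 1 - 2 * sum(pmin(a, b)) / sum(a + b)
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  structure(d, class = c("bray_curtis", "matrix", "array"))
}

# Gower-centered inner-product matrix from a dissimilarity matrix.
gower_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  -0.5 * j %*% (d^2) %*% j
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of the squared
#' dissimilarities followed by eigendecomposition. Coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' negative eigenvalues are reported but no correction is applied. Axis
#' signs are fixed so the largest-magnitude loading on each axis is
#' positive.
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`).
#' @param k Number of axes to return; must not exceed the number of
#'   positive eigenvalues.
#' @return List of class `pcoa_result`: `points` (n x k), `eigenvalues`
#'   (all, decreasing), `prop_explained` (over positive eigenvalues), and
#'   `negative` (TRUE if any eigenvalue is meaningfully negative).
#' @export
pcoa <- function(d, k = 2) {
  b <- gower_center(d)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  npos <- sum(e$values > tol)
  if (k > npos)
    stop("k = ", k, " exceeds the number of positive eigenvalues (",
         npos, ")")
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(as.matrix(d))
  colnames(pts) <- paste0("PCo", seq_len(k))
  structure(list(points = pts, eigenvalues = e$values,
                 prop_explained = pmax(e$values, 0) / sum(pmax(e$values, 0)),
                 negative = any(e$values < -tol)),
            class = "pcoa_result")
}

# All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutational multivariate analysis of variance
#'
#' Distance-based PERMANOVA with sequential (Type I) decomposition over
#' one or more categorical terms, using the hat-matrix trace form on the
#' Gower-centered matrix. The permutation p-value is
#' `(#\{F* >= F_obs\} + 1) / (n_perm + 1)` under unrestricted permutation
#' of samples, or within-block permutation when `blocks` is given
#' (approximating a split-plot error structure by preserving
#' exchangeability within blocks). `n_perm = "exact"` enumerates all `n!`
#' sample permutations (n <= 9) and returns the exact
#' `p = #\{F* >= F_obs\} / n!` including the identity.
#'
#' @param d Dissimilarity matrix (or `dist`).
#' @param factors Data frame of sample-aligned categorical variables.
#' @param terms Character vector naming columns of `factors`, fitted
#'   sequentially.
#' @param n_perm Number of permutations (>= 99), or `"exact"`.
#' @param seed Integer seed for the permutation stream.
#' @param blocks Optional factor restricting permutations within blocks.
#' @return Object of class `permanova`: a data frame with one row per
#'   term plus `Residual` and `Total` (`Df`, `SumOfSqs`, `R2`, `F`,
#'   `p`), with attributes `n_perm` and `seed`.
#' @export
permanova <- function(d, factors, terms = names(factors), n_perm = 999,
                      seed = 1L, blocks = NULL) {
  g <- gower_center(d)
  n <- nrow(g)
  stopifnot(nrow(factors) == n)
  for (tm in terms) {
    lv <- table(factors[[tm]])
    if (any(lv < 2))
      stop("term `", tm, "` has singleton level(s): ",
           paste(names(lv)[lv < 2], collapse = ", "))
  }
  exact <- identical(n_perm, "exact")
  if (!exact && n_perm < 99) stop("`n_perm` must be >= 99 (or \"exact\")")
  if (exact && n > 9) stop("exact enumeration limited to n <= 9 samples")

  hats <- vector("list", length(terms))
  x <- matrix(1, n, 1)
  h_prev <- x %*% solve(crossprod(x)) %*% t(x)
  df <- numeric(length(terms))
  rank_prev <- 1L
  for (i in seq_along(terms)) {
    x <- stats::model.matrix(
      stats::as.formula(paste("~", paste(terms[seq_len(i)], collapse = "+"))),
      data = factors)
    qx <- qr(x)
    h <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    h <- h %*% solve(crossprod(h)) %*% t(h)
    hats[[i]] <- h - h_prev
    df[i] <- qx$rank - rank_prev
    rank_prev <- qx$rank
    h_prev <- h
  }
  h_model <- h_prev
  df_res <- n - rank_prev
  ss_stats <- function(gp) {
    ss_terms <- vapply(hats, function(hd) sum(hd * gp), numeric(1))
    ss_res <- sum((diag(n) - h_model) * gp)
    f <- (ss_terms / df) / (ss_res / df_res)
    list(ss = ss_terms, ss_res = ss_res, f = f)
  }
  obs <- ss_stats(g)
  ss_total <- sum(diag(g))

  perm_f <- function(idx) ss_stats(g[idx, idx])$f
  if (exact) {
    perms <- all_permutations(n)
    fp <- apply(perms, 1, perm_f)
    fp <- matrix(fp, nrow = length(terms))
    p <- rowMeans(fp >= obs$f)
    n_perm_used <- nrow(perms)
  } else {
    shuffle <- if (is.null(blocks)) {
      function() sample.int(n)
    } else {
      blocks <- as.factor(blocks)
      function() {
        idx <- seq_len(n)
        for (b in levels(blocks)) {
          w <- which(blocks == b)
          idx[w] <- w[sample.int(length(w))]
        }
        idx
      }
    }
    with_seed(seed, {
      count <- numeric(length(terms))
      for (r in seq_len(n_perm)) {
        f <- perm_f(shuffle())
        count <- count + (f >= obs$f - 1e-12)
      }
    })
    p <- (count + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1),
    SumOfSqs = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p = c(p, NA, NA))
  structure(out, class = c("permanova", "data.frame"),
            n_perm = n_perm_used, seed = seed)
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", attr(x, "n_perm"), " permutations)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

# Welch t statistics for all rows of y between two groups.
row_welch_t <- function(y, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(y[, g1, drop = FALSE])
  m2 <- rowMeans(y[, g2, drop = FALSE])
  v1 <- rowSums((y[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((y[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m2 - m1) / se
  t[se == 0 & m1 == m2] <- 0
  t[se == 0 & m1 != m2] <- sign(m2 - m1)[se == 0 & m1 != m2] * Inf
  t
}

# Empirical-Bayes shrinkage of per-OTU variances: method-of-moments fit of
# a scaled inverse-chi-square prior to the log sample variances.
moderate_variances <- function(s2, df) {
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(df / 2) + log(df / 2)
  excess <- stats::var(e) - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * stats::uniroot(function(x) trigamma(x) - excess,
                             c(1e-4, 1e7))$root
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(s2_post = if (is.finite(d0)) (d0 * s02 + df * s2) / (d0 + df)
       else rep(s02, length(s2)),
       d0 = d0, s02 = s02)
}

#' Differential-abundance screen for SIP fractions
#'
#' A transparent stand-in screen for selecting differentially abundant
#' OTUs between two sample groups (e.g. 13C-heavy vs 13C-light fractions,
#' or management systems within a fraction). Per OTU it reports the log2
#' fold-change of mean relative abundance (after adding a pseudocount to
#' every cell) and a t statistic on log2 relative abundances, with
#' Benjamini-Hochberg FDR adjustment of the p-values.
#'
#' Two p-value methods are available. The default, `"moderated"`, is an
#' empirical-Bayes moderated t: per-OTU variances are shrunk toward a
#' common scaled inverse-chi-square prior fitted by method of moments,
#' and the statistic is referred to a t distribution with augmented
#' degrees of freedom. This gives continuous p-values and usable power at
#' the small group sizes typical of SIP designs (n = 4 per group), where
#' any label-permutation p-value is floored at one over the number of
#' distinct arrangements (1/70 for 4 vs 4) -- above an FDR threshold of
#' 0.01 before adjustment. `"permutation"` is the assumption-free
#' alternative: a two-sided p from group-label shuffles of a per-OTU
#' Welch statistic (exhaustive when feasible, otherwise `n_perm` random
#' shuffles), with the null optionally pooled across OTUs. The screen is
#' deliberately simple and is not numerically comparable to
#' negative-binomial Wald methods.
#'
#' @param counts OTU x sample count matrix.
#' @param group Factor (or vector) with exactly two levels assigning each
#'   sample (column) to a group; each group needs >= 2 samples. Fold
#'   changes are level 2 relative to level 1.
#' @param pseudocount Count added to every cell before relative-abundance
#'   conversion.
#' @param p_method `"moderated"` (default) or `"permutation"`; see
#'   Details.
#' @param n_perm Maximum number of random shuffles for the permutation
#'   method.
#' @param seed Integer seed (permutation method only).
#' @param fdr FDR threshold used for the `significant` flag.
#' @param pool_null Pool permuted statistics across OTUs (permutation
#'   method; default TRUE).
#' @return Data frame of class `enrichment_screen`: `otu`, `log2fc`,
#'   `stat`, `p`, `padj`, `direction` (`"up"` = higher in level 2),
#'   `significant`; attributes `contrast`, `p_method`, and `fdr`.
#' @export
enrichment_screen <- function(counts, group, pseudocount = 1,
                              p_method = c("moderated", "permutation"),
                              n_perm = 999, seed = 1L, fdr = 0.01,
                              pool_null = TRUE) {
  p_method <- match.arg(p_method)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("`group` must have exactly two levels")
  if (any(table(group) < 2)) stop("each group needs >= 2 samples")
  if (ncol(counts) != length(group)) stop("group/column mismatch")
  lv <- levels(group)
  rel <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  y <- log2(rel)
  g1 <- which(group == lv[1])
  g2 <- which(group == lv[2])
  lfc <- log2(rowMeans(rel[, g2, drop = FALSE]) /
                rowMeans(rel[, g1, drop = FALSE]))

  if (p_method == "moderated") {
    n1 <- length(g1); n2 <- length(g2)
    df <- n1 + n2 - 2
    m1 <- rowMeans(y[, g1, drop = FALSE])
    m2 <- rowMeans(y[, g2, drop = FALSE])
    s2 <- (rowSums((y[, g1, drop = FALSE] - m1)^2) +
             rowSums((y[, g2, drop = FALSE] - m2)^2)) / df
    mod <- moderate_variances(s2, df)
    stat <- (m2 - m1) / sqrt(mod$s2_post * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(stat), df + mod$d0)
  } else {
    stat <- row_welch_t(y, g1, g2)
    n <- length(group)
    n2 <- length(g2)
    if (choose(n, n2) <= max(n_perm, 2000)) {
      assign2 <- utils::combn(n, n2)
    } else {
      with_seed(seed, {
        assign2 <- replicate(n_perm, sample.int(n, n2))
      })
    }
    null_t <- apply(assign2, 2, function(idx2)
      row_welch_t(y, setdiff(seq_len(n), idx2), idx2))
    abs_obs <- abs(stat)
    if (pool_null) {
      pool <- abs(as.vector(null_t))
      pool <- pool[is.finite(pool)]
      srt <- sort(pool)
      ge <- length(srt) - findInterval(abs_obs - 1e-12, srt)
      p <- (ge + 1) / (length(srt) + 1)
    } else {
      p <- (rowSums(abs(null_t) >= abs_obs - 1e-12) + 1) /
        (ncol(null_t) + 1)
    }
  }
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(otu = rownames(counts), log2fc = lfc, stat = stat,
                    p = p, padj = padj,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    significant = padj < fdr, row.names = NULL)
  structure(out, class = c("enrichment_screen", "data.frame"),
            contrast = paste(lv[2], "vs", lv[1]),
            p_method = p_method, fdr = fdr)
}

#' Spearman correlations between enriched OTUs and soil attributes
#'
#' Correlates the per-sample relative abundance of FDR-significant OTUs
#' from an [enrichment_screen()] with soil chemical, metabolic, and
#' thermodynamic variables measured on the matching experimental units.
#' Rows (OTUs) are ordered by decreasing log2 fold-change, as in the
#' field's clustered-image maps; columns are ordered by average-linkage
#' hierarchical clustering on `1 - |rho|`. A constant variable yields
#' `NA`, not zero.
#'
#' @param screen An `enrichment_screen` result.
#' @param counts OTU x sample count matrix (same OTUs).
#' @param sample_units Character vector (length = ncol(counts)) giving the
#'   experimental unit id of each sample.
#' @param soil Data frame with a `unit_id` column and numeric soil /
#'   metabolic variables.
#' @param fdr Selection threshold (defaults to the screen's).
#' @return Matrix of Spearman correlations (OTUs x variables) of class
#'   `otu_soil_correlations`, with attribute `log2fc` (row order) and
#'   `col_order`.
#' @export
otu_soil_correlations <- function(screen, counts, sample_units, soil,
                                  fdr = attr(screen, "fdr")) {
  stopifnot(inherits(screen, "enrichment_screen"))
  sel <- screen[screen$padj < fdr, ]
  if (!nrow(sel)) stop("no OTUs pass FDR < ", fdr)
  sel <- sel[order(-sel$log2fc), ]
  if (is.null(soil$unit_id)) stop("`soil` needs a `unit_id` column")
  m <- match(sample_units, soil$unit_id)
  if (anyNA(m)) stop("sample unit(s) missing from `soil`: ",
                     paste(unique(sample_units[is.na(m)]), collapse = ", "))
  vars <- names(soil)[vapply(soil, is.numeric, logical(1))]
  vars <- setdiff(vars, "replicate")
  soil_mat <- as.matrix(soil[m, vars, drop = FALSE])
  rel <- sweep(counts, 2, colSums(counts), "/")
  abund <- t(rel[sel$otu, , drop = FALSE])
  rho <- suppressWarnings(
    stats::cor(abund, soil_mat, method = "spearman",
               use = "pairwise.complete.obs"))
  ok <- colSums(is.finite(rho)) > 0
  col_order <- colnames(rho)
  if (sum(ok) >= 3) {
    dd <- stats::as.dist(1 - abs(stats::cor(soil_mat[, ok, drop = FALSE],
                                            method = "spearman",
                                            use = "pairwise.complete.obs")))
    dd[!is.finite(dd)] <- 1
    hc <- stats::hclust(dd, method = "average")
    col_order <- c(colnames(rho)[ok][hc$order], colnames(rho)[!ok])
  }
  rho <- rho[, col_order, drop = FALSE]
  structure(rho, class = c("otu_soil_correlations", "matrix", "array"),
            log2fc = stats::setNames(sel$log2fc, sel$otu),
            col_order = col_order)
}
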