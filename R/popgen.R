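# Validation analytics: PCA, discriminant clustering, Weir-Cockerham FST,
# identity-by-state duplicate detection, trio parentage.

# dosage matrix cleanup: OTV codes become missing
.clean_dosage <- function(g) {
  g[g == OTV_CODE] <- NA
  g
}

#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per SNP, columns centered (optionally
#' unit-scaled), and the matrix decomposed by SVD (`prcomp`). All-missing
#' SNPs are dropped (logged in the `dropped` attribute).
#'
#' @param genotypes samples x SNPs dosage matrix (NA missing; OTV codes are
#'   treated as missing).
#' @param scale. unit-scale columns (default FALSE).
#' @return a `pca_result` list: `coordinates` (samples x components),
#'   `variance_explained` (percent per component, nonincreasing).
#' @export
pca_genotypes <- function(genotypes, scale. = FALSE) {
  g <- .clean_dosage(genotypes)
  if (nrow(g) < 2) stop("PCA needs at least 2 samples")
  mu <- colMeans(g, na.rm = TRUE)
  dropped <- which(is.nan(mu))
  if (length(dropped)) {
    g <- g[, -dropped, drop = FALSE]
    mu <- mu[-dropped]
  }
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  if (scale.) {
    sdv <- apply(g, 2, stats::sd)
    keep <- sdv > 0
    g <- g[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(g, center = TRUE, scale. = scale.)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = pc$x, variance_explained = ve,
                 dropped = dropped), class = "pca_result")
}

# BIC of the k-means partition under a spherical Gaussian mixture with
# cluster-specific variances (classification likelihood); parameter count
# k*d means + k variances + (k-1) weights
.kmeans_bic <- function(scores, km) {
  n <- nrow(scores); d <- ncol(scores)
  nk <- km$size
  sig2 <- pmax(km$withinss / (nk * d), 1e-9)
  ll <- sum(-nk * d / 2 * (log(2 * pi * sig2) + 1) + nk * log(nk / n))
  -2 * ll + (length(nk) * (d + 2) - 1) * log(n)
}

#' Discriminant clustering of principal components
#'
#' A light reimplementation of discriminant analysis of principal
#' components: PCA, then k-means over the retained PCs for each `k` in
#' `k_range` with the cluster number selected by BIC, then a linear
#' discriminant projection onto at most `k - 1` axes. Seeded and
#' deterministic per seed.
#'
#' @param genotypes samples x SNPs dosage matrix.
#' @param k_range candidate cluster numbers (values exceeding the sample
#'   count are skipped).
#' @param n_pcs number of retained principal components (capped at the
#'   rank).
#' @param seed integer seed for the k-means starts.
#' @return list with `k` (selected), `labels`, `bic` (named vector),
#'   `coords` (discriminant coordinates; NULL when `k = 1`),
#'   `pca` (the underlying `pca_result`).
#' @export
dapc_lite <- function(genotypes, k_range = 1:8, n_pcs = 10, seed = 1) {
  pca <- pca_genotypes(genotypes)
  n_pcs <- min(n_pcs, ncol(pca$coordinates))
  scores <- pca$coordinates[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(scores)
  k_range <- k_range[k_range <= n]
  bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  kms <- list()
  withr::with_seed(seed, {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      km <- if (k == 1) {
        wss <- sum(scale(scores, scale = FALSE)^2)
        list(cluster = rep(1L, n), size = n, tot.withinss = wss, withinss = wss)
      } else {
        # k exceeding the number of distinct points is skipped
        tryCatch(stats::kmeans(scores, centers = k, nstart = 10, iter.max = 50),
                 error = function(e) NULL)
      }
      kms[[i]] <- km
      bic[i] <- if (is.null(km)) NA_real_ else .kmeans_bic(scores, km)
    }
  })
  best <- which.min(bic)
  k <- k_range[best]
  labels <- kms[[best]]$cluster
  coords <- NULL
  if (k > 1) {
    ld <- MASS::lda(scores, grouping = factor(labels))
    coords <- stats::predict(ld, as.data.frame(scores))$x
  }
  list(k = k, labels = labels, bic = bic, coords = coords, pca = pca)
}

# Weir & Cockerham (1984) variance components for one pair/set of groups.
# Returns c(a_sum, abc_sum) over polymorphic loci.
.wc_components <- function(g, groups) {
  groups <- droplevels(factor(groups))
  r <- nlevels(groups)
  idx <- lapply(levels(groups), function(l) which(groups == l))
  nmat <- sapply(idx, function(i) colSums(!is.na(g[i, , drop = FALSE])))   # loci x r
  pmat <- sapply(idx, function(i) colMeans(g[i, , drop = FALSE], na.rm = TRUE) / 2)
  hmat <- sapply(idx, function(i) colMeans(g[i, , drop = FALSE] == 1, na.rm = TRUE))
  nmat <- matrix(nmat, ncol = r); pmat <- matrix(pmat, ncol = r)
  hmat <- matrix(hmat, ncol = r)
  nbar <- rowMeans(nmat)
  nsum <- rowSums(nmat)
  nc <- (nsum - rowSums(nmat^2) / nsum) / (r - 1)
  pbar <- rowSums(nmat * pmat) / nsum
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * hmat) / nsum
  ok <- rowSums(nmat >= 1) == r & nbar > 1 & nc > 0 & pbar > 0 & pbar < 1
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a[ok]), abc = sum((a + b + cc)[ok]))
}

#' Pairwise Weir-Cockerham FST
#'
#' Multi-locus ratio-of-sums Weir & Cockerham (1984) theta between every
#' pair of groups, computed over loci polymorphic in the pair; negative
#' estimates are reported as-is. Missing genotypes reduce the per-locus
#' sample sizes. With `pairwise = FALSE`, the single multi-population
#' estimate over all groups is returned.
#'
#' @param genotypes samples x SNPs dosage matrix (0/1/2; NA and OTV treated
#'   as missing).
#' @param groups factor/vector of group labels per sample; at least 2 groups
#'   of at least 2 samples each.
#' @param pairwise return the symmetric pairwise matrix (default) or one
#'   overall estimate.
#' @return symmetric FST matrix with zero diagonal, or a single number.
#' @export
fst_wc <- function(genotypes, groups, pairwise = TRUE) {
  g <- .clean_dosage(genotypes)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  if (!pairwise) {
    comp <- .wc_components(g, groups)
    return(unname(comp["a"] / comp["abc"]))
  }
  lev <- levels(groups)
  m <- matrix(0, nlevels(groups), nlevels(groups), dimnames = list(lev, lev))
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in seq((i + 1), length(lev))) {
      sel <- groups %in% lev[c(i, j)]
      comp <- .wc_components(g[sel, , drop = FALSE], groups[sel])
      m[i, j] <- m[j, i] <- comp["a"] / comp["abc"]
    }
  }
  m
}

#' Identity-by-state matrix and duplicate detection
#'
#' `IBS(i, j)` is the mean over shared non-missing loci of
#' `1 - |g_i - g_j| / 2`; OTV codes are treated as missing. Pairs without
#' shared loci get NA.
#'
#' @param genotypes samples x SNPs dosage matrix.
#' @return symmetric IBS matrix with unit diagonal.
#' @export
ibs_matrix <- function(genotypes) {
  g <- .clean_dosage(genotypes)
  obs <- !is.na(g)
  ind <- lapply(0:2, function(v) {
    m <- (g == v) & obs
    m[is.na(m)] <- FALSE
    m * 1
  })
  shared <- (obs * 1) %*% t(obs * 1)
  dsum <- matrix(0, nrow(g), nrow(g))
  for (a in 0:2) for (b in 0:2) {
    w <- abs(a - b)
    if (w > 0) dsum <- dsum + w * (ind[[a + 1]] %*% t(ind[[b + 1]]))
  }
  ibs <- 1 - (dsum / shared) / 2
  ibs[shared == 0] <- NA
  diag(ibs) <- ifelse(diag(shared) > 0, 1, NA)
  dimnames(ibs) <- list(rownames(g), rownames(g))
  ibs
}

#' Find duplicate sample pairs by IBS
#'
#' @param ibs an IBS matrix from [ibs_matrix()].
#' @param threshold duplicates are pairs with `IBS > threshold`
#'   (default 0.97).
#' @return data.frame `sample1`, `sample2`, `ibs`.
#' @export
find_duplicates <- function(ibs, threshold = 0.97) {
  hits <- which(upper.tri(ibs) & !is.na(ibs) & ibs > threshold, arr.ind = TRUE)
  data.frame(sample1 = rownames(ibs)[hits[, 1]],
             sample2 = colnames(ibs)[hits[, 2]],
             ibs = ibs[hits], stringsAsFactors = FALSE)
}

# Mendelian conflict of offspring o against parent pair (g1, g2), vectorized
.trio_conflict <- function(o, g1, g2) {
  (o == 0L & (g1 == 2L | g2 == 2L)) |
    (o == 2L & (g1 == 0L | g2 == 0L)) |
    (o == 1L & ((g1 == 0L & g2 == 0L) | (g1 == 2L & g2 == 2L)))
}

#' Assign trio parentage by Mendelian exclusion
#'
#' For each offspring, every unordered candidate parent pair is scored by
#' its mismatch rate: the fraction of informative loci (all three genotypes
#' called) where the offspring genotype cannot be produced by one allele
#' from each parent (opposing homozygotes against either parent, or a
#' heterozygous offspring with two identical homozygous parents). The
#' unique pair minimizing the mismatch rate is assigned when its rate is at
#' most `eps`; ties or no qualifying pair leave the offspring unassigned.
#' A per-parent opposing-homozygote screen (`oh_rate`, also used to shortlist
#' pairs for speed: a pair's mismatch rate is never below either parent's
#' opposing-homozygote rate) is reported alongside.
#'
#' @param offspring samples x loci dosage matrix of offspring.
#' @param candidate_parents samples x loci dosage matrix of candidate
#'   parents (unsexed; pairs are unordered).
#' @param eps mismatch-rate tolerance covering genotyping error
#'   (default 0.01).
#' @param min_call_rate offspring below this call-rate floor are left
#'   unassigned and flagged.
#' @return a `trio_assignment` data.frame: `offspring_id`, `parent1`,
#'   `parent2`, `mismatch_rate`, `n_informative`, `assigned`, `low_call_rate`;
#'   the per-parent screen is in `attr(, "oh_rate")`.
#' @export
assign_trios <- function(offspring, candidate_parents, eps = 0.01,
                         min_call_rate = 0.5) {
  off <- .clean_dosage(offspring)
  par <- .clean_dosage(candidate_parents)
  n_off <- nrow(off); n_par <- nrow(par)
  # opposing-homozygote prescreen: OH(parent) <= pair mismatch, so parents
  # with OH above the tolerance (plus missing-data slack) can be skipped
  O0 <- (off == 0L); O2 <- (off == 2L); Oobs <- !is.na(off)
  P0 <- (par == 0L); P2 <- (par == 2L); Pobs <- !is.na(par)
  z <- function(m) { m[is.na(m)] <- FALSE; m * 1 }
  oh_cnt <- z(O0) %*% t(z(P2)) + z(O2) %*% t(z(P0))
  oh_n <- (Oobs * 1) %*% t(Pobs * 1)
  oh_rate <- oh_cnt / oh_n
  shortlist_max <- max(2 * eps, 0.02)

  res <- data.frame(offspring_id = rownames(off), parent1 = NA_character_,
                    parent2 = NA_character_, mismatch_rate = NA_real_,
                    n_informative = NA_integer_, assigned = FALSE,
                    low_call_rate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n_off)) {
    o <- off[i, ]
    if (mean(!is.na(o)) < min_call_rate) { res$low_call_rate[i] <- TRUE; next }
    cand <- which(oh_rate[i, ] <= shortlist_max)
    if (length(cand) < 2) next
    best <- NULL; best_rate <- Inf; tie <- FALSE
    for (ai in seq_along(cand)[-length(cand)]) {
      for (bi in seq((ai + 1), length(cand))) {
        p1 <- cand[ai]; p2 <- cand[bi]
        g1 <- par[p1, ]; g2 <- par[p2, ]
        inf <- !is.na(o) & !is.na(g1) & !is.na(g2)
        if (!any(inf)) next
        rate <- sum(.trio_conflict(o[inf], g1[inf], g2[inf])) / sum(inf)
        if (rate < best_rate - 1e-12) {
          best <- c(p1, p2); best_rate <- rate; tie <- FALSE
        } else if (abs(rate - best_rate) <= 1e-12) {
          tie <- TRUE
        }
      }
    }
    if (!is.null(best) && !tie && best_rate <= eps) {
      res$parent1[i] <- rownames(par)[best[1]]
      res$parent2[i] <- rownames(par)[best[2]]
      res$mismatch_rate[i] <- best_rate
      g1 <- par[best[1], ]; g2 <- par[best[2], ]
      res$n_informative[i] <- sum(!is.na(o) & !is.na(g1) & !is.na(g2))
      res$assigned[i] <- TRUE
    }
  }
  attr(res, "oh_rate") <- oh_rate
  class(res) <- c("trio_assignment", "data.frame")
  res
}
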