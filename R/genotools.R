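#' Construct a genotype dosage matrix
#'
#' @param dosages Integer matrix (individuals x variants) with entries in
#'   {0, 1, 2, NA}; counts of the counted allele.
#' @param variants Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`, `freq`.
#' @param ids Individual identifiers (length nrow(dosages)).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, ids) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages),
            length(ids) == nrow(dosages))
  req <- c("snp_id", "chrom", "pos", "counted_allele", "other_allele",
           "freq")
  if (!all(req %in% names(variants))) {
    stop(sprintf("variants missing column(s): %s",
                 paste(setdiff(req, names(variants)), collapse = ", ")),
         call. = FALSE)
  }
  vals <- dosages[!is.na(dosages)]
  if (length(vals) > 0 && !all(vals %in% 0:2)) {
    stop("dosages must be in {0, 1, 2, NA}", call. = FALSE)
  }
  if (any(variants$freq < 0 | variants$freq > 1, na.rm = TRUE)) {
    stop("counted-allele frequencies must be in [0, 1]", call. = FALSE)
  }
  dimnames(dosages) <- list(ids, variants$snp_id)
  structure(list(dosages = dosages, variants = variants, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the allele counts, the p-value is the sum
#' of the probabilities of all heterozygote counts (of the same parity,
#' allele counts fixed) whose probability does not exceed that of the
#' observed count.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop_param("HWE test undefined for zero total count")
  n1 <- 2 * n_hom1 + n_het  # count of allele 1
  # possible heterozygote counts share the parity of the allele count
  h <- seq(n1 %% 2, min(n1, 2 * n - n1), by = 2)
  # log Pr(het = h | allele counts): multinomial over genotype
  # configurations, 2^h gamete arrangements per heterozygote
  logp <- lgamma(n + 1) - lgamma((n1 - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((2 * n - n1 - h) / 2 + 1) + h * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[h == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Removes variants failing any of: minor allele frequency > `maf_min`
#' (computed from observed dosages), missingness < `miss_max`, and
#' Hardy-Weinberg exact test p >= `hwe_p_min`.
#'
#' @param G A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param miss_max Maximum genotype missingness (exclusive).
#' @param hwe_p_min Hardy-Weinberg exact-test p-value threshold.
#' @return Filtered `genotype_matrix`; attribute `report` gives per-filter
#'   removal counts.
#' @export
variant_qc <- function(G, maf_min = 0.05, miss_max = 0.05,
                       hwe_p_min = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"), ncol(G$dosages) > 0)
  dos <- G$dosages
  n_miss <- colSums(is.na(dos))
  n_obs <- nrow(dos) - n_miss
  miss_rate <- n_miss / nrow(dos)
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    if (n_obs[j] == 0) return(0)
    hwe_exact_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  fail_maf <- is.na(maf) | maf <= maf_min
  fail_miss <- miss_rate >= miss_max
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_miss | fail_hwe)
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         G$variants[keep, , drop = FALSE], G$ids)
  attr(out, "report") <- list(n_in = ncol(dos), n_out = sum(keep),
                              removed_maf = sum(fail_maf),
                              removed_missing = sum(fail_miss),
                              removed_hwe = sum(fail_hwe))
  out
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_kb` kilobases, pairs of variants with
#' squared dosage correlation above `r2_max` are resolved by removing the
#' member with the lower minor allele frequency (ties: the later position);
#' the window then advances by `step` retained variants. No retained pair
#' within a window exceeds `r2_max`.
#'
#' @param G A `genotype_matrix`, variants sorted by (chrom, pos).
#' @param window_kb Window size in kb.
#' @param step Window step in variants.
#' @param r2_max Squared-correlation threshold.
#' @return Character vector of retained snp_ids.
#' @export
ld_prune <- function(G, window_kb = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  by_chrom <- split(seq_len(nrow(v)), v$chrom)
  for (idx in by_chrom) {
    if (is.unsorted(v$pos[idx])) {
      stop("variants must be position-sorted within chromosome",
           call. = FALSE)
    }
  }
  dos <- G$dosages
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  removed <- rep(FALSE, ncol(dos))
  for (idx in by_chrom) {
    start <- 1L
    repeat {
      alive <- idx[!removed[idx]]
      if (length(alive) == 0 || start > length(alive)) break
      w_start <- alive[start]
      in_win <- alive[v$pos[alive] >= v$pos[w_start] &
                        v$pos[alive] <= v$pos[w_start] + window_kb * 1000]
      if (length(in_win) > 1) {
        repeat {
          win_alive <- in_win[!removed[in_win]]
          if (length(win_alive) < 2) break
          X <- dos[, win_alive, drop = FALSE]
          r2 <- suppressWarnings(
            stats::cor(X, use = "pairwise.complete.obs")^2)
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[mx[1], mx[2]] <= r2_max) break
          a <- win_alive[mx[1]]; b <- win_alive[mx[2]]
          drop_j <- if (maf[a] < maf[b]) a
          else if (maf[b] < maf[a]) b
          else if (v$pos[a] >= v$pos[b]) a else b
          removed[drop_j] <- TRUE
        }
      }
      start <- start + step
      if (start > length(idx)) break
    }
  }
  v$snp_id[!removed]
}

#' Principal-component covariates from genotypes
#'
#' Dosages are mean-imputed and standardized per SNP by sqrt(2p(1-p)); the
#' top-k left singular vectors, scaled by their singular values, are the
#' per-individual component scores. The sign convention makes the
#' largest-magnitude loading of each component positive.
#'
#' @param G A `genotype_matrix` (after QC and LD pruning).
#' @param k Number of components.
#' @return Numeric matrix (individuals x k) with columns PC1..PCk.
#' @export
pca_covariates <- function(G, k = 10) {
  stopifnot(inherits(G, "genotype_matrix"), k >= 0)
  n <- nrow(G$dosages)
  if (k == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(G$ids, NULL)))
  }
  X <- G$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  X <- sweep(X, 2L, 2 * p)
  X[is.na(X)] <- 0
  sdv <- sqrt(2 * p * (1 - p))
  ok <- sdv > 0
  X <- sweep(X[, ok, drop = FALSE], 2L, sdv[ok], "/")
  if (k > min(dim(X))) stop_param("k exceeds the rank of the matrix")
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(G$ids, paste0("PC", seq_len(k)))
  scores
}

#' Polygenic risk score with plink score semantics
#'
#' Allele-aligned weighted dosage average: weight SNPs are matched to the
#' genotype matrix by snp_id; where the counted allele differs from the
#' effect allele the dosage is flipped to `2 - dosage`; missing dosages are
#' imputed as twice the effect-allele frequency; the score is
#' `sum(w_j * dose_j) / (2 * m_matched)` (the plink default average), or the
#' plain sum with `average = FALSE`.
#'
#' @param G A `genotype_matrix`.
#' @param weights Data frame with columns `snp_id`, `effect_allele`,
#'   `weight`.
#' @param average Divide by `2 * m_matched` (plink default).
#' @return Named numeric vector of per-individual scores; attribute
#'   `report` lists unmatched SNPs and the match count.
#' @export
prs_score <- function(G, weights, average = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"),
            all(c("snp_id", "effect_allele", "weight") %in% names(weights)))
  if (anyDuplicated(weights$snp_id)) {
    stop("duplicate snp_ids in weight table", call. = FALSE)
  }
  if (any(!is.finite(weights$weight))) {
    stop("non-finite weights", call. = FALSE)
  }
  m <- match(weights$snp_id, G$variants$snp_id)
  matched <- !is.na(m)
  if (!any(matched)) stop_param("no weight SNPs present in genotypes")
  wj <- weights$weight[matched]
  cols <- m[matched]
  ea <- toupper(weights$effect_allele[matched])
  counted <- toupper(G$variants$counted_allele[cols])
  other <- toupper(G$variants$other_allele[cols])
  flip <- ea != counted
  bad <- flip & ea != other
  if (any(bad)) {
    # effect allele matches neither allele: treated as unmatched
    keep <- !bad
    wj <- wj[keep]; cols <- cols[keep]; flip <- flip[keep]
  }
  if (length(cols) == 0) stop_param("no weight SNPs present in genotypes")
  dos <- G$dosages[, cols, drop = FALSE]
  # effect-allele frequency in the matrix orientation
  eaf <- G$variants$freq[cols]
  eaf[flip] <- 1 - eaf[flip]
  for (j in seq_along(cols)) {
    x <- dos[, j]
    if (flip[j]) x <- 2 - x
    x[is.na(x)] <- 2 * eaf[j]
    dos[, j] <- x
  }
  total <- drop(dos %*% wj)
  score <- if (average) total / (2 * length(cols)) else total
  names(score) <- G$ids
  unmatched <- weights$snp_id[!weights$snp_id %in%
                                G$variants$snp_id[cols]]
  attr(score, "report") <- list(n_matched = length(cols),
                                unmatched = unmatched)
  score
}

#' Standardize values to mean 0, SD 1
#'
#' Centres and scales within the supplied cohort using the population
#' (divide-by-n) standard deviation, so the transform is exactly
#' idempotent.
#'
#' @param values Numeric vector, length >= 2, nonzero variance.
#' @return z-scored vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop_param("zscore needs >= 2 values")
  mu <- mean(values, na.rm = TRUE)
  s <- sqrt(mean((values - mu)^2, na.rm = TRUE))
  if (!is.finite(s) || s == 0) stop_param("zscore undefined for zero variance")
  (values - mu) / s
}
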