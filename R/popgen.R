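# Genotype-side statistics: MAF / call-rate filters, VanRaden kinship,
# genotype PCA, LD r2 / decay / pruning, Weir-Cockerham FST and nucleotide
# diversity in sliding windows.

#' Filter SNPs on minor allele frequency and call rate
#'
#' Keeps SNPs whose minor allele frequency (computed on non-missing calls)
#' exceeds `maf_min` and whose fraction of non-missing calls exceeds
#' `call_rate_min` (VCFtools `--maf` / `--max-missing` semantics).
#' Idempotent; an empty result is a warning, not an error.
#'
#' @param g a `genotype_matrix`.
#' @param maf_min MAF strict lower bound (default 0.05).
#' @param call_rate_min call-rate strict lower bound (default 0.8).
#' @return the filtered `genotype_matrix`.
#' @export
filter_variants <- function(g, maf_min = 0.05, call_rate_min = 0.8) {
  n_called <- colSums(!is.na(g$dosage))
  call_rate <- n_called / nrow(g$dosage)
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > maf_min & call_rate > call_rate_min
  if (!any(keep)) warning("no SNPs pass the filters")
  subset_snps(g, keep)
}

# mean-impute missing calls; returns plain matrix
.impute_mean <- function(dosage) {
  cm <- colMeans(dosage, na.rm = TRUE)
  idx <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(idx)) dosage[idx] <- cm[idx[, 2]]
  dosage
}

#' VanRaden kinship matrix
#'
#' Missing calls are imputed to the per-SNP mean; each SNP column is
#' centered at 2p and scaled by sqrt(2p(1-p)) with p the alt-allele
#' frequency; K = ZZ'/m over the m SNPs with non-zero variance
#' (zero-variance SNPs are skipped). Symmetric and positive semi-definite
#' up to numerical tolerance.
#'
#' @param g a `genotype_matrix` (normally already filtered).
#' @return accession x accession kinship matrix.
#' @export
kinship <- function(g) {
  x <- .impute_mean(g$dosage)
  p <- colMeans(x) / 2
  v <- 2 * p * (1 - p)
  keep <- v > 0 & apply(x, 2, function(col) any(col != col[1]))
  x <- x[, keep, drop = FALSE]
  p <- p[keep]; v <- v[keep]
  z <- sweep(sweep(x, 2, 2 * p), 2, sqrt(v), `/`)
  K <- tcrossprod(z) / ncol(z)
  (K + t(K)) / 2
}

#' Genotype principal components
#'
#' Top eigenvectors of the kinship matrix scaled by the square root of
#' their eigenvalues (i.e. principal component scores of the standardized
#' genotypes).
#'
#' @param g a `genotype_matrix`.
#' @param n_pcs number of components (truncated to the rank with a
#'   warning if larger).
#' @param K optional precomputed kinship matrix.
#' @return accession x n_pcs score matrix.
#' @export
genotype_pca <- function(g, n_pcs = 3, K = NULL) {
  if (is.null(K)) K <- kinship(g)
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  rank <- sum(lam > 1e-10 * max(lam))
  if (n_pcs > rank) {
    warning("n_pcs exceeds rank; truncated to ", rank)
    n_pcs <- rank
  }
  sc <- e$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(n_pcs)]), n_pcs)
  dimnames(sc) <- list(rownames(K), paste0("PC", seq_len(n_pcs)))
  sc
}

#' Pairwise LD r-squared
#'
#' Squared Pearson correlation of dosages over accessions with non-missing
#' calls at both SNPs (composite LD). Needs >= 2 shared calls with
#' variance at both SNPs; otherwise NA.
#'
#' @param g a `genotype_matrix`.
#' @param a,b SNP ids or column indices.
#' @return r2 in [0, 1], or NA if undefined.
#' @export
ld_r2 <- function(g, a, b) {
  ia <- if (is.character(a)) match(a, g$map$snp) else a
  ib <- if (is.character(b)) match(b, g$map$snp) else b
  x <- g$dosage[, ia]; y <- g$dosage[, ib]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

# pairwise-complete r2 matrix among a set of dosage columns
.r2_matrix <- function(dosage) {
  suppressWarnings(cor(dosage, use = "pairwise.complete.obs"))^2
}

#' LD decay curve and half-decay distance
#'
#' All within-chromosome SNP pairs closer than `max_dist_bp` are binned by
#' physical distance (`bin_bp` wide bins) and the mean r2 per bin is
#' reported. Two decay distances are interpolated linearly between bin
#' midpoints: `dist_half_max` where the curve falls to half its
#' short-distance maximum (the first bin's mean r2), and `dist_r2_0.5`
#' where it falls to the absolute value 0.5 (the conventional reporting
#' threshold, used as the primary figure). A crossing is only defined when
#' the curve starts above the target; a curve that never decays to the
#' target within range gives NA, with `beyond_max_dist = TRUE` for the
#' half-maximum distance.
#'
#' @param g a `genotype_matrix`.
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp bin width in bp.
#' @return list with `curve` (data.frame: bin midpoint, mean r2, n pairs),
#'   `dist_r2_0.5`, `dist_half_max`, `beyond_max_dist`.
#' @export
ld_decay <- function(g, max_dist_bp = 1e6, bin_bp = 5e4) {
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    pos <- g$map$pos[idx]
    if (length(idx) < 2) next
    r2m <- .r2_matrix(g$dosage[, idx, drop = FALSE])
    pr <- which(upper.tri(r2m), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    sel <- d > 0 & d <= max_dist_bp & !is.na(r2m[pr])
    dists <- c(dists, d[sel])
    r2s <- c(r2s, r2m[pr][sel])
  }
  if (length(dists) == 0) stop("no SNP pairs within max_dist_bp")
  bin <- pmin(ceiling(dists / bin_bp), ceiling(max_dist_bp / bin_bp))
  mid <- (unique(sort(bin)) - 0.5) * bin_bp
  mean_r2 <- as.numeric(tapply(r2s, bin, mean))
  n_pairs <- as.integer(table(bin))
  curve <- data.frame(dist_bp = mid, mean_r2 = mean_r2, n_pairs = n_pairs)
  cross <- function(target) {
    if (curve$mean_r2[1] <= target) return(NA_real_)
    below <- which(curve$mean_r2 <= target)
    if (length(below) == 0) return(NA_real_)
    i <- below[1]
    x0 <- curve$dist_bp[i - 1]; x1 <- curve$dist_bp[i]
    y0 <- curve$mean_r2[i - 1]; y1 <- curve$mean_r2[i]
    x0 + (y0 - target) / (y0 - y1) * (x1 - x0)
  }
  half_max <- curve$mean_r2[1] / 2
  list(curve = curve,
       dist_r2_0.5 = cross(0.5),
       dist_half_max = cross(half_max),
       beyond_max_dist = is.na(cross(half_max)))
}

#' PLINK-style LD pruning
#'
#' Within successive windows of `window_snps` SNPs (advancing by
#' `step_snps`), any pair with r2 >= `r2_max` is resolved by removing the
#' later-positioned SNP; this is repeated until no violating pair remains
#' in the window. Processing is per chromosome on the position-sorted map.
#' The retained set size is the effective SNP number.
#'
#' @param g a `genotype_matrix`.
#' @param window_snps,step_snps window size and step in SNP count
#'   (defaults 50 / 50).
#' @param r2_max pruning threshold (default 0.2).
#' @return list: `keep` (retained SNP ids), `n_effective`.
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 50, r2_max = 0.2) {
  keep <- rep(TRUE, ncol(g$dosage))
  names(keep) <- g$map$snp
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    starts <- seq(1, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        r2m <- .r2_matrix(g$dosage[, act, drop = FALSE])
        r2m[is.na(r2m)] <- 0
        viol <- which(upper.tri(r2m) & r2m >= r2_max, arr.ind = TRUE)
        if (nrow(viol) == 0) break
        # first violating pair in position order; drop the later SNP
        viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
        keep[act[viol[1, 2]]] <- FALSE
      }
    }
  }
  list(keep = g$map$snp[keep], n_effective = sum(keep))
}

# Weir-Cockerham (1984) per-SNP variance components a, b, c for diploid
# data with heterozygote counts; subpops with no calls at a SNP drop out.
.wc_components <- function(dosage, subpop) {
  sp <- factor(subpop)
  m <- ncol(dosage)
  a <- b <- cc <- rep(NA_real_, m)
  split_idx <- split(seq_len(nrow(dosage)), sp)
  for (j in seq_len(m)) {
    x <- dosage[, j]
    ni <- vapply(split_idx, function(ix) sum(!is.na(x[ix])), 0)
    use <- ni > 0
    if (sum(use) < 2) next
    ni <- ni[use]
    pi_ <- vapply(split_idx[use], function(ix) mean(x[ix], na.rm = TRUE) / 2, 0)
    hi <- vapply(split_idx[use], function(ix) mean(x[ix] == 1, na.rm = TRUE), 0)
    r <- length(ni)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi_) / (r * nbar)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (nbar <= 1 || nc == 0) next
    a[j] <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[j] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[j] <- hbar / 2
  }
  data.frame(a = a, b = b, c = cc)
}

#' Weir-Cockerham FST
#'
#' Per-SNP variance components of the Weir-Cockerham (1984) estimator and
#' the genome-wide ratio-of-sums estimate `sum(a) / sum(a + b + c)`.
#'
#' @param g a `genotype_matrix`.
#' @param subpop per-accession subpopulation labels (named by accession or
#'   in row order); >= 2 subpopulations each with >= 2 accessions.
#' @return list: `per_snp` (data.frame snp, a, b, c, fst), `fst` (global
#'   ratio-of-sums).
#' @export
wc_fst <- function(g, subpop) {
  subpop <- .align_labels(subpop, rownames(g$dosage))
  if (length(unique(subpop)) < 2) stop("need >= 2 subpopulations")
  if (any(table(subpop) < 2)) stop("each subpopulation needs >= 2 accessions")
  comp <- .wc_components(g$dosage, subpop)
  denom <- comp$a + comp$b + comp$c
  per_snp <- data.frame(snp = g$map$snp, comp,
                        fst = ifelse(!is.na(denom) & denom != 0,
                                     comp$a / denom, NA_real_))
  ok <- !is.na(denom)
  list(per_snp = per_snp,
       fst = sum(comp$a[ok]) / sum(denom[ok]))
}

.align_labels <- function(labels, acc) {
  if (!is.null(names(labels))) {
    if (!all(acc %in% names(labels)))
      stop("labels missing for some accessions")
    labels <- labels[acc]
  } else stopifnot(length(labels) == length(acc))
  as.character(labels)
}

# sliding 1-based inclusive windows anchored at position 1; terminal
# windows clipped at the chromosome end
.windows <- function(chrom_len, window_bp, step_bp) {
  starts <- seq(1, chrom_len, by = step_bp)
  data.frame(start = starts, end = pmin(starts + window_bp - 1, chrom_len))
}

.chrom_len <- function(g, ch) {
  len <- g$chrom_length_bp
  if (is.null(len)) return(max(g$map$pos[g$map$chrom == ch]))
  if (!is.null(names(len))) len[[ch]] else len
}

#' Windowed Weir-Cockerham FST
#'
#' Windows are 1-based inclusive, `window_bp` wide, advanced by `step_bp`
#' and anchored at position 1; terminal partial windows are kept. The
#' window value is the ratio of summed variance components over the SNPs
#' it contains; empty windows get NA with `n_snps = 0`.
#'
#' @inheritParams wc_fst
#' @param window_bp,step_bp window and step size in bp (defaults 100 kb /
#'   20 kb).
#' @return data.frame with `chrom, start, end, value, n_snps`.
#' @export
fst_windows <- function(g, subpop, window_bp = 1e5, step_bp = 2e4) {
  subpop <- .align_labels(subpop, rownames(g$dosage))
  if (length(unique(subpop)) < 2) stop("need >= 2 subpopulations")
  if (any(table(subpop) < 2)) stop("each subpopulation needs >= 2 accessions")
  comp <- .wc_components(g$dosage, subpop)
  .window_stat(g, window_bp, step_bp, function(idx) {
    ok <- idx[!is.na(comp$a[idx])]
    if (length(ok) == 0) return(NA_real_)
    denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
    if (denom == 0) return(NA_real_)
    sum(comp$a[ok]) / denom
  })
}

#' Windowed nucleotide diversity
#'
#' Per SNP, the unbiased expected heterozygosity 2p(1-p) * n/(n-1) with n
#' the number of non-missing alleles; the window value is the sum over its
#' SNPs divided by the window length in bp (per-site pi). Window layout as
#' in [fst_windows()].
#'
#' @param g a `genotype_matrix`.
#' @param window_bp,step_bp window and step size in bp.
#' @return data.frame with `chrom, start, end, value, n_snps`.
#' @export
pi_windows <- function(g, window_bp = 1e5, step_bp = 2e4) {
  n_alleles <- 2 * colSums(!is.na(g$dosage))
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  het <- ifelse(n_alleles > 1,
                2 * p * (1 - p) * n_alleles / (n_alleles - 1), NA_real_)
  .window_stat(g, window_bp, step_bp, function(idx) {
    ok <- idx[!is.na(het[idx])]
    sum(het[ok])
  }, divide_by_length = TRUE)
}

.window_stat <- function(g, window_bp, step_bp, fun,
                         divide_by_length = FALSE) {
  out <- list()
  for (ch in unique(g$map$chrom)) {
    len <- .chrom_len(g, ch)
    w <- .windows(len, window_bp, step_bp)
    snp_idx <- which(g$map$chrom == ch)
    pos <- g$map$pos[snp_idx]
    vals <- numeric(nrow(w)); ns <- integer(nrow(w))
    for (i in seq_len(nrow(w))) {
      idx <- snp_idx[pos >= w$start[i] & pos <= w$end[i]]
      ns[i] <- length(idx)
      if (length(idx) == 0) { vals[i] <- NA_real_; next }
      v <- fun(idx)
      if (divide_by_length) v <- v / (w$end[i] - w$start[i] + 1)
      vals[i] <- v
    }
    out[[ch]] <- data.frame(chrom = ch, start = w$start, end = w$end,
                            value = vals, n_snps = ns,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export window statistics as BED-style TSV
#'
#' Converts the package's 1-based inclusive windows to BED half-open
#' coordinates (start0 = start - 1) on write.
#'
#' @param windows output of [fst_windows()] or [pi_windows()].
#' @param path output TSV path.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chrom, start0 = windows$start - 1,
                    end = windows$end, value = windows$value,
                    n_snps = windows$n_snps)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
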