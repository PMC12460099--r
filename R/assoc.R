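# Mixed-linear-model association scan with kinship + PC covariates, the
# dual significance rules, QTL interval construction and haplotype
# contrasts.

#' Mixed-linear-model association scan
#'
#' Fits, for each SNP, y = W alpha + x beta + u + e with u ~ (0, s2_g K)
#' and e ~ (0, s2_e I). K is eigendecomposed once; the variance ratio
#' delta = s2_e / s2_g is estimated under the null (covariates only) by
#' maximum likelihood on a log10 grid with `optimize()` refinement, and
#' reused for every SNP (the population-parameters-previously-determined
#' approximation). Each SNP then gets a generalized-least-squares Wald
#' test of beta (t reference distribution, n - p - 1 df). Missing dosages
#' are mean-imputed; SNPs monomorphic in the tested subset are skipped
#' (p = NA).
#'
#' @param g a `genotype_matrix`.
#' @param y named per-accession phenotype vector (e.g. BLUE STIs).
#' @param K kinship matrix (defaults to [kinship()] of `g`).
#' @param covariates optional accession x q covariate matrix (e.g. genotype
#'   PCs); an intercept is always added.
#' @param env label recorded in the output (environment / phenotype tag).
#' @return data.frame of class `assoc_result` with columns
#'   `snp, chrom, pos, beta, se, p, env`; attributes `delta`, `h2_null`
#'   (null-model variance ratio diagnostics).
#' @export
lmm_scan <- function(g, y, K = NULL, covariates = NULL, env = "env1") {
  acc <- rownames(g$dosage)
  if (is.null(names(y))) {
    stopifnot(length(y) == length(acc))
    names(y) <- acc
  }
  use <- intersect(acc, names(y)[!is.na(y)])
  if (length(use) < 10) stop("too few accessions with phenotype")
  y <- y[use]
  X <- .impute_mean(g$dosage[use, , drop = FALSE])
  if (is.null(K)) K <- kinship(g)
  K <- K[use, use]
  W <- matrix(1, length(use), 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[use, , drop = FALSE]
    W <- cbind(W, cv)
  }
  if (qr(W)$rank < ncol(W)) stop("singular covariate matrix")
  n <- length(use)

  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Ut <- t(e$vectors)
  yt <- drop(Ut %*% y)
  Wt <- Ut %*% W

  # null ML over delta = s2_e / s2_g
  negll <- function(log10d) {
    d <- 10^log10d
    v <- lam + d
    ws <- 1 / sqrt(v)
    fit <- lm.fit(Wt * ws, yt * ws)
    rss <- sum(fit$residuals^2)
    0.5 * (n * log(2 * pi * rss / n) + sum(log(v)) + n)
  }
  grid <- seq(-5, 5, length.out = 61)
  vals <- vapply(grid, negll, 0)
  i0 <- which.min(vals)
  lo <- grid[max(i0 - 1, 1)]; hi <- grid[min(i0 + 1, length(grid))]
  opt <- optimize(negll, c(lo, hi))
  delta <- 10^opt$minimum

  v <- lam + delta
  ws <- 1 / sqrt(v)
  ys <- yt * ws
  Ws <- Wt * ws
  Xt <- (Ut %*% X) * ws
  qrW <- qr(Ws)
  ry <- qr.resid(qrW, ys)
  rX <- qr.resid(qrW, Xt)
  sxx <- colSums(rX^2)
  mono <- apply(X, 2, function(col) all(col == col[1])) | sxx < 1e-12
  sxy <- colSums(rX * ry)
  beta <- sxy / sxx
  df <- n - ncol(W) - 1
  syy <- sum(ry^2)
  s2 <- pmax(syy - beta^2 * sxx, 0) / df
  se <- sqrt(s2 / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  beta[mono] <- NA; se[mono] <- NA; p[mono] <- NA

  res <- data.frame(snp = g$map$snp, chrom = g$map$chrom, pos = g$map$pos,
                    beta = beta, se = se, p = p, env = env,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("assoc_result", "data.frame")
  attr(res, "delta") <- delta
  attr(res, "h2_null") <- mean(lam) / (mean(lam) + delta)
  res
}

#' Significance threshold from the effective SNP number
#'
#' The per-test threshold is the reciprocal of the number of approximately
#' independent markers after LD pruning (a Bonferroni-style correction on
#' the effective tests).
#'
#' @param n_effective effective SNP count (> 0).
#' @return the p-value threshold 1 / n_effective.
#' @export
effective_snp_threshold <- function(n_effective) {
  stopifnot(n_effective > 0)
  1 / n_effective
}

#' Call significant SNPs under the dual rule
#'
#' A SNP is significant if its p-value beats the strict threshold in any
#' single environment (`single_env_strict`), or beats the relaxed
#' threshold in at least `min_envs` distinct environments / phenotypes
#' (`multi_env_relaxed`). The satisfied rule is recorded (strict takes
#' precedence when both hold).
#'
#' @param results list of `assoc_result` data.frames (one per environment
#'   or phenotype; the `env` column labels them).
#' @param strict_p strict single-environment threshold (e.g.
#'   [effective_snp_threshold()] output).
#' @param relaxed_p relaxed threshold (default 1e-5).
#' @param min_envs minimum supporting environments for the relaxed rule
#'   (default 2).
#' @return data.frame of class `significant_set`: `snp, chrom, pos, min_p,
#'   n_envs_relaxed, envs, rule`.
#' @export
call_significant <- function(results, strict_p, relaxed_p = 1e-5,
                             min_envs = 2) {
  all_res <- do.call(rbind, lapply(results, as.data.frame))
  all_res <- all_res[!is.na(all_res$p), ]
  sp <- split(all_res, all_res$snp)
  rows <- lapply(sp, function(d) {
    strict_hit <- any(d$p < strict_p)
    relaxed_envs <- unique(d$env[d$p < relaxed_p])
    relaxed_hit <- length(relaxed_envs) >= min_envs
    if (!strict_hit && !relaxed_hit) return(NULL)
    data.frame(snp = d$snp[1], chrom = d$chrom[1], pos = d$pos[1],
               min_p = min(d$p),
               n_envs_relaxed = length(relaxed_envs),
               envs = paste(sort(unique(d$env[d$p < max(strict_p, relaxed_p)])),
                            collapse = ","),
               rule = if (strict_hit) "single_env_strict"
                      else "multi_env_relaxed",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp = character(), chrom = character(),
                      pos = numeric(), min_p = numeric(),
                      n_envs_relaxed = integer(), envs = character(),
                      rule = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("significant_set", "data.frame")
  out
}

#' Build and merge QTL intervals around significant SNPs
#'
#' Each significant SNP defines the interval [pos - flank, pos + flank]
#' (1-based inclusive), clipped at 1 and the chromosome length; intervals
#' on a chromosome that overlap or touch are merged. The lead SNP of a
#' merged interval is its minimum-p member.
#'
#' @param sig a `significant_set`.
#' @param flank_bp flank on each side (default 100,000).
#' @param chrom_length_bp optional chromosome length (scalar or named) for
#'   right clipping.
#' @return data.frame of class `qtl_intervals`: `chrom, start, end,
#'   lead_snp, lead_p, n_snps, span_bp`, sorted and non-overlapping per
#'   chromosome.
#' @export
define_qtl <- function(sig, flank_bp = 1e5, chrom_length_bp = NULL) {
  if (nrow(sig) == 0)
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), lead_snp = character(),
                                lead_p = numeric(), n_snps = integer(),
                                span_bp = numeric()),
                     class = c("qtl_intervals", "data.frame")))
  out <- list()
  for (ch in unique(sig$chrom)) {
    d <- sig[sig$chrom == ch, ]
    d <- d[order(d$pos), ]
    len <- if (is.null(chrom_length_bp)) Inf
           else if (!is.null(names(chrom_length_bp))) chrom_length_bp[[ch]]
           else chrom_length_bp
    start <- pmax(d$pos - flank_bp, 1)
    end <- pmin(d$pos + flank_bp, len)
    cur_s <- start[1]; cur_e <- end[1]; members <- 1L
    ivs <- list()
    flush <- function(s, e, mem) {
      dd <- d[mem, ]
      lead <- which.min(dd$min_p)
      data.frame(chrom = ch, start = s, end = e,
                 lead_snp = dd$snp[lead], lead_p = dd$min_p[lead],
                 n_snps = length(mem), span_bp = e - s + 1,
                 stringsAsFactors = FALSE)
    }
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      if (start[i] <= cur_e + 1) {       # overlap or touch
        cur_e <- max(cur_e, end[i])
        members <- c(members, i)
      } else {
        ivs[[length(ivs) + 1]] <- flush(cur_s, cur_e, members)
        cur_s <- start[i]; cur_e <- end[i]; members <- i
      }
    }
    ivs[[length(ivs) + 1]] <- flush(cur_s, cur_e, members)
    out[[ch]] <- do.call(rbind, ivs)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  class(res) <- c("qtl_intervals", "data.frame")
  res
}

#' Haplotype-group phenotype contrast within a QTL interval
#'
#' Accessions are grouped by the exact string of dosages over the SNPs in
#' the region (accessions with any missing call there are dropped);
#' heterozygous dosages form their own strings. The two largest groups of
#' size >= `min_group` are contrasted with a two-sided Welch t test on the
#' phenotype.
#'
#' @param g a `genotype_matrix`.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param y named per-accession phenotype vector.
#' @param min_group minimum haplotype group size (default 5).
#' @return list of class `haplotype_contrast`: `haplotype` (named
#'   assignment, Hap1 = largest), `group_sizes`, `group_means`,
#'   `t`, `df`, `p`.
#' @export
haplotype_contrast <- function(g, region, y, min_group = 5) {
  idx <- which(g$map$chrom == region$chrom &
                 g$map$pos >= region$start & g$map$pos <= region$end)
  if (length(idx) == 0) stop("no SNPs in region")
  d <- g$dosage[, idx, drop = FALSE]
  complete <- rowSums(is.na(d)) == 0
  d <- d[complete, , drop = FALSE]
  strings <- apply(d, 1, paste, collapse = "")
  tab <- sort(table(strings), decreasing = TRUE)
  big <- names(tab)[tab >= min_group]
  if (length(big) < 2)
    stop("fewer than 2 haplotype groups reach min_group = ", min_group)
  hap_names <- setNames(paste0("Hap", seq_along(big)), big)
  assign <- hap_names[strings]
  names(assign) <- rownames(d)
  assign <- assign[!is.na(assign)]
  y1 <- y[names(assign)[assign == "Hap1"]]
  y2 <- y[names(assign)[assign == "Hap2"]]
  y1 <- y1[!is.na(y1)]; y2 <- y2[!is.na(y2)]
  tt <- t.test(y1, y2, var.equal = FALSE, alternative = "two.sided")
  structure(list(haplotype = assign,
                 group_sizes = c(Hap1 = length(y1), Hap2 = length(y2)),
                 group_means = c(Hap1 = mean(y1), Hap2 = mean(y2)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "haplotype_contrast")
}
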