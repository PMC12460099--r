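# Variant filters, kinship, genotype PCA, LD statistics, FST and pi.

test_that("variant filter applies MAF and call-rate rules and is idempotent", {
  # 5 accessions x 4 SNPs: kept / monomorphic / low-MAF boundary / low call
  dos <- cbind(c(0, 0, 0, 0, 1),       # MAF 0.1, call 1.0 -> kept
               c(2, 2, 2, 2, 2),       # monomorphic -> dropped
               c(0, 0, 0, 0, 0),       # monomorphic -> dropped
               c(1, NA, NA, 0, 2))     # call rate 0.6 -> dropped
  g <- geno_from_dosage(dos)
  gf <- filter_variants(g)
  expect_equal(ncol(gf$dosage), 1)
  expect_equal(gf$map$pos, 1000)
  gff <- filter_variants(gf)
  expect_identical(gf$dosage, gff$dosage)
  # hand-set toy: per-SNP brute force over MAF / missingness
  set.seed(5)
  dos10 <- matrix(sample(c(0L, 1L, 2L, NA), 200, replace = TRUE,
                         prob = c(0.45, 0.2, 0.25, 0.1)), 20, 10)
  g10 <- geno_from_dosage(dos10)
  gf10 <- filter_variants(g10, 0.05, 0.8)
  keep_hand <- vapply(seq_len(10), function(j) {
    x <- dos10[, j]
    cr <- mean(!is.na(x))
    p <- mean(x, na.rm = TRUE) / 2
    min(p, 1 - p) > 0.05 && cr > 0.8
  }, TRUE)
  expect_equal(gf10$map$snp, g10$map$snp[keep_hand])
  expect_warning(filter_variants(geno_from_dosage(cbind(c(0L, 0L, 0L)))),
                 "no SNPs")
})

test_that("kinship is symmetric PSD with duplicate-row consistency", {
  cfg <- sim_config(n_accessions = 60, n_chrom = 2, n_snps_per_chrom = 200,
                    target_fst = 0.2, seed = 6)
  sim <- simulate_genotypes(cfg)
  g <- filter_variants(sim$geno)
  # duplicate an accession
  dos <- rbind(g$dosage, DUP = g$dosage[1, ])
  g2 <- genotype_matrix(dos, g$map, chrom_length_bp = g$chrom_length_bp)
  K <- kinship(g2)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  expect_equal(K["DUP", rownames(g$dosage)[1]],
               K[rownames(g$dosage)[1], rownames(g$dosage)[1]],
               tolerance = 1e-10)
  # mean self-kinship near 1 + F under Balding-Nichols
  expect_equal(mean(diag(kinship(g))), 1 + cfg$target_fst, tolerance = 0.1)
})

test_that("genotype PCA scores are orthogonal and cluster subpopulations", {
  cfg <- sim_config(n_accessions = 120, n_subpops = 4, n_chrom = 2,
                    n_snps_per_chrom = 400, target_fst = 0.25, seed = 7)
  sim <- simulate_genotypes(cfg)
  g <- filter_variants(sim$geno)
  pcs <- genotype_pca(g, 3)
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  sil <- cluster::silhouette(
    as.integer(factor(sim$truth$subpop[rownames(pcs)])), dist(pcs))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # identical accessions get identical scores
  dos <- rbind(g$dosage, DUP = g$dosage[1, ])
  pcs2 <- genotype_pca(genotype_matrix(dos, g$map), 2)
  expect_equal(pcs2["DUP", ], pcs2[rownames(g$dosage)[1], ],
               tolerance = 1e-6)
  expect_warning(genotype_pca(geno_from_dosage(cbind(c(0L, 2L), c(0L, 2L))),
                              n_pcs = 5), "rank")
})

test_that("LD r2 handles self, complement coding and null expectation", {
  set.seed(8)
  dos <- matrix(rbinom(400 * 3, 2, 0.4), 400, 3)
  dos[, 2] <- 2L - dos[, 1]
  g <- geno_from_dosage(dos)
  expect_equal(ld_r2(g, 1, 1), 1)
  expect_equal(ld_r2(g, 1, 2), 1, tolerance = 1e-12)
  # independent SNPs: r2 on the 1/n scale
  r2s <- replicate(30, {
    d <- matrix(rbinom(400 * 2, 2, 0.4), 400, 2)
    ld_r2(geno_from_dosage(d), 1, 2)
  })
  expect_lt(mean(r2s), 5 / 400)
  expect_true(is.na(ld_r2(geno_from_dosage(cbind(c(1L, 1L, 1L),
                                                 c(0L, 1L, 2L))), 1, 2)))
})

test_that("LD decay recovers a constructed monotone profile", {
  # Markov chain of SNP columns: each is the previous with 10% of entries
  # resampled, so pairs at lag L have r2 ~ 0.81^L and the mean curve
  # crosses 0.5 near lag 3.3 (33 kb at 10-kb spacing)
  set.seed(9)
  n <- 800
  dos <- matrix(0L, n, 25)
  dos[, 1] <- rbinom(n, 2, 0.5)
  for (j in 2:25) {
    x <- dos[, j - 1]
    idx <- runif(n) < 0.1
    x[idx] <- rbinom(sum(idx), 2, 0.5)
    dos[, j] <- x
  }
  g <- geno_from_dosage(dos, spacing = 1e4, chrom_length_bp = 2.6e5)
  dec <- ld_decay(g, max_dist_bp = 2e5, bin_bp = 1e4)
  expect_gt(dec$curve$mean_r2[1], dec$curve$mean_r2[nrow(dec$curve)])
  expect_false(is.na(dec$dist_r2_0.5))
  expect_lt(abs(dec$dist_r2_0.5 - 3.3e4), 1.5e4)  # within ~1.5 bins
  # half-maximum crossing: 0.81^L = 0.81/2 at L ~ 4.3 lags
  expect_lt(abs(dec$dist_half_max - 3.8e4), 1.5e4)
  # unlinked SNPs: flat curve, half decay beyond range
  set.seed(10)
  flat <- geno_from_dosage(matrix(rbinom(200 * 30, 2, 0.4), 200, 30),
                           spacing = 1e4)
  dflat <- ld_decay(flat, 3e5, 5e4)
  expect_true(is.na(dflat$dist_r2_0.5))
  expect_true(dflat$beyond_max_dist)
  expect_error(ld_decay(flat, max_dist_bp = 1), "no SNP pairs")
})

test_that("LD pruning matches the exhaustive oracle on a 10-SNP window", {
  set.seed(11)
  n <- 120
  base1 <- rbinom(n, 2, 0.5); base2 <- rbinom(n, 2, 0.3)
  dos <- cbind(base1,                       # 1 kept
               base1,                       # 2 dup of 1 -> removed
               rbinom(n, 2, 0.5),           # 3 independent
               base2,                       # 4 kept
               ifelse(runif(n) < 0.9, base2, rbinom(n, 2, 0.3)), # 5 ~ 4
               rbinom(n, 2, 0.4),           # 6 independent
               2L - base1,                  # 7 complement of 1 -> removed
               rbinom(n, 2, 0.2),           # 8 independent
               rbinom(n, 2, 0.5),           # 9 independent
               rbinom(n, 2, 0.3))           # 10 independent
  g <- geno_from_dosage(dos)
  pr <- ld_prune(g, window_snps = 10, step_snps = 10, r2_max = 0.2)
  # oracle: replay the greedy rule with scalar loops
  keep <- rep(TRUE, 10)
  repeat {
    act <- which(keep)
    viol <- NULL
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        r2 <- suppressWarnings(cor(dos[, act[ii]], dos[, act[jj]])^2)
        if (!is.na(r2) && r2 >= 0.2) { viol <- c(act[ii], act[jj]); break }
      }
      if (!is.null(viol)) break
    }
    if (is.null(viol)) break
    keep[viol[2]] <- FALSE
  }
  expect_equal(pr$keep, g$map$snp[keep])
  expect_equal(pr$n_effective, sum(keep))
  # no retained pair violates the threshold
  act <- match(pr$keep, g$map$snp)
  r2m <- suppressWarnings(cor(dos[, act]))^2
  expect_lt(max(r2m[upper.tri(r2m)], na.rm = TRUE), 0.2)
})

test_that("pruning keeps independent SNPs and halves perfect pairs", {
  set.seed(12)
  ind <- matrix(rbinom(300 * 8, 2, 0.4), 300, 8)
  g <- geno_from_dosage(ind)
  expect_equal(ld_prune(g)$n_effective, 8)
  dup <- geno_from_dosage(cbind(ind[, 1], ind[, 1]))
  pr <- ld_prune(dup)
  expect_equal(pr$n_effective, 1)
  expect_equal(pr$keep, dup$map$snp[1])  # later-positioned SNP removed
})

test_that("Weir-Cockerham FST matches the scalar oracle and limits", {
  g <- tiny_geno()
  sp <- tiny_subpop()
  res <- wc_fst(g, sp)
  # frozen hand values from the scalar transcription (3 SNPs)
  expect_equal(res$per_snp$fst,
               c(0.2040816326531, 0.3966005665722, 0.2040816326531),
               tolerance = 1e-10)
  comp <- t(vapply(1:3, function(j)
    wc_oracle_snp(list(g$dosage[1:3, j], g$dosage[4:5, j])), numeric(3)))
  expect_equal(res$per_snp$a, comp[, "a"], tolerance = 1e-12)
  expect_equal(res$fst, sum(comp[, "a"]) / sum(comp), tolerance = 1e-12)
  # fixed alternative alleles between two subpops -> per-SNP FST = 1
  fixed <- geno_from_dosage(cbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L)))
  spf <- setNames(c("G1", "G1", "G2", "G2"), rownames(fixed$dosage))
  expect_equal(wc_fst(fixed, spf)$per_snp$fst, c(1, 1))
  # identical subpop frequencies -> FST near 0
  set.seed(13)
  same <- geno_from_dosage(matrix(rbinom(200 * 100, 2, 0.3), 200, 100))
  sps <- setNames(rep(c("G1", "G2"), each = 100), rownames(same$dosage))
  expect_lt(abs(wc_fst(same, sps)$fst), 0.01)
  expect_error(wc_fst(g, setNames(rep("G1", 5), names(sp))), ">= 2")
})

test_that("windowed FST and pi follow the window layout and closed forms", {
  g <- tiny_geno()
  sp <- tiny_subpop()
  fw <- fst_windows(g, sp, window_bp = 500, step_bp = 250)
  # chromosome of length 1000: starts 1, 251, 501, 751; the SNP at 900
  # falls in both of the last (overlapping) windows
  expect_equal(fw$start, c(1, 251, 501, 751))
  expect_equal(fw$end, c(500, 750, 1000, 1000))
  expect_equal(fw$n_snps, c(2L, 1L, 1L, 1L))
  comp <- t(vapply(1:3, function(j)
    wc_oracle_snp(list(g$dosage[1:3, j], g$dosage[4:5, j])), numeric(3)))
  expect_equal(fw$value[1], sum(comp[1:2, "a"]) / sum(comp[1:2, ]),
               tolerance = 1e-12)
  expect_equal(fw$value[4], unname(comp[3, "a"] / sum(comp[3, ])),
               tolerance = 1e-12)
  # an empty window reports NA with zero SNPs
  fw2 <- fst_windows(g, sp, window_bp = 200, step_bp = 200)
  expect_equal(fw2$n_snps[2], 0L)
  expect_true(is.na(fw2$value[2]))
  # pi: frozen hand values 2p(1-p) n/(n-1) with n = 10 alleles
  pw <- pi_windows(g, window_bp = 1000, step_bp = 1000)
  expect_equal(pw$value[1],
               (0.4666666666667 + 0.5333333333333 + 0.4666666666667) / 1000,
               tolerance = 1e-10)
  # monomorphic window -> 0
  mono <- geno_from_dosage(cbind(c(2L, 2L, 2L), c(0L, 0L, 0L)),
                           chrom_length_bp = 5000)
  expect_equal(pi_windows(mono, 5000, 5000)$value, 0)
  # single SNP at p = 0.5, large n, 100-kb window -> pi ~ 0.5 / 1e5
  half <- geno_from_dosage(cbind(rep(c(0L, 2L), 500)),
                           chrom_length_bp = 1e5)
  expect_equal(pi_windows(half, 1e5, 1e5)$value, 0.5 / 1e5,
               tolerance = 1e-3)
})

test_that("BED export shifts to half-open coordinates", {
  g <- tiny_geno()
  pw <- pi_windows(g, 500, 500)
  f <- tempfile()
  write_windows_bed(pw, f)
  bed <- read.delim(f)
  expect_equal(bed$start0, pw$start - 1)
  expect_equal(bed$end, pw$end)
})

test_that("VCF and dosage TSV round-trips preserve the genotype matrix", {
  skip_if_not_installed("vcfR")
  cfg <- sim_config(n_accessions = 20, n_chrom = 2, n_snps_per_chrom = 30,
                    missing_rate = 0.05, seed = 14)
  sim <- simulate_genotypes(cfg)
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$geno, f)
  back <- read_vcf(f)
  expect_equal(unname(back$dosage), unname(sim$geno$dosage))
  expect_equal(back$map$pos, sim$geno$map$pos)
  f2 <- tempfile(fileext = ".tsv")
  write_dosage_tsv(sim$geno, f2)
  back2 <- read_dosage_tsv(f2)
  expect_equal(back2$dosage, sim$geno$dosage)
})
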