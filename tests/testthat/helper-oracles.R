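# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately plain, scalar-loop implementation kept
# separate from the package's vectorized code paths.

# --- Weir & Cockerham (1984) per-SNP components, scalar transcription ----
wc_oracle_snp <- function(dos_by_pop) {
  ni <- vapply(dos_by_pop, length, 0)
  r <- length(ni)
  p_i <- vapply(dos_by_pop, function(x) sum(x) / (2 * length(x)), 0)
  h_i <- vapply(dos_by_pop, function(x) mean(x == 1), 0)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * p_i) / (r * nbar)
  s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * h_i) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# --- naive Ward minimum-variance agglomeration (1-D), ESS-increase form --
ward_oracle <- function(x, k) {
  clusters <- as.list(seq_along(x))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      a <- x[clusters[[i]]]; b <- x[clusters[[j]]]
      cost <- length(a) * length(b) / (length(a) + length(b)) *
        (mean(a) - mean(b))^2
      if (cost < best[1] - 1e-12) best <- c(cost, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  assign <- integer(length(x))
  for (s in seq_along(clusters)) assign[clusters[[s]]] <- s
  assign
}

# canonical form of a partition (labels by first appearance), so two
# labelings can be compared up to permutation
canonical_partition <- function(a) {
  as.integer(factor(a, levels = unique(a)))
}

# --- straight-line recomputation of the membership-function chain -------
# standardize, eigendecompose the correlation matrix, fix signs, project,
# min-max scale, weight by contribution rates; all with explicit loops
mfv_oracle_d <- function(blue, threshold = 85) {
  n <- nrow(blue); m <- ncol(blue)
  x <- matrix(0, n, m)
  for (j in 1:m)
    x[, j] <- (blue[, j] - mean(blue[, j])) / sd(blue[, j])
  e <- eigen(cor(blue), symmetric = TRUE)
  lam <- e$values; vec <- e$vectors
  for (i in 1:m) {
    top <- which.max(abs(vec[, i]))
    if (vec[top, i] < 0) vec[, i] <- -vec[, i]
  }
  P <- 100 * lam / sum(lam)
  k <- 1
  while (sum(P[1:k]) < threshold) k <- k + 1
  F <- matrix(0, n, k)
  for (a in 1:n) for (i in 1:k)
    F[a, i] <- sum(vec[, i] * x[a, ])
  mu <- matrix(0, n, k)
  for (i in 1:k)
    mu[, i] <- (F[, i] - min(F[, i])) / (max(F[, i]) - min(F[, i]))
  W <- P[1:k] / sum(P[1:k])
  D <- numeric(n)
  for (a in 1:n) D[a] <- sum(mu[a, ] * W)
  D
}

# --- tiny fixtures -------------------------------------------------------
# 5 accessions (3 in G1, 2 in G2) x 3 SNPs; the hand-oracle matrix
tiny_geno <- function() {
  dos <- rbind(c(0, 0, 2), c(1, 0, 1), c(2, 1, 0), c(2, 1, 0), c(2, 2, 0))
  dimnames(dos) <- list(paste0("ACC", 1:5), c("C1_100", "C1_500", "C1_900"))
  storage.mode(dos) <- "integer"
  genotype_matrix(dos,
                  data.frame(snp = colnames(dos), chrom = "C1",
                             pos = c(100L, 500L, 900L)),
                  chrom_length_bp = 1000)
}

tiny_subpop <- function() {
  setNames(c("G1", "G1", "G1", "G2", "G2"), paste0("ACC", 1:5))
}

# small balanced phenotype table with exact salt/control ratios
balanced_pheno <- function(sti_by_acc, control = 20,
                           years = c("2022", "2023"), reps = c("R1", "R2")) {
  rows <- list()
  for (acc in names(sti_by_acc)) for (y in years) for (r in reps) {
    rows[[length(rows) + 1]] <- data.frame(
      accession = acc, year = y, rep = r,
      treatment = c("control", "salt"),
      trait = "plant_height",
      value = c(control, control * sti_by_acc[[acc]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# genotype matrix from an explicit dosage matrix, evenly spaced positions
geno_from_dosage <- function(dos, chrom = "C1", spacing = 1000,
                             chrom_length_bp = NULL) {
  storage.mode(dos) <- "integer"
  pos <- spacing * seq_len(ncol(dos))
  colnames(dos) <- paste0(chrom, "_", pos)
  if (is.null(rownames(dos)))
    rownames(dos) <- sprintf("ACC%03d", seq_len(nrow(dos)))
  genotype_matrix(dos, data.frame(snp = colnames(dos), chrom = chrom,
                                  pos = pos),
                  chrom_length_bp = chrom_length_bp)
}
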