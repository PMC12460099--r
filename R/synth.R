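# Synthetic panel generator: Balding-Nichols structured genotypes and
# phenotype trials with the exact random-effects structure the BLUE model
# assumes, so downstream stages have ground truth.

#' Default genetic correlation between trait STIs
#'
#' Correlation of the per-accession genetic effects across the four relative
#' traits. The default reflects a panel in which shoot fresh and dry weight
#' share most of their genetic basis while plant height and root dry weight
#' are nearly independent.
#'
#' @return a 4 x 4 positive-definite correlation matrix with RPH, RSFW,
#'   RSDW, RRDW rows/columns.
#' @export
default_genetic_cor <- function() {
  r <- matrix(c(
    1.00, 0.50, 0.50, 0.16,
    0.50, 1.00, 0.80, 0.35,
    0.50, 0.80, 1.00, 0.40,
    0.16, 0.35, 0.40, 1.00), 4, 4, byrow = TRUE)
  dimnames(r) <- list(.rel_traits, .rel_traits)
  r
}

#' Build a validated simulation configuration
#'
#' Parameters describing a structured diploid panel and a replicated
#' two-treatment (control / 200 mmol/L NaCl) trial measuring four seedling
#' traits. Defaults emulate a 240-accession panel in 4 subpopulations
#' phenotyped in 2 years x 3 replicates; per-trait STI means and genetic
#' standard deviations are set so BLUE-level summaries fall on the scale
#' typical of seedling salt-stress trials (trait means 0.5--0.6, CV 8--18%).
#'
#' @param n_accessions number of accessions in the panel.
#' @param n_subpops number of subpopulations.
#' @param n_chrom number of chromosomes (first half labelled A, second D).
#' @param n_snps_per_chrom SNPs simulated per chromosome.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param target_fst Balding-Nichols differentiation parameter in [0, 1).
#' @param maf_range range of ancestral minor-allele frequencies, within
#'   (0, 0.5].
#' @param missing_rate fraction of genotype calls set missing at random.
#' @param causal_loci `NULL` or a data.frame with columns `chrom`, `index`
#'   (SNP index within the chromosome) and one column per trait giving the
#'   additive effect, in STI units per standardized allele.
#' @param sigma2_g named per-trait genetic variances (STI^2 units).
#' @param sigma2_year,sigma2_rep,sigma2_year_rep,sigma2_e variance
#'   components of the year, replicate, year-within-replicate and residual
#'   random effects (STI^2 units).
#' @param n_years,n_reps trial design.
#' @param baseline_control named per-trait mean control measurement (cm for
#'   plant height, g for the weights).
#' @param control_cv coefficient of variation of the control measurement.
#' @param sti_mean named per-trait mean STI, each in (0, 1].
#' @param genetic_cor genetic correlation matrix across traits.
#' @param seed integer seed; all simulation randomness derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 240L,
                       n_subpops = 4L,
                       n_chrom = 4L,
                       n_snps_per_chrom = 500L,
                       chrom_length_bp = 5e7,
                       target_fst = 0.15,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       causal_loci = NULL,
                       sigma2_g = c(RPH = 0.05^2, RSFW = 0.09^2,
                                    RSDW = 0.10^2, RRDW = 0.08^2),
                       sigma2_year = 6e-4,
                       sigma2_rep = 3e-4,
                       sigma2_year_rep = 3e-4,
                       sigma2_e = 1.5e-3,
                       n_years = 2L,
                       n_reps = 3L,
                       baseline_control = c(RPH = 25, RSFW = 10,
                                            RSDW = 1.5, RRDW = 0.3),
                       control_cv = 0.05,
                       sti_mean = c(RPH = 0.62, RSFW = 0.49,
                                    RSDW = 0.58, RRDW = 0.59),
                       genetic_cor = default_genetic_cor(),
                       seed = 1L) {
  stopifnot(n_accessions >= 1, n_chrom >= 1, n_snps_per_chrom >= 1)
  if (n_subpops > n_accessions)
    stop("invalid design: n_subpops exceeds n_accessions")
  if (target_fst < 0 || target_fst >= 1)
    stop("target_fst must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  vc <- c(sigma2_year, sigma2_rep, sigma2_year_rep, sigma2_e, sigma2_g)
  if (any(vc < 0)) stop("all variance components must be >= 0")
  if (any(sti_mean <= 0 | sti_mean > 1))
    stop("sti_mean per trait must lie in (0, 1]")
  traits <- .rel_traits
  stopifnot(all(traits %in% names(sigma2_g)),
            all(traits %in% names(sti_mean)),
            all(traits %in% names(baseline_control)))
  if (!is.null(causal_loci)) {
    stopifnot(is.data.frame(causal_loci),
              all(c("chrom", "index") %in% names(causal_loci)))
    if (any(causal_loci$index < 1 | causal_loci$index > n_snps_per_chrom))
      stop("causal locus index outside SNP count")
  }
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_subpops = as.integer(n_subpops),
              n_chrom = as.integer(n_chrom),
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              chrom_length_bp = chrom_length_bp,
              target_fst = target_fst,
              maf_range = maf_range,
              missing_rate = missing_rate,
              causal_loci = causal_loci,
              sigma2_g = sigma2_g[traits],
              sigma2_year = sigma2_year,
              sigma2_rep = sigma2_rep,
              sigma2_year_rep = sigma2_year_rep,
              sigma2_e = sigma2_e,
              n_years = as.integer(n_years),
              n_reps = as.integer(n_reps),
              baseline_control = baseline_control[traits],
              control_cv = control_cv,
              sti_mean = sti_mean[traits],
              genetic_cor = genetic_cor,
              traits = traits,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.chrom_labels <- function(n_chrom) {
  # first half At subgenome, second half Dt (allotetraploid convention)
  n_a <- ceiling(n_chrom / 2)
  c(sprintf("A%02d", seq_len(n_a)),
    sprintf("D%02d", seq_len(n_chrom - n_a)))
}

#' Simulate a structured genotype panel
#'
#' Draws ancestral allele frequencies uniformly in `maf_range`, then
#' subpopulation frequencies from the Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = target_fst`, and diploid dosages
#' binomially within each subpopulation. Genotype calls are set missing
#' completely at random at `missing_rate`. Per-accession genetic effects on
#' each trait (causal loci plus correlated polygenic background scaled to
#' the configured genetic variances) are returned as ground truth.
#'
#' @param cfg a [sim_config()] object.
#' @return a list with elements `geno` (a `genotype_matrix`: `dosage`
#'   accessions x SNPs in \{0, 1, 2, NA\}, `map` with `snp`, `chrom`, `pos`,
#'   `subgenome`, and `chrom_length_bp`) and `truth` (subpopulation
#'   assignment, accession x trait genetic effects, causal loci).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions
  acc <- sprintf("ACC%03d", seq_len(n))
  subpop <- sort(rep_len(sprintf("G%d", seq_len(cfg$n_subpops)), n))
  names(subpop) <- acc

  chroms <- .chrom_labels(cfg$n_chrom)
  m_per <- cfg$n_snps_per_chrom
  map_list <- vector("list", cfg$n_chrom)
  dosage_list <- vector("list", cfg$n_chrom)
  F <- cfg$target_fst
  for (ci in seq_along(chroms)) {
    pos <- sort(sample.int(cfg$chrom_length_bp, m_per, replace = FALSE))
    p_anc <- runif(m_per, cfg$maf_range[1], cfg$maf_range[2])
    # subpop x SNP allele frequencies
    if (F == 0) {
      p_sub <- matrix(rep(p_anc, each = cfg$n_subpops), cfg$n_subpops, m_per)
    } else {
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      p_sub <- matrix(rbeta(cfg$n_subpops * m_per,
                            rep(a, each = cfg$n_subpops),
                            rep(b, each = cfg$n_subpops)),
                      cfg$n_subpops, m_per)
    }
    sp_idx <- as.integer(factor(subpop, levels = unique(subpop)))
    probs <- p_sub[sp_idx, , drop = FALSE]
    dos <- matrix(rbinom(n * m_per, 2L, as.vector(probs)), n, m_per)
    dosage_list[[ci]] <- dos
    map_list[[ci]] <- data.frame(
      snp = paste0(chroms[ci], "_", pos),
      chrom = chroms[ci], pos = pos,
      subgenome = substr(chroms[ci], 1, 1),
      stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, dosage_list)
  map <- do.call(rbind, map_list)
  rownames(map) <- NULL
  dimnames(dosage) <- list(acc, map$snp)
  if (cfg$missing_rate > 0) {
    miss <- runif(length(dosage)) < cfg$missing_rate
    dosage[miss] <- NA_integer_
  }
  geno <- genotype_matrix(dosage, map, chrom_length_bp = cfg$chrom_length_bp)

  # ground-truth genetic effects: causal part on standardized dosage,
  # plus correlated polygenic residual topping variance up to sigma2_g
  traits <- cfg$traits
  g_causal <- matrix(0, n, length(traits), dimnames = list(acc, traits))
  causal <- cfg$causal_loci
  if (!is.null(causal) && nrow(causal) > 0) {
    for (i in seq_len(nrow(causal))) {
      ch <- causal$chrom[i]
      col_idx <- which(map$chrom == ch)[causal$index[i]]
      x <- dosage[, col_idx]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      xs <- if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
      for (tr in traits) {
        eff <- if (tr %in% names(causal)) causal[[tr]][i] else 0
        g_causal[, tr] <- g_causal[, tr] + eff * xs
      }
    }
  }
  resid_var <- pmax(cfg$sigma2_g - apply(g_causal, 2, var), 0)
  L <- chol(cfg$genetic_cor)
  z <- matrix(rnorm(n * length(traits)), n) %*% L
  g_poly <- sweep(z, 2, sqrt(resid_var), `*`)
  g <- g_causal + g_poly

  causal_map <- NULL
  if (!is.null(causal) && nrow(causal) > 0) {
    causal_map <- causal
    causal_map$snp <- vapply(seq_len(nrow(causal)), function(i)
      map$snp[which(map$chrom == causal$chrom[i])[causal$index[i]]], "")
    causal_map$pos <- vapply(seq_len(nrow(causal)), function(i)
      map$pos[which(map$chrom == causal$chrom[i])[causal$index[i]]], 0)
  }
  truth <- list(subpop = subpop, g = g, causal_loci = causal_map)
  list(geno = geno, truth = truth)
}

#' Simulate a replicated salt-stress phenotype trial
#'
#' For each accession, trait, year and replicate a latent salt-tolerance
#' index is drawn as `sti_mean + g + year + rep + year:rep + error` with the
#' configured variance components, then emitted as a paired control
#' measurement (`baseline x (1 + noise)`) and a salt measurement
#' (`control x latent STI`), so the downstream STI computation is exercised
#' on raw measurements. Latent STIs are clamped at 0.01 to keep
#' measurements positive; the clamp count is attached as an attribute.
#'
#' @param geno,truth output of [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return a long-format data.frame with columns
#'   `accession, year, rep, treatment, trait, value` (raw measurement
#'   names; class `phenotype_table`), with attribute `n_clamped`.
#' @export
simulate_phenotypes <- function(geno, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!identical(rownames(truth$g), rownames(geno$dosage)))
    stop("genotype matrix and truth record are inconsistent")
  set.seed(cfg$seed + 1L)
  acc <- rownames(truth$g)
  years <- as.character(2021L + seq_len(cfg$n_years))
  reps <- paste0("R", seq_len(cfg$n_reps))
  traits <- cfg$traits
  n <- length(acc)

  grid <- expand.grid(accession = acc, year = years, rep = reps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u_year <- setNames(rnorm(length(years), 0, sqrt(cfg$sigma2_year)), years)
  v_rep <- setNames(rnorm(length(reps), 0, sqrt(cfg$sigma2_rep)), reps)
  yr_key <- as.vector(outer(years, reps, paste, sep = ":"))
  w_yr <- setNames(rnorm(length(yr_key), 0, sqrt(cfg$sigma2_year_rep)), yr_key)

  n_clamped <- 0L
  out <- vector("list", length(traits))
  raw_names <- setNames(.raw_traits, .rel_traits)
  for (tr in traits) {
    eps <- rnorm(nrow(grid), 0, sqrt(cfg$sigma2_e))
    latent <- cfg$sti_mean[[tr]] + truth$g[grid$accession, tr] +
      u_year[grid$year] + v_rep[grid$rep] +
      w_yr[paste(grid$year, grid$rep, sep = ":")] + eps
    clamped <- latent < 0.01
    n_clamped <- n_clamped + sum(clamped)
    latent[clamped] <- 0.01
    control <- cfg$baseline_control[[tr]] *
      pmax(1 + rnorm(nrow(grid), 0, cfg$control_cv), 0.05)
    salt <- control * latent
    out[[tr]] <- rbind(
      data.frame(grid, treatment = "control", trait = raw_names[[tr]],
                 value = control, stringsAsFactors = FALSE),
      data.frame(grid, treatment = "salt", trait = raw_names[[tr]],
                 value = salt, stringsAsFactors = FALSE))
  }
  pheno <- do.call(rbind, out)
  rownames(pheno) <- NULL
  ord <- order(pheno$trait, pheno$accession, pheno$year, pheno$rep,
               pheno$treatment)
  pheno <- pheno[ord, ]
  rownames(pheno) <- NULL
  class(pheno) <- c("phenotype_table", "data.frame")
  attr(pheno, "n_clamped") <- n_clamped
  if (n_clamped > 0)
    message("simulate_phenotypes: clamped ", n_clamped,
            " latent STI values at 0.01")
  pheno
}
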