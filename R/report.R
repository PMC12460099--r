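# Pipeline orchestration: run every stage on a config, write tabular
# outputs and a digest manifest; subgroup ANOVA summaries with compact
# letter displays.

#' Default pipeline configuration
#'
#' A seeded demo configuration that runs the full chain end-to-end in
#' minutes on one CPU: a structured panel with a handful of planted causal
#' loci, the replicated two-year trial, the scoring chain, population
#' genetics and the association scan.
#'
#' @param seed integer seed.
#' @return a list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    sim = sim_config(
      n_accessions = 240L, n_subpops = 4L,
      n_chrom = 4L, n_snps_per_chrom = 600L, chrom_length_bp = 5e7,
      target_fst = 0.15, missing_rate = 0.02,
      causal_loci = data.frame(chrom = c("A01", "D02"),
                               index = c(300L, 300L),
                               RPH = c(0.030, 0.020),
                               RSFW = c(0.045, 0.030),
                               RSDW = c(0.050, 0.030),
                               RRDW = c(0.030, 0.040)),
      seed = seed),
    mfv_threshold = 85,
    n_classes = 5,
    gwas_trait = "RPH",
    n_pcs = 3,
    relaxed_p = 1e-5,
    min_envs = 2,
    flank_bp = 1e5,
    min_hap_group = 5,
    prune = list(window_snps = 50, step_snps = 50, r2_max = 0.2),
    window_bp = 1e5, step_bp = 2e4,
    phenotype_csv = NULL,   # external phenotype table; skips simulation
    vcf = NULL)             # external genotypes; skips simulation
}

#' Run the full pipeline
#'
#' Stages: simulate (skipped when external phenotype/genotype files are
#' configured) -> STI -> BLUE -> membership-function D value and
#' classification -> variant filters, kinship, genotype PCA, LD pruning,
#' FST / pi windows -> association scan over \{per-year means, BLUE\} of
#' the configured trait -> dual-rule significance -> QTL merging ->
#' haplotype contrast in the top QTL. All outputs are plain text in
#' `out_dir`; `manifest.json` lists each file with an md5 digest, row
#' counts and the seed. A stage failure aborts with the stage name;
#' outputs of completed stages remain on disk.
#'
#' @param config list as produced by [default_config()], or a path to a
#'   YAML file holding the non-`sim` scalar entries.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package")
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(default_config(), user)
    if (!inherits(config$sim, "sim_config"))
      config$sim <- do.call(sim_config, config$sim)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character()
  emit <- function(fname, writer) {
    path <- file.path(out_dir, fname)
    writer(path)
    files <<- c(files, path)
    path
  }

  external <- !is.null(config$phenotype_csv) && !is.null(config$vcf)
  if (external) {
    pheno <- stage("load", read_phenotypes_csv(config$phenotype_csv))
    geno <- stage("load", read_vcf(config$vcf))
    truth <- NULL
  } else {
    sim <- stage("simulate", simulate_genotypes(config$sim))
    geno <- sim$geno
    truth <- sim$truth
    pheno <- stage("simulate",
                   simulate_phenotypes(geno, truth, config$sim))
    emit("phenotypes.csv", function(p) write_phenotypes_csv(pheno, p))
    emit("genotypes.vcf", function(p) write_vcf(geno, p))
    emit("dosage.tsv", function(p) write_dosage_tsv(geno, p))
    emit("truth.json", function(p) jsonlite::write_json(
      list(subpop = as.list(truth$subpop),
           causal_loci = truth$causal_loci),
      p, auto_unbox = TRUE, digits = NA))
  }

  sti <- stage("sti", compute_sti(pheno))
  emit("sti.csv", function(p) write.csv(sti, p, row.names = FALSE))

  blue_fit <- stage("blue", fit_blue_all(sti))
  emit("blue.csv", function(p) write.csv(
    data.frame(accession = rownames(blue_fit$blue), blue_fit$blue),
    p, row.names = FALSE))
  emit("varcomp.json", function(p) jsonlite::write_json(
    as.data.frame(blue_fit$varcomp), p, digits = NA))
  emit("trait_summary.tsv", function(p) write.table(
    summarize_traits(blue_fit$blue), p, sep = "\t", quote = FALSE,
    row.names = FALSE))
  corr <- stage("correlations", trait_correlations(blue_fit$blue))
  emit("correlations.tsv", function(p) write.table(
    data.frame(trait = rownames(corr$r), corr$r), p, sep = "\t",
    quote = FALSE, row.names = FALSE))

  mfv <- stage("mfv", mfv_score(blue_fit$blue, config$mfv_threshold,
                                config$n_classes))
  emit("pca.tsv", function(p) {
    tab <- rbind(eigenvalue = mfv$pca$eigenvalues,
                 contribution_pct = mfv$pca$contribution,
                 cumulative_pct = mfv$pca$cumulative,
                 mfv$pca$loadings)
    colnames(tab) <- paste0("PC", seq_len(ncol(tab)))
    write.table(data.frame(factor = rownames(tab), tab,
                           check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  emit("d_values.csv", function(p) write.csv(
    data.frame(accession = names(mfv$D),
               mfv$F, mu = mfv$mu, D = mfv$D,
               class = as.character(mfv$classification$class),
               check.names = FALSE),
    p, row.names = FALSE))
  emit("classification.tsv", function(p) write.table(
    mfv$classification$summary, p, sep = "\t", quote = FALSE,
    row.names = FALSE))

  gf <- stage("filter", filter_variants(geno))
  K <- stage("kinship", kinship(gf))
  pcs <- stage("pca_geno", genotype_pca(gf, config$n_pcs, K = K))
  pruned <- stage("prune", ld_prune(gf, config$prune$window_snps,
                                    config$prune$step_snps,
                                    config$prune$r2_max))
  emit("pruned.snps", function(p) writeLines(pruned$keep, p))
  strict_p <- effective_snp_threshold(pruned$n_effective)

  if (!is.null(truth)) {
    fw <- stage("fst", fst_windows(gf, truth$subpop,
                                   config$window_bp, config$step_bp))
    emit("fst_windows.bed", function(p) write_windows_bed(fw, p))
  }
  pw <- stage("pi", pi_windows(gf, config$window_bp, config$step_bp))
  emit("pi_windows.bed", function(p) write_windows_bed(pw, p))

  # environments: per-year accession mean STI plus the BLUE
  tr <- config$gwas_trait
  sti_tr <- sti[sti$trait == tr, ]
  envs <- list()
  for (yr in sort(unique(sti_tr$year))) {
    d <- sti_tr[sti_tr$year == yr, ]
    envs[[yr]] <- tapply(d$sti, d$accession, mean)
  }
  envs[["BLUE"]] <- blue_fit$blue[, tr]
  scans <- stage("gwas", lapply(names(envs), function(e)
    lmm_scan(gf, envs[[e]], K = K, covariates = pcs,
             env = paste0(tr, "_", e))))
  emit("association.tsv", function(p) write.table(
    do.call(rbind, lapply(scans, as.data.frame)), p, sep = "\t",
    quote = FALSE, row.names = FALSE))

  sig <- stage("significant", call_significant(
    scans, strict_p, config$relaxed_p, config$min_envs))
  emit("significant.tsv", function(p) write.table(
    sig, p, sep = "\t", quote = FALSE, row.names = FALSE))

  qtl <- stage("qtl", define_qtl(sig, config$flank_bp,
                                 geno$chrom_length_bp))
  emit("qtl.tsv", function(p) write.table(
    qtl, p, sep = "\t", quote = FALSE, row.names = FALSE))

  hap <- NULL
  if (nrow(qtl) > 0) {
    top <- qtl[which.min(qtl$lead_p), ]
    hap <- tryCatch(
      haplotype_contrast(gf, top, envs[["BLUE"]], config$min_hap_group),
      error = function(e) NULL)
    if (!is.null(hap))
      emit("haplotype_contrast.tsv", function(p) write.table(
        data.frame(chrom = top$chrom, start = top$start, end = top$end,
                   n_hap1 = hap$group_sizes[1], n_hap2 = hap$group_sizes[2],
                   mean_hap1 = hap$group_means[1],
                   mean_hap2 = hap$group_means[2],
                   t = hap$t, p = hap$p),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  manifest <- list(
    seed = if (!is.null(config$sim$seed)) config$sim$seed else NA,
    config_hash = unname(.hash_config(config)),
    n_accessions = nrow(geno$dosage),
    n_snps = ncol(geno$dosage),
    n_snps_filtered = ncol(gf$dosage),
    n_effective_snps = pruned$n_effective,
    strict_p = strict_p,
    n_significant = nrow(sig),
    n_qtl = nrow(qtl),
    files = lapply(files, function(f) list(
      name = basename(f),
      md5 = unname(tools::md5sum(f)),
      rows = length(readLines(f)) - 1L)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(geno = geno, truth = truth, sti = sti, blue = blue_fit,
                 mfv = mfv, K = K, pcs = pcs, pruned = pruned,
                 scans = scans, significant = sig, qtl = qtl, hap = hap,
                 out_dir = out_dir))
}

.hash_config <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)   # scratch only; hashed then deleted
  tools::md5sum(tf)
}

#' Subgroup means with one-way ANOVA and letter display
#'
#' Group means, the one-way ANOVA F test, and a compact letter display
#' from Tukey HSD pairwise comparisons at `alpha` (groups sharing no
#' letter differ significantly). Groups of size 1 are excluded with a
#' warning.
#'
#' @param values numeric vector (e.g. D values or a trait).
#' @param groups group labels, same length.
#' @param alpha significance level for the letters (default 0.05).
#' @return list: `table` (group, n, mean, letters), `F`, `p`.
#' @export
summarize_subgroups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2)) {
    warning("excluding size-1 group(s): ",
            paste(names(tab)[tab < 2], collapse = ", "))
    keep <- groups %in% names(tab)[tab >= 2]
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  d <- data.frame(v = values, g = factor(groups))
  fit <- aov(v ~ g, data = d)
  an <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$g
  lev <- levels(d$g)
  p_pair <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  for (rn in rownames(tuk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    p_pair[pair[1], pair[2]] <- p_pair[pair[2], pair[1]] <- tuk[rn, "p adj"]
  }
  means <- tapply(d$v, d$g, mean)
  letters <- .letter_display(p_pair[order(-means), order(-means)], alpha)
  out <- data.frame(group = names(sort(-means)),
                    n = as.integer(table(d$g)[names(sort(-means))]),
                    mean = as.numeric(sort(means, decreasing = TRUE)),
                    letters = letters,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(table = out, F = an[1, "F value"], p = an[1, "Pr(>F)"])
}

# insert-and-absorb compact letter display from a pairwise p matrix whose
# rows/cols are ordered by descending mean
.letter_display <- function(p_pair, alpha) {
  k <- nrow(p_pair)
  # letter groups: maximal sets of mutually non-different groups, built
  # greedily over the mean-ordered sequence
  sets <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(p_pair[i, sets[[s]]] > alpha)) {
        sets[[s]] <- c(sets[[s]], i)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- i
  }
  # absorb sets contained in others
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) for (b in seq_along(sets))
    if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]))
      keep[a] <- FALSE
  sets <- sets[keep]
  out <- character(k)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}
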