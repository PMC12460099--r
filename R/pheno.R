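# Phenotype chain: salt-tolerance index (salt/control ratio), BLUE from the
# REML mixed model STI ~ accession + (1|rep) + (1|year:rep) + (1|year),
# trait summaries and correlations.

#' Compute salt-tolerance indices
#'
#' For every (accession, year, rep, trait) cell, STI is the mean salt-stress
#' measurement divided by the mean control measurement (the ratio of cell
#' means when a cell holds several plants). Trait names are converted to
#' their relative form (plant height -> RPH, shoot fresh weight -> RSFW,
#' shoot dry weight -> RSDW, root dry weight -> RRDW). Cells missing either
#' treatment are dropped with a warning; a zero control mean is an error.
#'
#' @param pheno long-format phenotype table with columns
#'   `accession, year, rep, treatment, trait, value`.
#' @return data.frame of class `sti_table` with columns
#'   `accession, year, rep, trait, sti`.
#' @export
compute_sti <- function(pheno) {
  stopifnot(all(c("accession", "year", "rep", "treatment", "trait",
                  "value") %in% names(pheno)))
  pheno <- as.data.frame(pheno)
  agg <- stats::aggregate(value ~ accession + year + rep + trait + treatment,
                          data = pheno, FUN = mean)
  ctl <- agg[agg$treatment == "control", ]
  slt <- agg[agg$treatment == "salt", ]
  key <- function(d) paste(d$accession, d$year, d$rep, d$trait, sep = "\r")
  ctl_k <- key(ctl); slt_k <- key(slt)
  common <- intersect(ctl_k, slt_k)
  n_drop <- length(union(ctl_k, slt_k)) - length(common)
  if (n_drop > 0)
    warning(n_drop, " cell(s) missing a control or salt record were dropped")
  ctl <- ctl[match(common, ctl_k), ]
  slt <- slt[match(common, slt_k), ]
  if (any(ctl$value == 0)) stop("control measurement mean of 0 in some cell")
  out <- data.frame(accession = ctl$accession, year = ctl$year,
                    rep = ctl$rep,
                    trait = relative_trait_name(ctl$trait),
                    sti = slt$value / ctl$value,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$sti))) stop("non-finite STI computed")
  out <- out[order(out$trait, out$accession, out$year, out$rep), ]
  rownames(out) <- NULL
  class(out) <- c("sti_table", "data.frame")
  out
}

#' Fit the BLUE mixed model for one trait
#'
#' REML fit of `STI ~ 0 + accession + (1|rep) + (1|year:rep) + (1|year)`
#' via lme4: accession is the fixed effect, replicate, year and
#' replicate-within-year are independent random intercepts (variance
#' estimates are non-negative by construction). With accession coded
#' without an intercept, the fixed-effect coefficients are the estimated
#' marginal means on the STI scale, reported as the BLUEs. A trait
#' observed in a single year degrades to a replicate-only random effect
#' with a warning.
#'
#' @param sti an `sti_table` (possibly holding several traits).
#' @param trait trait to fit (e.g. `"RPH"`).
#' @return list of class `blue_fit`: `blue` (named per-accession vector),
#'   `varcomp` (named vector `sigma2_rep`, `sigma2_year`,
#'   `sigma2_year_rep`, `sigma2_e`), `fit_log` (convergence info).
#' @export
fit_blue <- function(sti, trait) {
  d <- as.data.frame(sti)
  d <- d[d$trait == trait, ]
  if (nrow(d) == 0) stop("no records for trait ", trait)
  d$accession <- factor(d$accession)
  d$rep <- factor(d$rep)
  d$year <- factor(d$year)
  single_year <- nlevels(d$year) < 2
  if (single_year) {
    warning("trait ", trait,
            " observed in a single year; fitting replicate-only random effects")
    form <- sti ~ 0 + accession + (1 | rep)
  } else {
    if (nlevels(d$rep) < 2)
      stop("need >= 2 replicate levels to estimate variance components")
    d$year_rep <- interaction(d$year, d$rep, sep = ":")
    form <- sti ~ 0 + accession + (1 | rep) + (1 | year_rep) + (1 | year)
  }
  msgs <- character()
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore"))),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  fe <- lme4::fixef(fit)
  names(fe) <- sub("^accession", "", names(fe))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    i <- match(grp, vc$grp)
    if (is.na(i)) 0 else vc$vcov[i]
  }
  varcomp <- c(sigma2_rep = getv("rep"),
               sigma2_year = getv("year"),
               sigma2_year_rep = getv("year_rep"),
               sigma2_e = getv("Residual"))
  structure(list(blue = fe, varcomp = varcomp,
                 fit_log = list(trait = trait,
                                converged = length(fit@optinfo$conv$lme4) == 0,
                                optimizer = fit@optinfo$optimizer,
                                messages = msgs,
                                single_year = single_year,
                                reml_criterion = as.numeric(
                                  lme4::REMLcrit(fit)))),
            class = "blue_fit")
}

#' Fit BLUEs for every trait in an STI table
#'
#' @param sti an `sti_table`.
#' @param traits traits to fit; defaults to all present.
#' @return list with `blue` (accession x trait matrix), `varcomp`
#'   (trait x component matrix) and `fits` (per-trait `blue_fit`).
#' @export
fit_blue_all <- function(sti, traits = NULL) {
  if (is.null(traits)) traits <- unique(as.data.frame(sti)$trait)
  fits <- lapply(traits, function(tr) fit_blue(sti, tr))
  names(fits) <- traits
  acc <- sort(unique(unlist(lapply(fits, function(f) names(f$blue)))))
  blue <- matrix(NA_real_, length(acc), length(traits),
                 dimnames = list(acc, traits))
  for (tr in traits) blue[names(fits[[tr]]$blue), tr] <- fits[[tr]]$blue
  varcomp <- do.call(rbind, lapply(fits, function(f) f$varcomp))
  rownames(varcomp) <- traits
  list(blue = blue, varcomp = varcomp, fits = fits)
}

#' Per-trait descriptive statistics
#'
#' Max, min, mean, sample standard deviation (n - 1) and coefficient of
#' variation CV = 100 * SD / mean for each trait column.
#'
#' @param blue accession x trait matrix (e.g. of BLUE STIs).
#' @return data.frame with columns `trait, max, min, mean, sd, cv`.
#' @export
summarize_traits <- function(blue) {
  stopifnot(nrow(blue) >= 2)
  out <- data.frame(
    trait = colnames(blue),
    max = apply(blue, 2, max, na.rm = TRUE),
    min = apply(blue, 2, min, na.rm = TRUE),
    mean = colMeans(blue, na.rm = TRUE),
    sd = apply(blue, 2, sd, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$cv <- ifelse(out$mean == 0, NA_real_, 100 * out$sd / out$mean)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations between traits
#'
#' @param blue accession x trait matrix; requires >= 3 accessions.
#' @return list with `r` (correlation matrix) and `p` (two-sided p-values
#'   from the t distribution with n - 2 df; diagonal NA). Zero-variance
#'   traits give NA entries with a warning.
#' @export
trait_correlations <- function(blue) {
  stopifnot(nrow(blue) >= 3)
  k <- ncol(blue)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(blue), colnames(blue)))
  p <- r
  diag(r) <- 1
  zerovar <- apply(blue, 2, function(x) sd(x, na.rm = TRUE) == 0)
  if (any(zerovar))
    warning("zero-variance trait(s): ",
            paste(colnames(blue)[zerovar], collapse = ", "))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || zerovar[i] || zerovar[j]) next
    ct <- cor.test(blue[, i], blue[, j], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}
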