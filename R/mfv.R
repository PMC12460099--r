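# Membership-function-value scoring chain: correlation-matrix PCA on the
# trait STIs, component selection at a cumulative-contribution threshold,
# comprehensive index scores F, min-max membership values, contribution-rate
# weights, the composite D value, and Ward classification into tolerance
# groups.

#' Principal component analysis of the trait matrix
#'
#' Columns are standardized to mean 0 / SD 1 and the correlation matrix is
#' eigendecomposed, so eigenvalues sum to the number of traits and the
#' contribution rate of component i is 100 * lambda_i / sum(lambda).
#' Sign convention: each eigenvector's largest-magnitude coefficient is
#' positive. Missing cells are imputed by the trait mean with a warning;
#' a constant trait is an error naming the trait.
#'
#' @param blue accession x trait matrix (BLUE STIs); needs at least as many
#'   accessions as traits.
#' @return list of class `pca_result`: `eigenvalues` (descending),
#'   `loadings` (trait x PC unit-norm eigenvectors), `contribution`
#'   (percent), `cumulative` (percent), `scores` (accession x PC),
#'   `center`, `scale`, `x_std`.
#' @export
run_pca <- function(blue) {
  blue <- as.matrix(blue)
  stopifnot(nrow(blue) >= ncol(blue))
  if (anyNA(blue)) {
    warning("missing cells imputed by trait mean")
    for (j in seq_len(ncol(blue))) {
      m <- mean(blue[, j], na.rm = TRUE)
      blue[is.na(blue[, j]), j] <- m
    }
  }
  sds <- apply(blue, 2, sd)
  if (any(sds == 0))
    stop("constant trait(s): ",
         paste(colnames(blue)[sds == 0], collapse = ", "))
  ctr <- colMeans(blue)
  x_std <- scale(blue, center = ctr, scale = sds)
  e <- eigen(cor(blue), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  vec <- e$vectors
  # largest-magnitude coefficient of each eigenvector made positive
  for (i in seq_len(ncol(vec))) {
    top <- which.max(abs(vec[, i]))
    if (vec[top, i] < 0) vec[, i] <- -vec[, i]
  }
  dimnames(vec) <- list(colnames(blue), paste0("PC", seq_along(lam)))
  contribution <- 100 * lam / sum(lam)
  structure(list(eigenvalues = lam,
                 loadings = vec,
                 contribution = contribution,
                 cumulative = cumsum(contribution),
                 scores = x_std %*% vec,
                 center = ctr, scale = sds,
                 x_std = x_std),
            class = "pca_result")
}

#' Number of principal components at a cumulative-contribution threshold
#'
#' The smallest k whose cumulative contribution rate reaches the threshold
#' (default 85%).
#'
#' @param pca a `pca_result`, or a numeric vector of cumulative
#'   contribution rates in percent.
#' @param threshold percent in (0, 100].
#' @return integer k.
#' @export
select_components <- function(pca, threshold = 85) {
  stopifnot(threshold > 0, threshold <= 100)
  cum <- if (inherits(pca, "pca_result")) pca$cumulative else as.numeric(pca)
  k <- which(cum >= threshold)[1]
  if (is.na(k)) k <- length(cum)
  as.integer(k)
}

#' Comprehensive index scores
#'
#' F[a, i] = sum_j E[j, i] * x[a, j] over the standardized traits, for each
#' retained component i -- the projection of each accession onto the
#' retained eigenvectors.
#'
#' @param pca a `pca_result` (supplies loadings and the standardization).
#' @param k number of retained components.
#' @param blue optional new accession x trait matrix; standardized with the
#'   PCA's center/scale. Defaults to the matrix the PCA was run on.
#' @return accession x k matrix F.
#' @export
comprehensive_scores <- function(pca, k, blue = NULL) {
  stopifnot(inherits(pca, "pca_result"), k >= 1,
            k <= ncol(pca$loadings))
  x <- if (is.null(blue)) pca$x_std
       else scale(as.matrix(blue)[, rownames(pca$loadings), drop = FALSE],
                  center = pca$center, scale = pca$scale)
  if (ncol(x) != nrow(pca$loadings)) stop("dimension mismatch")
  x %*% pca$loadings[, seq_len(k), drop = FALSE]
}

#' Membership function values
#'
#' Column-wise min-max scaling of the comprehensive scores across the
#' panel: mu = (F - Fmin) / (Fmax - Fmin), so each column spans [0, 1].
#'
#' @param F accession x PC score matrix with >= 2 rows.
#' @return matrix of the same shape with values in [0, 1].
#' @export
membership <- function(F) {
  F <- as.matrix(F)
  stopifnot(nrow(F) >= 2)
  rng <- apply(F, 2, range)
  if (any(rng[2, ] == rng[1, ]))
    stop("constant comprehensive-score column; membership undefined ",
         "(all accessions identical on that component -- drop it or ",
         "check the input)")
  sweep(sweep(F, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], `/`)
}

#' Contribution-rate weights of the retained components
#'
#' W_i = P_i / sum(P) over the retained components only, so weights sum
#' to 1.
#'
#' @param P positive contribution rates (percent) of the retained PCs.
#' @return numeric weights summing to 1.
#' @export
mfv_weights <- function(P) {
  P <- as.numeric(P)
  if (length(P) == 0) stop("empty contribution-rate vector")
  stopifnot(all(P > 0))
  P / sum(P)
}

#' Composite D value
#'
#' D = sum_i mu_i * W_i per accession; bounded in [0, 1].
#'
#' @param mu accession x PC membership matrix.
#' @param W weights (length = ncol(mu), summing to 1).
#' @return named numeric vector of D values.
#' @export
d_value <- function(mu, W) {
  mu <- as.matrix(mu)
  stopifnot(length(W) == ncol(mu))
  drop(mu %*% W)
}

#' Ward classification of D values into tolerance groups
#'
#' Agglomerative clustering of the one-dimensional D values (Euclidean
#' distance, Ward's minimum variance linkage), tree cut at `n_classes`,
#' classes relabelled I, II, ... by descending class mean D (class I is
#' the most tolerant).
#'
#' @param D named per-accession D values; length >= `n_classes`.
#' @param n_classes number of groups (default 5).
#' @return list of class `tolerance_classification`: `class` (named factor
#'   with roman levels), `summary` (per-class n, mean, min and max D).
#' @export
classify_tolerance <- function(D, n_classes = 5) {
  stopifnot(length(D) >= n_classes)
  hc <- hclust(dist(D), method = "ward.D2")
  raw <- cutree(hc, k = n_classes)
  means <- tapply(D, raw, mean)
  ord <- order(means, decreasing = TRUE)
  roman <- as.character(utils::as.roman(seq_len(n_classes)))
  relabel <- setNames(roman, names(means)[ord])
  cls <- factor(relabel[as.character(raw)], levels = roman)
  names(cls) <- names(D)
  summ <- data.frame(
    class = roman,
    n = as.integer(table(cls)[roman]),
    mean_d = as.numeric(tapply(D, cls, mean)[roman]),
    min_d = as.numeric(tapply(D, cls, min)[roman]),
    max_d = as.numeric(tapply(D, cls, max)[roman]),
    stringsAsFactors = FALSE)
  structure(list(class = cls, summary = summ,
                 linkage = "ward.D2 on Euclidean distances of D"),
            class = "tolerance_classification")
}

#' Full membership-function-value scoring chain
#'
#' Runs PCA on the BLUE STI matrix, selects components at the cumulative
#' threshold, computes comprehensive scores, membership values,
#' contribution-rate weights and the composite D value, and classifies the
#' panel into tolerance groups.
#'
#' @param blue accession x trait matrix of BLUE STIs.
#' @param threshold cumulative contribution threshold in percent.
#' @param n_classes number of tolerance classes.
#' @return list of class `mfv_result`: `pca`, `k`, `F`, `mu`, `W`, `D`,
#'   `classification`.
#' @export
mfv_score <- function(blue, threshold = 85, n_classes = 5) {
  pca <- run_pca(blue)
  k <- select_components(pca, threshold)
  F <- comprehensive_scores(pca, k)
  mu <- membership(F)
  W <- mfv_weights(pca$contribution[seq_len(k)])
  D <- d_value(mu, W)
  structure(list(pca = pca, k = k, F = F, mu = mu, W = W, D = D,
                 classification = classify_tolerance(D, n_classes)),
            class = "mfv_result")
}
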