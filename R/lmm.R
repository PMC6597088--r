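#' Build the fixed-effect design matrix for the association model
#'
#' Intercept + sex + batch + backcross dummies + mean-centred carcass
#' weight. Factor levels with no observations are dropped; in
#' single-backcross scans the backcross term is removed automatically.
#'
#' @param pheno a `phenotype_table` (or data.frame with sex, batch,
#'   backcross, carcass_weight).
#' @param include_backcross include the backcross fixed effect.
#' @return numeric design matrix (n x p), full rank enforced.
#' @export
model_matrix_gwas <- function(pheno, include_backcross = TRUE) {
  terms <- "~ factor(sex) + factor(batch)"
  if (include_backcross && length(unique(pheno$backcross)) > 1L)
    terms <- paste(terms, "+ factor(backcross)")
  terms <- paste(terms, "+ I(carcass_weight - mean(carcass_weight))")
  X <- stats::model.matrix(stats::as.formula(terms), data = pheno)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[setdiff(seq_len(ncol(X)),
                                     qr_x$pivot[seq_len(qr_x$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  X
}

#' REML variance components under the null mixed model
#'
#' Model y = X beta + u + e with u ~ N(0, sigma_u^2 K),
#' e ~ N(0, sigma_e^2 I). The kinship is eigendecomposed once; the REML
#' log-likelihood is profiled over the variance ratio
#' lambda = sigma_u^2 / sigma_e^2 on a log10 grid and refined with
#' Brent optimization. Deterministic for fixed input.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (full rank).
#' @param K n x n kinship matrix.
#' @return list (class `lmm_null`): sigma_u2, sigma_e2, lambda, loglik,
#'   h2 (sigma_u2 / (sigma_u2 + sigma_e2)), plus the eigendecomposition
#'   for reuse by [lmm_scan()].
#' @export
fit_null <- function(y, X, K) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix in fit_null")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- crossprod(e$vectors, y)
  Xt <- crossprod(e$vectors, X)
  p <- ncol(X)
  reml <- function(log10_lambda) {
    lam <- 10^log10_lambda
    w <- lam * d + 1
    sw <- 1 / sqrt(w)
    Xw <- Xt * sw
    yw <- yt * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              determinant(XtX, logarithm = TRUE)$modulus[1])
  }
  grid <- seq(-6, 6, by = 0.25)
  ll <- vapply(grid, reml, 0)
  i <- which.max(ll)
  if (i == 1L) {
    lam <- 0
    loglik <- reml(-Inf)
  } else {
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-6)
    lam <- 10^opt$maximum
    loglik <- opt$objective
  }
  w <- lam * d + 1
  sw <- 1 / sqrt(w)
  fit <- stats::lm.fit(Xt * sw, yt * sw)
  s2 <- sum(fit$residuals^2) / (n - p)
  structure(list(sigma_u2 = lam * s2, sigma_e2 = s2, lambda = lam,
                 loglik = loglik, h2 = lam * s2 / (lam * s2 + s2),
                 eigen_vectors = e$vectors, eigen_values = d),
            class = "lmm_null")
}

#' Mixed-model association scan with variance components fixed from the null
#'
#' For every marker, the additive effect is estimated by generalized least
#' squares under V = sigma_u^2 K + sigma_e^2 I using the null-model
#' variance components (the EMMAX-style approximation), with a Wald t-test
#' on n - p - 1 degrees of freedom. With sigma_u2 = 0 the scan is exactly
#' ordinary least squares. Missing genotype codes are mean-imputed per
#' marker; markers constant after imputation are reported as NA and
#' counted.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix.
#' @param G individuals x markers code matrix (-1/0/+1, NA allowed) or a
#'   `genotype_matrix`.
#' @param null a `lmm_null` from [fit_null()] on the same y and X.
#' @return data.frame (class `assoc_result`): marker, a_hat, se, stat,
#'   p_value; attribute `n_skipped_constant`.
#' @export
lmm_scan <- function(y, X, G, null) {
  M <- if (is.matrix(G)) G else G$codes
  n <- length(y)
  p <- ncol(X)
  M <- impute_marker_means(M)
  sw <- 1 / sqrt(null$lambda * null$eigen_values + 1)
  U <- null$eigen_vectors
  yw <- drop(crossprod(U, y)) * sw
  Xw <- crossprod(U, X) * sw
  Mw <- crossprod(U, M) * sw
  qx <- qr(Xw)
  yr <- qr.resid(qx, yw)
  Mr <- qr.resid(qx, Mw)
  gg <- colSums(Mr^2)
  const <- gg < 1e-12
  gy <- colSums(Mr * yr)
  a <- gy / gg
  df <- n - p - 1L
  rss <- sum(yr^2) - a^2 * gg
  s2 <- rss / df
  se <- sqrt(s2 / gg)
  stat <- a / se
  pv <- 2 * stats::pt(-abs(stat), df)
  a[const] <- se[const] <- stat[const] <- pv[const] <- NA_real_
  if (any(const))
    message(sum(const), " constant marker(s) skipped in scan")
  out <- data.frame(marker = colnames(M) %||% seq_len(ncol(M)),
                    a_hat = a, se = se, stat = stat, p_value = pv,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped_constant") <- sum(const)
  class(out) <- c("assoc_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up q-values and significance classes
#'
#' q(i) = min over j >= i of (m / j) * p(j) on the sorted p-vector, mapped
#' back to input order and capped at 1. Classes: significant (q <= 0.05),
#' suggestive (0.05 < q <= 0.1), ns.
#'
#' @param p numeric p-values in [0, 1] (NA passed through).
#' @param significant,suggestive thresholds.
#' @return data.frame: p_value, q_value, class.
#' @export
bh_fdr <- function(p, significant = 0.05, suggestive = 0.1) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m) {
    o <- order(pp)
    qs <- pmin(1, rev(cummin(rev(pp[o] * m / seq_len(m)))))
    qq <- numeric(m); qq[o] <- qs
    q[ok] <- qq
  }
  cls <- rep(NA_character_, length(p))
  cls[!is.na(q) & q <= significant] <- "significant"
  cls[!is.na(q) & q > significant & q <= suggestive] <- "suggestive"
  cls[!is.na(q) & q > suggestive] <- "ns"
  data.frame(p_value = p, q_value = q, class = cls, stringsAsFactors = FALSE)
}

#' Full association analysis for one trait
#'
#' Marker QC, kinship (computed if not supplied), null REML fit, EMMAX
#' scan and BH-FDR classification. `backcross = NULL` analyses the merged
#' dataset with a backcross fixed effect; naming one backcross restricts
#' to its individuals and drops the backcross term.
#'
#' @param G a `genotype_matrix`.
#' @param pheno a `phenotype_table` aligned to `G`.
#' @param backcross NULL or one backcross name.
#' @param kinship optional precomputed kinship (merged-data order).
#' @param qc apply [marker_qc()] first.
#' @param log2_transform log2-transform the trait before analysis.
#' @return list: `results` (assoc_result + q_value + class), `null`
#'   (variance components), `qc_report`.
#' @export
run_gwas <- function(G, pheno, backcross = NULL, kinship = NULL, qc = TRUE,
                     log2_transform = FALSE) {
  stopifnot(identical(G$info$id, pheno$id))
  if (!is.null(backcross)) {
    rows <- which(G$info$backcross == backcross)
    if (!length(rows)) stop("unknown backcross: ", backcross)
    G <- subset_genotypes(G, rows)
    if (!is.null(kinship)) kinship <- kinship[rows, rows, drop = FALSE]
    pheno <- pheno[rows, , drop = FALSE]
  }
  qc_report <- NULL
  if (qc) {
    q <- marker_qc(G)
    G <- q$G
    qc_report <- q$report
  }
  if (is.null(kinship)) kinship <- centered_kinship(G)
  y <- pheno$trait
  if (log2_transform) y <- log2(y)
  X <- model_matrix_gwas(pheno, include_backcross = is.null(backcross))
  null <- fit_null(y, X, kinship)
  res <- lmm_scan(y, X, G, null)
  fdr <- bh_fdr(res$p_value)
  res$q_value <- fdr$q_value
  res$class <- fdr$class
  list(results = res, null = null, qc_report = qc_report)
}

subset_genotypes <- function(G, rows) {
  G$codes <- G$codes[rows, , drop = FALSE]
  G$info <- G$info[rows, , drop = FALSE]
  if (!is.null(G$pedigree)) G$pedigree <- G$pedigree[rows, , drop = FALSE]
  G
}

#' Manhattan/QQ data table for an association scan
#'
#' @param results an `assoc_result` (optionally with q-values) whose marker
#'   names are normalized keys (`chrom:pos:ref:alt`).
#' @return data.frame: marker, chrom, pos, p_value, neg_log10_p, and the
#'   expected quantile `neg_log10_exp` for a QQ plot.
#' @export
assoc_plot_data <- function(results) {
  parts <- strsplit(results$marker, ":", fixed = TRUE)
  out <- data.frame(marker = results$marker,
                    chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    p_value = results$p_value,
                    neg_log10_p = -log10(results$p_value),
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$p_value)
  r <- rank(out$p_value[ok], ties.method = "first")
  out$neg_log10_exp <- NA_real_
  out$neg_log10_exp[ok] <- -log10(r / (sum(ok) + 1))
  out
}
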