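#' Genewise method-of-moments NB dispersion
#'
#' On size-factor-normalized counts, within each group compute the
#' sample mean `m` and unbiased variance `v` and estimate the
#' negative-binomial dispersion as `(v - m) / m^2` (so that
#' `Var = mu + alpha * mu^2`).  Per-group estimates are averaged across
#' groups and floored at `alpha_min`.
#'
#' @param cm a [count_matrix()].
#' @param groups list of two (or more) cell-type labels, each with at
#'   least two replicates.
#' @param sf size factors (default: [size_factors()] of `cm`).
#' @param alpha_min dispersion floor (default 1e-8).
#' @return data.frame `gene_id`, `mean` (grand mean of group means of
#'   normalized counts), `alpha` (floored genewise estimate),
#'   `alpha_raw` (unfloored average, can be negative).
#' @export
estimate_dispersion <- function(cm, groups, sf = size_factors(cm),
                                alpha_min = 1e-8) {
  norm <- sweep(cm$counts, 2, sf[colnames(cm$counts)], "/")
  per_group <- sapply(groups, function(g) {
    idx <- group_columns(cm, g)
    if (length(idx) < 2L)
      stop("group '", g, "' has fewer than 2 replicates")
    x <- norm[, idx, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    est <- ifelse(m > 0, (v - m) / m^2, 0)
    est
  })
  means <- sapply(groups, function(g)
    rowMeans(norm[, group_columns(cm, g), drop = FALSE]))
  raw <- rowMeans(per_group)
  data.frame(gene_id = rownames(cm$counts),
             mean = rowMeans(means),
             alpha = pmax(alpha_min, raw),
             alpha_raw = raw,
             row.names = NULL)
}

#' Moderate genewise dispersions toward a mean-dispersion trend
#'
#' With few replicates the genewise moment estimator has only a handful
#' of degrees of freedom, and plugging it straight into a Wald statistic
#' gives t-like (heavy) tails and an inflated false-positive rate.  As
#' in mainstream count-based DE tools, genewise estimates are therefore
#' squeezed toward a parametric trend `alpha(mu) = a0 + a1 / mu`, fitted
#' by iteratively reweighted least squares over genes with positive raw
#' estimates.  The squeeze weight is `df / (df + prior_df)` where `df`
#' is the residual degrees of freedom of the genewise estimate.
#'
#' @param disp output of [estimate_dispersion()].
#' @param df residual degrees of freedom behind each genewise estimate
#'   (sum over groups of replicates - 1).
#' @param prior_df prior degrees of freedom of the trend (default 20;
#'   larger means stronger moderation).
#' @param alpha_min dispersion floor.
#' @return `disp` with `alpha` replaced by the moderated value and extra
#'   columns `alpha_trend`, plus attributes `a0`, `a1`.
#' @export
moderate_dispersion <- function(disp, df, prior_df = 20, alpha_min = 1e-8) {
  est <- disp$alpha_raw
  mu <- disp$mean
  ok <- is.finite(est) & est > 0 & mu > 0
  if (sum(ok) < 10) {
    # too few usable genes to fit a trend; fall back to a robust
    # common dispersion
    a0 <- max(alpha_min, median(est[is.finite(est)], na.rm = TRUE))
    a1 <- 0
  } else {
    a0 <- max(median(est[ok]), alpha_min); a1 <- 1
    for (i in 1:20) {
      w <- 1 / (a0 + a1 / mu[ok])^2
      fit <- tryCatch(lm(est[ok] ~ I(1 / mu[ok]), weights = w),
                      error = function(e) NULL)
      if (is.null(fit)) break
      a0n <- max(unname(coef(fit)[1]), alpha_min)
      a1n <- max(unname(coef(fit)[2]), 0)
      if (!is.finite(a0n) || !is.finite(a1n)) break
      conv <- abs(a0n - a0) < 1e-8 && abs(a1n - a1) < 1e-8
      a0 <- a0n; a1 <- a1n
      if (conv) break
    }
  }
  trend <- pmax(alpha_min, a0 + a1 / pmax(mu, 1e-8))
  w <- df / (df + prior_df)
  disp$alpha_trend <- trend
  disp$alpha <- pmax(alpha_min, w * pmax(est, alpha_min) + (1 - w) * trend)
  attr(disp, "a0") <- a0
  attr(disp, "a1") <- a1
  disp
}

#' Negative-binomial Wald test between two cell types
#'
#' Per gene, `log2FC = log2((mA + c) / (mB + c))` on size-factor
#' normalized group means (pseudo-mean `c` guards against zeros), with a
#' delta-method standard error from the NB variance
#' `Var(K) = mu + alpha * mu^2`; `z = log2FC / SE` is referred to the
#' standard normal, two-sided.  The fold change is `groupA` over
#' `groupB`.
#'
#' @param cm a [count_matrix()].
#' @param groupA,groupB cell-type labels (A is the numerator).
#' @param dispersions data.frame with `gene_id`, `alpha` covering every
#'   gene of `cm` (see [estimate_dispersion()] / [moderate_dispersion()]).
#' @param sf size factors.
#' @param pseudo_mean pseudo-mean `c` (default 0.5 normalized counts).
#' @return data.frame with `gene_id`, `baseMeanA`, `baseMeanB`,
#'   `log2FC`, `p`; `FDR` is left `NA` for [bh_adjust()] to fill.
#' @export
nb_wald_test <- function(cm, groupA, groupB, dispersions,
                         sf = size_factors(cm), pseudo_mean = 0.5) {
  a <- dispersions$alpha[match(rownames(cm$counts), dispersions$gene_id)]
  if (any(is.na(a)))
    stop("dispersions missing for ",
         sum(is.na(a)), " gene(s), e.g. ",
         rownames(cm$counts)[which(is.na(a))[1]])
  norm <- sweep(cm$counts, 2, sf[colnames(cm$counts)], "/")
  ia <- group_columns(cm, groupA); ib <- group_columns(cm, groupB)
  nA <- length(ia); nB <- length(ib)
  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  c0 <- pseudo_mean
  l2fc <- log2((mA + c0) / (mB + c0))
  # Var of a mean of normalized NB counts; size factors enter through the
  # Poisson part (1/sf per sample), the overdispersion part scales with m^2.
  pois_a <- rowSums(outer(mA, 1 / sf[colnames(cm$counts)][ia])) / nA^2
  pois_b <- rowSums(outer(mB, 1 / sf[colnames(cm$counts)][ib])) / nB^2
  vA <- pois_a + a * mA^2 / nA
  vB <- pois_b + a * mB^2 / nB
  se2 <- (vA / (mA + c0)^2 + vB / (mB + c0)^2) / log(2)^2
  z <- ifelse(se2 > 0, l2fc / sqrt(se2), 0)
  p <- 2 * pnorm(-abs(z))
  data.frame(gene_id = rownames(cm$counts),
             baseMeanA = mA, baseMeanB = mB,
             log2FC = l2fc, p = p, FDR = NA_real_,
             row.names = NULL)
}

#' Call differentially expressed genes
#'
#' A gene is `up` when its fold change (A over B) is at least `fc_min`
#' and its FDR below `fdr_max`; `down` when the fold change is at most
#' `1 / fc_min` at the same FDR; otherwise `ns`.  With the defaults this
#' is the fold change >= 2, FDR < 0.01 rule.
#'
#' @param results data.frame from [nb_wald_test()] with `FDR` filled.
#' @param fc_min fold-change threshold on the ratio scale (default 2,
#'   i.e. |log2FC| >= 1); must exceed 1.
#' @param fdr_max FDR threshold (default 0.01).
#' @return list with character vectors `up` and `down` (disjoint) and
#'   the annotated `results` (added `call` column).
#' @export
call_degs <- function(results, fc_min = 2, fdr_max = 0.01) {
  if (fc_min <= 1)
    stop("fc_min must be > 1")
  if (any(is.na(results$FDR)))
    stop("FDR not filled; run bh_adjust() on the p-values first")
  lfc_min <- log2(fc_min)
  call <- rep("ns", nrow(results))
  call[results$log2FC >= lfc_min & results$FDR < fdr_max] <- "up"
  call[results$log2FC <= -lfc_min & results$FDR < fdr_max] <- "down"
  results$call <- call
  list(up = results$gene_id[call == "up"],
       down = results$gene_id[call == "down"],
       results = results)
}

#' One-call DE contrast under the standard thresholds
#'
#' Convenience wrapper: dispersion estimation (+ trend moderation by
#' default), Wald test, BH adjustment and DEG calling for one contrast.
#'
#' @param cm a [count_matrix()].
#' @param contrast `"A:B"` string or character vector `c(A, B)`; fold
#'   change is A over B.
#' @param fc_min,fdr_max see [call_degs()].
#' @param moderate apply [moderate_dispersion()] (default TRUE).
#' @param prior_df see [moderate_dispersion()].
#' @param sf size factors (default computed from `cm`).
#' @return as [call_degs()], plus element `contrast`.
#' @export
de_contrast <- function(cm, contrast, fc_min = 2, fdr_max = 0.01,
                        moderate = TRUE, prior_df = 20,
                        sf = size_factors(cm)) {
  ab <- if (length(contrast) == 1L) strsplit(contrast, ":")[[1]] else contrast
  if (length(ab) != 2L)
    stop("contrast must name two cell types, e.g. 'AC:BC'")
  disp <- estimate_dispersion(cm, as.list(ab), sf = sf)
  if (moderate) {
    df <- sum(sapply(ab, function(g) length(group_columns(cm, g)) - 1L))
    disp <- moderate_dispersion(disp, df = df, prior_df = prior_df)
  }
  res <- nb_wald_test(cm, ab[1], ab[2], disp, sf = sf)
  res$FDR <- bh_adjust(res$p)
  out <- call_degs(res, fc_min = fc_min, fdr_max = fdr_max)
  out$contrast <- paste(ab, collapse = ":")
  out
}

#' @rdname de_contrast
#' @param de result of [de_contrast()] / [call_degs()].
#' @param file output TSV path.
#' @export
write_de <- function(de, file) {
  write.table(de$results, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
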