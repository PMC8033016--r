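#' @include AllClasses.R
NULL

#' Spearman correlation with strength category
#'
#' Rank correlation (average ranks for ties) with the conventional strength
#' categories applied to the magnitude of rho: weak (|rho| < 0.4), moderate
#' (0.4 <= |rho| <= 0.6), strong (|rho| > 0.6). The boundaries themselves
#' (0.4, 0.6) are moderate.
#'
#' @param x,y paired numeric vectors, length >= 3, neither constant
#' @return one-row data.frame with \code{rho}, \code{p_value}, \code{n},
#'   \code{category}
#' @examples
#' spearmanWithCategory(1:10, (1:10)^3)  # rho 1, strong
#' @export
spearmanWithCategory <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) .stopf("need at least 3 complete pairs, got %d", n)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    .stopf("correlation undefined: input is constant")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  data.frame(rho = rho, p_value = ct$p.value, n = n,
             category = rhoCategory(rho))
}

#' Correlation strength category
#'
#' @param rho Spearman coefficient(s)
#' @return \code{"weak"}, \code{"moderate"} or \code{"strong"} per
#'   \eqn{|rho|} (< 0.4 / 0.4-0.6 / > 0.6)
#' @export
rhoCategory <- function(rho) {
  a <- abs(rho)
  ifelse(a < 0.4, "weak", ifelse(a <= 0.6, "moderate", "strong"))
}

#' Compare a feature across atrial regions
#'
#' Rank-based omnibus test (Kruskal-Wallis) across all regions with at
#' least two values, followed by all pairwise Wilcoxon rank-sum tests with
#' Bonferroni-corrected significance: a pair is significant when its
#' p-value is strictly below \code{familyAlpha / choose(k, 2)} (0.05/6 =
#' 0.0083 for four regions). Exact rank-sum p-values are used when both
#' groups have n <= 10 and no ties; the large-sample approximation
#' otherwise. When the continuous feature is normally distributed in every
#' group (Shapiro-Wilk), \code{gaussian = TRUE} switches to ANOVA +
#' pairwise t-tests; the default path is rank-based, matching median/IQR
#' reporting.
#'
#' @param values numeric feature values (e.g. one per patient-region)
#' @param regions region label per value
#' @param familyAlpha family-wise alpha, default 0.05
#' @param gaussian use ANOVA/t-tests instead of rank tests
#' @return list with \code{omnibus_p}, \code{alpha_corrected},
#'   \code{n_pairs} and a \code{pairs} data.frame
#'   (\code{region1, region2, p_value, significant})
#' @export
compareRegions <- function(values, regions, familyAlpha = 0.05,
                           gaussian = FALSE) {
  regions <- as.character(regions)
  keep <- is.finite(values)
  values <- values[keep]; regions <- regions[keep]
  sizes <- table(regions)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    .warnf("region(s) with fewer than 2 values excluded: %s",
           paste(small, collapse = ", "))
    keep <- !(regions %in% small)
    values <- values[keep]; regions <- regions[keep]
  }
  groups <- unique(regions)
  k <- length(groups)
  if (k < 2L) .stopf("need at least 2 regions with >= 2 values")
  nPairs <- k * (k - 1L) / 2L
  alphaC <- familyAlpha / nPairs
  omni <- if (gaussian)
    summary(stats::aov(values ~ factor(regions)))[[1L]][["Pr(>F)"]][1L]
  else stats::kruskal.test(values, factor(regions))$p.value
  combs <- utils::combn(sort(groups), 2L)
  pv <- apply(combs, 2L, function(pair) {
    a <- values[regions == pair[1L]]
    b <- values[regions == pair[2L]]
    if (gaussian) stats::t.test(a, b)$p.value
    else {
      useExact <- length(a) <= 10L && length(b) <= 10L &&
        !anyDuplicated(c(a, b))
      suppressWarnings(stats::wilcox.test(a, b, exact = useExact)$p.value)
    }
  })
  list(omnibus_p = omni, alpha_corrected = alphaC, n_pairs = nPairs,
       pairs = data.frame(region1 = combs[1L, ], region2 = combs[2L, ],
                          p_value = pv, significant = pv < alphaC))
}

## the fingerprint features correlated with CB
.cbFeatures <- c(median_voltage_mv = "medianVoltageMv",
                 pct_low_voltage = "pctLowVoltage",
                 median_rs_ratio = "medianRsRatio",
                 pct_sp = "pctSp", pct_sdp = "pctSdp", pct_ldp = "pctLdp",
                 pct_fp = "pctFp", median_fd_ms = "medianFdMs")

.regionFpOf <- function(fp, regionLabel) {
  if (regionLabel == "ALL") return(fp@overall)
  fp@regions[[regionLabel]]
}

#' Correlate conduction block with the fingerprint features
#'
#' Across a cohort of patient fingerprints, Spearman correlations between
#' the per-patient conduction-block percentage and every EGM feature
#' (median voltage, low-voltage percentage, R/S ratio, type proportions,
#' fractionation duration), for one region or the pooled entry. A feature
#' that is constant across patients (or has too few complete pairs) is
#' reported as undefined rather than aborting the table.
#'
#' @param fingerprints list of [PatientFingerprint-class] (>= 3)
#' @param regionLabel one of \code{RA}, \code{BB}, \code{PVA}, \code{LA}
#'   or \code{"ALL"} for the pooled fingerprints
#' @return data.frame with one row per feature: \code{feature},
#'   \code{rho}, \code{p_value}, \code{n}, \code{category} (\code{NA}
#'   where undefined)
#' @export
correlateCbWithFeatures <- function(fingerprints, regionLabel = "ALL") {
  if (length(fingerprints) < 3L)
    .stopf("need at least 3 fingerprints, got %d", length(fingerprints))
  regs <- lapply(fingerprints, .regionFpOf, regionLabel = regionLabel)
  ok <- !vapply(regs, is.null, logical(1))
  regs <- regs[ok]
  cb <- vapply(regs, function(r) r@pctCb, numeric(1))
  out <- lapply(names(.cbFeatures), function(fname) {
    vals <- vapply(regs, function(r) slot(r, .cbFeatures[[fname]]),
                   numeric(1))
    res <- tryCatch(spearmanWithCategory(vals, cb), error = function(e) NULL)
    if (is.null(res))
      data.frame(feature = fname, rho = NA_real_, p_value = NA_real_,
                 n = sum(is.finite(vals) & is.finite(cb)),
                 category = NA_character_)
    else cbind(feature = fname, res)
  })
  do.call(rbind, out)
}
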