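#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, clipped to 1 and order-preserving with
#' the input (delegates to \code{stats::p.adjust} after validating the
#' input).
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @return adjusted values, same order as the input.
#' @examples
#' adjustBH(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
#' @export
adjustBH <- function(p_values) {
  .assert(is.numeric(p_values), "p-values must be numeric")
  .assert(all(is.finite(p_values) & p_values >= 0 & p_values <= 1),
          "p-values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Label DE direction
#'
#' \code{up} if fdr < threshold and log2fc > 0, \code{down} if fdr <
#' threshold and log2fc < 0, otherwise \code{ns} ("in the latter" group B
#' relative to group A).
#'
#' @param results DataFrame/data.frame with \code{log2fc} and \code{fdr}.
#' @param thresholds a \code{\link{thresholdConfig}}.
#' @return \code{results} with the \code{direction} column (re)set.
#' @export
classifyDirection <- function(results, thresholds = thresholdConfig()) {
  .assert(all(c("log2fc", "fdr") %in% colnames(results)),
          "results must carry log2fc and fdr")
  sig <- results$fdr < thresholds@fdr_threshold
  results$direction <- ifelse(sig & results$log2fc > 0, "up",
                              ifelse(sig & results$log2fc < 0, "down", "ns"))
  results
}

# per-feature method-of-moments dispersion shrunk toward a lowess trend on
# the mean. The trend is fit without robustness iterations (the moment
# estimates are right-skewed; robust fitting tracks below their mean and
# makes the test anticonservative) and the per-feature estimate gets weight
# df/(df + prior_df): at the 4 residual df of a 3-vs-3 design the moment
# estimate is too noisy for equal weighting to stay calibrated. Floor 1e-8.
.estimateDispersions <- function(y, grp_a, grp_b, prior_df = 20) {
  mu <- rowMeans(y)
  nA <- length(grp_a); nB <- length(grp_b)
  df <- nA + nB - 2L
  vA <- apply(y[, grp_a, drop = FALSE], 1L, var)
  vB <- apply(y[, grp_b, drop = FALSE], 1L, var)
  s2 <- (vA * (nA - 1L) + vB * (nB - 1L)) / df
  mu_g <- (rowMeans(y[, grp_a, drop = FALSE]) +
             rowMeans(y[, grp_b, drop = FALSE])) / 2
  phi_mom <- ifelse(mu_g > 0, (s2 - mu_g) / mu_g^2, NA_real_)
  ok <- !is.na(phi_mom) & mu_g > 0
  phi_trend <- rep(mean(pmax(phi_mom[ok], 0), na.rm = TRUE), length(mu))
  if (!any(ok)) phi_trend[] <- 0
  if (sum(ok) >= 10L && length(unique(mu_g[ok])) >= 5L) {
    fit <- lowess(log(mu_g[ok]), pmax(phi_mom[ok], 0), f = 0.5, iter = 0)
    phi_trend <- approx(fit$x, fit$y, xout = log(pmax(mu_g, min(mu_g[ok]))),
                        rule = 2, ties = mean)$y
  }
  w <- df / (df + prior_df)
  pmax(w * pmax(ifelse(is.na(phi_mom), 0, phi_mom), 0) + (1 - w) * phi_trend,
       1e-8)
}

# exact conditional NB test on quantile-adjusted counts: given the total
# count S of both groups, the group-B sum is compared with its conditional
# distribution under equal means; two-sided p sums all outcomes no more
# probable than the observed one (double tail)
.exactNBTest <- function(yA, yB, phi) {
  SA <- sum(yA); SB <- sum(yB); S <- SA + SB
  if (S == 0L) return(1)
  nA <- length(yA); nB <- length(yB)
  mu <- S / (nA + nB)
  k <- 0:S
  lp <- dnbinom(k, size = nB / phi, mu = nB * mu, log = TRUE) +
    dnbinom(S - k, size = nA / phi, mu = nA * mu, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pobs <- pr[SB + 1L]
  min(1, sum(pr[pr <= pobs * (1 + 1e-10)]) / sum(pr))
}

#' Two-group differential expression test
#'
#' Library-size-normalized negative-binomial test per feature: counts are
#' scaled to the geometric-mean library size (quantile adjustment), the NB
#' dispersion is estimated per feature by method of moments and shrunk toward
#' a lowess mean-dispersion trend with weight df/(df + 20) on the per-feature
#' estimate (floor 1e-8), and a two-sided
#' p-value comes from the exact conditional test comparing the group sums
#' given their total. Log2 fold changes (group B over group A) are computed
#' on pseudocounted group-mean CPM. All-zero features are flagged and get
#' p = 1, log2fc = 0.
#'
#' @param x \linkS4class{ExpressionMatrix} on the counts layer.
#' @param design sample design covering all samples of \code{x}.
#' @param group_a,group_b design group labels to compare (fold changes are B
#'   over A); defaults to the first two groups in the design.
#' @param thresholds a \code{\link{thresholdConfig}} (FDR cutoff and
#'   pseudocount).
#' @param library_sizes optional named per-sample library-size override;
#'   default: column sums of the raw counts.
#' @return \link[S4Vectors]{DataFrame} with columns \code{feature_id},
#'   \code{log2fc}, \code{p_value}, \code{fdr}, \code{direction}
#'   (\code{up}/\code{down}/\code{ns}), \code{mean_abundance} (mean CPM) and
#'   \code{flagged} (all-zero features).
#' @examples
#' design <- makeSampleDesign()
#' m <- matrix(rpois(60, 50), 10, 6,
#'             dimnames = list(paste0("g", 1:10), design$sample_id))
#' testTwoGroup(ExpressionMatrix(m), design)
#' @export
testTwoGroup <- function(x, design, group_a = NULL, group_b = NULL,
                         thresholds = thresholdConfig(),
                         library_sizes = NULL) {
  .assert(is(x, "ExpressionMatrix"), "x must be an ExpressionMatrix")
  .assert(identical(exprLayer(x), "counts"),
          "the DE test runs on the counts layer (got %s)", exprLayer(x))
  validateSampleDesign(design)
  v <- exprValues(x)
  .assert(all(colnames(v) %in% design$sample_id),
          "all samples of x must appear in the design")
  grp <- setNames(design$group, design$sample_id)[colnames(v)]
  if (is.null(group_a)) group_a <- unique(design$group)[1L]
  if (is.null(group_b)) group_b <- unique(design$group)[2L]
  .assert(all(c(group_a, group_b) %in% grp),
          "groups %s/%s not present among the samples", group_a, group_b)
  idx_a <- which(grp == group_a); idx_b <- which(grp == group_b)
  .assert(length(idx_a) >= 2L && length(idx_b) >= 2L,
          "each group needs >= 2 replicates")
  v <- v[, c(idx_a, idx_b), drop = FALSE]
  grp_a <- seq_along(idx_a)
  grp_b <- length(idx_a) + seq_along(idx_b)

  if (nrow(v) == 0L) {
    return(DataFrame(feature_id = character(0), log2fc = numeric(0),
                     p_value = numeric(0), fdr = numeric(0),
                     direction = character(0), mean_abundance = numeric(0),
                     flagged = logical(0)))
  }
  libs <- .resolveLibSizes(v, library_sizes)
  common <- exp(mean(log(libs)))
  y <- round(sweep(v, 2L, common / libs, "*"))
  phi <- .estimateDispersions(y, grp_a, grp_b)

  cpm <- sweep(v, 2L, libs, "/") * 1e6
  mean_a <- rowMeans(cpm[, grp_a, drop = FALSE])
  mean_b <- rowMeans(cpm[, grp_b, drop = FALSE])
  pc <- thresholds@pseudocount
  log2fc <- log2((mean_b + pc) / (mean_a + pc))
  flagged <- rowSums(v) == 0
  log2fc[flagged] <- 0

  p <- vapply(seq_len(nrow(y)), function(i) {
    if (flagged[i]) return(1)
    .exactNBTest(y[i, grp_a], y[i, grp_b], phi[i])
  }, numeric(1))

  res <- DataFrame(feature_id = rownames(v), log2fc = log2fc, p_value = p,
                   fdr = adjustBH(p), direction = "ns",
                   mean_abundance = rowMeans(cpm), flagged = flagged)
  classifyDirection(res, thresholds)
}
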