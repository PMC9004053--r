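#' Pearson co-expression filter
#'
#' Sample Pearson correlation with a two-sided p-value from the t-transform
#' with n-2 degrees of freedom. Constant vectors leave r undefined; they are
#' reported as r = 0, p = 1 and flagged.
#'
#' @param x,y equal-length numeric vectors, n >= 3, finite.
#' @return list with \code{r}, \code{p} and \code{flagged}.
#' @examples
#' pearsonFilter(c(1, 2, 3), c(2, 4, 6))$r  # 1
#' @export
pearsonFilter <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3L, "need n >= 3")
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  n <- length(x)
  if (var(x) == 0 || var(y) == 0) {
    return(list(r = 0, p = 1, flagged = TRUE))
  }
  r <- cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, flagged = FALSE)
}

#' Classify a direction triple into a ceRNA pattern
#'
#' The sponge-consistent signatures: (up, down, up) is \code{up-down-up}
#' (circRNA up, shared miRNA down, mRNA up) and (down, up, down) is
#' \code{down-up-down}; every other combination is no pattern.
#'
#' @param circ_dir,mirna_dir,mrna_dir direction labels
#'   (\code{up}/\code{down}/\code{ns}).
#' @return \code{"up-down-up"}, \code{"down-up-down"} or \code{NA}.
#' @export
classifyPattern <- function(circ_dir, mirna_dir, mrna_dir) {
  dirs <- c(circ_dir, mirna_dir, mrna_dir)
  .assert(all(dirs %in% c("up", "down", "ns")),
          "directions must be up, down or ns")
  if (circ_dir == "up" && mirna_dir == "down" && mrna_dir == "up") {
    "up-down-up"
  } else if (circ_dir == "down" && mirna_dir == "up" && mrna_dir == "down") {
    "down-up-down"
  } else {
    NA_character_
  }
}

#' Assemble circRNA-miRNA-mRNA ceRNA triplets
#'
#' Emits exactly the triplets where (a) the circRNA and mRNA are
#' differentially expressed in the same direction and the miRNA in the
#' opposite direction, (b) the miRNA has at least one seed site (of at least
#' the configured strength) on both the circRNA and the mRNA and the pair
#' shares at least \code{min_shared_mirnas} miRNAs, and (c) the Pearson
#' correlation between the circRNA and mRNA abundance profiles satisfies the
#' configured sign and p-value threshold. Output is sorted by (comparison,
#' circ_id, mirna_id, mrna_id); per-miRNA interaction counts are attached as
#' \code{metadata()$mirna_interactions}.
#'
#' @param de_circ,de_mirna,de_mrna DE tables from \code{\link{testTwoGroup}}
#'   (or any table with \code{feature_id} and \code{direction}).
#' @param target_map a \linkS4class{TargetMap}.
#' @param circ_expr,mrna_expr \linkS4class{ExpressionMatrix} objects
#'   (normalized layers) covering all DE features of their layer, same
#'   samples. Correlations are computed on log2(abundance + pseudocount),
#'   the standard co-expression scale.
#' @param thresholds a \code{\link{thresholdConfig}}.
#' @param comparison label recorded per triplet, e.g. \code{"A_vs_B"}.
#' @return \link[S4Vectors]{DataFrame}, one row per triplet: ids, pattern,
#'   site counts on circRNA and mRNA, number of shared miRNAs of the pair,
#'   Pearson r and p, comparison.
#' @export
assembleTriplets <- function(de_circ, de_mirna, de_mrna, target_map,
                             circ_expr, mrna_expr,
                             thresholds = thresholdConfig(),
                             comparison = "A_vs_B") {
  .assert(is(target_map, "TargetMap"), "target_map must be a TargetMap")
  .assert(is(circ_expr, "ExpressionMatrix") && is(mrna_expr, "ExpressionMatrix"),
          "expression inputs must be ExpressionMatrix objects")
  .assert(setequal(colnames(circ_expr), colnames(mrna_expr)),
          "circ and mRNA expression must cover the same samples")
  cm <- log2(exprValues(circ_expr) + thresholds@pseudocount)
  mmx <- log2(exprValues(mrna_expr)[, colnames(circ_expr), drop = FALSE] +
                thresholds@pseudocount)
  .assert(all(de_circ$feature_id[de_circ$direction != "ns"] %in% rownames(cm)),
          "circ expression must cover all DE circRNAs")
  .assert(all(de_mrna$feature_id[de_mrna$direction != "ns"] %in% rownames(mmx)),
          "mRNA expression must cover all DE mRNAs")

  dir_of <- function(de) setNames(de$direction, de$feature_id)
  dc <- dir_of(de_circ); dmi <- dir_of(de_mirna); dmr <- dir_of(de_mrna)

  sites <- as.data.frame(mreSites(target_map))
  sites <- sites[.SITE_RANK[sites$site_type] >=
                   .SITE_RANK[thresholds@min_site_type], , drop = FALSE]
  # site counts per (miRNA, target)
  cnt <- stats::aggregate(list(n = rep(1L, nrow(sites))),
                          by = list(mirna_id = sites$mirna_id,
                                    target_id = sites$target_id),
                          FUN = sum)
  nsite <- setNames(cnt$n, paste(cnt$mirna_id, cnt$target_id))

  circ_cand <- .csort(names(dc)[dc %in% c("up", "down")])
  pair_cache <- new.env(parent = emptyenv())
  pearOf <- function(ci, mi) {
    key <- paste(ci, mi)
    got <- pair_cache[[key]]
    if (!is.null(got)) return(got)
    res <- pearsonFilter(cm[ci, ], mmx[mi, ])
    pair_cache[[key]] <- res
    res
  }
  shared_cache <- new.env(parent = emptyenv())
  nShared <- function(ci, mi) {
    key <- paste(ci, mi)
    got <- shared_cache[[key]]
    if (!is.null(got)) return(got)
    on_c <- unique(sites$mirna_id[sites$target_id == ci])
    on_m <- unique(sites$mirna_id[sites$target_id == mi])
    n <- length(intersect(on_c, on_m))
    shared_cache[[key]] <- n
    n
  }

  rows <- list()
  for (ci in circ_cand) {
    d <- dc[[ci]]
    opp <- if (d == "up") "down" else "up"
    mirs <- .csort(unique(sites$mirna_id[sites$target_id == ci]))
    mirs <- mirs[!is.na(dmi[mirs]) & dmi[mirs] == opp]
    for (mir in mirs) {
      tgts <- .csort(unique(sites$target_id[sites$mirna_id == mir &
                                              sites$target_id != ci]))
      tgts <- tgts[tgts %in% names(dmr) & dmr[tgts] == d]
      for (mr in tgts) {
        if (nShared(ci, mr) < thresholds@min_shared_mirnas) next
        pf <- pearOf(ci, mr)
        if (thresholds@corr_sign == "positive" && pf$r <= 0) next
        if (pf$p >= thresholds@corr_p_threshold) next
        rows[[length(rows) + 1L]] <- DataFrame(
          comparison = comparison, circ_id = ci, mirna_id = mir,
          mrna_id = mr,
          pattern = if (d == "up") "up-down-up" else "down-up-down",
          sites_on_circ = nsite[[paste(mir, ci)]],
          sites_on_mrna = nsite[[paste(mir, mr)]],
          shared_mirnas = nShared(ci, mr),
          pearson_r = pf$r, pearson_p = pf$p)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else DataFrame(
    comparison = character(0), circ_id = character(0),
    mirna_id = character(0), mrna_id = character(0), pattern = character(0),
    sites_on_circ = integer(0), sites_on_mrna = integer(0),
    shared_mirnas = integer(0), pearson_r = numeric(0),
    pearson_p = numeric(0))
  out <- out[.corder(out$comparison, out$circ_id, out$mirna_id, out$mrna_id), ,
             drop = FALSE]
  tab <- table(out$mirna_id)
  metadata(out)$mirna_interactions <- setNames(as.integer(tab), names(tab))
  out
}

#' circRNA / host-transcript co-expression
#'
#' For every consensus circRNA whose host transcript is quantified in the
#' mRNA matrix, reports the Pearson correlation between the circRNA and its
#' linear counterpart, whether both are differentially expressed, and a flag
#' for significantly positive pairs (r > 0, p below the correlation
#' threshold). circRNAs without a host are omitted.
#'
#' @param consensus consensus GRanges with \code{host_transcript} (see
#'   \code{\link{mapToHost}}).
#' @param circ_expr,mrna_expr \linkS4class{ExpressionMatrix} objects, same
#'   samples.
#' @param de_circ,de_mrna DE tables for the two layers.
#' @param thresholds a \code{\link{thresholdConfig}}.
#' @return \link[S4Vectors]{DataFrame}: \code{circ_id},
#'   \code{host_transcript}, \code{r}, \code{p}, \code{both_de},
#'   \code{positive_corr}.
#' @export
hostCorrelation <- function(consensus, circ_expr, mrna_expr, de_circ,
                            de_mrna, thresholds = thresholdConfig()) {
  host <- mcols(consensus)$host_transcript
  .assert(!is.null(host), "consensus carries no host_transcript; see mapToHost()")
  cm <- log2(exprValues(circ_expr) + thresholds@pseudocount)
  mmx <- log2(exprValues(mrna_expr)[, colnames(circ_expr), drop = FALSE] +
                thresholds@pseudocount)
  dc <- setNames(de_circ$direction, de_circ$feature_id)
  dm <- setNames(de_mrna$direction, de_mrna$feature_id)
  ids <- mcols(consensus)$circ_id
  keep <- which(!is.na(host) & host %in% rownames(mmx) & ids %in% rownames(cm))
  rows <- lapply(keep, function(i) {
    pf <- pearsonFilter(cm[ids[i], ], mmx[host[i], ])
    DataFrame(circ_id = ids[i], host_transcript = host[i],
              r = pf$r, p = pf$p,
              both_de = isTRUE(dc[ids[i]] != "ns") && isTRUE(dm[host[i]] != "ns"),
              positive_corr = pf$r > 0 & pf$p < thresholds@corr_p_threshold)
  })
  out <- if (length(rows)) do.call(rbind, rows) else DataFrame(
    circ_id = character(0), host_transcript = character(0), r = numeric(0),
    p = numeric(0), both_de = logical(0), positive_corr = logical(0))
  out[.corder(out$circ_id), , drop = FALSE]
}
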