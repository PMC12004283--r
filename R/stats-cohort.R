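# The nine contrast columns of the results table, in reporting order.
contrastNames <- function() {
  c("AcqVsStr.HC", "AcqVsStr.UWS", "AcqVsStr.MCS",
    "HCvsMCS.Acq", "HCvsMCS.Str",
    "HCvsUWS.Acq", "HCvsUWS.Str",
    "HCvsDOC.Acq", "HCvsDOC.Str")
}

# Pair a subject's stimulus windows across conditions by protocol position:
# the k-th acquaintance window is paired with the k-th stranger window.
pairByPosition <- function(df) {
  acq <- df[df$condition == "acquaintance", ]
  str <- df[df$condition == "stranger", ]
  acq <- acq[order(acq$windowId), ]
  str <- str[order(str$windowId), ]
  k <- min(nrow(acq), nrow(str))
  if (k == 0L) return(NULL)
  data.frame(x = acq$value[seq_len(k)], y = str$value[seq_len(k)])
}

#' Run all group/condition comparisons on a normalized cohort table
#'
#' Computes the nine contrasts of the standard results layout for each of the
#' twelve HRV measures: within-group acquaintance-vs-stranger comparisons
#' (Wilcoxon signed-rank, windows paired by protocol position) for HC, UWS
#' and MCS, and between-group comparisons (Wilcoxon rank-sum) of HC against
#' MCS, UWS and the combined DOC group, separately per condition. The
#' sampling unit is the normalized window-level value pooled across a group's
#' subjects (e.g. 17 HC x 6 acquaintance windows = 102 values); set
#' `unit = "subject"` to use per-subject condition means instead.
#' p-values are Bonferroni-corrected within each contrast across the
#' `mFamily` measures; the effect size is \code{r = |Z| / sqrt(n1 + n2)}.
#'
#' @param cohortResult output of [runCohort()] (uses its `normalized` or
#'   `conditionMeans` table according to `unit`).
#' @param unit sampling unit: `"window"` (default) or `"subject"`.
#' @param mFamily Bonferroni family size (default 12, the feature family).
#' @param alpha significance level applied to corrected p-values.
#' @return data.frame, one row per contrast x feature: `contrast`, `feature`,
#'   `n1`, `n2`, `mdn1`, `mdn2`, `Z`, `p_raw`, `p_corrected`, `r`,
#'   `significant`, `method`, `note`.
#' @export
compareCohort <- function(cohortResult, unit = c("window", "subject"),
                          mFamily = 12L, alpha = 0.05) {
  unit <- match.arg(unit)
  tab <- if (unit == "window") cohortResult$normalized
         else cohortResult$conditionMeans
  feats <- hrvFeatureNames()
  rows <- list()

  runPaired <- function(df, contrast, feature) {
    pairs <- NULL
    if (!is.null(df) && nrow(df)) {
      ps <- lapply(split(df, df$subject_id), pairByPosition)
      ps <- ps[!vapply(ps, is.null, logical(1))]
      if (length(ps)) pairs <- do.call(rbind, ps)
    }
    if (is.null(pairs) || nrow(pairs) < 6L)
      return(resultRow(contrast, feature, note = "insufficient-pairs"))
    res <- tryCatch(pairedWilcoxon(pairs$x, pairs$y),
                    hrvDataError = function(e) NULL)
    if (is.null(res))
      return(resultRow(contrast, feature, note = "insufficient-pairs"))
    resultRow(contrast, feature, n1 = nrow(pairs), n2 = nrow(pairs),
              mdn1 = stats::median(pairs$x), mdn2 = stats::median(pairs$y),
              Z = res$Z, p = res$p, method = res$method)
  }
  runRanksum <- function(a, b, contrast, feature) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 4L || length(b) < 4L)
      return(resultRow(contrast, feature, note = "insufficient-samples"))
    res <- ranksumWilcoxon(a, b)
    resultRow(contrast, feature, n1 = length(a), n2 = length(b),
              mdn1 = stats::median(a), mdn2 = stats::median(b),
              Z = res$Z, p = res$p, method = res$method)
  }
  resultRow <- function(contrast, feature, n1 = NA_integer_,
                        n2 = NA_integer_, mdn1 = NA_real_, mdn2 = NA_real_,
                        Z = NA_real_, p = NA_real_, method = NA_character_,
                        note = NA_character_) {
    data.frame(contrast = contrast, feature = feature, n1 = n1, n2 = n2,
               mdn1 = mdn1, mdn2 = mdn2, Z = Z, p_raw = p,
               p_corrected = NA_real_, r = NA_real_, significant = NA,
               method = method, note = note, stringsAsFactors = FALSE)
  }

  for (f in feats) {
    ft <- tab[tab$feature == f, , drop = FALSE]
    for (g in GROUPS) {
      contrast <- sprintf("AcqVsStr.%s", g)
      gt <- ft[ft$group == g, , drop = FALSE]
      rows[[paste(contrast, f)]] <- if (unit == "window") {
        runPaired(gt, contrast, f)
      } else {
        acq <- gt$value[gt$condition == "acquaintance"]
        str <- gt$value[gt$condition == "stranger"]
        k <- min(length(acq), length(str))
        if (k >= 6L) {
          res <- pairedWilcoxon(acq[seq_len(k)], str[seq_len(k)])
          resultRow(contrast, f, k, k, stats::median(acq), stats::median(str),
                    res$Z, res$p, method = res$method)
        } else resultRow(contrast, f, note = "insufficient-pairs")
      }
    }
    condMap <- c(acquaintance = "Acq", stranger = "Str")
    for (condName in names(condMap)) {
      cond <- condMap[[condName]]
      ct <- ft[ft$condition == condName, , drop = FALSE]
      hc <- ct$value[ct$group == "HC"]
      mcs <- ct$value[ct$group == "MCS"]
      uws <- ct$value[ct$group == "UWS"]
      rows[[paste0("HCvsMCS.", cond, f)]] <-
        runRanksum(hc, mcs, sprintf("HCvsMCS.%s", cond), f)
      rows[[paste0("HCvsUWS.", cond, f)]] <-
        runRanksum(hc, uws, sprintf("HCvsUWS.%s", cond), f)
      rows[[paste0("HCvsDOC.", cond, f)]] <-
        runRanksum(hc, c(mcs, uws), sprintf("HCvsDOC.%s", cond), f)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (ct in unique(out$contrast)) {
    sel <- out$contrast == ct
    out$p_corrected[sel] <- bonferroni(out$p_raw[sel], m = mFamily)
  }
  ok <- !is.na(out$Z) & !is.na(out$n1)
  out$r[ok] <- abs(out$Z[ok]) / sqrt(out$n1[ok] + out$n2[ok])
  out$significant <- !is.na(out$p_corrected) & out$p_corrected < alpha
  out
}

#' Lay out comparison results as the contrast-by-feature summary matrix
#'
#' 12 rows (the HRV measures, reporting order) by 9 columns (the three
#' within-group condition contrasts and the six between-group contrasts),
#' each cell a significance marker. The full result records remain attached
#' as the `"comparisons"` attribute.
#'
#' @param comparisons output of [compareCohort()] (any subset of contrasts).
#' @param markers length-2 character: marker for significant / not.
#' @return Character matrix with feature rownames and contrast colnames.
#' @export
buildResultsTable <- function(comparisons, markers = c("***", "-")) {
  feats <- hrvFeatureNames()
  cols <- contrastNames()
  m <- matrix(NA_character_, nrow = length(feats), ncol = length(cols),
              dimnames = list(feats, cols))
  if (!is.null(comparisons) && nrow(comparisons)) {
    for (i in seq_len(nrow(comparisons))) {
      f <- comparisons$feature[i]; ct <- comparisons$contrast[i]
      if (f %in% feats && ct %in% cols)
        m[f, ct] <- if (isTRUE(comparisons$significant[i])) markers[1L]
                    else markers[2L]
    }
  }
  attr(m, "comparisons") <- comparisons
  m
}
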