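# Statistical kernel: rank-sum, t, correlation, NB differential
# expression and the DEG/DML/DEsiRNA call wrappers.

test_result <- function(statistic, p_value, method, n_a, n_b,
                        degenerate = FALSE) {
  list(statistic = unname(statistic), p_value = unname(p_value),
       method = method, n_a = n_a, n_b = n_b, degenerate = degenerate)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when n_a + n_b <= 12 and there are no ties;
#' otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param group_a,group_b numeric vectors.
#' @return a test-result list (statistic, p_value, method, n_a, n_b).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  wt <- suppressWarnings(wilcox.test(group_a, group_b,
                                     exact = (n <= 12 && !ties),
                                     correct = TRUE))
  test_result(wt$statistic, wt$p.value,
              if (n <= 12 && !ties) "wilcoxon-exact" else "wilcoxon-normal",
              length(group_a), length(group_b))
}

#' Two-sided Student's t-test (pooled variance)
#'
#' Pooled-variance t with n_a + n_b - 2 degrees of freedom. Degenerate
#' zero-variance input yields p = 1 for equal means and p = 0 (flagged)
#' otherwise. Welch's unequal-variance form is available via `welch`.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @param welch use the Welch form instead of pooled variance.
#' @return a test-result list.
#' @export
students_t_test <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 observations per group")
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(test_result(if (eq) 0 else Inf, if (eq) 1 else 0,
                       "student-t", length(group_a), length(group_b),
                       degenerate = TRUE))
  }
  tt <- t.test(group_a, group_b, var.equal = !welch)
  test_result(tt$statistic, tt$p.value,
              if (welch) "welch-t" else "student-t",
              length(group_a), length(group_b))
}

#' Pearson correlation with two-sided p-value
#'
#' r and the t-transform p-value with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a test-result list (statistic = r).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(test_result(NA_real_, NA_real_, "pearson", length(x), length(y),
                       degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  test_result(unname(ct$estimate), ct$p.value, "pearson",
              length(x), length(y))
}

# median-of-ratios size factors (geometric-mean reference)
size_factors <- function(counts) {
  logs <- log(counts)
  logs[!is.finite(logs)] <- NA
  ref <- rowMeans(logs, na.rm = FALSE)
  ok <- is.finite(ref)
  if (!any(ok)) return(rep(1, ncol(counts)))
  apply(counts, 2, function(cj)
    exp(median(log(cj[ok]) - ref[ok], na.rm = TRUE)))
}

#' Negative-binomial two-group differential test
#'
#' Counts are scaled by median-of-ratios size factors; the log2 fold
#' change is log2((mean_b + 0.5) / (mean_a + 0.5)) on normalized
#' counts; the Wald statistic uses the NB delta-method standard error
#' with the supplied (or method-of-moments, floored at 1e-8) dispersion
#' and a standard-normal reference. Calls follow |log2FC| >= `lfc` and
#' p <= `alpha`.
#'
#' @param counts_a,counts_b integer replicate counts (>= 2 each).
#' @param size_factors_a,size_factors_b per-sample size factors
#'   (default 1).
#' @param dispersion optional NB dispersion (alpha, variance =
#'   mu + alpha mu^2); estimated by method of moments when NULL.
#' @param lfc,alpha call thresholds (defaults 1 and 0.001).
#' @return list(log2fc, p_value, statistic, dispersion, call).
#' @export
nb_differential_test <- function(counts_a, counts_b,
                                 size_factors_a = rep(1, length(counts_a)),
                                 size_factors_b = rep(1, length(counts_b)),
                                 dispersion = NULL, lfc = 1, alpha = 0.001) {
  if (length(counts_a) < 2 || length(counts_b) < 2)
    stop("need at least 2 replicates per group")
  a <- counts_a / size_factors_a; b <- counts_b / size_factors_b
  if (all(a == 0) && all(b == 0))
    return(list(log2fc = 0, p_value = 1, statistic = 0,
                dispersion = NA_real_, call = "ns"))
  ma <- mean(a); mb <- mean(b)
  if (is.null(dispersion)) {
    # per-group method of moments on the NB scale (alpha is shared
    # across groups even when the means differ), df-weighted
    al_a <- if (ma > 0) (var(a) - ma) / ma^2 else 0
    al_b <- if (mb > 0) (var(b) - mb) / mb^2 else 0
    dispersion <- max(((length(a) - 1) * al_a + (length(b) - 1) * al_b) /
                      (length(a) + length(b) - 2), 1e-8)
  }
  log2fc <- log2((mb + 0.5) / (ma + 0.5))
  # delta method on log(mean + 0.5) with the variance evaluated at the
  # pooled mean (null-referenced), which keeps the Wald z calibrated at
  # small replicate numbers: Var(mean) = (mu/n)(1 + alpha mu)
  mu_p <- (ma * length(a) + mb * length(b)) / (length(a) + length(b))
  v0 <- (mu_p / length(a) + mu_p / length(b)) *
        (1 + dispersion * mu_p) / (mu_p + 0.5)^2
  se <- sqrt(v0) / log(2)
  z <- if (se > 0) log2fc / se else 0
  p <- 2 * pnorm(-abs(z))
  call <- "ns"
  if (p <= alpha && log2fc >= lfc) call <- "up"
  if (p <= alpha && log2fc <= -lfc) call <- "down"
  list(log2fc = log2fc, p_value = p, statistic = z,
       dispersion = dispersion, call = call)
}

#' Matrix-level NB differential expression
#'
#' Runs [nb_differential_test()] over all features of a count matrix
#' for one two-group contrast. Per-feature method-of-moments dispersions
#' are stabilized by shrinking towards a mean-dispersion trend fitted
#' across features (lowess on log mean), which makes the Wald test
#' calibrated at small replicate numbers.
#'
#' @param counts feature x sample integer matrix.
#' @param group_a,group_b column indices of the two groups.
#' @param lfc,alpha call thresholds.
#' @param shrink weight of the trend in the shrunk dispersion
#'   (default 0.8).
#' @return data.frame feature_id, base_mean, log2fc, p_value, call.
#' @export
nb_de_matrix <- function(counts, group_a, group_b, lfc = 1, alpha = 0.001,
                         shrink = 0.8) {
  sf <- size_factors(counts[, c(group_a, group_b), drop = FALSE])
  sfa <- sf[seq_along(group_a)]
  sfb <- sf[length(group_a) + seq_along(group_b)]
  na <- counts[, group_a, drop = FALSE] / rep(sfa, each = nrow(counts))
  nb <- counts[, group_b, drop = FALSE] / rep(sfb, each = nrow(counts))
  mu <- rowMeans(cbind(na, nb))
  mua <- rowMeans(na); mub <- rowMeans(nb)
  va <- apply(na, 1, var); vb <- apply(nb, 1, var)
  al_a <- ifelse(mua > 0, (va - mua) / pmax(mua, 1e-8)^2, 0)
  al_b <- ifelse(mub > 0, (vb - mub) / pmax(mub, 1e-8)^2, 0)
  disp_mom <- pmax(((ncol(na) - 1) * al_a + (ncol(nb) - 1) * al_b) /
                   (ncol(na) + ncol(nb) - 2), 1e-8)
  ok <- mu > 0
  disp_trend <- rep(1e-8, nrow(counts))
  if (sum(ok) >= 10) {
    # iter = 0: plain local mean; the robust iterations would downweight
    # the long right tail of the MoM estimates and bias the trend low
    lo <- lowess(log(mu[ok]), disp_mom[ok], f = 0.5, iter = 0)
    disp_trend[ok] <- pmax(approx(lo$x, lo$y, xout = log(mu[ok]),
                                  rule = 2)$y, 1e-8)
  } else disp_trend[ok] <- pmax(mean(disp_mom[ok]), 1e-8)
  disp <- pmax(shrink * disp_trend + (1 - shrink) * disp_mom, 1e-8)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- nb_differential_test(counts[i, group_a], counts[i, group_b],
                              sfa, sfb, dispersion = disp[i],
                              lfc = lfc, alpha = alpha)
    data.frame(log2fc = r$log2fc, p_value = r$p_value, call = r$call,
               stringsAsFactors = FALSE)
  })
  out <- cbind(data.frame(feature_id = rownames(counts),
                          base_mean = mu, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Differential calls across the allopolyploidization contrasts
#'
#' For the three contrasts RAC vs AC, NAC vs RAC and NAC vs AC: DEG
#' mode applies the NB test at |log2FC| >= 1, p <= 0.001 to a count
#' matrix; DML and DEsiRNA modes apply the two-sided pooled-variance
#' t-test at p < 0.05 to per-replicate feature values (methylation
#' percent levels or RPM).
#'
#' @param x for mode "DEG" a `count_matrix`; for "DML"/"DEsiRNA" a
#'   data.frame feature_id, genotype, replicate, value.
#' @param mode one of DEG, DML, DEsiRNA.
#' @param classes optional named character vector feature_id -> class
#'   (e.g. donor/free) for the proportion summaries.
#' @param t_alpha t-test threshold for DML/DEsiRNA (default 0.05).
#' @param deg_lfc,deg_alpha DEG thresholds.
#' @return list(calls = per-feature per-contrast data.frame,
#'   proportions = per-contrast per-class call proportions).
#' @export
call_differential_sets <- function(x, mode = c("DEG", "DML", "DEsiRNA"),
                                   classes = NULL, t_alpha = 0.05,
                                   deg_lfc = 1, deg_alpha = 0.001) {
  mode <- match.arg(mode)
  contrasts <- list(c("AC", "RAC"), c("RAC", "NAC"), c("AC", "NAC"))
  names(contrasts) <- c("RAC_vs_AC", "NAC_vs_RAC", "NAC_vs_AC")
  calls <- list()
  for (cn in names(contrasts)) {
    ga <- contrasts[[cn]][1]; gb <- contrasts[[cn]][2]
    if (mode == "DEG") {
      ia <- which(x$samples$genotype == ga)
      ib <- which(x$samples$genotype == gb)
      if (length(ia) < 2 || length(ib) < 2) {
        warning("contrast ", cn, " skipped: missing replicates"); next
      }
      de <- nb_de_matrix(x$counts, ia, ib, lfc = deg_lfc, alpha = deg_alpha)
      calls[[cn]] <- data.frame(contrast = cn, de, stringsAsFactors = FALSE)
    } else {
      feats <- unique(x$feature_id)
      va <- x[x$genotype == ga, ]; vb <- x[x$genotype == gb, ]
      rows <- lapply(feats, function(fid) {
        a <- va$value[va$feature_id == fid]
        b <- vb$value[vb$feature_id == fid]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2)
          return(data.frame(contrast = cn, feature_id = fid,
                            diff = NA_real_, p_value = NA_real_,
                            call = NA_character_, stringsAsFactors = FALSE))
        tt <- students_t_test(a, b)
        d <- mean(b) - mean(a)
        call <- if (!is.na(tt$p_value) && tt$p_value < t_alpha)
          (if (d > 0) "up" else "down") else "ns"
        data.frame(contrast = cn, feature_id = fid, diff = d,
                   p_value = tt$p_value, call = call,
                   stringsAsFactors = FALSE)
      })
      calls[[cn]] <- do.call(rbind, rows)
    }
  }
  calls <- do.call(rbind, c(calls, make.row.names = FALSE))
  props <- NULL
  if (!is.null(classes) && !is.null(calls) && nrow(calls)) {
    calls$class <- unname(classes[calls$feature_id])
    agg <- stats::aggregate(call ~ contrast + class, data = calls,
      FUN = function(v) mean(v %in% c("up", "down")))
    up <- stats::aggregate(call ~ contrast + class, data = calls,
      FUN = function(v) mean(v == "up"))
    names(agg)[3] <- "prop_called"; names(up)[3] <- "prop_up"
    props <- merge(agg, up)
  }
  list(calls = calls, proportions = props)
}

# significance stars used in the class comparison tables
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
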