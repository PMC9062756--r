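# Clinical association statistics --------------------------------------------
#
# Normality-gated correlation and group-difference tests with FDR control:
# Shapiro-Wilk decides between Pearson and Spearman (and between t-test and
# Mann-Whitney U); partial correlations residualise both variables on the
# covariates (on ranks for the Spearman branch); multiplicity is handled by
# Benjamini-Hochberg step-up adjustment by default.

#' Normality gate via the Shapiro-Wilk test
#'
#' @param values numeric vector, n >= 3.
#' @param alpha gate level; the vector is called nonnormal when the
#'   Shapiro-Wilk p-value is below `alpha`.
#' @return "normal" or "nonnormal".  Constant input returns "nonnormal"
#'   with a warning.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop_invalid("need at least 3 values")
  if (sd(values) == 0) {
    warning("degenerate input: constant vector treated as nonnormal")
    return("nonnormal")
  }
  p <- shapiro.test(values)$p.value
  if (p < alpha) "nonnormal" else "normal"
}

# exact permutation p-value for Spearman's rho at small n (full enumeration)
spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- all_permutations(n)
  stats <- abs(apply(perms, 1, function(pm) cor(rx, ry[pm])))
  mean(stats >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

spearman_p <- function(x, y) {
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  if (n >= 10) {
    if (abs(rho) >= 1) return(list(rho = rho, p = 0))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2))
  } else {
    list(rho = rho, p = spearman_exact_p(x, y))
  }
}

residualise <- function(v, covariates) {
  stats::lm.fit(cbind(1, covariates), v)$residuals
}

#' Normality-gated (partial) correlation
#'
#' Pearson when both variables pass the Shapiro-Wilk gate at `gate_alpha`,
#' Spearman otherwise.  With covariates, both variables are residualised on
#' the covariates first (after rank transformation in the Spearman branch)
#' and the gate is applied to the residuals; degrees of freedom are reduced
#' by the number of covariates.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param covariates optional numeric matrix (same rows) to partial out.
#' @param gate_alpha level of the normality gate.
#' @param xname,yname variable names recorded in the result.
#' @return one-row data frame: `x`, `y`, `method`, `estimate`, `p_value`,
#'   `n`, `covariates`.
#' @export
correlate <- function(x, y, covariates = NULL, gate_alpha = 0.05,
                      xname = "x", yname = "y") {
  if (length(x) != length(y)) stop_invalid("x and y differ in length")
  if (length(x) < 4) stop_invalid("need at least 4 paired observations")
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (ncol(covariates) == 0) covariates <- NULL
  }
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(x))
      stop_invalid("covariates must have one row per observation")
    keep <- keep & apply(is.finite(covariates), 1, all)
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) stop_data("zero-variance variable")
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)

  if (is.null(covariates)) {
    gate <- normality_gate(x, gate_alpha) == "normal" &&
      normality_gate(y, gate_alpha) == "normal"
    if (gate) {
      ct <- cor.test(x, y, method = "pearson")
      method <- "pearson"; est <- unname(ct$estimate); p <- ct$p.value
    } else {
      sp <- spearman_p(x, y)
      method <- "spearman"; est <- sp$rho; p <- sp$p
    }
  } else {
    rx_raw <- residualise(x, covariates)
    ry_raw <- residualise(y, covariates)
    gate <- normality_gate(rx_raw, gate_alpha) == "normal" &&
      normality_gate(ry_raw, gate_alpha) == "normal"
    if (gate) {
      rx <- rx_raw; ry <- ry_raw; method <- "partial_pearson"
    } else {
      rx <- residualise(rank(x), apply(covariates, 2, rank))
      ry <- residualise(rank(y), apply(covariates, 2, rank))
      method <- "partial_spearman"
    }
    est <- cor(rx, ry)
    df <- n - 2L - n_cov
    if (df < 1) stop_invalid("too few observations for the covariate set")
    tt <- est * sqrt(df / max(1 - est^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  data.frame(x = xname, y = yname, method = method,
             estimate = max(-1, min(1, est)), p_value = min(1, p), n = n,
             covariates = if (n_cov) paste(colnames(covariates),
                                           collapse = ",") else "",
             stringsAsFactors = FALSE)
}

#' Normality-gated group comparison
#'
#' Continuous variables: Welch t-test when both groups pass the
#' Shapiro-Wilk gate, Mann-Whitney U otherwise; group summaries report
#' mean (SD) or median (IQR) accordingly.  Nominal variables: chi-square
#' test on the contingency table.
#'
#' @param values numeric (continuous) or character/factor (nominal) vector.
#' @param labels two-level group vector.
#' @param type "continuous" or "nominal" (guessed from `values` by default).
#' @param gate_alpha level of the normality gate.
#' @param varname variable name recorded in the result.
#' @return one-row data frame: `variable`, `test`, `statistic`, `p_value`,
#'   `summary_g1`, `summary_g2`, `n`.
#' @export
group_compare <- function(values, labels, type = NULL, gate_alpha = 0.05,
                          varname = "value") {
  groups <- unique(labels)
  if (length(groups) != 2) stop_invalid("exactly two groups required")
  if (any(table(labels) == 0)) stop_invalid("one group is empty")
  if (is.null(type))
    type <- if (is.numeric(values)) "continuous" else "nominal"

  if (type == "nominal") {
    tab <- table(values, labels)
    ct <- suppressWarnings(chisq.test(tab))
    return(data.frame(variable = varname, test = "chi_square",
                      statistic = unname(ct$statistic),
                      p_value = ct$p.value,
                      summary_g1 = paste(tab[, 1], collapse = "/"),
                      summary_g2 = paste(tab[, 2], collapse = "/"),
                      n = length(values), stringsAsFactors = FALSE))
  }

  v1 <- values[labels == groups[1]]
  v2 <- values[labels == groups[2]]
  if (length(v1) < 2 || length(v2) < 2)
    stop_invalid("each group needs at least 2 observations")
  normal <- suppressWarnings(
    normality_gate(v1, gate_alpha) == "normal" &&
      normality_gate(v2, gate_alpha) == "normal")
  if (normal) {
    tt <- t.test(v1, v2)
    data.frame(variable = varname, test = "t",
               statistic = unname(tt$statistic), p_value = tt$p.value,
               summary_g1 = sprintf("%.2f (%.2f)", mean(v1), sd(v1)),
               summary_g2 = sprintf("%.2f (%.2f)", mean(v2), sd(v2)),
               n = length(values), stringsAsFactors = FALSE)
  } else {
    wt <- suppressWarnings(wilcox.test(v1, v2))
    data.frame(variable = varname, test = "mann_whitney",
               statistic = unname(wt$statistic), p_value = wt$p.value,
               summary_g1 = sprintf("%.2f (%.2f)", median(v1), IQR(v1)),
               summary_g2 = sprintf("%.2f (%.2f)", median(v2), IQR(v2)),
               n = length(values), stringsAsFactors = FALSE)
  }
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjustment by default; "BY" applies the
#' Benjamini-Yekutieli variant and "qvalue" the Storey estimator with a
#' fixed lambda of 0.5 (the q-value route some toolboxes default to).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param method "BH" (default), "BY", or "qvalue".
#' @return adjusted values (q-values), same length and order.
#' @export
fdr_adjust <- function(p_values, method = c("BH", "BY", "qvalue")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_invalid("p-values must lie in [0, 1]")
  if (method == "qvalue") {
    pi0 <- min(1, mean(p_values > 0.5) / 0.5)
    if (pi0 <= 0) pi0 <- 1 / length(p_values)
    return(pmin(1, pi0 * p.adjust(p_values, "BH")))
  }
  p.adjust(p_values, method)
}

#' Tidy association table with family-wise FDR adjustment
#'
#' Runs [correlate()] for every (x, y) variable pair in `data`, then
#' adjusts the whole family of p-values with [fdr_adjust()].
#'
#' @param data data frame holding all variables.
#' @param x_vars,y_vars column names to correlate (all pairs).
#' @param covariates optional column names to partial out.
#' @param gate_alpha normality-gate level.
#' @param fdr_method passed to [fdr_adjust()].
#' @return data frame, one row per pair, with a `q_value` column.
#' @export
association_table <- function(data, x_vars, y_vars, covariates = NULL,
                              gate_alpha = 0.05, fdr_method = "BH") {
  cov_mat <- if (length(covariates))
    as.matrix(data[, covariates, drop = FALSE]) else NULL
  rows <- list()
  for (xv in x_vars) for (yv in y_vars) {
    if (xv == yv) next
    rows[[length(rows) + 1L]] <- correlate(
      data[[xv]], data[[yv]], covariates = cov_mat,
      gate_alpha = gate_alpha, xname = xv, yname = yv)
  }
  out <- do.call(rbind, rows)
  out$q_value <- if (nrow(out) > 1) fdr_adjust(out$p_value, fdr_method)
  else out$p_value
  out
}
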