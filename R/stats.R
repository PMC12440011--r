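#' Group summary: mean, SEM, n
#'
#' SEM uses the sample standard deviation (n-1 denominator) divided by
#' sqrt(n). With a single observation the SEM is undefined and flagged.
#'
#' @param x numeric vector of per-organoid (or per-well) values
#' @return list with `mean`, `sd`, `sem`, `n` and `sem_defined`
#' @export
mean_sem <- function(x) {
  if (length(x) == 0) stop("empty group")
  n <- length(x)
  s <- if (n > 1) sd(x) else NA_real_
  list(mean = mean(x), sd = s,
       sem = if (n > 1) s / sqrt(n) else NA_real_,
       n = n, sem_defined = n > 1)
}

#' Per-condition summaries of grouped measurements
#'
#' @param groups named list of numeric vectors (condition -> values)
#' @return data.frame with one row per condition (condition, mean, sem, n)
#' @export
group_summary <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  do.call(rbind, lapply(names(groups), function(g) {
    s <- mean_sem(groups[[g]])
    data.frame(condition = g, mean = s$mean, sem = s$sem, n = s$n,
               stringsAsFactors = FALSE)
  }))
}

#' One-way fixed-effects ANOVA
#'
#' Classical between/within decomposition with an F test on
#' (k-1, N-k) degrees of freedom, fitted via [stats::aov()]. The pooled
#' within-group mean square (MSE) is retained as the error term for
#' Fisher's LSD comparisons.
#'
#' @param groups named list of numeric vectors, one per condition; at least
#'   two groups with at least two values each
#' @return object of class `anova_result`: `F`, `p`, `df_between`,
#'   `df_within`, `mse`, plus the group means and sizes
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group needs n >= 2")
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), ns), levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  res <- list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
              df_between = tab[1, "Df"], df_within = tab[2, "Df"],
              mse = tab[2, "Mean Sq"],
              means = vapply(groups, mean, numeric(1)), n = ns,
              groups = names(groups))
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g (MSE = %.4g)\n",
              x$df_between, x$df_within, x$F, x$p, x$mse))
  invisible(x)
}

#' Fisher's LSD pairwise comparisons
#'
#' Uncorrected pairwise t tests using the ANOVA pooled error term:
#' t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j)), two-sided p on the
#' within-group degrees of freedom. No multiplicity correction is applied.
#'
#' @param groups the same named list passed to [one_way_anova()]
#' @param anova the corresponding [one_way_anova()] result
#' @return symmetric matrix of two-sided p values (diagonal NA)
#' @export
fisher_lsd <- function(groups, anova) {
  stopifnot(inherits(anova, "anova_result"))
  if (!identical(sort(names(groups)), sort(anova$groups)))
    stop("groups do not match the ANOVA result")
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      gi <- names(groups)[i]; gj <- names(groups)[j]
      tij <- (anova$means[[gi]] - anova$means[[gj]]) /
        sqrt(anova$mse * (1 / anova$n[[gi]] + 1 / anova$n[[gj]]))
      p[i, j] <- p[j, i] <- 2 * pt(-abs(tij), df = anova$df_within)
    }
  }
  p
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' dCt = mean Ct(target) - mean Ct(housekeeping) per condition;
#' ddCt = dCt(treated) - dCt(control); fold change = 2^-ddCt.
#'
#' @param ct data.frame with columns `condition`, `gene`, `ct` (Ct > 0)
#' @param target target gene name
#' @param housekeeping housekeeping gene name (e.g. beta-actin)
#' @param control control condition label
#' @param treated treated condition label
#' @return list with `fold_change`, `ddct` and the per-condition `dct`
#' @export
ddct_fold_change <- function(ct, target, housekeeping, control, treated) {
  stopifnot(all(c("condition", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be > 0")
  dct_for <- function(cond) {
    tgt <- ct$ct[ct$condition == cond & ct$gene == target]
    hk <- ct$ct[ct$condition == cond & ct$gene == housekeeping]
    if (length(tgt) == 0 || length(hk) == 0)
      stop(sprintf("condition '%s' missing target or housekeeping measurements", cond))
    mean(tgt) - mean(hk)
  }
  dct <- c(control = dct_for(control), treated = dct_for(treated))
  ddct <- dct[["treated"]] - dct[["control"]]
  list(fold_change = 2^(-ddct), ddct = ddct, dct = dct)
}

#' Fold change of group means relative to a control condition
#'
#' @param groups named list of numeric vectors
#' @param control control condition label
#' @return named numeric vector: mean(condition) / mean(control)
#' @export
fold_change <- function(groups, control) {
  if (!control %in% names(groups)) stop("control condition not found")
  m0 <- mean(groups[[control]])
  if (m0 == 0) stop("control mean is zero")
  vapply(groups, function(x) mean(x) / m0, numeric(1))
}
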