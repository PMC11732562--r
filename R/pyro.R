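#' Percent methylation from bisulfite C/T counts
#'
#' `100 * nC / (nC + nT)`: the fraction of reads in which a CpG cytosine
#' survived bisulfite conversion (i.e. was methylated), as a percentage.
#'
#' @param nC,nT Cytosine and thymine read counts per site (vectorised).
#' @return Percentages in `[0, 100]`.
#' @export
percent_methylation <- function(nC, nT) {
  if (any(nC < 0) || any(nT < 0)) {
    .stopf("percent_methylation: counts must be >= 0")
  }
  tot <- nC + nT
  if (any(tot == 0)) {
    .stopf("percent_methylation: site with no coverage (nC + nT == 0)")
  }
  100 * nC / tot
}

#' Bisulfite conversion quality control
#'
#' Non-CpG cytosines are not methylated in mammalian somatic tissue, so any
#' unconverted signal there measures conversion failure. Efficiency is
#' pooled over control sites; a sample failing the minimum is flagged for
#' exclusion from downstream tests.
#'
#' @param controls data.frame with `converted` and `unconverted` counts per
#'   control cytosine (at least one row), or two vectors via `unconverted`.
#' @param unconverted Optional vector when `controls` is given as the
#'   converted counts.
#' @param min_efficiency Pass threshold on pooled efficiency (default 0.95).
#' @return List: `pass` (logical) and `efficiency` in `[0, 1]`.
#' @export
conversion_qc <- function(controls, unconverted = NULL,
                          min_efficiency = 0.95) {
  if (is.data.frame(controls)) {
    conv <- controls$converted; unconv <- controls$unconverted
  } else {
    conv <- controls; unconv <- unconverted
  }
  if (length(conv) < 1L || is.null(unconv)) {
    .stopf("conversion_qc: need converted/unconverted counts for >= 1 control cytosine")
  }
  eff <- sum(conv) / (sum(conv) + sum(unconv))
  list(pass = eff >= min_efficiency, efficiency = eff)
}

#' Balanced two-way ANOVA of percent methylation
#'
#' Fixed-effects two-way ANOVA with interaction for a
#' condition x CpG-site layout with equal replication per cell — the
#' design used to test an overall exercise effect across the CpGs of a
#' promoter. Unbalanced designs are rejected (the balanced decomposition
#' is the only one implemented). When a factor's sum of squares is zero
#' (e.g. all cells constant) its p-value is reported as 1 by convention.
#'
#' @param data data.frame with columns `condition`, `site`, `percent`
#'   (one row per replicate measurement).
#' @param transform `"none"` (default; percentages analysed untransformed)
#'   or `"asin_sqrt"` (variance-stabilising arcsine-square-root of the
#'   proportion).
#' @return data.frame of class `"anova_table"` with rows condition, site,
#'   condition:site, residual and columns `term, ss, df, ms, f, p`;
#'   attribute `ss_total` carries the total sum of squares.
#' @export
two_way_anova <- function(data, transform = c("none", "asin_sqrt")) {
  transform <- match.arg(transform)
  req <- c("condition", "site", "percent")
  if (!all(req %in% names(data))) {
    .stopf("two_way_anova: 'data' needs columns %s", paste(req, collapse = ", "))
  }
  tab <- table(data$condition, data$site)
  if (length(unique(as.vector(tab))) != 1L) {
    .stopf("two_way_anova: unbalanced design (unequal replicates per cell); only the balanced decomposition is implemented")
  }
  if (tab[1L] < 2L) {
    .stopf("two_way_anova: need >= 2 replicates per cell")
  }
  y <- data$percent
  if (transform == "asin_sqrt") y <- asin(sqrt(y / 100))
  d <- data.frame(y = y, condition = factor(data$condition),
                  site = factor(data$site))
  fit <- stats::aov(y ~ condition * site, data = d)
  s <- summary(fit)[[1L]]
  terms <- trimws(rownames(s))
  ss <- s[["Sum Sq"]]; df <- s[["Df"]]
  out <- data.frame(
    term = c(terms[match(c("condition", "site", "condition:site"), terms)],
             "residual"),
    ss = c(ss[match(c("condition", "site", "condition:site"), terms)],
           ss[length(ss)]),
    df = c(df[match(c("condition", "site", "condition:site"), terms)],
           df[length(df)]),
    stringsAsFactors = FALSE)
  out$ms <- out$ss / out$df
  out$f <- c(out$ms[1:3] / out$ms[4L], NA)
  out$p <- c(stats::pf(out$f[1:3], out$df[1:3], out$df[4L],
                       lower.tail = FALSE), NA)
  out$p[1:3][out$ss[1:3] <= 1e-12] <- 1
  out$p[1:3][is.nan(out$f[1:3]) | is.na(out$p[1:3])] <- 1
  attr(out, "ss_total") <- sum(out$ss)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Per-CpG condition tests
#'
#' Two-sided two-sample (Welch) t-test of the condition effect within each
#' CpG site, unadjusted by default — mirroring per-site significance stars
#' on a methylation bar plot. Bonferroni correction is available behind the
#' `adjust` flag.
#'
#' @inheritParams two_way_anova
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame: `site, mean_sedentary, mean_trained, delta, p_value`
#'   sorted by site.
#' @export
per_cpg_tests <- function(data, adjust = c("none", "bonferroni"),
                          transform = c("none", "asin_sqrt")) {
  adjust <- match.arg(adjust)
  transform <- match.arg(transform)
  y <- data$percent
  if (transform == "asin_sqrt") y <- asin(sqrt(y / 100))
  sites <- sort(unique(data$site))
  rows <- lapply(sites, function(s) {
    sel <- data$site == s
    a <- y[sel & data$condition == "trained"]
    b <- y[sel & data$condition == "sedentary"]
    if (length(a) < 2L || length(b) < 2L) {
      .stopf("per_cpg_tests: site '%s' has fewer than 2 replicates per condition", s)
    }
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
    data.frame(site = s,
               mean_sedentary = mean(data$percent[sel & data$condition == "sedentary"]),
               mean_trained = mean(data$percent[sel & data$condition == "trained"]),
               delta = mean(data$percent[sel & data$condition == "trained"]) -
                 mean(data$percent[sel & data$condition == "sedentary"]),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") {
    out$p_value <- pmin(1, out$p_value * nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Per-site summary (mean and SEM per condition)
#'
#' @inheritParams two_way_anova
#' @return data.frame with one row per condition x site:
#'   `condition, site, n, mean, sem`.
#' @export
pyro_summary <- function(data) {
  agg <- stats::aggregate(percent ~ condition + site, data = data,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sem = stats::sd(v) / sqrt(length(v))))
  out <- data.frame(condition = agg$condition, site = agg$site,
                    n = agg$percent[, "n"], mean = agg$percent[, "mean"],
                    sem = agg$percent[, "sem"], stringsAsFactors = FALSE)
  out[order(out$site, out$condition), ]
}
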