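#' Normality-gated statistical reports
#'
#' The statistics layer mirrors the study design: every comparison first
#' gates on Shapiro-Wilk normality (level `gate_level`, default 0.05) and
#' then runs either the parametric test or its rank-based counterpart.
#'
#' @name gated_tests
NULL

.shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

.group_summary <- function(values, groups) {
  do.call(rbind, lapply(split(values, groups), function(v) {
    n <- length(v)
    se <- stats::sd(v) / sqrt(n)
    data.frame(n = n, mean = mean(v), sd = stats::sd(v),
               ci_lo = mean(v) - stats::qt(0.975, n - 1) * se,
               ci_hi = mean(v) + stats::qt(0.975, n - 1) * se)
  }))
}

.cbt_test <- function(test_name, statistic, p_value, gate, summary = NULL,
                      posthoc = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), gate = gate, summary = summary,
                 posthoc = posthoc),
            class = "cbt_test")
}

#' @export
print.cbt_test <- function(x, ...) {
  cat("<cbt_test> ", x$test_name, ": statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Within-group comparison of the four axial areas
#'
#' Repeated-measures comparison of medial/anterior/lateral/posterior values
#' over subjects of one group: Shapiro-Wilk on the two-way residuals selects
#' either repeated-measures ANOVA (balanced block `value ~ area + subject`)
#' with Tukey's post hoc, or Friedman's test with pairwise paired Wilcoxon
#' (Holm-adjusted). The medial-lateral and anterior-posterior contrasts are
#' reported with their direction.
#'
#' @param data data.frame with columns `subject`, `area`, `value`; every
#'   subject must have all four areas.
#' @param gate_level normality gate level.
#' @return a `cbt_test` with `posthoc` (all pairwise contrasts) and
#'   `contrasts` rows for M-L and A-P directions.
#' @export
compare_areas_within_group <- function(data, gate_level = 0.05) {
  stopifnot(all(c("subject", "area", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$area <- factor(data$area)
  if (nlevels(data$subject) < 2L)
    stop("at least 2 subjects are required")
  if (any(table(data$subject, data$area) != 1L))
    stop("every subject needs exactly one value per area")

  fit <- stats::aov(value ~ area + subject, data = data)
  gate_p <- .shapiro_p(stats::residuals(fit))
  # zero-variance residuals (perfectly additive data) carry no normality
  # evidence; the parametric branch handles them exactly
  gate <- list(shapiro_p = gate_p,
               normal = is.na(gate_p) || gate_p >= gate_level)

  area_means <- tapply(data$value, data$area, mean)
  if (gate$normal) {
    an <- summary(fit)[[1]]
    p <- an["area", "Pr(>F)"]
    stat <- an["area", "F value"]
    tk <- stats::TukeyHSD(fit, "area")$area
    posthoc <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p = tk[, "p adj"], row.names = NULL)
    name <- "repeated-measures ANOVA + Tukey"
  } else {
    fr <- stats::friedman.test(value ~ area | subject, data = data)
    p <- fr$p.value
    stat <- unname(fr$statistic)
    lv <- levels(data$area)
    prs <- utils::combn(lv, 2)
    wide <- stats::reshape(data[c("subject", "area", "value")],
                           idvar = "subject", timevar = "area",
                           direction = "wide")
    pv <- apply(prs, 2, function(pr) {
      stats::wilcox.test(wide[[paste0("value.", pr[1])]],
                         wide[[paste0("value.", pr[2])]],
                         paired = TRUE, exact = FALSE)$p.value
    })
    posthoc <- data.frame(contrast = paste(prs[2, ], prs[1, ], sep = "-"),
                          diff = area_means[prs[2, ]] - area_means[prs[1, ]],
                          p = stats::p.adjust(pv, "holm"), row.names = NULL)
    name <- "Friedman + paired Wilcoxon (Holm)"
  }

  dir_contrast <- function(a, b, tag) {
    row <- posthoc[posthoc$contrast %in%
                     c(paste(a, b, sep = "-"), paste(b, a, sep = "-")), ]
    d <- area_means[a] - area_means[b]
    data.frame(contrast = tag,
               direction = if (d > 0) paste0(toupper(substr(a, 1, 1)), ">",
                                             toupper(substr(b, 1, 1)))
               else paste0(toupper(substr(a, 1, 1)), "<",
                           toupper(substr(b, 1, 1))),
               diff = unname(d), p = row$p[1], row.names = NULL)
  }
  contrasts <- rbind(dir_contrast("medial", "lateral", "M-L"),
                     dir_contrast("anterior", "posterior", "A-P"))
  out <- .cbt_test(name, stat, p, gate,
                   summary = data.frame(area = names(area_means),
                                        mean = unname(area_means)),
                   posthoc = posthoc)
  out$contrasts <- contrasts
  out
}

#' Between-group comparison of one measure
#'
#' One-way comparison across groups: Shapiro-Wilk on within-group residuals
#' selects one-way ANOVA with Tukey's post hoc or Kruskal-Wallis with
#' Dunn's post hoc (Holm-adjusted).
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length.
#' @param gate_level normality gate level.
#' @return a `cbt_test` with group summaries and pairwise post hoc table.
#' @export
compare_groups <- function(values, groups, gate_level = 0.05) {
  groups <- factor(groups)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations")
  if (stats::sd(values) == 0)
    stop("degenerate input: values are constant across all groups")
  resid <- values - stats::ave(values, groups)
  gate_p <- .shapiro_p(resid)
  # zero-variance residuals (perfectly additive data) carry no normality
  # evidence; the parametric branch handles them exactly
  gate <- list(shapiro_p = gate_p,
               normal = is.na(gate_p) || gate_p >= gate_level)

  if (gate$normal) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, "groups")$groups
    posthoc <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p = tk[, "p adj"], row.names = NULL)
    out <- .cbt_test("one-way ANOVA + Tukey", an["groups", "F value"],
                     an["groups", "Pr(>F)"], gate,
                     summary = .group_summary(values, groups),
                     posthoc = posthoc)
  } else {
    kw <- stats::kruskal.test(values, groups)
    out <- .cbt_test("Kruskal-Wallis + Dunn (Holm)", kw$statistic,
                     kw$p.value, gate,
                     summary = .group_summary(values, groups),
                     posthoc = .dunn_posthoc(values, groups))
  }
  out
}

## Dunn's pairwise rank-mean z tests after Kruskal-Wallis, Holm-adjusted,
## with the usual tie correction.
.dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  rm <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  lv <- levels(groups)
  prs <- utils::combn(lv, 2)
  z <- apply(prs, 2, function(pr) {
    se <- sqrt(n * (n + 1) / 12 * tie_corr *
                 (1 / ng[pr[1]] + 1 / ng[pr[2]]))
    (rm[pr[1]] - rm[pr[2]]) / se
  })
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), "holm")
  data.frame(contrast = paste(prs[1, ], prs[2, ], sep = "-"),
             z = unname(z), p = unname(p), row.names = NULL)
}

#' Normality-gated correlation
#'
#' Pearson's product-moment correlation when both margins pass the
#' Shapiro-Wilk gate, Spearman's rank correlation otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 4`, non-constant.
#' @param gate_level normality gate level.
#' @return a `cbt_test`; `statistic` is the correlation coefficient,
#'   `method` records which coefficient was used.
#' @export
correlate <- function(x, y, gate_level = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("at least 4 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant margin")
  px <- .shapiro_p(x); py <- .shapiro_p(y)
  normal <- isTRUE(px >= gate_level) && isTRUE(py >= gate_level)
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  out <- .cbt_test(if (normal) "Pearson correlation" else
    "Spearman correlation",
    unname(ct$estimate), ct$p.value,
    gate = list(shapiro_p_x = px, shapiro_p_y = py, normal = normal))
  out$method <- method
  out
}

#' Intraclass correlation coefficient from a subjects-by-measurements matrix
#'
#' Variance-components ICC from the two-way ANOVA mean squares of an
#' `n` subjects x `k` measurements table. `mode = "intra"` is the two-way
#' mixed, consistency, single-measurement form ICC(3,1) =
#' `(MSR - MSE) / (MSR + (k-1) MSE)` for one rater's repeats;
#' `mode = "inter"` is the two-way random, absolute-agreement form ICC(2,1) =
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` across raters.
#'
#' @param measurements numeric matrix, subjects in rows, repeats/raters in
#'   columns; `>= 2` of each.
#' @param mode `"intra"` or `"inter"`.
#' @return scalar ICC.
#' @export
icc <- function(measurements, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 measurements")
  if (stats::sd(as.numeric(m)) == 0)
    stop("zero total variance; ICC undefined")
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  sse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (mode == "intra") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}
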