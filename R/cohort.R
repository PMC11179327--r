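#' Default cohort parameters
#'
#' Per-group means and SDs of the demographic, alignment and regional-CBT
#' variables used by the cohort generator: four groups (OA/healthy x
#' male/female) with age, height, weight, BMI, FTA and MCT moments, plus the
#' 24 standardized regional CBT values. Regional SDs are derived from the
#' printed 95% confidence intervals as `SD = sqrt(n) * halfwidth / 1.96`.
#'
#' @return list with `demographics` (data.frame) and `regional` (data.frame
#'   with `band`, `sector`, `group`, `mean`, `sd`).
#' @export
cohort_defaults <- function() {
  demo <- utils::read.csv(system.file("extdata", "cohort_demographics.csv",
                                      package = "cbtmorph"),
                          stringsAsFactors = FALSE)
  reg <- utils::read.csv(system.file("extdata", "cohort_regional_cbt.csv",
                                     package = "cbtmorph"),
                         stringsAsFactors = FALSE)
  n_by_group <- stats::setNames(demo$n[!duplicated(demo$group)],
                                demo$group[!duplicated(demo$group)])
  reg$sd <- sqrt(n_by_group[reg$group]) * (reg$ci_hi - reg$ci_lo) / 2 / 1.96
  list(demographics = demo, regional = reg[reg$band != "total", ])
}

#' Specify a synthetic cohort
#'
#' Group sizes, the MCT-CBT correlation per group, and optional overrides of
#' the default moments. Within each subject the MCT coronal angle and the
#' most-proximal-medial standardized CBT are jointly Gaussian with the
#' group's correlation `rho`; all other variables are independent Gaussians
#' truncated to wide physical ranges.
#'
#' @param n named vector of group sizes for `oa_male`, `oa_female`,
#'   `healthy_male`, `healthy_female` (defaults: the study's 22/38/28/25).
#' @param rho named vector of MCT vs most-proximal-medial-CBT correlations
#'   (defaults: 0.594 and 0.554 in the OA male/female groups, 0 in healthy).
#' @param seed integer seed.
#' @param defaults moments as returned by [cohort_defaults()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(oa_male = 22, oa_female = 38,
                              healthy_male = 28, healthy_female = 25),
                        rho = c(oa_male = 0.594, oa_female = 0.554,
                                healthy_male = 0, healthy_female = 0),
                        seed = 1L,
                        defaults = cohort_defaults()) {
  groups <- c("oa_male", "oa_female", "healthy_male", "healthy_female")
  n_full <- stats::setNames(rep(0, length(groups)), groups)
  n_full[names(n)] <- n
  rho_full <- stats::setNames(rep(0, length(groups)), groups)
  rho_full[names(rho)] <- rho
  if (any(abs(rho_full) > 1)) stop("|rho| must be <= 1")
  if (any(n_full < 0)) stop("group sizes must be >= 0")
  if (any(defaults$demographics$sd < 0) || any(defaults$regional$sd < 0))
    stop("negative SD in cohort defaults")
  structure(list(n = n_full, rho = rho_full, seed = as.integer(seed),
                 defaults = defaults),
            class = "cohort_spec")
}

.region_column <- function(band, sector) {
  paste0("cbt_", gsub(" ", "_", band), "_", sector)
}

## Draw a normal sample truncated to [lo, hi] by resampling the tails;
## bounds are wide, so the moment distortion is negligible.
.rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic cohort table
#'
#' One row per subject with group, sex, demographics, FTA, MCT and the 24
#' standardized regional CBT values, drawn from the group moments of the
#' spec. The MCT angle and the most-proximal-medial CBT are drawn jointly
#' Gaussian with the group's `rho`; seeded, so identical specs reproduce
#' the table bit-for-bit.
#'
#' @param spec a [cohort_spec].
#' @return data.frame (`subject`, `group`, `sex`, `age`, `height_cm`,
#'   `weight_kg`, `bmi`, `fta`, `mct`, then 24 `cbt_<band>_<sector>`
#'   columns, x 10^-3 standardized scale).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  demo <- spec$defaults$demographics
  reg <- spec$defaults$regional
  labels <- region_labels()
  cols <- c("subject", "group", "sex", "age", "height_cm", "weight_kg",
            "bmi", "fta", "mct", .region_column(labels$band, labels$sector))

  rows <- list()
  sid <- 0L
  for (g in names(spec$n)) {
    ng <- spec$n[[g]]
    if (ng == 0) next
    dg <- demo[demo$group == g, ]
    moment <- function(v) dg[dg$variable == v, c("mean", "sd")]
    out <- data.frame(subject = sid + seq_len(ng), group = g,
                      sex = if (grepl("female", g)) "female" else "male",
                      stringsAsFactors = FALSE)
    sid <- sid + ng
    m <- moment("age"); out$age <- .rnorm_trunc(ng, m$mean, m$sd, 40, 100)
    m <- moment("height_cm")
    out$height_cm <- .rnorm_trunc(ng, m$mean, m$sd, 120, 200)
    m <- moment("weight_kg")
    out$weight_kg <- .rnorm_trunc(ng, m$mean, m$sd, 30, 120)
    m <- moment("bmi"); out$bmi <- .rnorm_trunc(ng, m$mean, m$sd, 12, 45)
    m <- moment("fta"); out$fta <- .rnorm_trunc(ng, m$mean, m$sd, 150, 220)

    # joint draw: MCT and the most-proximal-medial region
    mm <- moment("mct")
    key <- reg[reg$group == g & reg$band == "most proximal" &
                 reg$sector == "medial", ]
    r <- spec$rho[[g]]
    z1 <- stats::rnorm(ng)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(ng)
    out$mct <- mm$mean + mm$sd * z1
    out[[.region_column("most proximal", "medial")]] <-
      key$mean + key$sd * z2

    for (i in seq_len(nrow(labels))) {
      if (labels$band[i] == "most proximal" && labels$sector[i] == "medial")
        next
      rr <- reg[reg$group == g & reg$band == labels$band[i] &
                  reg$sector == labels$sector[i], ]
      out[[.region_column(labels$band[i], labels$sector[i])]] <-
        .rnorm_trunc(ng, rr$mean, rr$sd, 1, 60)
    }
    rows[[g]] <- out[, cols]
  }
  if (length(rows) == 0L) {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    empty$group <- character(0); empty$sex <- character(0)
    return(empty[, cols])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Table-shaped summaries from a cohort
#'
#' Emitters mirroring the study's result tables from any cohort table:
#' within-group area comparisons per height band, between-group comparisons
#' per region, M/L and A/P ratio comparisons, and correlations of FTA or MCT
#' with the regional CBT per group.
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param with `"mct"` or `"fta"` for [cohort_correlations()].
#' @return data.frames in long form; see each function.
#' @name cohort_tables
NULL

#' @rdname cohort_tables
#' @export
cohort_area_comparison <- function(cohort) {
  bands <- unique(region_labels()$band)
  out <- list()
  for (g in unique(cohort$group)) {
    cg <- cohort[cohort$group == g, ]
    for (b in bands) {
      long <- do.call(rbind, lapply(.sectors, function(s)
        data.frame(subject = cg$subject, area = s,
                   value = cg[[.region_column(b, s)]])))
      ts <- compare_areas_within_group(long)
      out[[length(out) + 1L]] <- data.frame(
        group = g, band = b, test = ts$test_name, p = ts$p_value,
        ml_direction = ts$contrasts$direction[1],
        ml_p = ts$contrasts$p[1],
        ap_direction = ts$contrasts$direction[2],
        ap_p = ts$contrasts$p[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @rdname cohort_tables
#' @export
cohort_group_comparison <- function(cohort) {
  labels <- region_labels()
  do.call(rbind, lapply(seq_len(nrow(labels)), function(i) {
    col <- .region_column(labels$band[i], labels$sector[i])
    ts <- compare_groups(cohort[[col]], cohort$group)
    data.frame(band = labels$band[i], sector = labels$sector[i],
               test = ts$test_name, p = ts$p_value,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname cohort_tables
#' @export
cohort_ratio_comparison <- function(cohort) {
  bands <- unique(region_labels()$band)
  do.call(rbind, lapply(bands, function(b) {
    ml <- cohort[[.region_column(b, "medial")]] /
      cohort[[.region_column(b, "lateral")]]
    ap <- cohort[[.region_column(b, "anterior")]] /
      cohort[[.region_column(b, "posterior")]]
    ts_ml <- compare_groups(ml, cohort$group)
    ts_ap <- compare_groups(ap, cohort$group)
    data.frame(band = b, ml_p = ts_ml$p_value, ap_p = ts_ap$p_value,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname cohort_tables
#' @export
cohort_correlations <- function(cohort, with = c("mct", "fta")) {
  with <- match.arg(with)
  labels <- region_labels()
  out <- list()
  for (g in unique(cohort$group)) {
    cg <- cohort[cohort$group == g, ]
    for (i in seq_len(nrow(labels))) {
      col <- .region_column(labels$band[i], labels$sector[i])
      ts <- correlate(cg[[with]], cg[[col]])
      out[[length(out) + 1L]] <- data.frame(
        group = g, band = labels$band[i], sector = labels$sector[i],
        method = ts$method, cc = ts$statistic, p = ts$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
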