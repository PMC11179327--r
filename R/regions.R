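#' Height-band and sector labels of the 24-region diaphyseal partition
#'
#' Six height bands over 30-70% of tibial length crossed with four 90-degree
#' axial sectors.
#'
#' @name region_labels
NULL

.height_bands <- data.frame(
  band = c("most distal", "distal", "central distal",
           "central proximal", "proximal", "most proximal"),
  lo = c(0.30, 0.37, 0.43, 0.50, 0.57, 0.63),
  hi = c(0.37, 0.43, 0.50, 0.57, 0.63, 0.70),
  stringsAsFactors = FALSE)

.sectors <- c("medial", "anterior", "lateral", "posterior")

#' All 24 region labels
#'
#' @return data.frame with 24 rows (`band`, `sector`), ordered proximal to
#'   distal within medial/anterior/lateral/posterior sector order.
#' @export
region_labels <- function() {
  out <- expand.grid(sector = .sectors,
                     band = rev(.height_bands$band),
                     stringsAsFactors = FALSE)[, c("band", "sector")]
  rownames(out) <- NULL
  out
}

#' Tibial length from landmarks
#'
#' Euclidean distance from the midpoint of the two tibial eminence points to
#' the midpoint of the medial and lateral talar-dome points (100% of tibial
#' length).
#'
#' @param landmarks named list with `eminence_medial`, `eminence_lateral`,
#'   `talar_dome_medial`, `talar_dome_lateral`.
#' @return length in mm.
#' @export
compute_tibial_length <- function(landmarks) {
  prox <- (landmarks$eminence_medial + landmarks$eminence_lateral) / 2
  dist <- (landmarks$talar_dome_medial + landmarks$talar_dome_lateral) / 2
  L <- sqrt(sum((prox - dist)^2))
  if (L < 1e-9) stop("eminence and talar midpoints coincide")
  L
}

#' Assign height bands from height fractions
#'
#' Half-open bands over the diaphysis: \[0.30, 0.37), \[0.37, 0.43),
#' \[0.43, 0.50), \[0.50, 0.57), \[0.57, 0.63) and the uppermost band closed,
#' \[0.63, 0.70\]. Fractions outside 30-70% return `"outside"`.
#'
#' @param z_fraction numeric vector of height fractions `(z - z_distal)/L`.
#' @return character vector of band names or `"outside"`.
#' @export
assign_height_band <- function(z_fraction) {
  out <- rep("outside", length(z_fraction))
  for (i in seq_len(nrow(.height_bands))) {
    hit <- if (i == nrow(.height_bands))
      z_fraction >= .height_bands$lo[i] & z_fraction <= .height_bands$hi[i]
    else
      z_fraction >= .height_bands$lo[i] & z_fraction < .height_bands$hi[i]
    out[hit] <- .height_bands$band[i]
  }
  out
}

#' Assign axial sectors from tibial-frame coordinates
#'
#' Four 90-degree wedges of the axial (xy) plane centred on the medial,
#' anterior, lateral and posterior directions. Medial points toward the body
#' midline: the effective medial axis is `-x` for a right tibia and `+x` for
#' a left one. Wedge boundaries are half-open counter-clockwise (an azimuth
#' exactly on the 45-degree boundary belongs to the next sector
#' counter-clockwise, e.g. medial/anterior boundary -> anterior).
#'
#' @param x,y tibial-frame coordinates (mm); `(0, 0)` is rejected.
#' @param side `"right"` or `"left"`.
#' @return character vector of sector names.
#' @export
assign_sector <- function(x, y, side = c("right", "left")) {
  side <- match.arg(side)
  if (any(x == 0 & y == 0))
    stop("cannot assign a sector to a point on the z-axis")
  x_eff <- if (side == "right") -x else x
  theta <- atan2(y, x_eff) * 180 / pi
  k <- floor(((theta + 45) %% 360) / 90) + 1L
  .sectors[k]
}

#' Standardize a thickness by tibial length
#'
#' `actual / L * 1e3`, the dimensionless (x 10^-3) scale that removes
#' body-size effects.
#'
#' @param actual thickness in mm.
#' @param L tibial length in mm, `> 0`.
#' @return standardized value (x 10^-3).
#' @export
standardize_cbt <- function(actual, L) {
  if (!is.numeric(L) || L <= 0) stop("tibial length L must be > 0")
  actual / L * 1e3
}

#' Aggregate a thickness map into the 24 standard regions
#'
#' Vertices are transformed into the tibial frame, assigned a height band
#' (fraction of tibial length above the talar-dome midpoint) and an axial
#' sector, and the converged thickness values averaged per region. Regions
#' with fewer than `min_points` converged vertices are flagged low-count but
#' still reported; empty regions get `NA` with `n_points = 0`. Also returns
#' the medial/lateral and anterior/posterior mean-thickness ratios per height
#' band and for the total diaphysis.
#'
#' @param map a `cbt_thickness_map`.
#' @param mesh the [cbt_mesh] the map lives on.
#' @param cs the [tibial_cs].
#' @param landmarks landmark list (for tibial length and the distal
#'   reference).
#' @param side `"right"` or `"left"`.
#' @param min_points low-count threshold (default 20).
#' @return object of class `regional_cbt`: `regional` (24-row data.frame
#'   with `band`, `sector`, `n_points`, `mean_actual` mm,
#'   `mean_standardized` x 10^-3, `low_count`), `ratios` (per band + total:
#'   `ml_ratio`, `ap_ratio`), and `tibial_length`.
#' @export
aggregate_regions <- function(map, mesh, cs, landmarks,
                              side = c("right", "left"), min_points = 20L) {
  side <- match.arg(side)
  L <- compute_tibial_length(landmarks)
  v_cs <- to_cs(mesh$vertices, cs)
  z_ref <- to_cs((landmarks$talar_dome_medial +
                    landmarks$talar_dome_lateral) / 2, cs)[3]
  zf <- (v_cs[, 3] - z_ref) / L
  band <- assign_height_band(zf)
  sector <- assign_sector(v_cs[, 1], v_cs[, 2], side)

  labels <- region_labels()
  rows <- lapply(seq_len(nrow(labels)), function(i) {
    sel <- band == labels$band[i] & sector == labels$sector[i] &
      map$converged
    n <- sum(sel)
    m <- if (n > 0) mean(map$thickness[sel]) else NA_real_
    data.frame(band = labels$band[i], sector = labels$sector[i],
               n_points = n, mean_actual = m,
               mean_standardized = standardize_cbt(m, L),
               low_count = n < min_points, stringsAsFactors = FALSE)
  })
  regional <- do.call(rbind, rows)

  ratio_for <- function(sel_band) {
    sector_mean <- function(sct) {
      sel <- sel_band & sector == sct & map$converged
      if (any(sel)) mean(map$thickness[sel]) else NA_real_
    }
    c(ml_ratio = sector_mean("medial") / sector_mean("lateral"),
      ap_ratio = sector_mean("anterior") / sector_mean("posterior"))
  }
  bands <- rev(.height_bands$band)
  ratios <- do.call(rbind, lapply(bands, function(b)
    data.frame(band = b, t(ratio_for(band == b)),
               stringsAsFactors = FALSE)))
  ratios <- rbind(ratios,
                  data.frame(band = "total",
                             t(ratio_for(band != "outside")),
                             stringsAsFactors = FALSE))
  rownames(ratios) <- NULL

  structure(list(regional = regional, ratios = ratios, tibial_length = L),
            class = "regional_cbt")
}

#' @export
print.regional_cbt <- function(x, ...) {
  cat("<regional_cbt> 24 regions, tibial length ",
      round(x$tibial_length, 1), " mm\n", sep = "")
  print(x$regional)
  invisible(x)
}
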