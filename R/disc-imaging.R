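#' Maximum-intensity projection of a z-stack
#'
#' Collapses each channel of a calibrated z-stack to 2-D by taking, at every
#' pixel, the maximum over z. All quantification downstream (disc area, Elav
#' fraction, Caspase focus calling) operates on these projections.
#'
#' @param stack A `disc_image_stack` (see [generate_disc_image()]) or a single
#'   row x col x z numeric array.
#' @return For a stack, a named list of 2-D matrices (one per channel); for an
#'   array, a single matrix.
#' @export
max_intensity_projection <- function(stack) {
  project <- function(arr) {
    if (!is.array(arr) || length(dim(arr)) != 3L || dim(arr)[3] < 1L) {
      stop_contract("a z-stack must be a 3-D array with at least one plane",
                    "coprecip_contract_error")
    }
    apply(arr, c(1, 2), max)
  }
  if (inherits(stack, "disc_image_stack")) {
    lapply(stack$channels, project)
  } else {
    project(stack)
  }
}

# Otsu threshold of an arbitrary numeric vector (values rescaled to [0, 1]).
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) <= 0) {
    stop_contract("cannot threshold a constant image", "coprecip_contract_error")
  }
  nv <- (vals - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(nv, ncol = 1)), range = c(0, 1))
  th * diff(rng) + rng[1]
}

# 8-connectivity labeling: EBImage::bwlabel (4-connectivity) followed by a
# union-find merge of components that touch diagonally.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k < 2L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Segment the disc from a DAPI maximum-intensity projection
#'
#' Automatic global (Otsu) thresholding of the DAPI projection, retention of
#' the largest connected foreground component (8-connectivity), and hole
#' filling; the disc area is the mask pixel count times the pixel area.
#'
#' @param dapi_mip 2-D DAPI projection (matrix).
#' @param pixel_size Micrometres per pixel.
#' @return A list `(mask, disc_area_um2)` where `mask` is a logical matrix.
#' @export
segment_disc <- function(dapi_mip, pixel_size) {
  check_scalar_number(pixel_size, "pixel_size", min = 1e-9)
  if (diff(range(dapi_mip)) <= 0) {
    stop_contract("image is constant: no disc to segment", "coprecip_no_disc_error")
  }
  th <- otsu_threshold(as.vector(dapi_mip))
  fg <- dapi_mip > th
  if (!any(fg)) {
    stop_contract("no foreground found: no disc in image", "coprecip_no_disc_error")
  }
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  largest <- which.max(sizes)
  mask <- lab == largest
  mask <- EBImage::fillHull(mask) > 0
  list(mask = mask, disc_area_um2 = sum(mask) * pixel_size^2)
}

#' Elav-positive area as a percentage of the disc
#'
#' Elav positivity is decided by an automatic (Otsu) threshold computed from
#' the intensities inside the disc mask only; the result is
#' `100 * positive-in-mask pixels / mask pixels`. A constant in-mask signal is
#' degenerate for thresholding and is treated as all-positive when nonzero
#' (the stained region fills the disc) and all-negative when zero.
#'
#' @param elav_mip 2-D Elav projection.
#' @param disc_mask Logical disc mask from [segment_disc()].
#' @return Percent of disc area that is Elav-positive, in \\[0, 100\\].
#' @export
elav_fraction <- function(elav_mip, disc_mask) {
  if (!any(disc_mask)) {
    stop_contract("disc mask is empty", "coprecip_contract_error")
  }
  vals <- elav_mip[disc_mask]
  if (diff(range(vals)) <= 0) {
    return(if (vals[1] > 0) 100 else 0)
  }
  th <- otsu_threshold(vals)
  100 * sum(vals > th) / length(vals)
}

#' Estimate basal Caspase fluorescence inside the disc
#'
#' Robust central estimate — the median of the in-mask Caspase projection —
#' so that sparse bright apoptotic foci (a small fraction of disc pixels) do
#' not inflate the basal level from which the 3x focus threshold is set.
#'
#' @param caspase_mip 2-D Caspase projection.
#' @param disc_mask Logical disc mask.
#' @return Basal fluorescence estimate (intensity units).
#' @export
estimate_basal_fluorescence <- function(caspase_mip, disc_mask) {
  if (!any(disc_mask)) {
    stop_contract("disc mask is empty", "coprecip_contract_error")
  }
  median(caspase_mip[disc_mask])
}

#' Call Caspase-3-positive apoptotic foci
#'
#' Pixels inside the disc at or above 3x the basal fluorescence (the
#' "starting from 3 times basal" rule makes the threshold inclusive) are
#' grouped into 8-connected components; components are kept only when their
#' area is strictly greater than 1 and strictly less than 60 square
#' micrometres. Each kept focus carries its area, mean fluorescence and
#' centroid.
#'
#' @param caspase_mip 2-D Caspase projection.
#' @param disc_mask Logical disc mask.
#' @param basal Basal fluorescence (> 0), e.g. from
#'   [estimate_basal_fluorescence()].
#' @param pixel_size Micrometres per pixel.
#' @param threshold_multiple Focus threshold as a multiple of basal (default 3).
#' @param area_gate Exclusive `(lower, upper)` area gate in square
#'   micrometres (default `c(1, 60)`).
#' @return A tibble with one row per focus: `label`, `area_um2`,
#'   `mean_fluorescence`, `centroid_row`, `centroid_col`.
#' @export
call_caspase_foci <- function(caspase_mip, disc_mask, basal, pixel_size,
                              threshold_multiple = 3, area_gate = c(1, 60)) {
  check_scalar_number(basal, "basal", min = 1e-12)
  check_scalar_number(pixel_size, "pixel_size", min = 1e-9)
  thr <- threshold_multiple * basal
  bw <- (caspase_mip >= thr) & disc_mask
  empty <- tibble(label = integer(), area_um2 = numeric(),
                  mean_fluorescence = numeric(), centroid_row = numeric(),
                  centroid_col = numeric())
  if (!any(bw)) return(empty)
  lab <- label_components(bw)
  ids <- seq_len(max(lab))
  px <- lab[lab > 0L]
  areas_px <- tabulate(px, nbins = max(lab))
  area_um2 <- areas_px * pixel_size^2
  keep <- area_um2 > area_gate[1] & area_um2 < area_gate[2]
  if (!any(keep)) return(empty)
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs_at <- lab[lab > 0L]
  vals_at <- caspase_mip[lab > 0L]
  mean_fluor <- vapply(ids, function(i) mean(vals_at[labs_at == i]), numeric(1))
  cr <- vapply(ids, function(i) mean(idx[labs_at == i, 1]), numeric(1))
  cc <- vapply(ids, function(i) mean(idx[labs_at == i, 2]), numeric(1))
  out <- tibble(
    label = ids, area_um2 = area_um2, mean_fluorescence = mean_fluor,
    centroid_row = cr, centroid_col = cc
  )[keep, , drop = FALSE]
  out$label <- seq_len(nrow(out))
  out
}

#' Quantify one disc stack end to end
#'
#' Runs the full image pipeline on one calibrated stack: maximum-intensity
#' projection, DAPI disc segmentation, Elav area fraction, basal Caspase
#' estimation and focus calling. Returns a `disc_quant` object whose
#' [glance()] is the per-disc summary row (`disc_area_um2`,
#' `elav_fraction_pct`, `n_foci`, `mean_focus_area_um2`,
#' `mean_focus_fluorescence`) and whose [tidy()] is the per-focus table.
#'
#' @param stack A `disc_image_stack`.
#' @param disc_id Identifier recorded in the summary row.
#' @inheritParams call_caspase_foci
#' @return A `disc_quant` object.
#' @export
quantify_disc <- function(stack, disc_id = "disc", threshold_multiple = 3,
                          area_gate = c(1, 60)) {
  if (!inherits(stack, "disc_image_stack")) {
    stop_contract("`stack` must be a disc_image_stack", "coprecip_contract_error")
  }
  mips <- max_intensity_projection(stack)
  seg <- segment_disc(mips$dapi, stack$pixel_size)
  elav_pct <- elav_fraction(mips$elav, seg$mask)
  basal <- estimate_basal_fluorescence(mips$caspase, seg$mask)
  foci <- call_caspase_foci(mips$caspase, seg$mask, basal, stack$pixel_size,
                            threshold_multiple = threshold_multiple,
                            area_gate = area_gate)
  structure(
    list(
      disc_id = disc_id,
      disc_area_um2 = seg$disc_area_um2,
      elav_fraction_pct = elav_pct,
      basal_fluorescence = basal,
      foci = foci,
      mask = seg$mask,
      mips = mips,
      pixel_size = stack$pixel_size
    ),
    class = "disc_quant"
  )
}

#' @export
print.disc_quant <- function(x, ...) {
  cat(sprintf(
    "<disc_quant> %s: disc %.1f um2, Elav %.1f%%, %d Caspase focus/foci\n",
    x$disc_id, x$disc_area_um2, x$elav_fraction_pct, nrow(x$foci)
  ))
  invisible(x)
}

#' @rdname quantify_disc
#' @param x A `disc_quant` object.
#' @param ... Unused.
#' @method tidy disc_quant
#' @export
tidy.disc_quant <- function(x, ...) {
  dplyr::mutate(x$foci, disc_id = x$disc_id, .before = 1)
}

#' @rdname quantify_disc
#' @method glance disc_quant
#' @export
glance.disc_quant <- function(x, ...) {
  tibble(
    disc_id = x$disc_id,
    disc_area_um2 = x$disc_area_um2,
    elav_fraction_pct = x$elav_fraction_pct,
    n_foci = nrow(x$foci),
    mean_focus_area_um2 = if (nrow(x$foci)) mean(x$foci$area_um2) else NA_real_,
    mean_focus_fluorescence = if (nrow(x$foci)) mean(x$foci$mean_fluorescence)
      else NA_real_
  )
}

#' Plot a quantified disc
#'
#' Caspase projection as a raster with the disc outline implied by masking,
#' called foci marked at their centroids and scaled by area.
#'
#' @param object A `disc_quant` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disc_quant
#' @export
autoplot.disc_quant <- function(object, ...) {
  img <- object$mips$caspase
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$row, df$col)]
  df$in_disc <- object$mask[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = ifelse(.data$in_disc, .data$intensity, NA))) +
    ggplot2::scale_fill_viridis_c(na.value = "grey10", name = "Caspase") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s — %d focus/foci, Elav %.1f%%",
                      object$disc_id, nrow(object$foci), object$elav_fraction_pct),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$foci)) {
    p <- p + ggplot2::geom_point(
      data = object$foci,
      ggplot2::aes(.data$centroid_col, .data$centroid_row, size = .data$area_um2),
      colour = "red", shape = 1, stroke = 1
    ) +
      ggplot2::scale_size_area(name = expression(area ~ (mu * m^2)))
  }
  p
}

#' Classify disc sizes against a control distribution
#'
#' Disc areas are classed as below, within, or above two sample standard
#' deviations of the control mean — the convention used to describe the
#' broadened size distribution of perturbed discs relative to controls.
#'
#' @param test_areas Numeric vector of test disc areas (um2).
#' @param control_areas Numeric vector of control disc areas (>= 2 values;
#'   sample SD uses n - 1).
#' @return A one-row tibble: `frac_below`, `frac_within`, `frac_above`
#'   (summing to 1), plus the `lower` and `upper` bounds used.
#' @export
classify_disc_sizes <- function(test_areas, control_areas) {
  if (length(control_areas) < 2L) {
    stop_contract("at least 2 control areas are required", "coprecip_contract_error")
  }
  if (!length(test_areas)) {
    stop_contract("no test areas supplied", "coprecip_contract_error")
  }
  m <- mean(control_areas)
  s <- sd(control_areas)
  lower <- m - 2 * s
  upper <- m + 2 * s
  n <- length(test_areas)
  below <- sum(test_areas < lower)
  above <- sum(test_areas > upper)
  tibble(
    frac_below = below / n,
    frac_within = (n - below - above) / n,
    frac_above = above / n,
    lower = lower,
    upper = upper
  )
}
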