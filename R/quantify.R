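#' Segment heterochromatin domains in a density field
#'
#' Thresholds the field at `threshold` inside the nucleus mask and labels
#' 8-connected components; components smaller than `min_area` are dropped.
#' The default threshold is the model's own interface midpoint
#' \eqn{\phi_h^{max}/2}. Deterministic for fixed inputs.
#'
#' @param field Numeric matrix (e.g. a \eqn{\phi_h} field) on the geometry
#'   grid, or an imported map normalized with [normalize_density_map()].
#' @param geom A [nucleus_geometry()].
#' @param threshold Density threshold.
#' @param min_area Minimum region area in rescaled length^2 (converted to
#'   cells via the grid spacing).
#' @return A `domain_set`: tibble with one row per region — `label`, `x`,
#'   `y` (centroid, grid coordinates), `area` (length^2), `eq_radius`
#'   (`sqrt(area/pi)`), `mean_density`, `boundary_distance` (minimum lamina
#'   distance of the region), `klass` (`NA` until [classify_domains()]) —
#'   with the label image and segmentation provenance as attributes. Empty
#'   segmentation gives a zero-row set.
#' @export
segment_domains <- function(field, geom, threshold = NULL, min_area = 0.01) {
  stopifnot(inherits(geom, "nucleus_geometry"),
            identical(dim(field), dim(geom$mask)))
  if (is.null(threshold)) threshold <- 0.4
  stopifnot(is.finite(threshold), min_area >= 0)
  h <- geom$spacing
  bw <- matrix(FALSE, nrow(field), ncol(field))
  bw[geom$mask] <- is.finite(field[geom$mask]) & field[geom$mask] >= threshold
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  empty <- tibble::tibble(label = integer(), x = numeric(), y = numeric(),
                          area = numeric(), eq_radius = numeric(),
                          mean_density = numeric(),
                          boundary_distance = numeric(),
                          klass = character())
  prov <- list(threshold = threshold, min_area = min_area, spacing = h)
  if (nlab == 0)
    return(structure(empty, label_image = labm, provenance = prov,
                     class = c("domain_set", class(empty))))
  px <- which(labm > 0, arr.ind = TRUE)
  lv <- labm[px]
  area_cells <- tabulate(lv, nbins = nlab)
  xs <- tapply(px[, 1], lv, mean)
  ys <- tapply(px[, 2], lv, mean)
  dens <- tapply(field[px], lv, mean)
  bd <- tapply(geom$lamina_distance[px], lv, min)
  ds <- tibble::tibble(label = seq_len(nlab),
                       x = as.numeric(xs), y = as.numeric(ys),
                       area = area_cells * h^2,
                       eq_radius = sqrt(area_cells * h^2 / pi),
                       mean_density = as.numeric(dens),
                       boundary_distance = as.numeric(bd),
                       klass = NA_character_)
  keep <- ds$area >= min_area
  labm[!(labm %in% ds$label[keep])] <- 0L
  ds <- ds[keep, ]
  structure(ds, label_image = labm, provenance = prov,
            class = c("domain_set", class(empty)))
}

#' Classify domains as interior or lamina-associated (LAD)
#'
#' A region is a LAD when its minimum distance to the nuclear boundary is at
#' most `lad_cutoff`; otherwise it is an interior domain.
#'
#' @param ds A `domain_set` from [segment_domains()].
#' @param geom A [nucleus_geometry()].
#' @param lad_cutoff Distance cutoff (rescaled length). Default `2 * delta`
#'   of the standard parameter set (0.14).
#' @return The `domain_set` with `klass` filled (`"interior"` or `"LAD"`).
#' @export
classify_domains <- function(ds, geom, lad_cutoff = 0.14) {
  stopifnot(inherits(ds, "domain_set"), lad_cutoff >= 0)
  ds$klass <- ifelse(ds$boundary_distance <= lad_cutoff, "LAD", "interior")
  message(sprintf("%d interior, %d LAD domains",
                  sum(ds$klass == "interior"), sum(ds$klass == "LAD")))
  ds
}

#' LAD thickness sampled in angular bins around the periphery
#'
#' For each angular bin a ray is cast from the nuclear rim toward the
#' center; where the ray starts inside thresholded LAD material, the
#' thickness is the length of the contiguous LAD run from the boundary.
#' Bins whose rays do not meet boundary-contiguous material contribute no
#' sample.
#'
#' @param ds A classified `domain_set` (see [classify_domains()]).
#' @param field The density field the set was segmented from (unused beyond
#'   provenance; thickness is measured on the label image).
#' @param geom A [nucleus_geometry()] (circular geometry).
#' @param n_angular_bins Number of angular bins.
#' @return Tibble with columns `angle`, `thickness`; mean and standard error
#'   attached as attributes `mean` and `se`. Zero rows when there are no
#'   LADs.
#' @export
lad_thickness_profile <- function(ds, field, geom, n_angular_bins = 180) {
  stopifnot(inherits(ds, "domain_set"), inherits(geom, "nucleus_geometry"))
  labm <- attr(ds, "label_image")
  lad_labels <- ds$label[ds$klass == "LAD" & !is.na(ds$klass)]
  out <- tibble::tibble(angle = numeric(), thickness = numeric())
  if (!length(lad_labels)) {
    attr(out, "mean") <- NA_real_; attr(out, "se") <- NA_real_
    return(out)
  }
  h <- geom$spacing; cx <- geom$center[1]; cy <- geom$center[2]
  rs <- seq(geom$radius - h / 2, 0, by = -h)
  angles <- seq(0, 2 * pi, length.out = n_angular_bins + 1)[-(n_angular_bins + 1)]
  n <- nrow(labm)
  samp <- lapply(angles, function(a) {
    ri <- round(cx + cos(a) * rs / h); rj <- round(cy + sin(a) * rs / h)
    ok <- ri >= 1 & ri <= n & rj >= 1 & rj <= n
    lv <- labm[cbind(ri[ok], rj[ok])]
    inlad <- lv %in% lad_labels
    st <- which(inlad)[1]
    if (is.na(st) || st > 2) return(NULL)   # not boundary-contiguous
    stop_at <- which(!inlad & seq_along(inlad) > st)[1]
    if (is.na(stop_at)) stop_at <- length(inlad) + 1
    tibble::tibble(angle = a, thickness = (stop_at - st) * h)
  })
  out <- dplyr::bind_rows(samp)
  attr(out, "mean") <- mean(out$thickness)
  attr(out, "se") <- stats::sd(out$thickness) / sqrt(max(nrow(out), 1))
  out
}

#' Radial density profile around a point
#'
#' Mean field value in concentric annuli emerging from `center`, as used to
#' characterize the density fall-off from the core of a domain toward its
#' periphery. Annuli reaching outside the mask use in-mask cells only.
#'
#' @param field Numeric matrix on the geometry grid.
#' @param geom A [nucleus_geometry()].
#' @param center Grid coordinates (row, col) of the profile center; must be
#'   inside the mask.
#' @param r_max Outer radius of the profile (rescaled length).
#' @param n_annuli Number of annuli.
#' @return Tibble with `r` (annulus midpoint) and `density`.
#' @export
radial_density_profile <- function(field, geom, center, r_max, n_annuli = 20) {
  stopifnot(length(center) == 2,
            geom$mask[round(center[1]), round(center[2])])
  h <- geom$spacing
  n <- nrow(field)
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  rr <- sqrt((ii - center[1])^2 + (jj - center[2])^2) * h
  edges <- seq(0, r_max, length.out = n_annuli + 1)
  bin <- findInterval(rr, edges, rightmost.closed = TRUE)
  usable <- geom$mask & bin >= 1 & bin <= n_annuli & is.finite(field)
  dens <- tapply(field[usable], bin[usable], mean)
  tibble::tibble(r = (edges[-1] + edges[-length(edges)]) / 2,
                 density = as.numeric(dens[as.character(seq_len(n_annuli))]))
}

#' Average interface width of interior domains
#'
#' For each interior domain, the radial profile of the field from the domain
#' centroid is interpolated and the width of the descent between 80% and 20%
#' of the core density is recorded; the mean across domains estimates the
#' interface width set by the competition between interfacial and bulk
#' energies.
#'
#' @param field Density field.
#' @param ds A classified `domain_set` with at least one interior domain.
#' @param geom A [nucleus_geometry()].
#' @return Scalar width (rescaled length).
#' @export
interface_width <- function(field, ds, geom) {
  ints <- ds[!is.na(ds$klass) & ds$klass == "interior", ]
  stopifnot(nrow(ints) >= 1)
  h <- geom$spacing
  widths <- vapply(seq_len(nrow(ints)), function(i) {
    r_out <- 3 * ints$eq_radius[i] + 6 * h
    prof <- radial_density_profile(field, geom,
                                   c(ints$x[i], ints$y[i]),
                                   r_max = r_out,
                                   n_annuli = max(12L, ceiling(r_out / (h / 2))))
    prof <- prof[is.finite(prof$density), ]
    if (nrow(prof) < 5) return(NA_real_)
    core <- mean(prof$density[seq_len(max(2, floor(nrow(prof) * 0.15)))])
    base <- min(prof$density)
    hi <- base + 0.8 * (core - base); lo <- base + 0.2 * (core - base)
    r_hi <- cross_down(prof$r, prof$density, hi)
    r_lo <- cross_down(prof$r, prof$density, lo)
    if (is.na(r_hi) || is.na(r_lo) || r_lo <= r_hi) return(NA_real_)
    r_lo - r_hi
  }, numeric(1))
  mean(widths, na.rm = TRUE)
}

## first downward crossing of `level` by linear interpolation
cross_down <- function(r, y, level) {
  below <- which(y < level)
  if (!length(below) || below[1] == 1) return(NA_real_)
  i <- below[1]
  r[i - 1] + (r[i] - r[i - 1]) * (y[i - 1] - level) / (y[i - 1] - y[i])
}

#' Compare two conditions: size ratio and Welch test
#'
#' Ratio of means (b over a) with standard errors and an unpaired two-tailed
#' Welch t test, for any per-domain measurement (interior equivalent radii,
#' LAD thickness samples, ...).
#'
#' @param a,b Numeric vectors of per-domain measurements, or classified
#'   `domain_set`s (then interior `eq_radius` is compared).
#' @param measure Label recorded in the output.
#' @return A one-row `condition_comparison` tibble: `measure`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `ratio` (= mean_b/mean_a), `ratio_se`, `statistic`,
#'   `p_value`.
#' @export
compare_conditions <- function(a, b, measure = "eq_radius") {
  va <- as_measure_vector(a, measure)
  vb <- as_measure_vector(b, measure)
  stopifnot("both conditions must be non-empty" =
              length(va) > 0 && length(vb) > 0)
  ma <- mean(va); mb <- mean(vb)
  ratio <- mb / ma
  se_a <- stats::sd(va) / sqrt(length(va)); se_b <- stats::sd(vb) / sqrt(length(vb))
  ratio_se <- abs(ratio) * sqrt((se_a / ma)^2 + (se_b / mb)^2)
  tt <- if (length(va) >= 2 && length(vb) >= 2)
    stats::t.test(vb, va, var.equal = FALSE)
  else list(statistic = NA_real_, p.value = NA_real_)
  out <- tibble::tibble(measure = measure, n_a = length(va), n_b = length(vb),
                        mean_a = ma, mean_b = mb, ratio = ratio,
                        ratio_se = ratio_se,
                        statistic = unname(tt$statistic),
                        p_value = tt$p.value)
  class(out) <- c("condition_comparison", class(out))
  out
}

as_measure_vector <- function(x, measure) {
  if (inherits(x, "domain_set")) {
    stopifnot(measure %in% names(x))
    x[[measure]][!is.na(x$klass) & x$klass == "interior"]
  } else as.numeric(x)
}

#' Min-max normalize an imported grayscale density map
#'
#' Imported maps (PNG/TIFF grayscale, read with [read_density_map()]) have
#' arbitrary intensity scales; normalizing to [0, 1] makes a user-chosen
#' threshold meaningful.
#'
#' @param field Numeric matrix.
#' @return Matrix rescaled to [0, 1] (constant maps become 0).
#' @export
normalize_density_map <- function(field) {
  rng <- range(field, finite = TRUE)
  if (diff(rng) == 0) return(field * 0)
  (field - rng[1]) / diff(rng)
}

#' Read a grayscale image as a density matrix
#'
#' @param path PNG or TIFF file.
#' @return Numeric matrix (first channel if multi-channel).
#' @export
read_density_map <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) d <- d[, , 1]
  as.matrix(d)
}
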