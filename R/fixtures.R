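#' Synthetic density-field fixtures with planted ground truth
#'
#' Generates test fields emulating thresholded heterochromatin maps:
#' `"disks"` plants non-overlapping sharp disks at random interior
#' positions; `"annulus"` plants a boundary band of constant width (a
#' synthetic LAD); `"tanh_disk"` plants one disk with a tanh radial profile
#' of programmed interface width. Optional Gaussian pixel noise is added.
#' The planted ground truth is returned alongside the field.
#'
#' @param kind One of `"disks"`, `"annulus"`, `"tanh_disk"`.
#' @param geom A [nucleus_geometry()].
#' @param n Number of disks (for `"disks"`).
#' @param radius Disk radius (rescaled length).
#' @param width Band width (`"annulus"`) or interface width (`"tanh_disk"`).
#' @param level Field value inside planted shapes (background is 0).
#' @param noise Standard deviation of additive Gaussian noise.
#' @param seed RNG seed (placement and noise).
#' @param margin Clearance kept from the boundary and between disks.
#' @return List with `field` (matrix) and `truth` (tibble of planted shapes).
#' @export
generate_fixture <- function(kind = c("disks", "annulus", "tanh_disk"),
                             geom, n = 5, radius = 0.3, width = 0.2,
                             level = 0.8, noise = 0, seed = 1L,
                             margin = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(geom, "nucleus_geometry"))
  h <- geom$spacing
  if (is.null(margin)) margin <- 2 * h
  ng <- geom$grid_shape[1]
  ii <- matrix(seq_len(ng), ng, ng); jj <- t(ii)
  rr <- sqrt((ii - geom$center[1])^2 + (jj - geom$center[2])^2) * h
  field <- matrix(0, ng, ng)
  set.seed(seed)
  truth <- switch(kind,
    disks = {
      centers <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(centers) < n) {
        tries <- tries + 1
        if (tries > 5000 * n) stop("infeasible packing: ", n,
                                   " disks of radius ", radius)
        r_pos <- sqrt(stats::runif(1)) * (geom$radius - radius - margin)
        th <- stats::runif(1, 0, 2 * pi)
        cand <- c(geom$center[1] + cos(th) * r_pos / h,
                  geom$center[2] + sin(th) * r_pos / h)
        if (nrow(centers) > 0 &&
            any(sqrt(rowSums((t(t(centers) - cand))^2)) * h <
                  2 * radius + margin)) next
        centers <- rbind(centers, cand)
      }
      for (k in seq_len(n)) {
        d <- sqrt((ii - centers[k, 1])^2 + (jj - centers[k, 2])^2) * h
        field[d <= radius] <- level
      }
      tibble::tibble(shape = "disk", x = centers[, 1], y = centers[, 2],
                     radius = radius, width = NA_real_)
    },
    annulus = {
      band <- rr >= geom$radius - width & rr <= geom$radius
      field[band & geom$mask] <- level
      tibble::tibble(shape = "annulus", x = geom$center[1],
                     y = geom$center[2], radius = geom$radius, width = width)
    },
    tanh_disk = {
      d <- rr
      field <- level / 2 * (1 - tanh((d - radius) / (width / 2)))
      tibble::tibble(shape = "tanh_disk", x = geom$center[1],
                     y = geom$center[2], radius = radius, width = width)
    })
  if (noise > 0) field <- field + matrix(stats::rnorm(ng^2, 0, noise), ng, ng)
  field[!geom$mask] <- NA_real_
  list(field = field, truth = truth)
}
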