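#' Write a snapshot to portable plain-text files
#'
#' A snapshot directory holds each field as a headerless CSV matrix plus a
#' JSON sidecar with time, grid shape, spacing and the model parameters, so
#' a snapshot can be re-read (or read by any other tool) without R-specific
#' serialization.
#'
#' @param state A [field_state()].
#' @param geom A [nucleus_geometry()].
#' @param dir Output directory (created if needed).
#' @param p Optional [chrom_params()] recorded in the sidecar.
#' @return The directory path, invisibly.
#' @export
write_snapshot <- function(state, geom, dir, p = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(state$phi_n, file.path(dir, "phi_n.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(state$phi_d, file.path(dir, "phi_d.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(time = state$time, grid_shape = geom$grid_shape,
               spacing = geom$spacing, radius = geom$radius,
               shape = geom$shape,
               params = if (!is.null(p)) unclass(p) else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a snapshot written by [write_snapshot()]
#'
#' @param dir Snapshot directory.
#' @return List with `state` ([field_state()]), `geom`
#'   ([nucleus_geometry()] rebuilt from the sidecar) and `params`
#'   (`chrom_params` or NULL).
#' @export
read_snapshot <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  geom <- nucleus_geometry(radius = meta$radius, spacing = meta$spacing,
                           shape = meta$shape)
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = ",",
                                                header = FALSE))
  phi_n <- unname(rd("phi_n.csv")); phi_d <- unname(rd("phi_d.csv"))
  phi_n[!geom$mask] <- NA_real_; phi_d[!geom$mask] <- NA_real_
  p <- if (!is.null(meta$params)) do.call(chrom_params, as.list(meta$params))
  list(state = field_state(phi_n, phi_d, geom, time = meta$time),
       geom = geom, params = p)
}

#' Write the time series of a trajectory as CSV
#'
#' @param traj A `chrom_trajectory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_series <- function(traj, path) {
  utils::write.csv(traj$series, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-domain table as CSV
#'
#' Columns: label, x, y, area, eq_radius, mean_density, boundary_distance,
#' klass (plus seed when pooled).
#'
#' @param ds A `domain_set` or pooled domains tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_domains <- function(ds, path) {
  utils::write.csv(tibble::as_tibble(ds), path, row.names = FALSE)
  invisible(path)
}
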