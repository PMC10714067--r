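#' Write a simulated deployment to a directory tree
#'
#' One sub-directory per individual with `accel.csv` (t, ax, ay, az),
#' `magdepth.csv` (t, mx, my, mz, depth), `gps.csv` (t, lat, lon), an
#' `echograms/` folder (one ENR matrix CSV plus a JSON sidecar per
#' capture-attempt window), and a pooled `truth.json` at the top level.
#'
#' @param dep a [simulate_deployment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_deployment <- function(dep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dep$individuals)) {
    ind <- dep$individuals[[i]]
    d <- file.path(dir, sprintf("individual_%d", i))
    dir.create(d, showWarnings = FALSE)
    acc <- ind$sensors$accel
    fsa <- ind$sensors$accel_fs
    utils::write.csv(
      data.frame(t = (seq_len(nrow(acc)) - 1L) / fsa, acc),
      file.path(d, "accel.csv"), row.names = FALSE)
    utils::write.csv(ind$sensors$magdepth, file.path(d, "magdepth.csv"),
                     row.names = FALSE)
    utils::write.csv(ind$sensors$gps, file.path(d, "gps.csv"),
                     row.names = FALSE)
    if (length(ind$echograms) > 0L) {
      ed <- file.path(d, "echograms")
      dir.create(ed, showWarnings = FALSE)
      for (k in seq_along(ind$echograms)) {
        eg <- ind$echograms[[k]]$echogram
        utils::write.table(round(eg$enr, 2),
                           file.path(ed, sprintf("prca_%03d.csv", k)),
                           sep = ",", row.names = FALSE, col.names = FALSE)
        jsonlite::write_json(
          list(prca_id = eg$prca_id, t0 = eg$ping_t[1L],
               ping_rate_hz = 1 / diff(eg$ping_t[1:2]),
               range_res_m = eg$range_res),
          file.path(ed, sprintf("prca_%03d.json", k)), auto_unbox = TRUE)
      }
    }
  }
  jsonlite::write_json(dep$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", digits = 8)
  invisible(dir)
}

#' Read one individual's sensor streams from a deployment directory
#'
#' @param dir the individual's sub-directory written by
#'   [write_deployment()].
#' @param accel_fs sampling rate of `accel.csv`, Hz.
#' @return List mirroring the simulator's sensor bundle: `accel` matrix,
#'   `accel_fs`, `magdepth`, `gps`, `t0`.
#' @export
read_sensor_bundle <- function(dir, accel_fs = 200) {
  acc <- utils::read.csv(file.path(dir, "accel.csv"))
  list(accel = as.matrix(acc[, c("ax", "ay", "az")]),
       accel_fs = accel_fs,
       magdepth = utils::read.csv(file.path(dir, "magdepth.csv")),
       gps = utils::read.csv(file.path(dir, "gps.csv")),
       t0 = 0)
}
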