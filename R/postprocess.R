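# Reported quantities from a finished run: polarization profiles, percent
# changes, per-site time series, regional ion totals, and standard-format
# output files.

result_step_index <- function(result, t) {
  if (t < min(result$times) - 1e-12 || t > max(result$times) + 1e-12)
    stop(sprintf("t = %.4g s is outside the run span [%.4g, %.4g] s",
                 t, min(result$times), max(result$times)))
  which.min(abs(result$times - t))
}

#' Transmembrane-voltage profile along the node of Ranvier
#'
#' @param result a `tes_result`.
#' @param t time, seconds (snapped to the nearest outer step).
#' @return data.frame with arc positions `s` (0 = left node edge, 1 =
#'   right), `V` (mV) and the snap time `t`.
#' @export
transmembrane_voltage_profile <- function(result, t) {
  k <- result_step_index(result, t)
  data.frame(s = result$pairing$s, V = result$V[k, ],
             t = result$times[k])
}

#' Percent polarization change between two voltage profiles
#'
#' `100 * (post - pre) / |pre|` per site: with a negative resting voltage
#' this makes depolarization (voltage moving toward zero) positive and
#' hyperpolarization negative.
#'
#' @param pre,post profiles from [transmembrane_voltage_profile()] on the
#'   same sites.
#' @return data.frame with columns `s` and `pct`.
#' @export
percent_polarization_change <- function(pre, post) {
  if (nrow(pre) != nrow(post) || any(abs(pre$s - post$s) > 1e-9))
    stop("profiles are on different site sets")
  data.frame(s = pre$s, pct = 100 * (post$V - pre$V) / abs(pre$V))
}

#' Per-site time series of a recorded quantity
#'
#' Long-format table of one quantity at `k` equispaced sites along the node
#' (default 11, matching the 0, 10, ..., 100% positions).
#'
#' @param result a `tes_result`.
#' @param k number of equispaced sites.
#' @param quantity one of `"V"`, `"m"`, `"n"`, `"h"`, `"flux_Na"`,
#'   `"flux_K"`, `"flux_Ca"`, `"flux_Cl"`.
#' @return data.frame with columns `s`, `t` (s) and `value`.
#' @export
site_time_series <- function(result, k = 11, quantity = "V") {
  sites <- membrane_sample_points(result$pairing, k)
  idx <- match(sites$node_intra, result$pairing$node_intra)
  mat <- switch(quantity,
    V = result$V, m = result$m, n = result$n, h = result$h,
    flux_Na = result$flux$Na, flux_K = result$flux$K,
    flux_Ca = result$flux$Ca, flux_Cl = result$flux$Cl,
    stop("unknown quantity: ", quantity))
  data.frame(
    s = rep(sites$s_target, each = length(result$times)),
    t = rep(result$times, length(idx)),
    value = as.numeric(mat[, idx]))
}

#' Total amount of an ion in a region
#'
#' FEM-consistent integral of the concentration field over the
#' intracellular or extracellular region, linearly interpolated between
#' the two field checkpoints bracketing `t`.  Units are mol per metre of
#' depth (the domain is a 2D slice).
#'
#' @param result a `tes_result`.
#' @param region `"I"` or `"E"`.
#' @param ion ion name (`"Na"`, `"K"`, `"Ca"`, `"Cl"`).
#' @param t time, seconds.
#' @return data.frame with columns `region`, `ion`, `t`, `amount`.
#' @export
region_total <- function(result, region = "I", ion = "Ca", t = 0) {
  if (!region %in% c("I", "E"))
    stop("region must be \"I\" or \"E\": concentrations are not defined ",
         "on the membrane")
  if (!ion %in% names(result$config$ions)) stop("unknown ion: ", ion)
  work <- result_workspace(result)
  Ml <- work$sys[[region]]$Mlump
  ts <- vapply(result$checkpoints, `[[`, 0, "t")
  if (t < ts[1] - 1e-12 || t > ts[length(ts)] + 1e-12)
    stop("t outside the checkpointed span")
  amounts <- vapply(result$checkpoints,
                    function(ck) sum(Ml * ck$conc[[ion]][[region]]), 0)
  amount <- if (length(ts) == 1) amounts else approx(ts, amounts, t)$y
  data.frame(region = region, ion = ion, t = t, amount = amount)
}

# workspace reconstruction (cached on the result object's environment)
result_workspace <- function(result) {
  env <- attr(result, "workspace_cache")
  if (is.null(env)) env <- new.env()
  if (is.null(env$work)) {
    geom <- mesh_geom(result$mesh)
    env$work <- list(sys = list(I = region_system(result$mesh, "I", geom),
                                E = region_system(result$mesh, "E", geom)))
  }
  env$work
}

# ---------------------------------------------------------------------------
# File output
# ---------------------------------------------------------------------------

#' Write run outputs to a directory
#'
#' Writes per-site time-series CSVs (one per quantity, sites as columns
#' named by their percent position), the diagnostics table, a legacy-VTK
#' time series of the potential and concentration fields, and a provenance
#' JSON with the configuration hash of the generating run.
#'
#' @param result a `tes_result`.
#' @param outdir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(f) written <<- c(written, f)
  site_pct <- round(result$pairing$s * 100, 3)
  wide <- function(mat) {
    df <- data.frame(t = result$times, mat)
    names(df) <- c("t_s", paste0("site_", site_pct, "pct"))
    df
  }
  for (q in c("V", "m", "n", "h")) {
    f <- file.path(outdir, paste0(q, ".csv"))
    write.csv(wide(result[[q]]), f, row.names = FALSE)
    put(f)
  }
  for (nm in names(result$flux)) {
    f <- file.path(outdir, paste0("flux_", nm, ".csv"))
    write.csv(wide(result$flux[[nm]]), f, row.names = FALSE)
    put(f)
  }
  f <- file.path(outdir, "diagnostics.csv")
  write.csv(as.data.frame(result$diagnostics), f, row.names = FALSE)
  put(f)
  for (ck in result$checkpoints) {
    f <- file.path(outdir, sprintf("fields_t%07.3fms.vtk", ck$t * 1000))
    write_vtk_fields(result$mesh, ck, f,
                     work = result_workspace(result))
    put(f)
  }
  f <- file.path(outdir, "provenance.json")
  jsonlite::write_json(result$provenance, f, auto_unbox = TRUE, digits = NA)
  put(f)
  invisible(written)
}

# legacy VTK (ASCII) unstructured grid with nodal fields; concentrations
# are exported on the full mesh with zeros in the membrane region.
write_vtk_fields <- function(mesh, checkpoint, path, work) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(mesh$nodes); nc <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("pnpaxon fields t=%.6g s", checkpoint$t),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", np)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nc, 4 * nc), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(rep("5", nc), con)
  writeLines(sprintf("POINT_DATA %d", np), con)
  fields <- c(list(phi = checkpoint$phi),
              lapply(checkpoint$conc, function(f) {
                v <- numeric(np)
                v[work$sys$I$gnodes] <- f$I
                v[work$sys$E$gnodes] <- f$E
                v
              }))
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", fields[[nm]]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# S3 methods for results
# ---------------------------------------------------------------------------

#' @export
print.tes_result <- function(x, ...) {
  cat(sprintf("TES simulation: %.3g ms, %d outer steps, %d membrane sites\n",
              max(x$times) * 1000, length(x$times) - 1, ncol(x$V)))
  cat(sprintf("  mesh: %d nodes / %d cells ('%s')\n",
              nrow(x$mesh$nodes), nrow(x$mesh$tri), x$mesh$res$preset))
  k <- length(x$times)
  cat(sprintf("  final V range: %.2f .. %.2f mV (rest %.2f mV)\n",
              min(x$V[k, ]), max(x$V[k, ]), x$config$membrane$V_rest))
  invisible(x)
}

#' @export
summary.tes_result <- function(object, ...) {
  k <- length(object$times)
  on_idx <- result_step_index(object,
                              object$config$stepping$t_tes_on * 1e-3)
  pre <- transmembrane_voltage_profile(object, object$times[on_idx])
  post <- transmembrane_voltage_profile(object, object$times[k])
  pct <- percent_polarization_change(pre, post)
  ca0 <- region_total(object, "I", "Ca", object$times[1])$amount
  ca1 <- region_total(object, "I", "Ca", object$times[k])$amount
  out <- list(
    t_end_ms = max(object$times) * 1000,
    V_rest_mean = mean(pre$V),
    V_center_final = post$V[which.min(abs(post$s - 0.5))],
    max_depolarization_pct = max(pct$pct),
    s_max_depolarization = pct$s[which.max(pct$pct)],
    max_hyperpolarization_pct = min(pct$pct),
    s_max_hyperpolarization = pct$s[which.min(pct$pct)],
    Ca_intra_initial = ca0, Ca_intra_final = ca1,
    Ca_intra_change_pct = 100 * (ca1 - ca0) / ca0)
  class(out) <- "summary.tes_result"
  out
}

#' @export
print.summary.tes_result <- function(x, ...) {
  cat(sprintf("TES run, %.3g ms\n", x$t_end_ms))
  cat(sprintf("  resting transmembrane voltage: %.2f mV\n", x$V_rest_mean))
  cat(sprintf("  node-centre V at end of run:   %.2f mV\n", x$V_center_final))
  cat(sprintf("  max depolarization:  %+.2f%% at s = %.3f\n",
              x$max_depolarization_pct, x$s_max_depolarization))
  cat(sprintf("  max hyperpolarization: %+.2f%% at s = %.3f\n",
              x$max_hyperpolarization_pct, x$s_max_hyperpolarization))
  cat(sprintf("  intracellular Ca: %+.2f%% over the run\n",
              x$Ca_intra_change_pct))
  invisible(x)
}

#' Plot per-site voltage traces of a run
#'
#' @param x a `tes_result`.
#' @param k number of equispaced sites to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tes_result <- function(x, k = 11, ...) {
  sites <- membrane_sample_points(x$pairing, k)
  idx <- match(sites$node_intra, x$pairing$node_intra)
  graphics::matplot(x$times * 1000, x$V[, idx], type = "l", lty = 1,
                    xlab = "t (ms)", ylab = "V (mV)",
                    col = grDevices::hcl.colors(length(idx), "Zissou 1"), ...)
  graphics::legend("topright", legend = sprintf("%g%%", sites$s_target * 100),
                   col = grDevices::hcl.colors(length(idx), "Zissou 1"),
                   lty = 1, cex = 0.6, bty = "n")
  invisible(x)
}
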