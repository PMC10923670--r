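#' Run the full experiment matrix
#'
#' Expands `models x cases x Re` at fixed `Wi` in a deterministic order,
#' solves every combination (marching each (model, case) chain through the
#' sorted Reynolds list so continuation states are reused), and collects one
#' [build_metrics()] row per run.  Failed or unconverged runs are recorded
#' with `converged = FALSE`, never dropped.  With an output directory, each
#' run writes its metrics row (CSV), convergence history (CSV) and solution
#' field (VTU) under a content-hashed run id, and completed runs are skipped
#' on re-execution.
#'
#' @param models subset of `c("stenosis", "aneurysm")`.
#' @param cases subset of the four constitutive case tags.
#' @param Re vector of Reynolds numbers.
#' @param Wi Weissenberg number (fixed across the matrix).
#' @param h_far,h_lesion,ny mesh controls.
#' @param Ui inlet mean velocity.
#' @param outdir optional output directory for per-run artifacts.
#' @param n_stations axial sampling density for metrics.
#' @param quiet suppress progress messages.
#' @param ... further [solver_config()] arguments.
#' @return a `MetricsTable` data frame (one row per run).
#' @export
run_matrix <- function(models = c("stenosis", "aneurysm"),
                       cases = c("newtonian", "gen_newtonian", "oldroyd_b",
                                 "gen_oldroyd_b"),
                       Re = c(1000, 2000, 3000), Wi = 0.6,
                       h_far = 0.35, h_lesion = 0.15, ny = NULL, Ui = 0.046,
                       outdir = NULL, n_stations = 400, quiet = TRUE, ...) {
  Re <- sort(unique(Re))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  rows <- list()
  for (model in models) {
    spec <- if (model == "stenosis") stenosis_spec() else aneurysm_spec()
    geom <- build_channel(spec)
    mesh <- mesh_channel(geom, h_far = h_far, h_lesion = h_lesion, ny = ny)
    for (case in cases) {
      st <- NULL
      cc <- case_config(case)
      dof <- dof_map(mesh, elastic = cc$elastic)
      for (re_k in Re) {
        rid <- run_id(model, case, re_k, Wi, h_far, h_lesion, Ui)
        mfile <- if (!is.null(outdir))
          file.path(outdir, paste0(rid, "_metrics.csv")) else NULL
        if (!is.null(mfile) && file.exists(mfile)) {
          rows[[rid]] <- utils::read.csv(mfile, stringsAsFactors = FALSE)
          st <- NULL  # chain broken; next run restarts continuation
          next
        }
        if (!quiet) message(sprintf("run %s/%s Re=%g Wi=%g", model, case,
                                    re_k, Wi))
        row <- tryCatch({
          cfg <- solver_config(Re = re_k, Wi = if (cc$elastic) Wi else 0,
                               case = cc, Ui = Ui, ...)
          st_k <- if (is.null(st)) {
            solve_case(case = cc, Re = re_k, Wi = cfg$Wi, geom = geom,
                       mesh = mesh, Ui = Ui, ...)
          } else {
            s <- newton_solve(mesh, dof, cfg, initial_state = st)
            attr(s, "geom") <- geom; attr(s, "mesh") <- mesh
            s
          }
          st <- st_k
          m <- build_metrics(st_k, geom, mesh, n_stations = n_stations)
          m$error <- NA_character_
          if (!is.null(outdir)) {
            write_state_vtu(st_k, mesh, file.path(outdir,
                                                  paste0(rid, ".vtu")))
            utils::write.csv(attr(st_k, "history"),
                             file.path(outdir, paste0(rid, "_history.csv")),
                             row.names = FALSE)
          }
          m
        }, error = function(e) {
          failed_metrics_row(model, case, re_k, Wi, conditionMessage(e))
        })
        if (!is.null(mfile)) utils::write.csv(row, mfile, row.names = FALSE)
        rows[[rid]] <- row
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("metrics_table", "data.frame")
  out
}

run_id <- function(model, case, Re, Wi, h_far, h_lesion, Ui) {
  key <- sprintf("%s|%s|%.10g|%.10g|%.10g|%.10g|%.10g", model, case, Re, Wi,
                 h_far, h_lesion, Ui)
  tf <- tempfile()
  writeLines(key, tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  sprintf("%s_%s_re%g_%s", model, substr(case, 1, 6), Re, substr(h, 1, 8))
}

failed_metrics_row <- function(model, case, Re, Wi, msg) {
  data.frame(model = model, case = case, Re = Re, Wi = Wi, converged = FALSE,
             iterations = NA_integer_, umax = NA_real_, x_umax = NA_real_,
             umin_between = NA_real_, umin_masked = NA_real_,
             x_umin_masked = NA_real_, u_mean_between = NA_real_,
             vel_pct_dev = NA_real_, vel_pct_dev_between = NA_real_,
             vel_pct_dev_masked = NA_real_, pmin_between = NA_real_,
             pmax_between = NA_real_, x_pmin_between = NA_real_,
             pmin_span = NA_real_, pmax_span = NA_real_, p_pct_dev = NA_real_,
             wss_max = NA_real_, wss_max_x = NA_real_, wss_min = NA_real_,
             wss_min_x = NA_real_, recirc_extent = NA_real_,
             n_recirc = NA_integer_, error = msg, stringsAsFactors = FALSE)
}

#' Reference values reported for this configuration family
#'
#' Curated table of the published reference values that [reference_report()]
#' compares against: per-case velocity percent deviations for both models,
#' the generalized Oldroyd-B axial velocity and pressure extrema at
#' Re = 1000, Wi = 0.6, and the Reynolds-sweep extrema of the between-lesion
#' mean velocity.
#'
#' @return data frame `model`, `case`, `quantity`, `reference`.
#' @export
reference_values <- function() {
  rbind(
    data.frame(model = "stenosis",
               case = c("newtonian", "gen_newtonian", "oldroyd_b",
                        "gen_oldroyd_b"),
               quantity = "vel_pct_dev",
               reference = c(20.94, 23.52, 20.95, 27.33)),
    data.frame(model = "aneurysm",
               case = c("newtonian", "gen_newtonian", "oldroyd_b",
                        "gen_oldroyd_b"),
               quantity = "vel_pct_dev",
               reference = c(3.19, 8.32, 7.19, 8.72)),
    data.frame(model = "stenosis", case = "gen_oldroyd_b",
               quantity = c("umax", "umin_between", "pmin_between",
                            "pmax_between"),
               reference = c(0.1478, 0.1074, -14.25, -5.11)),
    data.frame(model = "aneurysm", case = "gen_oldroyd_b",
               quantity = c("pmin_span", "pmax_span"),
               reference = c(-0.35, 0.86)),
    data.frame(model = c("stenosis", "stenosis", "aneurysm", "aneurysm"),
               case = "sweep",
               quantity = c("max_u_mean_between", "min_u_mean_between",
                            "max_u_mean_between", "min_u_mean_between"),
               reference = c(0.152, 0.133, 0.072, 0.056)))
}

#' Side-by-side comparison report
#'
#' Joins the computed metrics of a run matrix against [reference_values()]:
#' per-case velocity percent deviations at Re = 1000, the generalized
#' Oldroyd-B extrema, and (when the matrix covers several Reynolds numbers)
#' the sweep extrema of the between-lesion mean velocity.  Discrepancy
#' columns are filled only where both a computed and a reference value
#' exist.
#'
#' @param metrics a [run_matrix()] result.
#' @param Re_main Reynolds number of the main comparison (default 1000).
#' @return data frame with `computed`, `reference`, `rel_discrepancy_pct`.
#' @export
reference_report <- function(metrics, Re_main = 1000) {
  stopifnot(is.data.frame(metrics))
  main <- metrics[metrics$Re == Re_main & metrics$converged, , drop = FALSE]
  rows <- list()
  grab <- function(model, case, quantity) {
    r <- main[main$model == model & main$case == case, , drop = FALSE]
    if (nrow(r) != 1 || is.null(r[[quantity]])) return(NA_real_)
    r[[quantity]]
  }
  ref <- reference_values()
  for (k in seq_len(nrow(ref))) {
    model <- ref$model[k]; case <- ref$case[k]; qty <- ref$quantity[k]
    comp <- if (case == "sweep") {
      sw <- metrics[metrics$model == model & metrics$converged, , drop = FALSE]
      if (length(unique(sw$Re)) < 2) NA_real_
      else if (qty == "max_u_mean_between") max(sw$u_mean_between)
      else min(sw$u_mean_between)
    } else grab(model, case, qty)
    rows[[k]] <- data.frame(model = model, case = case, quantity = qty,
                            computed = comp, reference = ref$reference[k],
                            rel_discrepancy_pct = if (is.na(comp)) NA_real_
                            else 100 * abs(comp - ref$reference[k]) /
                              abs(ref$reference[k]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("<metrics_table: %d runs>\n", nrow(x)))
  cols <- intersect(c("model", "case", "Re", "Wi", "converged", "umax",
                      "umin_between", "vel_pct_dev", "pmin_between",
                      "wss_max"), names(x))
  print.data.frame(x[, cols, drop = FALSE], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot an axial profile or WSS curve
#'
#' Base-graphics diagnostic plots used by the command-line front end.
#'
#' @param x an `axial_profile` or `wss_curve`.
#' @param which `"speed"` or `"p"` for axial profiles.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.axial_profile <- function(x, which = c("speed", "p"), ...) {
  which <- match.arg(which)
  graphics::plot(x$x, x[[which]], type = "l", xlab = "x",
                 ylab = if (which == "speed") "|U| on axis" else "p on axis",
                 ...)
  w <- attr(x, "windows")
  if (!is.null(w)) graphics::abline(v = w$between, lty = 3)
  invisible(x)
}

#' @rdname plot.axial_profile
#' @export
plot.wss_curve <- function(x, ...) {
  graphics::plot(x$x, x$wss, type = "l", xlab = "x (bottom wall)",
                 ylab = "WSS", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
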