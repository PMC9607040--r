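# Parametric sweeps reproducing the model's figure studies, plus the shipped
# figure recipes and optional plotting.

#' Define a parameter sweep
#'
#' @param fixed A \code{\link{flow_params}} object (or coercible mapping)
#'   giving the parameters held fixed.
#' @param sweep_param Name of the swept parameter (one of \code{"alpha"},
#'   \code{"reynolds"}, \code{"chi"}, \code{"lambda1"}, \code{"epsilon"}), or
#'   \code{"none"} for a single-point sweep.
#' @param sweep_values Finite, non-empty numeric vector of swept values.
#' @param observable One of \code{"G"}, \code{"mean_u"}, \code{"Q"},
#'   \code{"d_wall"}.
#' @param grid Abscissa grid: \code{y} points for the profile observables
#'   (\code{"G"}, \code{"mean_u"}), \code{alpha} values for the wall/flux
#'   observables (\code{"Q"}, \code{"d_wall"}); strictly monotone.
#' @param variants Character vector of constitutive variants to run.
#' @return An object of class \code{"sweep_spec"}.
#' @export
sweep_spec <- function(fixed, sweep_param = "none", sweep_values = NA_real_,
                       observable = c("G", "mean_u", "Q", "d_wall"),
                       grid = NULL, variants = c("linear", "ucm")) {
  observable <- match.arg(observable)
  fixed <- as_flow_params(fixed)
  if (!sweep_param %in% c("none", "alpha", "reynolds", "chi", "lambda1", "epsilon"))
    stop("unknown sweep parameter: ", sweep_param)
  if (sweep_param != "none") {
    if (length(sweep_values) == 0L || any(!is.finite(sweep_values)))
      stop("'sweep_values' must be finite and non-empty")
  }
  if (is.null(grid)) {
    grid <- if (observable %in% c("G", "mean_u")) seq(0, 1, length.out = 101)
            else seq(0.01, 2, length.out = 200)
  }
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing")
  variants <- match.arg(variants, c("linear", "ucm"), several.ok = TRUE)
  structure(list(fixed = fixed, sweep_param = sweep_param,
                 sweep_values = sweep_values, observable = observable,
                 grid = grid, variants = variants),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Evaluates the selected observable over the cartesian product of swept
#' values, abscissa grid and variants.  Parameter points where the solve
#' fails (e.g. degenerate modes) are reported with a warning and skipped; an
#' error is raised only if more than half of the points fail.
#'
#' @param spec A \code{\link{sweep_spec}}.
#' @return A long-format data frame of class \code{"sweep_result"} with
#'   columns \code{param}, \code{param_value}, \code{variant}, \code{x} (the
#'   abscissa: \code{y} for profiles, \code{alpha} otherwise), \code{observable}
#'   and \code{value}; fixed parameters and tolerances are attached as the
#'   \code{"metadata"} attribute.  Output is deterministic for a fixed spec.
#' @examples
#' sp <- sweep_spec(flow_params(0.5, 10, chi = 0.3), "lambda1", c(0, 0.5),
#'                  observable = "G", grid = seq(0, 1, length.out = 11))
#' head(run_sweep(sp))
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  vals <- if (spec$sweep_param == "none") NA_real_ else spec$sweep_values
  rows <- list(); failed <- 0L; total <- 0L
  for (v in vals) for (variant in spec$variants) {
    pl <- unclass(spec$fixed)
    pl$variant <- variant
    if (spec$sweep_param != "none") pl[[spec$sweep_param]] <- v
    if (spec$observable %in% c("G", "mean_u")) {
      total <- total + 1L
      res <- tryCatch({
        ob <- observables(as_flow_params(pl))
        val <- if (spec$observable == "G") ob$G(spec$grid) else ob$mean_u(spec$grid)
        data.frame(param = spec$sweep_param, param_value = v,
                   variant = variant, x = spec$grid,
                   observable = spec$observable, value = val)
      }, peristream_error = function(e) {
        warning(sprintf("sweep point failed (%s = %g, %s): %s",
                        spec$sweep_param, v, variant, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) failed <- failed + 1L else rows[[length(rows) + 1L]] <- res
    } else {
      for (a in spec$grid) {
        total <- total + 1L
        pl$alpha <- a
        res <- tryCatch({
          ob <- observables(as_flow_params(pl))
          val <- if (spec$observable == "Q") ob$Q else ob$d_wall
          data.frame(param = spec$sweep_param, param_value = v,
                     variant = variant, x = a,
                     observable = spec$observable, value = val)
        }, peristream_error = function(e) {
          warning(sprintf("sweep point failed (alpha = %g, %s): %s",
                          a, variant, conditionMessage(e)))
          NULL
        })
        if (is.null(res)) failed <- failed + 1L else rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (failed > total / 2)
    ps_error("peristream_sweep_error",
             sprintf("%d of %d sweep points failed", failed, total))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "metadata") <- list(fixed = unclass(spec$fixed),
                                observable = spec$observable,
                                variants = spec$variants,
                                n_failed = failed)
  class(out) <- c("sweep_result", class(out))
  out
}

# -- figure recipes ---------------------------------------------------------

#' Shipped figure recipes
#'
#' Returns the configuration of one of the parametric-study figures as a
#' \code{\link{sweep_spec}}.  Fixed parameter values are transcribed from the
#' figure captions; where a caption does not list the set of swept relaxation
#' times, a documented default set is used (overridable via
#' \code{sweep_values}).  Recipes are also shipped as YAML files under
#' \code{system.file("recipes", package = "peristream")}.
#'
#' @param name Recipe name: \code{"fig2"} ... \code{"fig9"} (profile recipes
#'   run both variants; panel (a) is the linear model, (b) upper convected).
#' @param sweep_values Optional override of the swept value set.
#' @param grid Optional override of the abscissa grid.
#' @return A \code{\link{sweep_spec}}.
#' @examples
#' figure_recipe("fig2")
#' @export
figure_recipe <- function(name, sweep_values = NULL, grid = NULL) {
  path <- system.file("recipes", paste0(name, ".yaml"), package = "peristream")
  if (path == "") stop("unknown recipe: ", name, "; see list_figure_recipes()")
  read_sweep_config(path, sweep_values = sweep_values, grid = grid)
}

#' @rdname figure_recipe
#' @export
list_figure_recipes <- function() {
  sort(sub("\\.yaml$", "",
           list.files(system.file("recipes", package = "peristream"),
                      pattern = "\\.yaml$")))
}

#' Read a sweep configuration from a YAML file
#'
#' The file is a flat mapping with keys \code{alpha}, \code{reynolds},
#' \code{chi}, \code{lambda1}, \code{epsilon} (the fixed parameters),
#' \code{sweep_param}, \code{sweep_values}, \code{observable},
#' \code{grid_from}/\code{grid_to}/\code{grid_n} (or explicit \code{grid}),
#' and \code{variants}.
#'
#' @param path YAML file path.
#' @param sweep_values,grid Optional overrides.
#' @return A \code{\link{sweep_spec}}.
#' @export
read_sweep_config <- function(path, sweep_values = NULL, grid = NULL) {
  cfg <- yaml::read_yaml(path)
  fixed <- as_flow_params(cfg[intersect(names(cfg),
            c("alpha", "reynolds", "chi", "lambda1", "epsilon"))])
  if (is.null(grid)) {
    grid <- if (!is.null(cfg$grid)) as.numeric(cfg$grid)
            else if (!is.null(cfg$grid_from))
              seq(cfg$grid_from, cfg$grid_to, length.out = cfg$grid_n)
            else NULL
  }
  sweep_spec(fixed,
             sweep_param = cfg$sweep_param %||% "none",
             sweep_values = sweep_values %||% as.numeric(cfg$sweep_values),
             observable = cfg$observable,
             grid = grid,
             variants = cfg$variants %||% c("linear", "ucm"))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sweep result to CSV
#'
#' Comma-separated, header row, '.' decimal separator.
#'
#' @param result A \code{"sweep_result"} data frame.
#' @param path Output file path.
#' @return The result, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(result)
}

#' Render sweep results as figures
#'
#' Purely presentational: one image per observable/variant panel, drawn with
#' ggplot2 when available.
#'
#' @param result A \code{"sweep_result"} data frame.
#' @param outdir Output directory for PNG files.
#' @param prefix File name prefix.
#' @return Character vector of written file paths (empty, with a warning, if
#'   the result has no rows or ggplot2 is unavailable).
#' @export
render_figures <- function(result, outdir = ".", prefix = "sweep") {
  if (is.null(result) || nrow(result) == 0L) {
    warning("empty sweep result; no figures rendered")
    return(character(0))
  }
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; no figures rendered")
    return(character(0))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  obs <- result$observable[1]
  xlab <- if (obs %in% c("G", "mean_u")) "y" else "alpha"
  files <- character(0)
  for (variant in unique(result$variant)) {
    d <- result[result$variant == variant, , drop = FALSE]
    d$curve <- factor(d$param_value)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value,
                                         colour = .data$curve)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = xlab, y = obs, colour = d$param[1],
                    title = sprintf("%s (%s Maxwell)", obs, variant)) +
      ggplot2::theme_minimal()
    f <- file.path(outdir, sprintf("%s_%s_%s.png", prefix, obs, variant))
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 150)
    files <- c(files, f)
  }
  files
}
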