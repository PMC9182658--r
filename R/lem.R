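# Latent Ergonomics Maps.
#
# A LEM is a height-map over the 2-D latent posture space: the latent
# square is sampled on a uniform grid, every grid point is decoded to a
# posture, the normalization is inverted, and the ergonomics score of the
# reconstructed posture becomes the map height. One map per score kind.
# Recorded motions are projected onto the map by encoding each frame.

#' Uniform latent grid
#'
#' @param resolution cells per axis (>= 2).
#' @param bounds `c(min, max)` per axis; the default [-1, 1] matches the
#'   tanh-bounded latent.
#' @return list of class `lem_grid` with cell-center coordinates `z1`,
#'   `z2`.
#' @export
latent_grid <- function(resolution = 100, bounds = c(-1, 1)) {
  if (resolution < 2) stop("resolution must be at least 2")
  if (bounds[2] <= bounds[1]) stop("bounds must be ordered")
  z <- seq(bounds[1], bounds[2], length.out = resolution)
  structure(list(z1 = z, z2 = z, resolution = resolution, bounds = bounds),
            class = "lem_grid")
}

#' Score kinds available for maps
#'
#' `rula`: discrete grand score (1-7). `rula_c`: continuous grand score
#' [1, 7]. `torque`: mean absolute quasi-static joint torque (N m) from
#' inverse dynamics with the foot-wrench approximation. `manipulability`:
#' right-arm endpoint manipulability from the shoulder chain.
#'
#' @return character vector of the recognized kinds.
#' @export
score_kinds <- function() c("rula", "rula_c", "torque", "manipulability")

# Evaluate one score kind on a matrix of raw joint vectors.
score_postures <- function(Q, kind, model = lemr_model(),
                           fit = rula_c_fit(), load = 0) {
  kind <- match.arg(kind, score_kinds())
  if (kind == "rula") return(as.numeric(rula(Q, load = load, model = model)))
  if (kind == "rula_c") return(rula_c(Q, load = load, model = model,
                                      fit = fit))
  if (is.null(dim(Q))) Q <- matrix(Q, 1)
  vapply(seq_len(nrow(Q)), function(i) {
    p <- posture(Q[i, ])
    if (kind == "torque") {
      tau <- inverse_dynamics(model, dyn_state(p), quasi_static = TRUE)
      mean(abs(tau))
    } else {
      manipulability(model, p, "hand_r", from = "t8")
    }
  }, 0)
}

#' Build a Latent Ergonomics Map
#'
#' For every cell of the latent grid: decode the latent point to a
#' normalized posture, invert the normalization, and evaluate the
#' ergonomics score of the reconstructed posture. The default 100 x 100
#' grid gives a 10,000-cell map.
#'
#' @param params trained `vae_params`.
#' @param norm the `lem_norm` the training data was normalized with.
#' @param kind one of [score_kinds()].
#' @param grid a [latent_grid()].
#' @param model a `lem_skeleton`.
#' @param fit a `rula_c_model` (for the RULA-based kinds).
#' @param load handled load (kg) passed to the RULA scorers.
#' @return object of class `lem_map`: `grid`, `scores`
#'   (resolution x resolution matrix, rows indexing z1), `kind`.
#' @export
build_lem <- function(params, norm, kind = "rula_c",
                      grid = latent_grid(), model = lemr_model(),
                      fit = rula_c_fit(), load = 0) {
  kind <- match.arg(kind, score_kinds())
  if (!inherits(norm, "lem_norm")) stop("norm must be a lem_norm")
  cells <- as.matrix(expand.grid(z1 = grid$z1, z2 = grid$z2))
  Xh <- vae_decode(params, cells)
  Q <- denormalize_postures(Xh, norm)
  sc <- score_postures(Q, kind, model, fit, load)
  scores <- matrix(sc, grid$resolution, grid$resolution)
  structure(list(grid = grid, scores = scores, kind = kind,
                 norm = norm), class = "lem_map")
}

#' @export
print.lem_map <- function(x, ...) {
  cat("Latent Ergonomics Map (", x$kind, "): ", x$grid$resolution, " x ",
      x$grid$resolution, " = ", length(x$scores), " cells, scores in [",
      sprintf("%.2f, %.2f", min(x$scores), max(x$scores)), "]\n", sep = "")
  invisible(x)
}

# nearest cell indices for latent points (clamped to the grid)
nearest_cell <- function(grid, Z) {
  idx <- function(zax, v) {
    i <- findInterval(v, zax, all.inside = TRUE)
    i + (v - zax[i] > zax[i + 1] - v)
  }
  cbind(idx(grid$z1, pmin(pmax(Z[, 1], grid$bounds[1]), grid$bounds[2])),
        idx(grid$z2, pmin(pmax(Z[, 2], grid$bounds[1]), grid$bounds[2])))
}

#' Project a motion onto a map
#'
#' Encodes every frame of a motion to its latent posterior mean and reads
#' the map score at the enclosing (nearest) cell. Encoded points outside
#' the grid bounds are clamped to the border cell.
#'
#' @param params trained `vae_params`.
#' @param motion a `lem_motion` (raw joint angles) or a T x n_dof matrix.
#' @param map a `lem_map` (provides grid and normalization).
#' @return object of class `lem_trace`: `time`, `Z` (T x 2 latent means),
#'   `scores` (map score per frame), `cells` (T x 2 cell indices).
#' @export
project_trace <- function(params, motion, map) {
  if (inherits(motion, "lem_motion")) {
    Q <- motion$Q; tt <- motion$time
  } else {
    Q <- motion; tt <- seq_len(NROW(motion))
  }
  if (NROW(Q) == 0) stop("empty motion")
  X <- pmin(pmax(normalize_postures(Q, map$norm), 0), 1)
  Z <- vae_encode(params, X)$mu
  cells <- nearest_cell(map$grid, Z)
  structure(list(time = tt, Z = Z, scores = map$scores[cells],
                 cells = cells), class = "lem_trace")
}

#' @export
print.lem_trace <- function(x, ...) {
  cat("Latent trace: ", length(x$time), " points, scores in [",
      sprintf("%.2f, %.2f", min(x$scores), max(x$scores)), "]\n", sep = "")
  invisible(x)
}

# discrete triadic bands for RULA action levels: 1-2 green, 3-4 yellow,
# 5-7 red
rula_band_value <- function(s) ifelse(s <= 2, 0, ifelse(s <= 4, 0.5, 1))

#' Render a map (and optional trace) to a PNG image and numeric export
#'
#' Colors the map with the triadic green-yellow-red code: discrete bands
#' for the RULA map (scores 1-2 green, 3-4 yellow, 5-7 red, following the
#' RULA action levels), continuous colors for the other kinds (min-max
#' normalized over the map). The trace, if given, is overlaid in magenta.
#' Alongside the image, the numeric map is written as delimited text
#' (columns z1, z2, score).
#'
#' @param map a `lem_map`.
#' @param path_png output image path.
#' @param trace optional `lem_trace`.
#' @param path_csv optional numeric export path (default: image path with
#'   a `.csv` extension).
#' @param scale integer pixel scale per cell.
#' @return invisibly, the RGB array written.
#' @export
render_lem <- function(map, path_png, trace = NULL, path_csv = NULL,
                       scale = 4) {
  res <- map$grid$resolution
  if (map$kind == "rula") {
    v <- rula_band_value(map$scores)
  } else {
    rng <- range(map$scores)
    v <- if (rng[2] > rng[1])
      (map$scores - rng[1]) / (rng[2] - rng[1]) else map$scores * 0
    # manipulability: high capability is good -> invert so red = poor
    if (map$kind == "manipulability") v <- 1 - v
  }
  cols <- score_to_color(as.numeric(v)) / 255
  img <- array(0, c(res, res, 3))
  # image rows top-to-bottom = z2 descending; columns = z1 ascending
  for (ch in 1:3)
    img[, , ch] <- t(matrix(cols[, ch], res, res))[res:1, ]
  if (!is.null(trace)) {
    for (k in seq_len(nrow(trace$cells))) {
      r <- res + 1 - trace$cells[k, 2]; cc <- trace$cells[k, 1]
      img[r, cc, ] <- c(1, 0, 1)      # magenta
    }
  }
  if (scale > 1) {
    big <- array(0, c(res * scale, res * scale, 3))
    ri <- rep(seq_len(res), each = scale)
    for (ch in 1:3) big[, , ch] <- img[ri, ri, ch]
    img <- big
  }
  png::writePNG(img, path_png)
  if (is.null(path_csv)) path_csv <- sub("\\.png$", ".csv", path_png)
  cells <- expand.grid(z1 = map$grid$z1, z2 = map$grid$z2)
  utils::write.csv(data.frame(z1 = cells$z1, z2 = cells$z2,
                              score = as.numeric(map$scores)),
                   path_csv, row.names = FALSE)
  invisible(img)
}

#' Save / load a map as delimited text
#' @param map a `lem_map`.
#' @param path file path (`.csv`).
#' @return `read_lem_csv` returns a data.frame (z1, z2, score).
#' @export
write_lem_csv <- function(map, path) {
  cells <- expand.grid(z1 = map$grid$z1, z2 = map$grid$z2)
  utils::write.csv(data.frame(z1 = cells$z1, z2 = cells$z2,
                              score = as.numeric(map$scores)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lem_csv
#' @export
read_lem_csv <- function(path) utils::read.csv(path)
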