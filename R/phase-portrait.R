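# Analytic Jacobian of (dF/dt, dM/dt) with respect to counts (F, M).
# At F = 0 the F-row reduces to (gF, 0) and similarly for M, so axis fixed
# points have a triangular Jacobian whose diagonal gives the within-axis and
# transverse eigenvalues exactly.
circuit_jacobian <- function(F, M, p) {
  fF <- log(F + 1)
  fM <- log(M + 1)
  g <- per_capita_rates(fF, fM, p)
  d <- per_capita_rate_grad(fF, fM, p)
  matrix(c(g$gF + F * d$gF_fF / (F + 1), F * d$gF_fM / (M + 1),
           M * d$gM_fF / (F + 1),        g$gM + M * d$gM_fM / (M + 1)),
         nrow = 2, byrow = TRUE)
}

# Roots of the on-axis per-capita growth p_self * f * (1 - f / K) - r on
# (0, f_max]: a quadratic in f, solved in closed form.
axis_roots <- function(p_self, r, K, f_max) {
  a <- -p_self / K
  b <- p_self
  cc <- -r
  if (abs(a) < 1e-300) {
    if (abs(b) < 1e-300) return(numeric(0))
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    # round-off guard: a tangency (double root) can leave disc barely < 0
    if (disc < 0 && disc > -1e-10 * max(b^2, abs(4 * a * cc))) disc <- 0
    if (disc < 0) return(numeric(0))
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  sort(roots[roots > 1e-9 & roots <= f_max])
}

# Newton refinement of an interior root of (gF, gM) = 0 in f-space.
interior_newton <- function(fF, fM, p, max_iter = 60, tol = 1e-13) {
  for (i in seq_len(max_iter)) {
    g <- per_capita_rates(fF, fM, p)
    if (!is.finite(g$gF) || !is.finite(g$gM)) return(NULL)
    if (max(abs(g$gF), abs(g$gM)) < tol) break
    d <- per_capita_rate_grad(fF, fM, p)
    J <- matrix(c(d$gF_fF, d$gF_fM, d$gM_fF, d$gM_fM), 2, byrow = TRUE)
    det_j <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (!is.finite(det_j) || abs(det_j) < 1e-14) return(NULL)
    step <- solve(J, c(g$gF, g$gM))
    fF <- fF - step[1]
    fM <- fM - step[2]
    if (!is.finite(fF) || !is.finite(fM)) return(NULL)
  }
  g <- per_capita_rates(fF, fM, p)
  if (max(abs(g$gF), abs(g$gM)) < 1e-11 && fF > 1e-9 && fM > 1e-9) {
    c(fF = fF, fM = fM)
  } else {
    NULL
  }
}

#' Find the fixed points of the circuit
#'
#' Locates all fixed points of the two-population model in the rectangle
#' `f in [0, f_max]` per axis (default `1.5 * K`, beyond which proliferation
#' is non-positive and no fixed points exist). The origin is always a fixed
#' point. Axis fixed points are roots of the on-axis quadratic
#' `p_XX f (1 - f/K_X) - r_X = 0` (closed form); interior fixed points are
#' found by sign-change scanning of the nullcline system on a grid followed
#' by Newton refinement, with duplicates merged.
#'
#' Each point is classified from the eigenvalues of the analytic Jacobian in
#' count space (real-part tolerance 1e-8):
#' * both real parts negative: stable; class is the position label `OFF`
#'   (origin), `ON` (interior), `ON_OFF` (F-axis) or `OFF_ON` (M-axis);
#' * on an axis, attracting within the axis but neutral or repelling
#'   transverse to it: `SEMI_STABLE`;
#' * otherwise `UNSTABLE`.
#'
#' @param params A [circuit_params()] object.
#' @param f_max Upper limit of the search domain per axis in f-units; default
#'   `1.5 * max(K_F, K_M)`.
#' @param grid_n Resolution of the interior sign-change scan.
#' @return A tibble with one row per fixed point: counts `F`, `M`, log-scale
#'   coordinates `fF`, `fM`, eigenvalues `eig1`, `eig2` (complex), `position`
#'   (`"off"`, `"on"`, `"on_off"`, `"off_on"`), `stability` (`"stable"`,
#'   `"semi_stable"`, `"unstable"`) and `class` (the six-way label).
#' @export
#' @examples
#' find_fixed_points(preset_params("control"))
find_fixed_points <- function(params, f_max = NULL, grid_n = 80) {
  p <- as_circuit_params(params)
  if (is.null(f_max)) f_max <- 1.5 * max(p$K_F, p$K_M)
  pts <- list(c(fF = 0, fM = 0))
  for (f in axis_roots(p$p_FF, p$r_F, p$K_F, f_max)) {
    pts[[length(pts) + 1]] <- c(fF = f, fM = 0)
  }
  for (f in axis_roots(p$p_MM, p$r_M, p$K_M, f_max)) {
    pts[[length(pts) + 1]] <- c(fF = 0, fM = f)
  }
  # interior: scan cells of a grid for simultaneous sign changes
  fs <- seq(f_max / grid_n, f_max, length.out = grid_n)
  gr <- expand.grid(fF = fs, fM = fs)
  g <- per_capita_rates(gr$fF, gr$fM, p)
  sF <- matrix(sign(g$gF), grid_n, grid_n)
  sM <- matrix(sign(g$gM), grid_n, grid_n)
  chg <- function(s) {
    (s[-grid_n, -grid_n] != s[-1, -grid_n]) |
      (s[-grid_n, -grid_n] != s[-grid_n, -1]) |
      (s[-grid_n, -grid_n] != s[-1, -1])
  }
  hit <- which(chg(sF) & chg(sM), arr.ind = TRUE)
  for (h in seq_len(nrow(hit))) {
    root <- interior_newton(fs[hit[h, 1]] + 0.5 * (fs[2] - fs[1]),
                            fs[hit[h, 2]] + 0.5 * (fs[2] - fs[1]), p)
    if (!is.null(root) && root[1] <= f_max + 1e-6 && root[2] <= f_max + 1e-6) {
      pts[[length(pts) + 1]] <- root
    }
  }
  mat <- do.call(rbind, pts)
  keep <- !duplicated(round(mat, 6))
  mat <- mat[keep, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    fF <- unname(mat[i, 1])
    fM <- unname(mat[i, 2])
    Fc <- exp(fF) - 1
    Mc <- exp(fM) - 1
    classify_fixed_point(Fc, Mc, p)
  }) |>
    dplyr::arrange(.data$fF, .data$fM)
}

#' Classify the stability of a fixed point
#'
#' Computes the Jacobian eigenvalues at a fixed point of the circuit and
#' assigns position, stability and the combined class label (see
#' [find_fixed_points()] for the rules).
#'
#' @param F,M Fixed-point coordinates in cell counts.
#' @param params A [circuit_params()] object.
#' @return A one-row tibble as in [find_fixed_points()].
#' @export
classify_fixed_point <- function(F, M, params) {
  p <- as_circuit_params(params)
  tol <- 1e-8
  J <- circuit_jacobian(F, M, p)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  fF <- log(F + 1)
  fM <- log(M + 1)
  on_F_axis <- M < 1e-9
  on_M_axis <- F < 1e-9
  position <- if (on_F_axis && on_M_axis) "off"
              else if (on_F_axis) "on_off"
              else if (on_M_axis) "off_on"
              else "on"
  if (all(Re(ev) < -tol)) {
    stability <- "stable"
    class <- toupper(position)
  } else if (on_F_axis || on_M_axis) {
    # axis Jacobian is triangular: diagonal entries are the within-axis and
    # transverse eigenvalues
    within <- c(if (on_F_axis) J[1, 1], if (on_M_axis) J[2, 2])
    transv <- c(if (on_F_axis) J[2, 2], if (on_M_axis) J[1, 1])
    if (on_F_axis && on_M_axis) {            # origin: directions are the axes
      within <- min(diag(J))
      transv <- max(diag(J))
    }
    if (all(within < -tol) && all(transv >= -tol)) {
      stability <- "semi_stable"
      class <- "SEMI_STABLE"
    } else {
      stability <- "unstable"
      class <- "UNSTABLE"
    }
  } else {
    stability <- "unstable"
    class <- "UNSTABLE"
  }
  tibble::tibble(F = F, M = M, fF = fF, fM = fM,
                 eig1 = as.complex(ev[1]), eig2 = as.complex(ev[2]),
                 position = position, stability = stability, class = class)
}

#' Nullclines of the circuit
#'
#' Zero-level curves of each population's net per-capita growth rate over a
#' grid in f-space (`f = log(count + 1)`), extracted with
#' `grDevices::contourLines`, plus the coordinate-axis branches (`F = 0` is
#' always a fibroblast nullcline, `M = 0` a macrophage nullcline).
#'
#' @param params A [circuit_params()] object.
#' @param f_max Grid upper limit in f-units (default `1.5 * max(K_F, K_M)`).
#' @param grid_n Grid resolution per axis.
#' @return A tibble with columns `cell_type` (`"F"` or `"M"`), `branch`
#'   (curve id within type; `"axis"` for the axis branches), `fF`, `fM`.
#' @export
compute_nullclines <- function(params, f_max = NULL, grid_n = 201) {
  p <- as_circuit_params(params)
  if (is.null(f_max)) f_max <- 1.5 * max(p$K_F, p$K_M)
  fs <- seq(0, f_max, length.out = grid_n)
  gr <- expand.grid(fF = fs, fM = fs)
  g <- per_capita_rates(gr$fF, gr$fM, p)
  out <- list()
  for (ct in c("F", "M")) {
    z <- matrix(if (ct == "F") g$gF else g$gM, grid_n, grid_n)
    cl <- grDevices::contourLines(x = fs, y = fs, z = z, levels = 0)
    for (i in seq_along(cl)) {
      out[[length(out) + 1]] <- tibble::tibble(
        cell_type = ct, branch = as.character(i),
        fF = cl[[i]]$x, fM = cl[[i]]$y)
    }
  }
  axes <- dplyr::bind_rows(
    tibble::tibble(cell_type = "F", branch = "axis", fF = 0, fM = fs),
    tibble::tibble(cell_type = "M", branch = "axis", fF = fs, fM = 0))
  dplyr::bind_rows(dplyr::bind_rows(out), axes)
}

#' Per-capita growth-rate field
#'
#' Net per-capita growth rates of both cell types over a rectangular grid of
#' the phase plane. Sign changes of each field occur exactly on the
#' corresponding nullcline.
#'
#' @param params A [circuit_params()] object.
#' @param f_max Grid upper limit in f-units (default `1.5 * max(K_F, K_M)`).
#' @param grid_n Grid resolution per axis.
#' @return A tibble with columns `fF`, `fM`, counts `F`, `M`, and per-capita
#'   rates `gF`, `gM` (per day).
#' @export
growth_rate_field <- function(params, f_max = NULL, grid_n = 50) {
  p <- as_circuit_params(params)
  if (is.null(f_max)) f_max <- 1.5 * max(p$K_F, p$K_M)
  fs <- seq(0, f_max, length.out = grid_n)
  gr <- expand.grid(fF = fs, fM = fs)
  g <- per_capita_rates(gr$fF, gr$fM, p)
  tibble::tibble(fF = gr$fF, fM = gr$fM,
                 F = exp(gr$fF) - 1, M = exp(gr$fM) - 1,
                 gF = g$gF, gM = g$gM)
}

#' Basins of attraction
#'
#' Integrates the circuit forward from a grid of initial conditions and
#' labels each cell by the attracting fixed point (stable or semi-stable)
#' nearest to the trajectory endpoint in f-space. Cells whose endpoint is not
#' within `unresolved_tol` of any attractor are labeled `"UNKNOWN"`.
#'
#' @param params A [circuit_params()] object.
#' @param fixed_points Optional precomputed [find_fixed_points()] table.
#' @param f_max Grid upper limit in f-units.
#' @param grid_n Basin grid resolution per axis.
#' @param t_end Integration horizon in days.
#' @param unresolved_tol Maximum f-space distance to an attractor.
#' @return A tibble with columns `fF0`, `fM0`, `F0`, `M0`, and `basin` (the
#'   class label of the reached attractor, by position for semi-stable
#'   points: e.g. `"OFF"`, `"ON"`, `"ON_OFF"`, `"OFF_ON"`, or `"UNKNOWN"`).
#' @export
find_basins <- function(params, fixed_points = NULL, f_max = NULL,
                        grid_n = 21, t_end = 200, unresolved_tol = 0.5) {
  p <- as_circuit_params(params)
  if (is.null(f_max)) f_max <- 1.5 * max(p$K_F, p$K_M)
  if (is.null(fixed_points)) fixed_points <- find_fixed_points(p, f_max)
  attr_pts <- dplyr::filter(fixed_points,
                            .data$stability %in% c("stable", "semi_stable"))
  fs <- seq(0, f_max, length.out = grid_n)
  gr <- expand.grid(fF0 = fs, fM0 = fs)
  labels <- character(nrow(gr))
  for (i in seq_len(nrow(gr))) {
    tr <- simulate_circuit(p, F0 = exp(gr$fF0[i]) - 1, M0 = exp(gr$fM0[i]) - 1,
                           t_end = t_end, dt_out = t_end)
    end <- tr[nrow(tr), ]
    if (nrow(attr_pts) == 0) {
      labels[i] <- "UNKNOWN"
      next
    }
    d <- sqrt((log(end$F + 1) - attr_pts$fF)^2 +
              (log(end$M + 1) - attr_pts$fM)^2)
    labels[i] <- if (min(d) <= unresolved_tol) {
      toupper(attr_pts$position[which.min(d)])
    } else {
      "UNKNOWN"
    }
  }
  tibble::tibble(fF0 = gr$fF0, fM0 = gr$fM0,
                 F0 = exp(gr$fF0) - 1, M0 = exp(gr$fM0) - 1, basin = labels)
}

#' Full phase portrait of a circuit
#'
#' Convenience wrapper computing fixed points, nullclines, the per-capita
#' growth-rate field and (optionally) basins of attraction for one parameter
#' set.
#'
#' @param params A [circuit_params()] object.
#' @param f_max Domain upper limit in f-units (default `1.5 * max(K_F, K_M)`).
#' @param grid_n Field/nullcline grid resolution.
#' @param basins Compute basins of attraction? (slowest step)
#' @param basin_n Basin grid resolution per axis.
#' @param t_end Basin integration horizon in days.
#' @return An object of class `phase_portrait`: a list with elements
#'   `params`, `fixed_points`, `nullclines`, `field`, `basins` (NULL if not
#'   requested) and `f_max`.
#' @export
#' @examples
#' pp <- phase_portrait(preset_params("control"), basins = FALSE)
#' pp$fixed_points
phase_portrait <- function(params, f_max = NULL, grid_n = 101, basins = TRUE,
                           basin_n = 21, t_end = 200) {
  p <- as_circuit_params(params)
  if (is.null(f_max)) f_max <- 1.5 * max(p$K_F, p$K_M)
  fp <- find_fixed_points(p, f_max)
  structure(list(
    params = p,
    fixed_points = fp,
    nullclines = compute_nullclines(p, f_max, grid_n = max(grid_n, 101)),
    field = growth_rate_field(p, f_max, grid_n = grid_n),
    basins = if (basins) find_basins(p, fp, f_max, grid_n = basin_n,
                                     t_end = t_end) else NULL,
    f_max = f_max), class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat("<phase_portrait>\n")
  cat("  fixed points:\n")
  print(x$fixed_points[, c("F", "M", "position", "stability", "class")])
  if (!is.null(x$basins)) {
    cat("  basin composition:\n")
    print(table(x$basins$basin))
  }
  invisible(x)
}

#' @rdname phase_portrait
#' @param x A `phase_portrait` object.
#' @param ... Unused.
#' @export
tidy.phase_portrait <- function(x, ...) {
  x$fixed_points
}
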