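#' Parameters of the two-cell fibroblast-macrophage growth circuit
#'
#' The circuit couples two cell populations, fibroblasts (F) and macrophages
#' (M), through growth-factor exchange. After the fast growth-factor dynamics
#' are collapsed to quasi-steady state, each population keeps four effective
#' parameters: an autocrine and a paracrine proliferation coefficient, a
#' removal rate, and a carrying capacity on the log-count scale.
#'
#' Proliferation of population X is
#' `(p_XX * f(X) + p_YX * f(Y)) * (1 - f(X) / K_X)` with
#' `f(X) = log(X + 1)`, so carrying capacities `K_F`, `K_M` are in log cell
#' numbers and proliferation shuts off as `f(X)` approaches `K_X`.
#'
#' @param p_FF,p_MM Autocrine proliferation coefficients (per day per
#'   log-count unit) of fibroblasts and macrophages. May be negative
#'   (inhibitory).
#' @param p_MF Paracrine effect of macrophages on fibroblast proliferation.
#' @param p_FM Paracrine effect of fibroblasts on macrophage proliferation.
#' @param r_F,r_M Removal rates (per day), non-negative.
#' @param K_F,K_M Carrying capacities in log-count units, strictly positive.
#'
#' @return An object of class `circuit_params`: a named list of the eight
#'   rates.
#' @seealso [preset_params()] for documented regimes, [growth_rates()],
#'   [discrete_map()], [phase_portrait()].
#' @export
#' @examples
#' p <- circuit_params(p_FF = 0.6, p_FM = 0.3, r_F = 0.3, r_M = 0.8,
#'                     K_F = 9, K_M = 11.3)
#' tidy(p)
circuit_params <- function(p_FF = 0, p_MF = 0, p_FM = 0, p_MM = 0,
                           r_F = 0, r_M = 0, K_F = 1, K_M = 1) {
  p <- list(p_FF = p_FF, p_MF = p_MF, p_FM = p_FM, p_MM = p_MM,
            r_F = r_F, r_M = r_M, K_F = K_F, K_M = K_M)
  ok <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
               logical(1))
  if (!all(ok)) {
    stop("all circuit parameters must be finite numeric scalars; bad: ",
         paste(names(p)[!ok], collapse = ", "), call. = FALSE)
  }
  if (p$r_F < 0 || p$r_M < 0) {
    stop("removal rates r_F, r_M must be non-negative", call. = FALSE)
  }
  if (p$K_F <= 0 || p$K_M <= 0) {
    stop("carrying capacities K_F, K_M must be strictly positive",
         call. = FALSE)
  }
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 5), " = ",
             formatC(v, digits = 4, format = "g"), collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname circuit_params
#' @param x A `circuit_params` object (for `tidy()`).
#' @param ... Unused.
#' @export
tidy.circuit_params <- function(x, ...) {
  tibble::tibble(parameter = names(unlist(x)), value = unname(unlist(x)))
}

#' Coerce a named list or vector to circuit parameters
#'
#' @param x A `circuit_params` object, or a named list/vector containing the
#'   eight parameter names used by [circuit_params()].
#' @return A `circuit_params` object.
#' @export
as_circuit_params <- function(x) {
  if (inherits(x, "circuit_params")) return(x)
  x <- as.list(x)
  need <- c("p_FF", "p_MF", "p_FM", "p_MM", "r_F", "r_M", "K_F", "K_M")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("missing circuit parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  do.call(circuit_params, lapply(x[need], as.numeric))
}
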