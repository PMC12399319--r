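## Integral projection model with discrete seedling and adult stages.
##
## State vector: (S, n(z_1) ... n(z_m), A) — a discrete seedling class, m
## midpoint size bins for vegetative plants, and a discrete reproductive
## class that dies after reproduction (monocarpy).  One kernel is built per
## (year, zone) cell from the vital-rate model predictions for that cell
## plus the zone's pooled recruitment ratio.

#' Extended size bounds for the IPM mesh
#'
#' Observed ln-size bounds `[L, U]`, extended on each side to make room for
#' the growth and new-size distributions.  `mode = "range"` (default)
#' extends by `extend` times the observed range on each side; `mode =
#' "endpoint"` extends each endpoint by `extend` times its own magnitude.
#'
#' @param sizes Numeric vector of observed ln sizes (or a
#'   [build_transitions()] table, from which all `size_t0`/`size_t1`
#'   values are taken).
#' @param extend Fraction to extend by (default 0.2).
#' @param mode `"range"` or `"endpoint"`.
#' @return `c(L, U)` of the extended bounds.
#' @examples
#' size_bounds(c(1, 2, 3))  # c(0.6, 3.4)
#' @export
size_bounds <- function(sizes, extend = 0.2, mode = c("range", "endpoint")) {
  mode <- match.arg(mode)
  if (is.data.frame(sizes)) {
    sizes <- c(sizes$size_t0, sizes$size_t1)
  }
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) < 2L) stop_dunesync("need >= 2 observed sizes")
  L <- min(sizes); U <- max(sizes)
  if (L == U) stop_dunesync("degenerate size range: all sizes equal")
  if (mode == "range") {
    r <- U - L
    c(L - extend * r, U + extend * r)
  } else {
    c(L - extend * abs(L), U + extend * abs(U))
  }
}

## Discretize a Normal density at mesh midpoints and renormalize each
## column to mass exactly 1 (truncation / eviction correction).
discretized_normal <- function(mesh, h, mean, sd) {
  dens <- outer(mesh, mean, function(zp, mu) stats::dnorm(zp, mu, sd)) * h
  cs <- colSums(dens)
  if (any(cs <= 0)) stop_dunesync("growth/new-size density has zero mass on the mesh")
  sweep(dens, 2, cs, "/")
}

#' Assemble one (year, zone) IPM kernel
#'
#' Builds the `(m+2) x (m+2)` iteration matrix ordered (seedling, size
#' bins, adult) by midpoint-rule discretization over `m` equal bins on
#' `bounds`:
#' * seedling column: `s1 * d(z')` into the size bins;
#' * size-bin column `z`: `s2(z) (1 - a(z)) G(z', z)` into the size bins
#'   and `s2(z) a(z)` into the adult row;
#' * adult column: `r` into the seedling row (adults die after
#'   reproduction).
#' Growth and new-size kernels are Gaussian in `z'`, discretized and
#' column-renormalized to mass one, so no probability is evicted past the
#' bounds.
#'
#' @param components Named list with `s1` (scalar survival probability),
#'   `s2`, `a` (vectors over the mesh, or scalars), `g_mean` (vector over
#'   the mesh, or a function of the mesh), `g_sd`, `d_mean`, `d_sd`
#'   (scalars), and `r` (recruits per reproductive adult).
#' @param bounds `c(L, U)` mesh bounds (see [size_bounds()]).
#' @param m Number of size bins (default 200).
#' @param year,zone Optional labels stored on the kernel.
#' @return An object of class `ipm_kernel`: list with the iteration
#'   `matrix`, `mesh` midpoints, bin width `h`, the evaluated
#'   `components`, and labels.
#' @examples
#' k <- build_kernel(list(s1 = 0.5, s2 = 0.8, a = 0.25,
#'                        g_mean = function(z) 0.5 + 0.85 * z, g_sd = 0.2,
#'                        d_mean = 1.3, d_sd = 0.35, r = 2),
#'                   bounds = c(0, 4), m = 50)
#' growth_rate(k)$lambda
#' @export
build_kernel <- function(components, bounds, m = 200L, year = NA, zone = NA) {
  cmp <- components
  need <- c("s1", "s2", "a", "g_mean", "g_sd", "d_mean", "d_sd", "r")
  missing <- setdiff(need, names(cmp))
  if (length(missing)) {
    stop_dunesync("kernel components missing: ", paste(missing, collapse = ", "))
  }
  if (bounds[2] <= bounds[1]) stop_dunesync("bounds must satisfy L < U")
  m <- as.integer(m)
  h <- (bounds[2] - bounds[1]) / m
  mesh <- bounds[1] + (seq_len(m) - 0.5) * h

  expand <- function(x) if (length(x) == 1L) rep(x, m) else x
  s2 <- expand(if (is.function(cmp$s2)) cmp$s2(mesh) else cmp$s2)
  a <- expand(if (is.function(cmp$a)) cmp$a(mesh) else cmp$a)
  g_mean <- expand(if (is.function(cmp$g_mean)) cmp$g_mean(mesh) else cmp$g_mean)
  vals <- c(cmp$s1, s2, a, g_mean, cmp$g_sd, cmp$d_mean, cmp$d_sd, cmp$r)
  if (any(!is.finite(vals))) stop_dunesync("non-finite kernel component")
  if (cmp$s1 < 0 || cmp$s1 > 1 || any(s2 < 0 | s2 > 1) || any(a < 0 | a > 1) ||
      cmp$r < 0 || cmp$g_sd <= 0 || cmp$d_sd <= 0) {
    stop_dunesync("kernel component out of range")
  }

  G <- discretized_normal(mesh, h, g_mean, cmp$g_sd)
  dvec <- drop(discretized_normal(mesh, h, cmp$d_mean, cmp$d_sd))

  K <- matrix(0, m + 2L, m + 2L)
  K[2:(m + 1L), 1L] <- cmp$s1 * dvec
  K[2:(m + 1L), 2:(m + 1L)] <- sweep(G, 2, s2 * (1 - a), "*")
  K[m + 2L, 2:(m + 1L)] <- s2 * a
  K[1L, m + 2L] <- cmp$r

  structure(list(matrix = K, mesh = mesh, h = h, bounds = bounds, m = m,
                 components = list(s1 = cmp$s1, s2 = s2, a = a,
                                   g_mean = g_mean, g_sd = cmp$g_sd,
                                   d_mean = cmp$d_mean, d_sd = cmp$d_sd,
                                   d = dvec, G = G, r = cmp$r),
                 year = year, zone = zone),
            class = "ipm_kernel")
}

#' @export
print.ipm_kernel <- function(x, ...) {
  cat(sprintf("<ipm_kernel %dx%d, bounds [%.3g, %.3g]%s>\n",
              x$m + 2L, x$m + 2L, x$bounds[1], x$bounds[2],
              if (!is.na(x$year)) sprintf(", year %s zone %s", x$year, x$zone)
              else ""))
  invisible(x)
}

#' Asymptotic population growth rate by iteration
#'
#' Iterates the kernel on a population vector until the total growth ratio
#' converges; for a primitive kernel this is the dominant eigenvalue.
#'
#' @param kernel An [build_kernel()] object (or a plain square matrix).
#' @param tol Convergence tolerance on successive growth ratios
#'   (default 1e-8).
#' @param max_iter Maximum iterations (default 1e5).
#' @return List with `lambda`, the converged stage `structure` vector
#'   (summing to one), and `iterations`.  Errors if not converged.
#' @export
growth_rate <- function(kernel, tol = 1e-8, max_iter = 1e5L) {
  K <- if (inherits(kernel, "ipm_kernel")) kernel$matrix else kernel
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  v <- rep(1 / nrow(K), nrow(K))
  lam_prev <- NA_real_
  for (i in seq_len(max_iter)) {
    w <- K %*% v
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0) {
      stop_dunesync("population vector collapsed during iteration")
    }
    lam <- tot / sum(v)
    v <- as.numeric(w / tot)
    if (!is.na(lam_prev) && abs(lam - lam_prev) < tol) {
      return(list(lambda = lam, structure = v, iterations = i))
    }
    lam_prev <- lam
  }
  stop_dunesync("growth rate did not converge in ", max_iter, " iterations")
}

#' Kernel components for one (year, zone) cell from fitted vital rates
#'
#' Evaluates the five fitted vital-rate models at a (year, zone) cell over
#' a mesh and assembles the cell's kernel.
#'
#' @param fits Named list of [fit_vital_rate()] objects for `S1, S2, G, A,
#'   D`.
#' @param r_zone Pooled recruitment ratio for the zone (see
#'   [recruitment()]).
#' @param year,zone Cell labels.
#' @param bounds,m Mesh specification.
#' @return An `ipm_kernel`.
#' @export
cell_kernel <- function(fits, r_zone, year, zone, bounds, m = 200L) {
  stopifnot(all(RATES %in% names(fits)))
  h <- (bounds[2] - bounds[1]) / m
  mesh <- bounds[1] + (seq_len(m) - 0.5) * h
  build_kernel(list(
    s1 = predict_cell(fits$S1, year, zone),
    s2 = predict_cell(fits$S2, rep(year, m), rep(zone, m), mesh),
    a = predict_cell(fits$A, rep(year, m), rep(zone, m), mesh),
    g_mean = predict_cell(fits$G, rep(year, m), rep(zone, m), mesh),
    g_sd = fits$G$sigma,
    d_mean = predict_cell(fits$D, year, zone),
    d_sd = fits$D$sigma,
    r = r_zone
  ), bounds = bounds, m = m, year = year, zone = zone)
}

#' Zone-by-year table of asymptotic growth rates
#'
#' Builds the kernel and computes lambda for every (year, zone) cell at
#' which all five vital-rate fits have predictions; cells missing from any
#' fit are `NA`.
#'
#' @inheritParams cell_kernel
#' @param recruit Named per-zone recruitment vector ([recruitment()]).
#' @param transitions Transition table used to set the mesh bounds.
#' @param ... Passed to [size_bounds()].
#' @return Numeric matrix of lambda values, zones x years.
#' @export
lambda_table <- function(fits, recruit, transitions, m = 200L, ...) {
  bounds <- size_bounds(transitions, ...)
  all_cells <- lapply(fits[RATES], function(f)
    paste(f$cells$year, f$cells$zone, sep = ":"))
  years <- sort(unique(as.character(fits$S2$cells$year)))
  zones <- sort(unique(as.character(fits$S2$cells$zone)))
  out <- matrix(NA_real_, length(zones), length(years),
                dimnames = list(zone = zones, year = years))
  for (z in zones) for (y in years) {
    key <- paste(y, z, sep = ":")
    if (!all(vapply(all_cells, function(k) key %in% k, logical(1)))) next
    k <- cell_kernel(fits, recruit[[z]], y, z, bounds, m)
    out[z, y] <- growth_rate(k)$lambda
  }
  out
}
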