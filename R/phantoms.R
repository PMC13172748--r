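# Digital phantoms with closed-form oracles. A voxel belongs to a digital
# sphere iff its center lies within the analytic radius; voxelized volumes
# converge to the analytic ones as spacing shrinks (relative error < 1% at
# 0.1 cm spacing for radii >= 1 cm).

#' Digital sphere mask
#'
#' @param radius sphere radius in cm, `> 0`.
#' @param center physical center in cm (length 3), default grid center.
#' @param spacing isotropic voxel spacing in cm, or a length-3 vector.
#' @param grid_shape voxel counts per axis; by default sized so the sphere
#'   fits with `pad` cm of margin on every side.
#' @param pad margin in cm kept around the sphere when auto-sizing the grid
#'   (leave room for expansions and displaced companions). Default 1 cm.
#' @return A [mask_volume()].
#' @export
sphere_mask <- function(radius, center = NULL, spacing = 0.1,
                        grid_shape = NULL, pad = 1.0) {
  if (!is.numeric(radius) || radius <= 0)
    stop("`radius` must be positive (cm)", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(grid_shape)) {
    half <- radius + pad
    grid_shape <- 2L * as.integer(ceiling(half / spacing)) + 1L
  }
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (is.null(center)) center <- (grid_shape - 1) / 2 * spacing
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * spacing[a])
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  # tolerance swamps FP noise in the squared radii so boundary voxels are
  # included consistently wherever the sphere sits on the grid
  inside <- r2 <= radius^2 + 1e-9
  if (!any(inside))
    stop("grid too small: sphere contains no voxel centers", call. = FALSE)
  if (radius > min(center, (grid_shape - 1) * spacing - center))
    stop("grid too small: sphere of radius ", radius,
         " cm does not fit inside the grid", call. = FALSE)
  mask_volume(inside, spacing)
}

#' Concentric sphere phantom pair (uniform expansion)
#'
#' A standard sphere of radius `r0` and a concentric reference sphere of
#' radius `r0 + margin` — the idealised "reference drawn by uniformly
#' expanding the standard" scenario. The standard is contained in the
#' reference, so the entire non-overlap lies on the reference side.
#'
#' @param r0 standard sphere radius in cm. Default 2 cm (a mid-range GTV,
#'   about 33.5 cm^3).
#' @param margin expansion margin in cm, `>= 0`.
#' @param spacing voxel spacing in cm. Default 0.1 cm.
#' @param pad extra grid margin in cm beyond the reference radius.
#' @return A list with [mask_volume()] elements `std` and `ref`, plus the
#'   analytic volumes `V_std_analytic` and `V_ref_analytic` in cm^3.
#' @export
make_sphere_pair_uniform <- function(r0 = 2.0, margin = 0.6, spacing = 0.1,
                                     pad = 1.0) {
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  ref <- sphere_mask(r0 + margin, spacing = spacing, pad = pad)
  ctr <- (dim(ref$grid) - 1) / 2 * ref$spacing
  std <- sphere_mask(r0, center = ctr, spacing = spacing,
                     grid_shape = dim(ref$grid))
  list(std = std, ref = ref,
       V_std_analytic = 4 * pi / 3 * r0^3,
       V_ref_analytic = 4 * pi / 3 * (r0 + margin)^3)
}

#' Displaced sphere phantom pair
#'
#' A standard sphere of radius `r0` and a reference sphere of radius
#' `r_ref` whose center is displaced by `offset` — the "same reference
#' volume, different spatial relationship" scenario. With `r_ref = r0 +
#' margin` the reference volume matches the concentric pair's, but part of
#' the discrepant volume now lies farther from the standard, so for any
#' positive distance penalty the equivalent-volume coefficients drop while
#' the classic ones stay equal or lower.
#'
#' @param r0 standard sphere radius in cm.
#' @param r_ref reference sphere radius in cm.
#' @param offset displacement of the reference center in cm; a single
#'   number (applied along the first axis) or a length-3 vector.
#' @param spacing voxel spacing in cm. Default 0.1 cm.
#' @param pad extra grid margin in cm.
#' @return A list with [mask_volume()] elements `std` and `ref`.
#' @export
make_sphere_pair_displaced <- function(r0 = 2.0, r_ref = 2.6, offset = 0.6,
                                       spacing = 0.1, pad = 1.0) {
  offset <- as.numeric(offset)
  if (length(offset) == 1L) offset <- c(offset, 0, 0)
  if (length(offset) != 3L)
    stop("`offset` must be a single number or a length-3 vector (cm)",
         call. = FALSE)
  spacing3 <- rep_len(as.numeric(spacing), 3L)
  half <- max(r0, r_ref) + max(abs(offset)) + pad
  shape <- 2L * as.integer(ceiling(half / spacing3)) + 1L
  ctr <- (shape - 1) / 2 * spacing3
  std <- sphere_mask(r0, center = ctr, spacing = spacing, grid_shape = shape)
  ref <- sphere_mask(r_ref, center = ctr + offset, spacing = spacing,
                     grid_shape = shape)
  list(std = std, ref = ref)
}

#' Closed-form equivalent volume of a spherical shell
#'
#' The analytic oracle for the sphere phantoms: the equivalent volume of the
#' shell between radii `r0` and `r1`, whose distance to the inner sphere is
#' `r - r0`, is `integral(r0..r1) 4 pi r^2 ((r - r0)/d_r)^n dr`, evaluated
#' in closed form for `n` in 0, 1, 2.
#'
#' @param r0 inner radius in cm, `> 0`.
#' @param r1 outer radius in cm, `>= r0`.
#' @param d_r reference distance in cm. Default 1.
#' @param n penalty exponent: 0, 1, or 2.
#' @return Equivalent volume in cm^3 (`n = 0` gives the plain shell volume).
#' @examples
#' shell_ev_oracle(2, 2.6, n = 0)  # 40.11 cm^3, the shell volume
#' shell_ev_oracle(2, 2.6, n = 1)  # 13.07 cm^3
#' @export
shell_ev_oracle <- function(r0, r1, d_r = 1.0, n = 1) {
  if (!is.numeric(r0) || !is.numeric(r1) || r0 <= 0 || r1 < r0)
    stop("need r1 >= r0 > 0", call. = FALSE)
  if (!n %in% c(0, 1, 2))
    stop("closed forms are provided for n in {0, 1, 2}", call. = FALSE)
  F <- switch(as.character(n),
    "0" = function(r) r^3 / 3,
    "1" = function(r) (r^4 / 4 - r0 * r^3 / 3) / d_r,
    "2" = function(r) (r^5 / 5 - 2 * r0 * r^4 / 4 + r0^2 * r^3 / 3) / d_r^2)
  4 * pi * (F(r1) - F(r0))
}

#' Specification for a synthetic linear-gradient DVH
#'
#' Parameters of the generative model behind [synthesize_dvh()]: a
#' cumulative whole-body DVH whose rapid fall-off region follows the linear
#' dose-gradient law `PCT = B0 + B1 * d_PCT` exactly, anchored at a
#' prescription (100%) isodose volume of equivalent radius `R100`.
#'
#' @param B0 model intercept in percent (`> 100` for realistic VMAT plans:
#'   the fall-off trend extrapolates slightly above the prescription).
#'   Default 101.637, the bundled cohort mean.
#' @param B1 model slope in percent/cm, `< 0`. Default -28.369, the bundled
#'   cohort mean.
#' @param R100 equivalent-sphere radius of the 100% isodose volume in cm.
#'   Default 2 cm.
#' @param pct_span sampled dose range in percent, `low < high <= 100`.
#'   Default `c(48, 100)`, the rapid fall-off region.
#' @param sample_step sampling step in percent. Default 2.
#' @param noise_sd multiplicative volume noise (SD as a fraction of each
#'   volume). Default 0 (noiseless).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return An object of class `dvh_generator_spec`.
#' @export
dvh_generator_spec <- function(B0 = 101.637, B1 = -28.369, R100 = 2.0,
                               pct_span = c(48, 100), sample_step = 2,
                               noise_sd = 0, seed = 1L) {
  if (!is.numeric(B1) || B1 >= 0) stop("`B1` must be negative", call. = FALSE)
  if (!is.numeric(R100) || R100 <= 0)
    stop("`R100` must be positive (cm)", call. = FALSE)
  if (length(pct_span) != 2L || pct_span[1] >= pct_span[2])
    stop("`pct_span` must be (low, high) with low < high", call. = FALSE)
  if (pct_span[2] > 100)
    stop("`pct_span` must not exceed the 100% prescription level",
         call. = FALSE)
  if (pct_span[2] > B0)
    stop("`pct_span` upper end exceeds B0: the model gives negative ",
         "fall-off distances there", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(B0 = B0, B1 = B1, R100 = R100, pct_span = pct_span,
                 sample_step = sample_step, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "dvh_generator_spec")
}

#' Synthesise a cumulative DVH from the linear dose-gradient model
#'
#' Inverts the equivalent-sphere construction: for each sampled level
#' `pct < 100`, the fall-off distance is `d = (pct - B0) / B1`, the
#' equivalent radius `R = R100 + d`, and the covered volume
#' `(4 pi / 3) R^3`. The 100% level is the anchor knot with volume
#' `(4 pi / 3) R100^3` — the prescription plateau at which the linear
#' sub-prescription trend breaks, as in measured VMAT DVHs (which is why
#' fitted intercepts exceed 100). Optional multiplicative Gaussian noise is
#' applied to the sub-prescription volumes under the spec's seed (the
#' caller's RNG state is preserved), and cumulativity is restored by a
#' running maximum.
#'
#' @param spec a [dvh_generator_spec()].
#' @return A [dvh_curve()]. Noiseless output round-trips through
#'   [fit_gradient()] to the generating `B0`, `B1` at machine precision.
#' @export
synthesize_dvh <- function(spec) {
  stopifnot(inherits(spec, "dvh_generator_spec"))
  pct <- seq(spec$pct_span[1], spec$pct_span[2], by = spec$sample_step)
  if (max(pct) < 100) pct <- c(pct, 100)
  below <- pct[pct < 100]
  d <- (below - spec$B0) / spec$B1
  if (any(d <= 0))
    stop("span produces non-positive fall-off distances", call. = FALSE)
  vol_below <- 4 * pi / 3 * (spec$R100 + d)^3
  if (spec$noise_sd > 0) {
    vol_below <- with_preserved_seed(spec$seed, {
      vol_below * (1 + stats::rnorm(length(vol_below), sd = spec$noise_sd))
    })
    vol_below <- pmax(vol_below, 0)
  }
  vol100 <- 4 * pi / 3 * spec$R100^3
  pct_all <- c(below, 100)
  vol_all <- c(vol_below, vol100)
  # restore cumulativity (only noise can break it): volume must be
  # non-increasing in pct, so take the running max from high dose downward
  vol_all <- rev(cummax(rev(vol_all)))
  dvh_curve(pct_all, vol_all)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
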