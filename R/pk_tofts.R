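#' Fit the linearised extended Tofts model voxel-wise
#'
#' Estimates per-voxel pharmacokinetic parameters from a DCE concentration
#' series by ordinary least squares on the linearised extended Tofts form
#' \deqn{C_t(t_i) = a \int_0^{t_i} C_p \, d\tau + b \int_0^{t_i} C_t \, d\tau
#'   + c \, C_p(t_i),}
#' with cumulative trapezoidal integrals, recovering
#' \eqn{k_{ep} = -b}, \eqn{v_p = c}, \eqn{K^{trans} = a - k_{ep} v_p} and
#' \eqn{v_e = K^{trans}/k_{ep}}. The regression is deterministic — no
#' starting values, no iteration.
#'
#' Voxels whose solution is unphysical (negative \eqn{k_{ep}} or
#' \eqn{K^{trans}}, volume fractions outside \eqn{[0,1]}) are flagged
#' `fit_ok = FALSE` and left unclipped unless `clip = TRUE`, in which case
#' parameters are clipped into range and the flag records the original
#' violation. A tissue curve that is identically (numerically) zero is the
#' valid null solution: all parameters 0, `fit_ok = TRUE`.
#'
#' @param series a `dce_series` (see [simulate_dce()]): 4-D concentration
#'   array, times in minutes, AIF on the same grid.
#' @param mask 0/1 array of voxels to fit (matching the spatial grid).
#' @param clip if `TRUE`, clip out-of-range parameters into
#'   \eqn{k_{ep}, K^{trans} \ge 0}, \eqn{v_e, v_p \in [0, 1]}.
#' @return A `pk_maps` object: arrays `ktrans`, `kep`, `ve`, `vp`,
#'   `residual` (RMS fit error) and logical `fit_ok`, plus the `mask`.
#' @export
fit_extended_tofts <- function(series, mask, clip = FALSE) {
  times <- series$times
  if (length(times) < 4L) abort("need at least 4 time points")
  d4 <- dim(series$data)
  d <- d4[seq_len(3)]
  if (!all(dim(mask) == d)) abort("mask grid does not match the DCE series")
  vox <- which(mask > 0)
  if (!length(vox)) abort("mask is empty")
  cp <- series$aif
  nt <- length(times)
  zero <- function(v) array(v, d)
  maps <- list(ktrans = zero(0), kep = zero(0), ve = zero(0), vp = zero(0),
               residual = zero(0), fit_ok = array(FALSE, d))

  int_cp <- cumtrapz_vec(times, cp)
  if (max(abs(cp)) == 0) {
    warn("AIF is identically zero: design is singular, all voxels flagged")
    maps$mask <- mask
    return(structure(maps, class = "pk_maps"))
  }
  flat <- matrix(series$data, prod(d), nt)
  ct_scale <- max(abs(flat[vox, , drop = FALSE]))
  tol0 <- 1e-10 * max(ct_scale, max(cp))

  for (v in vox) {
    ct <- flat[v, ]
    if (max(abs(ct)) <= tol0) { # null tissue: exact zero solution
      maps$fit_ok[v] <- TRUE
      next
    }
    X <- cbind(int_cp, cumtrapz_vec(times, ct), cp)
    fit <- stats::.lm.fit(X, ct)
    if (fit$rank < 3L) { # degenerate design (e.g., exactly collinear columns)
      maps$residual[v] <- sqrt(mean(ct^2))
      next
    }
    co <- fit$coefficients[order(fit$pivot)]
    a <- co[1]; b <- co[2]
    cc <- co[3]
    kep <- -b
    vp <- cc
    ktrans <- a - kep * vp
    ve <- if (kep > 1e-12) ktrans / kep else 0
    ok <- kep >= -1e-8 && ktrans >= -1e-8 && vp >= -1e-8 && vp <= 1 + 1e-8 &&
      ve >= -1e-8 && ve <= 1 + 1e-8
    if (clip) {
      kep <- max(kep, 0); ktrans <- max(ktrans, 0)
      vp <- min(max(vp, 0), 1); ve <- min(max(ve, 0), 1)
    }
    maps$ktrans[v] <- ktrans; maps$kep[v] <- kep
    maps$ve[v] <- ve; maps$vp[v] <- vp
    maps$residual[v] <- sqrt(mean(fit$residuals^2))
    maps$fit_ok[v] <- ok
  }
  maps$mask <- mask
  structure(maps, class = "pk_maps")
}

# cumulative trapezoidal integral of y over x, starting at 0
cumtrapz_vec <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' @export
print.pk_maps <- function(x, ...) {
  n <- sum(x$mask > 0)
  cat(sprintf("<pk_maps> %d fitted voxels, %d flagged ok (%.1f%%)\n",
              n, sum(x$fit_ok), 100 * sum(x$fit_ok) / max(n, 1)))
  ok <- x$fit_ok
  if (any(ok)) {
    cat(sprintf("  median K-trans %.3f min^-1, k-ep %.3f min^-1, ve %.3f, vp %.3f\n",
                median(x$ktrans[ok]), median(x$kep[ok]),
                median(x$ve[ok]), median(x$vp[ok])))
  }
  invisible(x)
}

#' Export pharmacokinetic maps as image volumes
#'
#' Unpacks a `pk_maps` object into named `image_volume`s on the source grid;
#' voxels that were not fitted (or failed the physical-range check) carry 0
#' in the parameter volumes and are identified by the `fit_ok` volume.
#'
#' @param maps a `pk_maps` object from [fit_extended_tofts()].
#' @param spacing voxel spacing for the exported volumes (mm).
#' @param ok_only zero out voxels with `fit_ok = FALSE` (default `TRUE`).
#' @return Named list of `image_volume`s: `ktrans`, `kep`, `ve`, `vp`,
#'   `fit_ok`.
#' @export
pk_maps_to_volumes <- function(maps, spacing = c(1, 1, 1), ok_only = TRUE) {
  out <- lapply(c("ktrans", "kep", "ve", "vp"), function(nm) {
    arr <- maps[[nm]]
    if (ok_only) arr[!maps$fit_ok] <- 0
    image_volume(arr, spacing)
  })
  names(out) <- c("ktrans", "kep", "ve", "vp")
  out$fit_ok <- image_volume(maps$fit_ok + 0, spacing)
  out
}
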