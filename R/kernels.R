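# The six smoothing kernels compared for local polynomial interpolation.
# All satisfy K(0) = 1 and are nonincreasing on [0, h]; the exponential and
# Gaussian kinds use the e^-3 bandwidth scaling so that the bandwidth is a
# practical support scale, the remaining four have compact support [0, h].

KERNEL_KINDS <- c("exponential", "polynomial5", "gaussian", "epanechnikov",
                  "quartic", "constant")

#' Kernel specification
#'
#' @param kind one of `"exponential"`, `"polynomial5"`, `"gaussian"`,
#'   `"epanechnikov"`, `"quartic"`, `"constant"`.
#' @param bandwidth bandwidth `h` in metres, `> 0`.
#' @return Object of class `mk_kernel`.
#' @export
kernel_spec <- function(kind = KERNEL_KINDS, bandwidth = 50) {
  kind <- match.arg(kind)
  if (bandwidth <= 0) mk_stop("bandwidth must be > 0")
  structure(list(kind = kind, bandwidth = bandwidth), class = "mk_kernel")
}

#' @export
print.mk_kernel <- function(x, ...) {
  cat(sprintf("<mk_kernel %s, h = %g m>\n", x$kind, x$bandwidth))
  invisible(x)
}

#' Evaluate a kernel
#'
#' `exponential: exp(-3 r/h)`; `gaussian: exp(-3 (r/h)^2)`;
#' `quartic: (1-(r/h)^2)^2`, `epanechnikov: 1-(r/h)^2`,
#' `polynomial5: 1-(r/h)^5` and `constant: 1`, the last four for `r <= h`
#' and 0 beyond.
#'
#' @param spec an [kernel_spec()].
#' @param r distances `>= 0` (vectorised; `Inf` allowed, giving weight 0).
#' @return Weights in `[0, 1]`.
#' @export
kernel_value <- function(spec, r) {
  stopifnot(inherits(spec, "mk_kernel"))
  if (any(r < 0, na.rm = TRUE)) mk_stop("kernel radius must be >= 0")
  u <- r / spec$bandwidth
  w <- switch(spec$kind,
    exponential  = exp(-3 * u),
    gaussian     = exp(-3 * u^2),
    polynomial5  = ifelse(u <= 1, 1 - u^5, 0),
    epanechnikov = ifelse(u <= 1, 1 - u^2, 0),
    quartic      = ifelse(u <= 1, (1 - u^2)^2, 0),
    constant     = ifelse(u <= 1, 1, 0))
  w[!is.finite(r)] <- 0
  w
}

# Distance beyond which the kernel weight is negligible; used to trim
# neighbourhoods.  Compact kernels end at h; the two infinite-support kinds
# are cut at 3h (weight <= e^-9).
kernel_cutoff <- function(spec) {
  if (spec$kind %in% c("exponential", "gaussian")) 3 * spec$bandwidth
  else spec$bandwidth
}
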