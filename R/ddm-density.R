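#' Wiener first-passage-time density
#'
#' Density of the decision time at one absorbing boundary of a Wiener
#' diffusion with boundary separation `a`, relative starting point `z_rel`
#' (fraction of `a` above the lower boundary), drift `v`, and diffusion
#' coefficient 1. The density is evaluated through the two classical series
#' expansions — a small-time sum over reflected Gaussian images and a
#' large-time Fourier sine series — switching per time point to whichever
#' needs fewer terms for a truncation error below `eps`.
#'
#' Times are decision times (non-decision time already removed); `t0` in
#' `params` is ignored here.
#'
#' @param t positive decision times, seconds.
#' @param params a [ddm_params()] object.
#' @param drift drift rate `v`; scalar or vector matching `t`.
#' @param boundary `"upper"` (yes/eat) or `"lower"` (no/refuse).
#' @param eps series truncation tolerance.
#' @return vector of densities, nonnegative.
#' @examples
#' p <- ddm_params(a = 1.5, z_rel = 0.5, t0 = 0)
#' wiener_fpt_density(0.5, p, drift = 0, boundary = "upper")
#' @export
wiener_fpt_density <- function(t, params, drift, boundary = c("upper", "lower"),
                               eps = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"))
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("decision times must be finite and > 0", call. = FALSE)
  }
  n <- max(length(t), length(drift))
  t <- rep_len(t, n)
  v <- rep_len(drift, n)
  a <- params$a
  w <- params$z_rel
  if (boundary == "upper") {
    # first passage at the upper boundary equals lower-boundary passage of
    # the mirrored process
    v <- -v
    w <- 1 - w
  }
  tau <- t / a^2
  dens <- exp(-v * a * w - v^2 * t / 2) / a^2 * .fpt_density_std(tau, w, eps)
  pmax(dens, 0)
}

# Standardized (a = 1, v = 0) lower-boundary FPT density at scaled time tau,
# start w. Chooses the cheaper series per element.
.fpt_density_std <- function(tau, w, eps = 1e-7) {
  n <- length(tau)
  out <- numeric(n)

  # required series lengths (Navarro-Fuss style error bounds)
  ks <- rep(2, n)
  big_s <- 2 * sqrt(2 * pi * tau) * eps < 1
  ks[big_s] <- 2 + sqrt(-2 * tau[big_s] *
                          log(2 * sqrt(2 * pi * tau[big_s]) * eps))
  ks <- pmax(ks, sqrt(tau) + 1)
  kl <- 1 / (pi * sqrt(tau))
  big_l <- pi * tau * eps < 1
  kl[big_l] <- pmax(
    sqrt(-2 * log(pi * tau[big_l] * eps) / (pi^2 * tau[big_l])),
    kl[big_l]
  )

  small <- ks < kl
  if (any(small)) {
    ts <- tau[small]
    K <- ceiling(max(ks[small]))
    kk <- seq.int(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    acc <- 0
    for (k in kk) {
      acc <- acc + (w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * ts))
    }
    out[small] <- acc / sqrt(2 * pi * ts^3)
  }
  if (any(!small)) {
    tl <- tau[!small]
    K <- ceiling(max(kl[!small]))
    acc <- 0
    for (k in seq_len(K)) {
      acc <- acc + k * exp(-k^2 * pi^2 * tl / 2) * sin(k * pi * w)
    }
    out[!small] <- pi * acc
  }
  out
}

#' Probability of absorbing at the upper (yes/eat) boundary
#'
#' Closed-form absorption probability of the Wiener diffusion. With zero
#' drift it equals the relative starting point `z_rel`; the implementation
#' is continuous through `v = 0` and numerically stable for large `|v|`.
#'
#' @param params a [ddm_params()] object.
#' @param drift drift rate(s) `v`.
#' @return vector of probabilities in `[0, 1]`.
#' @examples
#' upper_choice_probability(ddm_params(z_rel = 1 / 3), drift = 0)
#' @export
upper_choice_probability <- function(params, drift) {
  stopifnot(inherits(params, "ddm_params"))
  a <- params$a
  z <- params$z_rel
  v <- drift
  out <- numeric(length(v))
  x <- 2 * v * a # log-odds scale of the absorption ratio
  tiny <- abs(x) < 1e-9
  out[tiny] <- z # v -> 0 limit
  pos <- !tiny & x > 0
  # stable for large positive drift: both expm1 terms -> -1
  out[pos] <- expm1(-x[pos] * z) / expm1(-x[pos])
  neg <- !tiny & x < 0
  # rescale by exp(x) so exponents stay negative for large negative drift
  out[neg] <- (exp(x[neg] * (1 - z)) - exp(x[neg] * 1)) /
    -expm1(x[neg])
  pmin(pmax(out, 0), 1)
}

#' Probability that the decision has not terminated by time `t`
#'
#' Survival mass of the first-passage time over both boundaries, used for
#' trials censored at the response deadline. Evaluated by Gauss-Legendre
#' quadrature of the two boundary densities on `(0, t)`.
#'
#' @param t decision-time horizon(s), seconds.
#' @param params a [ddm_params()] object.
#' @param drift drift rate(s).
#' @param nodes number of quadrature nodes.
#' @return survival probabilities in `[0, 1]`.
#' @export
wiener_survival <- function(t, params, drift, nodes = 48) {
  n <- max(length(t), length(drift))
  t <- rep_len(t, n)
  v <- rep_len(drift, n)
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tt <- gl$x * t[i]
    f <- wiener_fpt_density(tt, params, v[i], "upper") +
      wiener_fpt_density(tt, params, v[i], "lower")
    out[i] <- 1 - t[i] * sum(gl$w * f)
  }
  pmin(pmax(out, 0), 1)
}
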