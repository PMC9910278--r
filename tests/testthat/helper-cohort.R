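# Shared fixtures: small configurations and rating tables built in code.

small_config <- function(n = 4, seed = 101, ...) {
  cohort_config(n_participants = n, seed = seed, ...)
}

# A deterministic 180-item rating table with ample items in every quadrant
# and none in the neutral zone: 60 HTLH, 40 LTHH, 50 HTHH, 30 LTLH.
grid_ratings <- function() {
  quad <- function(n, t_sign, h_sign, offset) {
    tibble::tibble(
      tr = t_sign * (0.6 + ((seq_len(n) * 7 + offset) %% 45) / 10),
      hr = h_sign * (0.6 + ((seq_len(n) * 11 + offset) %% 45) / 10)
    )
  }
  out <- dplyr::bind_rows(
    quad(60, +1, -1, 0), quad(40, -1, +1, 1),
    quad(50, +1, +1, 2), quad(30, -1, -1, 3)
  )
  out$food_id <- sprintf("f%03d", seq_len(nrow(out)))
  out
}

# Bernoulli-logistic food choices for weight-fit tests: the generating
# model is exactly the one the fitter assumes.
logistic_choices <- function(n, w_taste, w_health, beta0 = 0, seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tr <- runif(n, -5, 5)
  hr <- runif(n, -5, 5)
  eta <- beta0 + w_taste * (tr - mean(tr)) + w_health * (hr - mean(hr))
  y <- rbinom(n, 1, plogis(eta))
  tibble::tibble(tr = tr, hr = hr, choice = ifelse(y == 1, "yes", "no"))
}

# Log-likelihood of the logistic model, used by grid-search oracles.
logistic_loglik <- function(b0, b1, b2, y, x1, x2) {
  eta <- b0 + b1 * x1 + b2 * x2
  sum(y * eta - log1p(exp(eta)))
}
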