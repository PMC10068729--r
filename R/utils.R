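# Internal helpers shared across modules.

GROUPS <- c("control", "ndg", "post_covid")
COMORBIDITIES <- c("hypertension", "diabetes", "cardiovascular", "depression")

# Deterministic 32-bit child seed from a root seed and a string label, so each
# (group, score) stream is independent of the order in which scores are drawn.
child_seed <- function(seed, ...) {
  label <- paste(..., sep = "/")
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483629
  as.integer((h + (seed %% 2147483629) * 48271) %% 2147483629)
}

# Truncated-normal draws by inverse-CDF so they vectorize and stay exact.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  u <- runif(n, p_lo, p_hi)
  # keep qnorm finite when the truncation region sits deep in a tail
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

# Mean and SD of a normal(mu, sigma) truncated to [lo, hi].
trunc_moments <- function(mu, sigma, lo = -Inf, hi = Inf) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  za <- dnorm(a); zb <- dnorm(b)
  pa <- pnorm(a); pb <- pnorm(b)
  z <- pb - pa
  za[!is.finite(a)] <- 0; zb[!is.finite(b)] <- 0
  m <- mu + sigma * (za - zb) / z
  t1 <- if (is.finite(lo)) a * za else 0
  t2 <- if (is.finite(hi)) b * zb else 0
  v <- sigma^2 * (1 + (t1 - t2) / z - ((za - zb) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) whose [lo, hi]-truncation matches a target mean/SD as
# closely as possible. Exact when the target is attainable (CV below the
# truncation family's ceiling); otherwise the mean is matched and the SD is
# the closest attainable.
solve_trunc_params <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (!is.finite(lo) && !is.finite(hi)) return(list(mu = mean, sigma = sd))
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    # keep the truncation region within 4 SD of the parent mean so the
    # retained mass stays numerically workable; at that edge the truncated
    # CV is already at the family's practical ceiling
    a <- if (is.finite(lo)) (lo - mu) / sigma else -Inf
    b <- if (is.finite(hi)) (hi - mu) / sigma else Inf
    if (a > 4 || b < -4) return(1e6 + max(a - 4, -4 - b)^2)
    tm <- trunc_moments(mu, sigma, lo, hi)
    20 * ((tm$mean - mean) / sd)^2 + ((tm$sd - sd) / sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

as_count <- function(x, lo = 0, hi = Inf) as.integer(pmin(pmax(round(x), lo), hi))

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
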