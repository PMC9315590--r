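# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, exhaustive enumeration, and
# permutation resampling.

# Gamma-variate evaluated from its closed form (independent re-statement).
oracle_gv <- function(t, p) {
  ifelse(t <= p$t0, 0,
         p$A * ((t - p$t0) / (p$alpha * p$beta))^p$alpha *
           exp(p$alpha - (t - p$t0) / p$beta))
}

# Analytic landmark times by dense scan of the generating curves:
# arterial/venous maxima, first crossing after the arterial peak, and the
# first time satisfying the plateau rule.
oracle_landmark_times <- function(art, ven, t_end = 60, plateau_frac = 0.5,
                                  slope_tol = 6, dt = 0.001) {
  tt <- seq(0, t_end, by = dt)
  a <- oracle_gv(tt, art); v <- oracle_gv(tt, ven)
  t_a <- tt[which.max(a)]
  t_v <- tt[which.max(v)]
  after <- tt > t_a & tt <= t_v
  cross <- which(after & a < v)
  t_av <- if (length(cross)) tt[cross[1]] else NA_real_
  post <- tt > t_v
  slope <- c(diff(v) / dt, 0)
  ok <- which(post & v <= plateau_frac * max(v) & abs(slope) <= slope_tol)
  t_lv <- if (length(ok)) tt[ok[1]] else t_end
  list(arterial = t_a, arteriovenous = t_av, venous = t_v,
       late_venous = t_lv, late_fallback = length(ok) == 0)
}

# Nearest member of `times` to a target time (ties to the earlier frame).
oracle_nearest_frame <- function(t_star, times) {
  times[which.min(abs(times - t_star))]
}

# Brute-force count of prominent local maxima on a sampled series.
oracle_n_peaks <- function(v, frac = 0.1) {
  n <- length(v); count <- 0L
  for (i in 2:(n - 1)) {
    if (!(v[i] > v[i - 1] && v[i] >= v[i + 1])) next
    if (v[i] == v[i + 1]) {
      j <- i
      while (j < n && v[j + 1] == v[j]) j <- j + 1
      if (!(j < n && v[j + 1] < v[j])) next
    }
    hi_l <- which(v[1:(i - 1)] > v[i])
    base_l <- min(v[(if (length(hi_l)) max(hi_l) else 1):i])
    hi_r <- which(v[i:n] > v[i])
    base_r <- min(v[i:(if (length(hi_r)) i - 1 + min(hi_r) else n)])
    if (v[i] - max(base_l, base_r) >= frac * max(v)) count <- count + 1L
  }
  count
}

# Triple-loop maximum intensity projection.
oracle_mip <- function(vol) {
  d <- dim(vol)
  out <- matrix(-Inf, d[2], d[3])
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    for (z in seq_len(d[1])) out[y, x] <- max(out[y, x], vol[z, y, x])
  }
  out
}

# Pairwise-concordance AUC: (#concordant + 0.5 #ties) / #pairs.
oracle_auc <- function(scores, truth, positive = "good") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  num <- 0
  for (p in pos) for (q in neg) {
    num <- num + (p > q) + 0.5 * (p == q)
  }
  num / (length(pos) * length(neg))
}

# Exact Mann-Whitney two-sided p by enumeration of all group assignments.
oracle_mw_exact_p <- function(a, b) {
  n <- length(a); vals <- c(a, b)
  ustat <- function(idx) {
    x <- vals[idx]; y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- ustat(seq_len(n))
  combs <- utils::combn(length(vals), n)
  mu <- n * length(b) / 2
  us <- apply(combs, 2, ustat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Permutation p value for a difference-of-means two-group test.
oracle_perm_t_p <- function(a, b, n_perm = 20000, seed = 42) {
  obs <- abs(mean(a) - mean(b))
  vals <- c(a, b); n <- length(a)
  withr::with_seed(seed, {
    cnt <- 0
    for (i in seq_len(n_perm)) {
      idx <- sample(length(vals), n)
      if (abs(mean(vals[idx]) - mean(vals[-idx])) >= obs - 1e-12) cnt <- cnt + 1
    }
    cnt / n_perm
  })
}

# Permutation p value for the Kruskal-Wallis H statistic.
oracle_perm_kw_p <- function(groups, n_perm = 5000, seed = 42) {
  vals <- unlist(groups); sizes <- lengths(groups)
  g <- rep(seq_along(groups), sizes)
  hstat <- function(gg) unname(stats::kruskal.test(vals, factor(gg))$statistic)
  obs <- hstat(g)
  withr::with_seed(seed, {
    cnt <- 0
    for (i in seq_len(n_perm)) {
      if (hstat(sample(g)) >= obs - 1e-12) cnt <- cnt + 1
    }
    cnt / n_perm
  })
}

# Small noiseless study shared by landmark/phase tests (built per call so
# tests stay independent; size is the generator's minimum).
tiny_study <- function(label = "good", seed = 1, noise_sd = 0, ...) {
  generate_study(label, size = c(8, 32, 32), seed = seed,
                 noise_sd = noise_sd, ...)
}
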