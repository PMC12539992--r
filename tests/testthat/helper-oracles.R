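# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force concordance: enumerate all (event, non-event) pairs.
oracle_c_statistic <- function(p, y) {
  y <- as.integer(y)
  pe <- p[y == 1L]; pn <- p[y == 0L]
  s <- 0
  for (a in pe) for (b in pn) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pe) * length(pn))
}

# Exhaustive two-sided Fisher p via choose(), probability-mass definition.
oracle_fisher <- function(a, b, cc, d) {
  m <- a + cc; nn <- b + d; k <- a + b; tot <- m + nn
  support <- max(0, k - nn):min(k, m)
  pr <- vapply(support, function(x)
    choose(m, x) * choose(nn, k - x) / choose(tot, k), 0)
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(a, b) {
  xs <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(xs)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  combs <- utils::combn(length(xs), n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Fine-grid likelihood maximisation for a 1-predictor logistic model.
oracle_grid_logistic <- function(x, y) {
  ll <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  best <- c(0, 0)
  width <- 8
  for (stage in 1:6) {
    as <- seq(best[1] - width, best[1] + width, length.out = 41)
    bs <- seq(best[2] - width, best[2] + width, length.out = 41)
    vals <- outer(as, bs, Vectorize(ll))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(as[ij[1]], bs[ij[2]])
    width <- width / 10
  }
  best
}

# Per-patient up/down counting for the categorical NRI.
oracle_nri <- function(p_old, p_new, y, cut = c(0.10, 0.20)) {
  band <- function(p) findInterval(p, cut, left.open = FALSE) # 0,1,2
  bo <- band(p_old); bn <- band(p_new)
  y <- as.logical(y)
  up <- bn > bo; down <- bn < bo
  (sum(up[y]) - sum(down[y])) / sum(y) +
    (sum(down[!y]) - sum(up[!y])) / sum(!y)
}

# Plain data frame stripped of cohort attributes, for content comparisons.
strip_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d)[setdiff(names(attributes(d)),
                        c("names", "row.names", "class"))] <- NULL
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}

# Small deterministic cohort for I/O and table tests.
tiny_cohort <- function(n = 6L) {
  records <- data.frame(
    id = sprintf("T%02d", seq_len(n)),
    age = c(50L, 66L, 75L, 48L, 62L, 80L)[seq_len(n)],
    sex = rep(c("M", "F"), length.out = n),
    weight_kg = seq(50, 70, length.out = n),
    albumin_gdl = c(4.0, 3.2, 3.6, 4.1, 3.4, 3.0)[seq_len(n)],
    cddp_dose_mg = c(80, 120, 160, 90, 110, 155)[seq_len(n)],
    hypertension = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)[seq_len(n)],
    diabetes = rep(FALSE, n),
    mg_supplement = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)[seq_len(n)],
    infusion_volume_l = c(4, 2.5, 4, 4, 2.0, 4)[seq_len(n)],
    infusion_duration_h = c(8, 4, 8, 8, 4.5, 8)[seq_len(n)],
    scr_baseline = c(0.7, 0.8, 0.6, 0.9, 0.7, 1.0)[seq_len(n)],
    scr_followup_max14d = c(0.8, 1.2, 1.5, 0.95, 0.75, 2.2)[seq_len(n)],
    stringsAsFactors = FALSE)
  for (fl in drug_flags()) records[[fl]] <- rep(FALSE, n)
  records$gem <- c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)[seq_len(n)]
  new_cohort(records, provenance = "synthetic")
}
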