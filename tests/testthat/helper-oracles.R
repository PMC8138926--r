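# Independent oracles used by the property tests. These deliberately use
# naive per-threshold / enumeration formulations rather than the package's
# vectorized implementations.

# Brute force over all 256 thresholds: between-class variance
# w0 w1 (mu0 - mu1)^2 computed directly from the histogram; smallest
# maximizer wins.
oracle_otsu <- function(h) {
  lev <- 0:255
  total <- sum(h)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:255) {
    lo <- lev <= t
    n0 <- sum(h[lo]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[lo] * lev[lo]) / n0
    mu1 <- sum(h[!lo] * lev[!lo]) / n1
    v <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (v > best_v + 1e-9) { best_v <- v; best_t <- t }
  }
  best_t
}

oracle_otsu_variance_curve <- function(h) {
  lev <- 0:255
  total <- sum(h)
  vapply(0:255, function(t) {
    lo <- lev <= t
    n0 <- sum(h[lo]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) return(NA_real_)
    mu0 <- sum(h[lo] * lev[lo]) / n0
    mu1 <- sum(h[!lo] * lev[!lo]) / n1
    (n0 / total) * (n1 / total) * (mu0 - mu1)^2
  }, numeric(1))
}

# Full hypergeometric enumeration of all 2x2 tables with the observed
# margins; two-sided p = sum of probabilities <= observed (relative
# tolerance 1e-7). choose() is exact in double for totals <= 40.
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  p_obs <- probs[a_range == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive optimal 1-D 2-partition: split the sorted scores at every
# gap and minimize total within-cluster sum of squares. Returns cluster
# membership (1/2) in input order, 1 = lower cluster.
oracle_best_2partition <- function(scores) {
  ord <- order(scores)
  s <- scores[ord]
  n <- length(s)
  wss <- function(x) if (length(x) <= 1) 0 else sum((x - mean(x))^2)
  best_cut <- 1
  best <- Inf
  for (cut in 1:(n - 1)) {
    v <- wss(s[1:cut]) + wss(s[(cut + 1):n])
    if (v < best - 1e-12) { best <- v; best_cut <- cut }
  }
  membership <- integer(n)
  membership[ord] <- rep(c(1L, 2L), times = c(best_cut, n - best_cut))
  membership
}

# G^2 of a candidate split computed as a deviance difference between the
# saturated children model and the parent model (log-likelihood form),
# rather than the O*log(O/E) sum used by the implementation.
oracle_g2 <- function(response, group) {
  ll <- function(v) {
    n <- table(v)
    n <- n[n > 0]
    sum(n * log(n / sum(n)))
  }
  2 * (ll(response[group]) + ll(response[!group]) - ll(response))
}

# Best valid split at one node by exhaustive search over predictors.
oracle_best_split <- function(data, predictors, response, min_leaf) {
  best_var <- NULL
  best_g2 <- 0
  for (v in predictors) {
    grp <- data[[v]] == levels(data[[v]])[1]
    if (sum(grp) < min_leaf || sum(!grp) < min_leaf) next
    g2 <- oracle_g2(data[[response]], grp)
    if (g2 > best_g2 + 1e-9) { best_g2 <- g2; best_var <- v }
  }
  list(var = best_var, g2 = best_g2)
}

# Random small cohort of binary predictors with a planted dependence of
# the response on one predictor.
random_binary_cohort <- function(n, informative_odds = 3) {
  x1 <- factor(sample(c("A", "B"), n, replace = TRUE))
  x2 <- factor(sample(c("A", "B"), n, replace = TRUE))
  x3 <- factor(sample(c("A", "B"), n, replace = TRUE))
  p <- ifelse(x1 == "A", informative_odds / (informative_odds + 1),
              1 / (informative_odds + 1))
  y <- factor(ifelse(runif(n) < p, "CASE", "CTRL"), levels = c("CASE", "CTRL"))
  data.frame(x1 = x1, x2 = x2, x3 = x3, y = y)
}

# Noiseless single-nucleus test image: one disc of the given gray on a
# bright background, optionally with a central dot of a second gray.
disc_image <- function(size = 41, radius = 12, gray = 160, background = 240,
                       dot_radius = 0, dot_gray = 120) {
  img <- matrix(background, size, size)
  ctr <- (size + 1) / 2
  for (r in 1:size) for (c in 1:size) {
    d2 <- (r - ctr)^2 + (c - ctr)^2
    if (d2 <= radius^2) img[r, c] <- gray
    if (dot_radius > 0 && d2 <= dot_radius^2) img[r, c] <- dot_gray
  }
  matrix(as.integer(img), size, size)
}
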