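# Independent oracles used to verify the package's statistics. Each is a
# deliberately naive implementation (exhaustive enumeration or textbook
# ANOVA decomposition via base model fits), kept separate from the code
# paths it checks.

# AUC by brute force over all positive x negative pairs; ties count 1/2.
oracle_auc <- function(scores, positives) {
  pos <- scores[as.logical(positives)]
  neg <- scores[!as.logical(positives)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Youden cut-off by exhaustive threshold search with explicit counting.
oracle_youden <- function(scores, positives, direction) {
  positives <- as.logical(positives)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    called <- if (direction == "greater_is_positive") scores > t else scores < t
    sens <- sum(called & positives) / sum(positives)
    spec <- sum(!called & !positives) / sum(!positives)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(cutoff = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# Kendall tau-b by explicit concordant/discordant pair counting.
oracle_tau_b <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0; Ta <- 0; Tb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- a[i] - a[j]; db <- b[i] - b[j]
    if (da == 0 && db == 0) next
    if (da == 0) Ta <- Ta + 1
    else if (db == 0) Tb <- Tb + 1
    else if (sign(da) == sign(db)) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + Ta) * (C + D + Tb))
}

# Cohen's kappa straight from the confusion-table definition.
oracle_kappa <- function(a, b) {
  levs <- union(unique(a), unique(b))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in levs) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  (po - pe) / (1 - pe)
}

# ICC(2,1) from mean squares extracted out of a base-R two-way ANOVA fit.
oracle_icc21 <- function(a, b) {
  n <- length(a)
  long <- data.frame(
    y = c(a, b),
    subject = factor(rep(seq_len(n), 2)),
    method = factor(rep(c("a", "b"), each = n))
  )
  ms <- anova(stats::lm(y ~ subject + method, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# One-way repeated-measures ANOVA through aov() with an Error stratum.
oracle_rm_anova <- function(values) {
  n <- nrow(values); k <- ncol(values)
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), k)),
    method = factor(rep(seq_len(k), each = n))
  )
  fit <- summary(stats::aov(y ~ method + Error(subject), data = long))
  tab <- fit[["Error: Within"]][[1]]
  list(f = tab["method", "F value"], p = tab["method", "Pr(>F)"])
}

# Small random cohort-like record set for round-trip property tests.
make_random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    athlete_id = sprintf("R%03d", seq_len(n)),
    decimal_age = round(runif(n, 10, 15), 3),
    stature_cm = round(runif(n, 130, 185), 2),
    body_mass_kg = round(runif(n, 28, 80), 2),
    mother_stature_cm = round(runif(n, 150, 180), 1),
    father_stature_cm = round(runif(n, 160, 195), 1),
    observed_sa_years = round(runif(n, 9, 17), 2),
    adult_height_tw3_cm = round(runif(n, 168, 195), 1),
    pah_tw3 = NA_real_, pah_kr = NA_real_,
    stringsAsFactors = FALSE
  )
}
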