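# Shared fixtures, built in code.

# Random plate with missing readings, for round-trip properties.
randomPlate <- function(nTime = 12, nWell = 4, missFrac = 0.1) {
  tm <- cumsum(runif(nTime, 0.2, 2))
  od <- matrix(round(runif(nTime * nWell, 0, 1.3), 6), nrow = nTime,
               dimnames = list(NULL, paste0("W", seq_len(nWell))))
  od[runif(length(od)) < missFrac] <- NA
  PlateTimeSeries(time = tm, od = od)
}

# Noiseless Zwietering-Gompertz OD well on the 0.5 h x 240 h protocol.
gompertzWell <- function(mu, lam, A = 2, baseline = 0.1, dt = 0.5, dur = 240) {
  tm <- seq(0, dur, by = dt)
  list(time = tm, od = baseline * exp(gompertzLogCurve(A, mu, lam, tm)))
}

# Brute-force one-way ANOVA from the sums-of-squares identity (oracle).
anovaOracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups); N <- length(all)
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  F <- msb / msw
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE),
       mse = msw, dfError = N - k)
}

# All-pairs LSD significance matrix from first principles (oracle).
lsdOracle <- function(groups, alpha = 0.05) {
  av <- anovaOracle(groups)
  k <- length(groups)
  means <- vapply(groups, mean, 0)
  ns <- lengths(groups)
  sig <- matrix(FALSE, k, k)
  if (av$p < alpha) {
    tc <- stats::qt(1 - alpha / 2, av$dfError)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      lsd <- tc * sqrt(av$mse * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd
    }
  }
  sig
}

# Letter display agrees with a significance matrix: share a letter iff
# non-significant.
lettersMatchSig <- function(lett, sig) {
  k <- length(lett)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(strsplit(lett[i], "")[[1]],
                              strsplit(lett[j], "")[[1]])) > 0
    if (share == sig[i, j]) return(FALSE)
  }
  TRUE
}
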