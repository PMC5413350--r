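# Shared fixtures, built in code at test time.

# small complete experiment: catalog + design + truth + counts + hits
makeSmallStudy <- function(seed = 101, nHost = 400, nSymbiont = 250,
                           nContaminant = 30, fracDE = 0.1,
                           dispersion = 0.1,
                           depths = c(host_only = 2e6,
                                      host_plus_symbiont = 2e6,
                                      capsule_symbiont = 6e6,
                                      cultured_symbiont = 6e6),
                           nCultured = 0, assignmentErrorRate = 0,
                           noHitRate = 0, ...) {
  cat <- simulateCatalog(nHost = nHost, nSymbiont = nSymbiont,
                         nContaminant = nContaminant, seed = seed)
  des <- simulateDesign(nCultured = nCultured, depths = depths)
  tr <- simulateTruth(cat, des, fracDE = fracDE, dispersion = dispersion,
                      seed = seed, ...)
  se <- simulateCounts(cat, des, tr)
  hits <- simulateHitTable(cat, assignmentErrorRate = assignmentErrorRate,
                           noHitRate = noHitRate, seed = seed)
  list(catalog = cat, design = des, truth = tr, se = se, hits = hits)
}

# independent brute-force step-up BH (oracle, kept free of p.adjust)
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# NB log-likelihood for a single gene (independent oracle)
nbLogLik <- function(y, mu, phi) {
  if (phi <= 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
}

# planted correlation-onset instance for lower-limit recovery
plantedOnset <- function(n = 5000, f0 = 1, noiseSd = 1, corSd = 0.3,
                         seed = 1) {
  set.seed(seed)
  ref <- sort(exp(stats::runif(n, log(0.01), log(1000))))
  names(ref) <- sprintf("g%05d", seq_len(n))
  comp <- ifelse(ref < f0, exp(stats::rnorm(n, 0, noiseSd)),
                 ref * exp(stats::rnorm(n, 0, corSd)))
  list(ref = ref, comp = comp, f0 = f0)
}
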