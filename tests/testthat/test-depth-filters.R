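test_that("FPKM matches its definition and an elementwise oracle", {
  m <- matrix(c(10, 0), 1, 2, dimnames = list("g1", c("a", "b")))
  got <- fpkm(m, lengthBp = 1000, librarySize = c(1e6, 1e6))
  expect_equal(unname(got["g1", ]), c(10, 0))
  expect_error(fpkm(m, lengthBp = 1000, librarySize = c(0, 1e6)),
               "zero library size")
  set.seed(41)
  x <- matrix(rpois(200, 20), 50, 4)
  rownames(x) <- paste0("g", 1:50)
  len <- sample(200:3000, 50)
  lib <- colSums(x)
  got <- fpkm(x, len, lib)
  for (i in seq_len(50)) for (j in 1:4)
    expect_equal(got[i, j], x[i, j] / (len[i] / 1e3) / (lib[j] / 1e6))
})

test_that("window curve counts, constants and medians match a brute-force oracle", {
  v <- setNames(seq_len(150), sprintf("g%03d", 1:150))
  cv <- windowCurve(v, rep(7, 150), window = 100, step = 1)
  expect_equal(nrow(cv), 51)
  expect_true(all(cv$companion == 7))
  expect_error(windowCurve(v, v, window = 1), "window")
  expect_error(windowCurve(v[1:50], v[1:50], window = 100), "exceeds")
  set.seed(43)
  ref <- setNames(rexp(300), sprintf("g%03d", 1:300))
  comp <- rexp(300)
  cv <- windowCurve(ref, comp, window = 50, step = 1)
  # independent re-sort-and-median at every position
  o <- order(ref, names(ref))
  for (s in c(1, 2, 100, 251)) {
    idx <- o[s:(s + 49)]
    expect_equal(cv$refMedian[s], median(ref[idx]))
    expect_equal(cv$companion[s], median(comp[idx]))
  }
  expect_true(all(diff(cv$refMedian) >= 0))
  # proportion mode arithmetic: 97/100 detected passes a 0.95 target
  det <- c(rep(TRUE, 97), rep(FALSE, 3))
  cvp <- windowCurve(setNames(1:100, sprintf("h%03d", 1:100)), det,
                     window = 100, statistic = "proportion")
  expect_equal(cvp$companion, 0.97)
})

test_that("lower-limit onset detection handles global correlation, noise, and recovery", {
  v <- setNames(exp(seq(0, 5, length.out = 400)),
                sprintf("g%03d", 1:400))
  cv <- windowCurve(v, v * exp(0.01 * seq_along(v)), window = 100)
  ll <- detectLowerLimit(cv, runLength = 20)
  expect_equal(as.numeric(ll), cv$refMedian[1])  # correlated throughout
  expect_false(attr(ll, "failed"))
  expect_error(detectLowerLimit(cv[1:10, ], runLength = 20), "exceeds")
  # pure noise companion: no onset exists
  set.seed(2)
  ref <- sort(exp(runif(3000, 0, 7)))
  names(ref) <- sprintf("g%04d", 1:3000)
  cvn <- windowCurve(ref, exp(rnorm(3000)), window = 100)
  lln <- detectLowerLimit(cvn, runLength = 20)
  expect_true(is.infinite(as.numeric(lln)))
  expect_true(attr(lln, "failed"))
  # planted floor recovered within a factor of 2 (median over seeds)
  rec <- vapply(1:5, function(sd) {
    p <- plantedOnset(n = 5000, f0 = 1, seed = sd)
    as.numeric(detectLowerLimit(windowCurve(p$ref, p$comp, 100), 20))
  }, 0)
  expect_gte(median(rec), 0.5)
  expect_lte(median(rec), 2)
})

test_that("absence threshold separates dropout from biology and filter obeys its boundary", {
  expect_equal(as.numeric(detectAbsenceThreshold(
    setNames(1:200, sprintf("g%03d", 1:200)), rep(TRUE, 200))), 0)
  set.seed(47)
  n <- 4000; m <- 20
  ref <- exp(runif(n, log(0.05), log(2000)))
  names(ref) <- sprintf("g%04d", 1:n)
  det <- runif(n) < plogis(2 * (log(ref) - log(m)))
  thr <- detectAbsenceThreshold(ref, det, window = 100,
                                detectionTarget = 0.95)
  expect_gt(as.numeric(thr), m)   # threshold sits above the midpoint
  kept <- applyAbsenceFilter(names(ref), ref, det, as.numeric(thr))
  # after filtering, detection no longer depends on expression level
  keptIdx <- names(ref) %in% kept
  fit <- suppressWarnings(glm(det[keptIdx] ~ log(ref[keptIdx]),
                              family = binomial))
  sl <- summary(fit)$coefficients[2, ]
  expect_lt(abs(sl[["Estimate"]]) - 3 * sl[["Std. Error"]], 0)
  # boundary: undetected gene exactly at threshold is retained
  expect_identical(applyAbsenceFilter("g", 5, FALSE, 5), "g")
  expect_identical(applyAbsenceFilter("g", 4.999, FALSE, 5), character(0))
  expect_identical(applyAbsenceFilter("g", 0.1, TRUE, 5), "g")
  # hand enumeration on 10 genes
  ids <- paste0("t", 1:10)
  fr <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  dt <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_setequal(applyAbsenceFilter(ids, fr, dt, 6.5),
                  c("t1", "t3", "t6", "t8", "t7", "t9", "t10"))
})

test_that("thresholds scale with the data and filters only ever remove", {
  p <- plantedOnset(n = 3000, f0 = 1, seed = 9)
  cv1 <- windowCurve(p$ref, p$comp, 100)
  cv2 <- windowCurve(p$ref * 37, p$comp * 37, 100)
  l1 <- as.numeric(detectLowerLimit(cv1, 20))
  l2 <- as.numeric(detectLowerLimit(cv2, 20))
  expect_equal(l2, 37 * l1, tolerance = 1e-12)
  set.seed(51)
  ref <- exp(runif(2000, log(0.05), log(500)))
  names(ref) <- sprintf("g%04d", 1:2000)
  det <- runif(2000) < plogis(1.5 * (log(ref) - log(5)))
  t1 <- as.numeric(detectAbsenceThreshold(ref, det, 100, 0.95))
  t2 <- as.numeric(detectAbsenceThreshold(ref * 10, det, 100, 0.95))
  expect_equal(t2, 10 * t1, tolerance = 1e-12)
  # raising the detection target never lowers the threshold
  t90 <- as.numeric(detectAbsenceThreshold(ref, det, 100, 0.90))
  expect_gte(t1, t90)
  # filtering is idempotent and only removes
  k1 <- applyAbsenceFilter(names(ref), ref, det, t1)
  expect_true(all(k1 %in% names(ref)))
  k2 <- applyAbsenceFilter(k1, ref[k1], det[names(ref) %in% k1], t1)
  expect_identical(k2, k1)
})

test_that("estimateThresholds assembles a coherent ThresholdSet from an experiment", {
  st <- makeSmallStudy(seed = 53, nHost = 700, nSymbiont = 400,
                       nContaminant = 0)
  asg <- classifyByBestHit(st$hits, transcriptIds = rownames(st$se))
  ths <- estimateThresholds(st$se,
                            asg$transcript_id[asg$label == "host"],
                            asg$transcript_id[asg$label == "symbiont"],
                            window = 100, runLength = 20)
  ll <- lowerLimits(ths)
  expect_true(all(c("host_only", "host_plus_symbiont",
                    "capsule_symbiont", "intracellular_symbiont") %in%
                    names(ll)))
  expect_true(all(is.finite(ll[c("host_only", "capsule_symbiont")])))
  expect_true(all(ll >= 0, na.rm = TRUE))
  expect_false(is.na(absenceThreshold(ths)))
  expect_s4_class(ths, "ThresholdSet")
})
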