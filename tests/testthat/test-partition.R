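hit <- function(q, grp, score, len = 200, pid = 80) {
  data.frame(qseqid = q, sseqid = paste0(grp, "|", q, "_", round(score)),
             pident = pid, length = len, mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = 1e-30, bitscore = score, taxon_group = grp)
}

test_that("best-hit voting follows taxon groups, discards fungal best hits, flags ties", {
  h <- rbind(hit("t1", "plant_or_green_alga", 200),
             hit("t2", "fungal", 300), hit("t2", "plant_or_green_alga", 250),
             hit("t3", "animal_or_vertebrate", 180),
             hit("t3", "plant_or_green_alga", 180),
             hit("t4", "fungal", 150), hit("t4", "mite", 150))
  a <- classifyByBestHit(h, transcriptIds = c("t1", "t2", "t3", "t4", "t5"))
  lab <- setNames(a$label, a$transcript_id)
  expect_identical(lab[["t1"]], "symbiont")
  expect_identical(lab[["t2"]], "contaminant")   # fungal outranks algal
  expect_identical(lab[["t3"]], "ambiguous")     # exact conflicting tie
  expect_identical(lab[["t4"]], "contaminant")   # tie within one label
  expect_identical(lab[["t5"]], "unknown")       # no hits
  bad <- hit("t6", "fungal", 100); bad$length <- -5L
  expect_error(classifyByBestHit(bad), "t6")
})

test_that("partition is complete, idempotent and matches truth on noiseless hits", {
  st <- makeSmallStudy(seed = 23, noHitRate = 0)
  a <- classifyByBestHit(st$hits, transcriptIds = rownames(st$se))
  expect_setequal(a$transcript_id, rownames(st$se))
  expect_equal(nrow(a), nrow(st$se))
  tab <- table(factor(a$label, c("host", "symbiont", "contaminant",
                                 "unknown", "ambiguous")))
  expect_equal(sum(tab), nrow(st$se))
  # noiseless: labels equal simulated organisms (contaminants collapsed)
  truthLab <- c(host = "host", symbiont = "symbiont",
                contaminant_fungus = "contaminant",
                contaminant_mite = "contaminant")[
                  organism(st$se)[match(a$transcript_id, rownames(st$se))]]
  expect_identical(unname(setNames(a$label, a$transcript_id)),
                   unname(truthLab))
  # idempotence: reclassifying the same hits changes nothing
  expect_identical(classifyByBestHit(st$hits,
                                     transcriptIds = rownames(st$se)), a)
})

test_that("expression-pattern rescue recovers clean patterns and scores well against truth", {
  st <- makeSmallStudy(seed = 29, noHitRate = 0.3)
  se <- st$se
  ths <- new("ThresholdSet",
             lowerLimits = c(host_only = 1, capsule_symbiont = 1),
             absenceThreshold = NA_real_, detectionTarget = 0.95,
             window = 100, curves = list())
  # hand-built clean patterns through a tiny synthetic matrix
  cnt <- counts(se)
  symClean <- rownames(se)[organism(se) == "symbiont"][1]
  a <- rescueUnknowns(symClean, se, ths)
  # clean symbiont: high in capsule, zero in host_only by construction
  fk <- fpkm(se)
  cls <- sampleClass(se)
  if (all(fk[symClean, cls == "capsule_symbiont"] > 1) &&
      all(fk[symClean, cls == "host_only"] < 1))
    expect_identical(a$label, "symbiont")
  # rescue scored against simulated organisms
  asg <- classifyByBestHit(st$hits, transcriptIds = rownames(se))
  unk <- asg$transcript_id[asg$label == "unknown"]
  resc <- rescueUnknowns(unk, se, ths)
  org <- organism(se)[match(resc$transcript_id, rownames(se))]
  confident <- resc$label != "unknown" &
    org %in% c("host", "symbiont")
  expect_gte(mean(resc$label[confident] == org[confident]), 0.95)
  # a rescued-symbiont call requires presence in capsule + absence in host
  noCaps <- se[, sampleClass(se) != "capsule_symbiont"]
  expect_error(rescueUnknowns(unk, noCaps, ths), "capsule_symbiont")
})

test_that("mirror-image expression patterns assign host and symbiont", {
  # 2 genes x 7 samples: g1 symbiont-patterned, g2 host-patterned
  cnt <- matrix(0L, 3, 7)
  rownames(cnt) <- c("g1", "g2", "g3")
  colnames(cnt) <- c(paste0("ho", 1:2), paste0("hp", 1:2),
                     paste0("cap", 1:3))
  cnt["g1", 5:7] <- 5000L
  cnt["g2", 1:2] <- 5000L
  cnt["g3", ] <- 3L   # weak everywhere: stays unknown
  des <- DataFrame(
    sample_id = colnames(cnt),
    sample_class = c("host_only", "host_only", "host_plus_symbiont",
                     "host_plus_symbiont", rep("capsule_symbiont", 3)),
    pair_id = NA_character_, library_prep = "low_input",
    target_depth = 1e4, row.names = colnames(cnt))
  des$pair_id <- c("E1", "E2", "E1", "E2", NA, NA, NA)
  se <- new("DualSeqExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = DataFrame(organism = rep("host", 3), length_bp = 1000L,
                        gc_fraction = 0.5, row.names = rownames(cnt)),
    colData = des))
  ths <- new("ThresholdSet",
             lowerLimits = c(host_only = 10, capsule_symbiont = 10),
             absenceThreshold = NA_real_, detectionTarget = 0.95,
             window = 100, curves = list())
  r <- rescueUnknowns(c("g1", "g2", "g3"), se, ths)
  expect_identical(r$label, c("symbiont", "host", "unknown"))
})

test_that("symbiont gene set matches a clause-by-clause hand oracle on a toy matrix", {
  set.seed(31)
  G <- 20
  ids <- sprintf("s%02d", 1:G)
  cls <- c(rep("host_only", 2), rep("host_plus_symbiont", 2),
           rep("capsule_symbiont", 3))
  cnt <- matrix(rpois(G * 7, 30), G, 7,
                dimnames = list(ids, paste0("x", 1:7)))
  # craft edge cases
  cnt[1, 5:7] <- c(5, 5, 5); cnt[1, 1:4] <- 0          # clean include
  cnt[2, 5:7] <- c(5, 5, 0); cnt[2, 3:4] <- 0          # fails both presence
  cnt[3, 1:2] <- 900                                    # high in host_only
  cnt[4, 5:7] <- 1                                      # marginal FPKM
  des <- DataFrame(sample_id = paste0("x", 1:7), sample_class = cls,
                   pair_id = c("E1", "E2", "E1", "E2", NA, NA, NA),
                   library_prep = "low_input", target_depth = 1e4,
                   row.names = paste0("x", 1:7))
  se <- new("DualSeqExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = DataFrame(organism = rep("symbiont", G),
                        length_bp = rep(1000L, G),
                        gc_fraction = rep(0.6, G), row.names = ids),
    colData = des))
  asg <- data.frame(transcript_id = ids, label = "symbiont",
                    evidence = "x")
  ll <- c(host_only = 5, capsule_symbiont = 2,
          intracellular_symbiont = 2)
  ths <- new("ThresholdSet", lowerLimits = ll,
             absenceThreshold = NA_real_, detectionTarget = 0.95,
             window = 100, curves = list())
  got <- buildSymbiontGeneSet(se, asg, ths)
  # independent clause-by-clause enumeration
  fk <- fpkm(counts(se), lengthBp = rep(1000, G))
  caps <- which(cls == "capsule_symbiont")
  hps <- which(cls == "host_plus_symbiont")
  ho <- which(cls == "host_only")
  keep <- vapply(seq_len(G), function(g) {
    c1 <- all(cnt[g, caps] >= 1) && all(fk[g, caps] > ll[["capsule_symbiont"]])
    c2 <- all(cnt[g, hps] >= 1) &&
      all(fk[g, hps] > ll[["intracellular_symbiont"]])
    c3 <- all(fk[g, ho] < ll[["host_only"]])
    (c1 || c2) && c3
  }, TRUE)
  expect_setequal(got, ids[keep])
  expect_true("s01" %in% got)
  expect_false("s02" %in% got && !keep[2])
  expect_false("s03" %in% got)
  expect_error(buildSymbiontGeneSet(se, asg[0, ], ths), "empty")
})
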